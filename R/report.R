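#' Run the full surveillance-scenario comparison on a cohort
#'
#' Orchestrates the whole pipeline for the requested scenarios: culture
#' filtering ([apply_scenario()]), new-finding extraction and relevance
#' classification ([extract_new_findings()]), intensification-trigger
#' detection ([detect_triggers()]), missed/delayed detection analysis
#' against scenario A, cost imputation and summaries
#' ([impute_missing_costs()], [cost_summary()]), and admission-cluster
#' bootstrap CIs for every rate ([bootstrap_rate()]). A single master seed
#' drives the scenario-B weekday assignment and all bootstrap streams
#' through derived substreams, so one seed reproduces an entire run.
#'
#' @param cohort an [sdd_cohort()].
#' @param scenarios character subset of \code{c("A", "B", "C")}; scenario A
#'   is always included as the reference.
#' @param seed master seed.
#' @param n_boot bootstrap iterations (default 1,000).
#' @param rules trigger rule table, see [default_trigger_rules()].
#' @param species_classes species-to-class map, see [species_class_table()].
#' @return list of class \code{sdd_study} with elements \code{scenarios}
#'   (per-scenario list: \code{cultures}, \code{findings}, \code{triggers},
#'   \code{ppm_rate}, \code{relevant_rate}, per-level relevant rates,
#'   \code{trigger_rate}, \code{delay}, \code{trigger_concordance},
#'   \code{costs}), \code{total_icu_days}, \code{seed}, \code{n_boot}.
#' @export
run_surveillance_study <- function(cohort, scenarios = c("A", "B", "C"),
                                   seed = 1L, n_boot = 1000L,
                                   rules = default_trigger_rules(),
                                   species_classes = species_class_table()) {
  scenarios <- union("A", scenarios)
  scenarios <- scenarios[order(match(scenarios, c("A", "B", "C")))]
  adm <- cohort$admissions
  total_days <- sum(adm$icu_days)
  out <- list()

  per_adm_counts <- function(ids) {
    cnt <- table(factor(ids, levels = adm$admission_id))
    as.numeric(cnt)
  }
  boot_of <- function(ids, purpose_seed) {
    bootstrap_rate(per_adm_counts(ids), adm$icu_days, n_boot = n_boot,
                   seed = purpose_seed)
  }

  for (sc in scenarios) {
    cultures <- apply_scenario(cohort, sc, seed = seed)
    findings <- extract_new_findings(cultures, cohort$isolates)
    triggers <- detect_triggers(cultures, cohort$isolates, adm,
                                rules = rules,
                                species_classes = species_classes)
    relevant <- findings[findings$relevance != "none", , drop = FALSE]
    sseed <- hash31(paste0("boot:", sc), seed = seed) %% 1000000000L
    res <- list(
      label = sc,
      cultures = cultures,
      findings = findings,
      triggers = triggers,
      ppm_rate = boot_of(findings$admission_id, sseed),
      relevant_rate = boot_of(relevant$admission_id, sseed + 1L),
      direct_rate = boot_of(
        relevant$admission_id[relevant$relevance == "direct"], sseed + 2L),
      high_rate = boot_of(
        relevant$admission_id[relevant$relevance == "high"], sseed + 3L),
      infection_rate = boot_of(
        relevant$admission_id[relevant$relevance == "infection_related"],
        sseed + 4L),
      trigger_rate = boot_of(triggers$admission_id, sseed + 5L))
    out[[sc]] <- res
  }

  ref <- out[["A"]]
  for (sc in setdiff(scenarios, "A")) {
    out[[sc]]$delay <- delay_analysis(
      ref$findings[ref$findings$relevance != "none", , drop = FALSE],
      out[[sc]]$findings[out[[sc]]$findings$relevance != "none", ,
                         drop = FALSE])
    if (nrow(ref$triggers))
      out[[sc]]$trigger_concordance <-
        trigger_concordance(ref$triggers, out[[sc]]$triggers)
  }

  # costing: SDD cultures only, imputed once per scenario subset
  for (sc in scenarios) {
    sdd_cul <- out[[sc]]$cultures[
      out[[sc]]$cultures$category != "clinical", , drop = FALSE]
    sdd_cul <- impute_missing_costs(sdd_cul, cohort$isolates)
    f <- out[[sc]]$findings
    sdd_relevant <- sum(f$relevance != "none" & f$source_category == "sdd")
    out[[sc]]$costs <- cost_summary(sdd_cul, adm, sdd_relevant, total_days)
  }

  structure(list(scenarios = out, total_icu_days = total_days, seed = seed,
                 n_boot = n_boot),
            class = "sdd_study")
}

#' Render the per-scenario comparison table
#'
#' Collapses a study into one row per scenario with the reported quantities:
#' culture counts, PPM and relevant-PPM detection rates per 1,000 ICU days
#' with 95\% CIs, the relevance-level split, relative yield versus scenario
#' A, trigger rates and capture, delayed-detection summaries, and the cost
#' block. Integer rounding (half away from zero) happens here and only
#' here; every number is reproducible from the stage outputs.
#'
#' @param study result of [run_surveillance_study()].
#' @return data.frame, one row per scenario, deterministic column order.
#' @export
render_report <- function(study) {
  rows <- lapply(study$scenarios, function(s) {
    rr <- function(x) round_half_up(x)
    ref <- study$scenarios[["A"]]
    data.frame(
      scenario = s$label,
      n_cultures = nrow(s$cultures),
      n_sdd_cultures = sum(s$cultures$category != "clinical"),
      ppm_rate = rr(s$ppm_rate$point),
      ppm_ci = sprintf("%d-%d", rr(s$ppm_rate$ci_low),
                       rr(s$ppm_rate$ci_high)),
      relevant_rate = rr(s$relevant_rate$point),
      relevant_ci = sprintf("%d-%d", rr(s$relevant_rate$ci_low),
                            rr(s$relevant_rate$ci_high)),
      direct_rate = rr(s$direct_rate$point),
      high_rate = rr(s$high_rate$point),
      infection_rate = rr(s$infection_rate$point),
      relative_yield = relative_yield(s$relevant_rate$point,
                                      ref$relevant_rate$point),
      trigger_rate = rr(s$trigger_rate$point),
      trigger_capture = if (ref$trigger_rate$n_events > 0)
        trigger_capture_percent(s$trigger_rate$n_events,
                                ref$trigger_rate$n_events) else NA_real_,
      n_missed = if (!is.null(s$delay)) s$delay$n_missed else 0L,
      n_delayed = if (!is.null(s$delay)) s$delay$n_delayed else 0L,
      median_delay = if (!is.null(s$delay)) s$delay$median_delay else NA_real_,
      total_cost = rr(s$costs$total_cost),
      cost_per_1000_days = rr(s$costs$cost_per_1000_days),
      cost_reduction = cost_reduction_percent(s$costs$total_cost,
                                              ref$costs$total_cost),
      cost_per_relevant_finding = rr(s$costs$cost_per_relevant_finding),
      stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' @export
print.sdd_study <- function(x, ...) {
  cat(sprintf("SDD surveillance scenario study: %d scenario(s), %.0f ICU days, seed %d\n",
              length(x$scenarios), x$total_icu_days, x$seed))
  print(render_report(x))
  invisible(x)
}

#' Write the study outputs as CSV files
#'
#' Writes the per-scenario findings, delay detail, trigger events and the
#' scenario comparison table (plus the scenario-B weekday assignment for
#' audit) under \code{dir}. Rerunning with identical inputs and seeds
#' produces byte-identical files.
#'
#' @param study result of [run_surveillance_study()].
#' @param dir output directory (created if absent).
#' @return invisibly, the written file paths.
#' @export
write_report <- function(study, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- character()
  wr <- function(df, name) {
    p <- file.path(dir, name)
    utils::write.csv(df, p, row.names = FALSE)
    paths <<- c(paths, p)
  }
  wr(render_report(study), "scenario_comparison.csv")
  for (sc in names(study$scenarios)) {
    s <- study$scenarios[[sc]]
    wr(s$findings, sprintf("findings_%s.csv", sc))
    wr(s$triggers, sprintf("triggers_%s.csv", sc))
    if (!is.null(s$delay)) wr(s$delay$detail, sprintf("delay_%s.csv", sc))
    aud <- attr(s$cultures, "dropped_weekday")
    if (!is.null(aud)) wr(aud, "scenario_b_assignments.csv")
  }
  invisible(paths)
}
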