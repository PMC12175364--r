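#' Total cost of a culture
#'
#' The cost per culture is the exact sum of its four components: order fee,
#' culture plate expenses, and laboratory costs for species identification
#' and susceptibility testing.
#'
#' @param order_fee,plate_cost,id_cost,susceptibility_cost numeric vectors
#'   in euro; no component may be missing (impute first) or negative.
#' @return numeric vector of totals.
#' @export
#' @examples
#' culture_total_cost(30, 24, 0, 0)    # 54
#' culture_total_cost(30, 24, 10, 70)  # 134
culture_total_cost <- function(order_fee, plate_cost, id_cost,
                               susceptibility_cost) {
  comps <- cbind(order_fee, plate_cost, id_cost, susceptibility_cost)
  if (anyNA(comps))
    stop("missing cost component; run impute_missing_costs first",
         call. = FALSE)
  if (any(comps < 0))
    stop("negative cost component", call. = FALSE)
  rowSums(comps)
}

#' Impute missing SDD culture costs by stratum median
#'
#' A culture whose cost record is missing receives the median total cost of
#' the non-missing SDD cultures in its positivity stratum (positive = at
#' least one isolate, negative = none), pooled across categories and sites.
#' Non-missing records are untouched; the imputed value lands in a derived
#' \code{cost_total} column and is flagged, leaving the component columns as
#' loaded.
#'
#' @param cultures SDD culture table (rows with \code{category} in
#'   \code{sdd_admission}/\code{sdd_surveillance}).
#' @param isolates isolate table, used to determine positivity.
#' @return \code{cultures} with added columns \code{cost_total} (complete)
#'   and \code{cost_imputed} (logical).
#' @export
impute_missing_costs <- function(cultures, isolates) {
  cul <- cultures
  comp <- as.matrix(cul[COST_COMPONENTS])
  missing <- rowSums(is.na(comp)) == ncol(comp)
  if (any(rowSums(is.na(comp)) %in% seq_len(ncol(comp) - 1)))
    stop("partially missing cost record; components must be all present or all missing",
         call. = FALSE)
  total <- rep(NA_real_, nrow(cul))
  total[!missing] <- rowSums(comp[!missing, , drop = FALSE])
  positive <- cul$culture_id %in% isolates$culture_id
  cul$cost_total <- total
  cul$cost_imputed <- missing
  for (pos in c(TRUE, FALSE)) {
    need <- missing & positive == pos
    if (!any(need)) next
    donors <- total[!missing & positive == pos]
    if (!length(donors))
      stop(sprintf(
        "cannot impute %s-culture costs: no complete donor records in that stratum",
        if (pos) "positive" else "negative"), call. = FALSE)
    cul$cost_total[need] <- stats::median(donors)
  }
  cul
}

#' Per-scenario SDD culture cost summary
#'
#' Aggregates imputed per-culture totals into the quantities of the costing
#' tables: total expenditure, cost per 1,000 ICU days, per-admission and
#' per-culture medians (IQR) and means (SD), and cost per clinically
#' relevant finding ("number needed to culture"). Only SDD cultures enter
#' (clinical cultures are excluded from costing); per-admission statistics
#' cover every admission passed in, including those left without SDD
#' cultures by the scenario filter. Euro amounts are returned unrounded;
#' round at reporting.
#'
#' @param cultures SDD cultures of the scenario, after
#'   [impute_missing_costs()] (must carry \code{cost_total}).
#' @param admissions admission table of the costed (cost-complete) cohort.
#' @param n_relevant_findings count of clinically relevant findings detected
#'   in these SDD cultures.
#' @param total_icu_days cohort denominator in days.
#' @return list of class \code{sdd_cost_summary}: \code{n_admissions},
#'   \code{n_cultures}, \code{total_cost}, \code{cost_per_1000_days},
#'   \code{median_per_admission}, \code{iqr_per_admission},
#'   \code{mean_per_admission}, \code{sd_per_admission},
#'   \code{median_per_culture}, \code{iqr_per_culture},
#'   \code{mean_per_culture}, \code{sd_per_culture},
#'   \code{cost_per_relevant_finding} (NA when the count is zero).
#' @export
cost_summary <- function(cultures, admissions, n_relevant_findings,
                         total_icu_days) {
  if (total_icu_days <= 0)
    stop("total_icu_days must be positive", call. = FALSE)
  if (!"cost_total" %in% names(cultures) || anyNA(cultures$cost_total))
    stop("cultures must carry a complete cost_total; run impute_missing_costs",
         call. = FALSE)
  per_adm <- rep(0, nrow(admissions))
  names(per_adm) <- admissions$admission_id
  agg <- tapply(cultures$cost_total, cultures$admission_id, sum)
  per_adm[names(agg)] <- agg
  total <- sum(cultures$cost_total)
  structure(list(
    n_admissions = nrow(admissions),
    n_cultures = nrow(cultures),
    total_cost = total,
    cost_per_1000_days = total / total_icu_days * 1000,
    median_per_admission = stats::median(per_adm),
    iqr_per_admission = quant8(per_adm, c(0.25, 0.75)),
    mean_per_admission = mean(per_adm),
    sd_per_admission = stats::sd(per_adm),
    median_per_culture = stats::median(cultures$cost_total),
    iqr_per_culture = quant8(cultures$cost_total, c(0.25, 0.75)),
    mean_per_culture = mean(cultures$cost_total),
    sd_per_culture = stats::sd(cultures$cost_total),
    cost_per_relevant_finding =
      if (n_relevant_findings > 0) total / n_relevant_findings else NA_real_
  ), class = "sdd_cost_summary")
}

#' @export
print.sdd_cost_summary <- function(x, ...) {
  cat(sprintf("SDD culture costs: %d admissions, %d cultures\n",
              x$n_admissions, x$n_cultures))
  cat(sprintf("  total EUR %s (EUR %s per 1,000 ICU days)\n",
              format(round_half_up(x$total_cost), big.mark = ","),
              format(round_half_up(x$cost_per_1000_days), big.mark = ",")))
  cat(sprintf("  per admission: median %s (IQR %s-%s), mean %s (SD %s)\n",
              round_half_up(x$median_per_admission),
              round_half_up(x$iqr_per_admission[1]),
              round_half_up(x$iqr_per_admission[2]),
              round_half_up(x$mean_per_admission),
              round_half_up(x$sd_per_admission)))
  cat(sprintf("  per culture:   median %s (IQR %s-%s), mean %s (SD %s)\n",
              round_half_up(x$median_per_culture),
              round_half_up(x$iqr_per_culture[1]),
              round_half_up(x$iqr_per_culture[2]),
              round_half_up(x$mean_per_culture),
              round_half_up(x$sd_per_culture)))
  if (!is.na(x$cost_per_relevant_finding))
    cat(sprintf("  per clinically relevant finding: EUR %s\n",
                format(round_half_up(x$cost_per_relevant_finding),
                       big.mark = ",")))
  invisible(x)
}

#' Cost reduction of a reduced scenario, in percent
#'
#' @param cost_scenario,cost_reference total (or per-1,000-day) costs.
#' @return integer percent reduction, rounded half away from zero.
#' @export
#' @examples
#' cost_reduction_percent(55208, 78774)  # 30
cost_reduction_percent <- function(cost_scenario, cost_reference) {
  if (any(cost_reference <= 0))
    stop("reference cost must be positive", call. = FALSE)
  round_half_up(100 * (1 - cost_scenario / cost_reference))
}
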