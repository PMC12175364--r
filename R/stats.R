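#' Admission-cluster percentile bootstrap for per-1,000-day rates
#'
#' All rates are cohort ratios (total events over total ICU days), and the
#' ICU admission is the independent unit, so resampling keeps each
#' admission's events and days together: replicates draw admissions with
#' replacement and recompute \eqn{\sum events / \sum days \times 1000}. The
#' 95\% CI is the 2.5th/97.5th percentile of the replicate distribution
#' (percentile bootstrap); the point estimate comes from the unresampled
#' data. A replicate whose resampled denominator is zero is redrawn.
#'
#' @param events per-admission event counts.
#' @param icu_days per-admission ICU days (same order as \code{events}).
#' @param n_boot number of bootstrap iterations (default 1,000).
#' @param seed integer seed; results are deterministic given the seed.
#' @param conf confidence level (default 0.95).
#' @return list of class \code{sdd_rate_estimate}: \code{point},
#'   \code{ci_low}, \code{ci_high} (per 1,000 ICU days), \code{n_events},
#'   \code{denom_days}, \code{n_boot}, \code{seed}.
#' @export
bootstrap_rate <- function(events, icu_days, n_boot = 1000L, seed = 1L,
                           conf = 0.95) {
  n <- length(events)
  if (!n) stop("no admissions to resample", call. = FALSE)
  if (length(icu_days) != n)
    stop("events and icu_days must have equal length", call. = FALSE)
  if (sum(icu_days) <= 0) stop("total ICU days must be positive",
                               call. = FALSE)
  events <- as.numeric(events)
  icu_days <- as.numeric(icu_days)
  point <- sum(events) / sum(icu_days) * 1000

  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)

  idx <- matrix(sample.int(n, n * n_boot, replace = TRUE), nrow = n_boot)
  ev <- matrix(events[idx], nrow = n_boot)
  dy <- matrix(icu_days[idx], nrow = n_boot)
  denom <- rowSums(dy)
  for (r in which(denom == 0)) {  # degenerate replicate: redraw
    repeat {
      i <- sample.int(n, n, replace = TRUE)
      if (sum(icu_days[i]) > 0) {
        ev[r, ] <- events[i]; dy[r, ] <- icu_days[i]
        denom[r] <- sum(icu_days[i])
        break
      }
    }
  }
  rates <- rowSums(ev) / denom * 1000
  alpha <- (1 - conf) / 2
  ci <- quant8(rates, c(alpha, 1 - alpha))
  structure(list(point = point, ci_low = ci[1], ci_high = ci[2],
                 n_events = sum(events), denom_days = sum(icu_days),
                 n_boot = n_boot, seed = seed),
            class = "sdd_rate_estimate")
}

#' @export
print.sdd_rate_estimate <- function(x, ...) {
  cat(sprintf("%.1f (95%% CI %.1f-%.1f) per 1,000 ICU days  [%d events / %.0f days, %d bootstrap iterations]\n",
              x$point, x$ci_low, x$ci_high, x$n_events, x$denom_days,
              x$n_boot))
  invisible(x)
}

SUBGROUP_KEYS <- c("admission_type", "immunocompromised", "covid",
                   "gi_surgery", "admission_cultures_positive",
                   "first_surveillance_set_positive")

#' Restrict a cohort to a subgroup
#'
#' Stratifiers mirror the cost-effectiveness subgroup analyses: admission
#' type, immunocompromised status, COVID-19 status, gastro-intestinal
#' surgery, positive vs negative admission cultures, and positive vs
#' negative first surveillance culture set. A surveillance set is the
#' cultures of one collection date; the first-surveillance stratifier is
#' defined only for admissions with at least two surveillance culture sets.
#' "Positive" means at least one isolate among the qualifying cultures.
#'
#' @param cohort an [sdd_cohort()].
#' @param key one of \code{"admission_type"}, \code{"immunocompromised"},
#'   \code{"covid"}, \code{"gi_surgery"},
#'   \code{"admission_cultures_positive"},
#'   \code{"first_surveillance_set_positive"}.
#' @param value stratum label: an admission type for \code{admission_type},
#'   else \code{TRUE}/\code{FALSE}.
#' @return the sub-cohort (an [sdd_cohort()]) of qualifying admissions with
#'   their cultures and isolates.
#' @export
stratify <- function(cohort, key, value) {
  adm <- cohort$admissions
  if (!key %in% SUBGROUP_KEYS)
    stop("unknown subgroup key: ", key, call. = FALSE)
  keep_ids <- switch(key,
    admission_type = adm$admission_id[adm$admission_type == value],
    immunocompromised = adm$admission_id[adm$immunocompromised == value],
    covid = adm$admission_id[adm$covid == value],
    gi_surgery = adm$admission_id[adm$gi_surgery == value],
    admission_cultures_positive = {
      cul <- cohort$cultures
      adm_cul <- cul[cul$category == "sdd_admission", , drop = FALSE]
      pos_cul <- adm_cul$culture_id %in% cohort$isolates$culture_id
      pos_adm <- unique(adm_cul$admission_id[pos_cul])
      if (isTRUE(value)) intersect(adm$admission_id, pos_adm)
      else setdiff(adm$admission_id, pos_adm)
    },
    first_surveillance_set_positive = {
      cul <- cohort$cultures
      sur <- cul[cul$category == "sdd_surveillance", , drop = FALSE]
      split_dates <- split(sur$collection_date, sur$admission_id)
      n_sets <- vapply(split_dates, function(d) length(unique(d)), 0L)
      eligible <- names(n_sets)[n_sets >= 2]
      first_pos <- vapply(eligible, function(id) {
        d <- sur[sur$admission_id == id, , drop = FALSE]
        first <- min(d$collection_date)
        any(d$culture_id[d$collection_date == first] %in%
              cohort$isolates$culture_id)
      }, logical(1))
      eligible[first_pos == isTRUE(value)]
    })
  adm2 <- adm[adm$admission_id %in% keep_ids, , drop = FALSE]
  cul2 <- cohort$cultures[cohort$cultures$admission_id %in% keep_ids, ,
                          drop = FALSE]
  iso2 <- cohort$isolates[cohort$isolates$culture_id %in% cul2$culture_id, ,
                          drop = FALSE]
  sdd_cohort(adm2, cul2, iso2)
}
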