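#' Organism class vocabulary
#'
#' Colonisation dynamics, topical-SDD targeting and intensification triggers
#' operate on organism classes rather than species: aerobic Gram-negative
#' bacteria, S. aureus, and yeasts are targeted by the topical regimen
#' (colistin/tobramycin and nystatin or amphotericin); other respiratory
#' pathogens are surveilled but not topically targeted. This table maps the
#' built-in species vocabulary to its class; supply your own mapping for
#' real laboratory exports.
#'
#' @return data.frame with columns \code{species}, \code{organism_class}
#'   (one of \code{"gram_negative"}, \code{"s_aureus"}, \code{"yeast"},
#'   \code{"other_respiratory"}) and \code{topical_target} (logical).
#' @export
species_class_table <- function() {
  data.frame(
    species = c("ECO", "KPN", "PAE", "ECL", "PMI",
                "SAU",
                "CAL", "CGL",
                "HIN", "SPN", "MCA"),
    organism_class = c(rep("gram_negative", 5),
                       "s_aureus",
                       rep("yeast", 2),
                       rep("other_respiratory", 3)),
    topical_target = c(rep(TRUE, 8), rep(FALSE, 3)),
    stringsAsFactors = FALSE)
}

ORGANISM_CLASSES <- c("gram_negative", "s_aureus", "yeast",
                      "other_respiratory")

#' Default SDD intensification trigger rules
#'
#' By protocol, persistent or recurrent colonisation with a topically
#' targeted organism detected after at least \code{min_sdd_day} days of SDD
#' application triggers intensification (eight-times-daily topical dosing
#' and/or nebulised antibiotics). The default table fires on any
#' topical-target class at any SDD site after \eqn{\ge} 4 days; site sets
#' and thresholds are configurable per organism class.
#'
#' @param min_sdd_day minimum whole days of SDD application (default 4).
#' @return data.frame with columns \code{rule_id}, \code{organism_class},
#'   \code{sites} (semicolon-joined subset of throat/rectum/sputum) and
#'   \code{min_sdd_day}.
#' @export
default_trigger_rules <- function(min_sdd_day = 4L) {
  data.frame(
    rule_id = c("gn_any_site", "sau_any_site", "yeast_any_site"),
    organism_class = c("gram_negative", "s_aureus", "yeast"),
    sites = rep("throat;rectum;sputum", 3),
    min_sdd_day = as.integer(min_sdd_day),
    stringsAsFactors = FALSE)
}

#' Whole days of SDD application at a given date
#'
#' The clock anchors at the calendar date of the first topical
#' administration: that date is day 0, so "after \eqn{\ge} 4 days of SDD"
#' means day index \eqn{\ge} 4. Dates before the start return a negative
#' index which callers filter out.
#'
#' @param sdd_start_time POSIXct (or Date) of first topical administration.
#' @param date Date of the culture.
#' @return integer day index (0 on the start date).
#' @export
sdd_day <- function(sdd_start_time, date) {
  as.integer(as.Date(date) - as.Date(sdd_start_time))
}

#' Detect colonisation-persistence events triggering SDD intensification
#'
#' Scans scenario cultures for isolates whose organism class and site match a
#' trigger rule and whose SDD day index is at least the rule's threshold.
#' Both SDD and clinical cultures are eligible (a clinical sputum sample can
#' reveal persistence just as a surveillance sample can). Repeated
#' detections of one class on one day — at multiple sites or in multiple
#' cultures — produce a single event, mirroring the finding-level dedup
#' philosophy; distinct classes on one day trigger separately.
#'
#' @param cultures culture table filtered by [apply_scenario()].
#' @param isolates isolate table.
#' @param admissions admission table (provides \code{sdd_start_time});
#'   admissions with a missing start time are skipped with a warning.
#' @param rules trigger rule table, see [default_trigger_rules()].
#' @param species_classes species-to-class mapping, see
#'   [species_class_table()].
#' @return data.frame of events: \code{admission_id}, \code{date},
#'   \code{sdd_day}, \code{organism_class}, \code{isolate_id} (first
#'   qualifying isolate), \code{rule_id}.
#' @export
detect_triggers <- function(cultures, isolates, admissions,
                            rules = default_trigger_rules(),
                            species_classes = species_class_table()) {
  empty <- data.frame(admission_id = character(),
                      date = as.Date(character()), sdd_day = integer(),
                      organism_class = character(), isolate_id = character(),
                      rule_id = character(), stringsAsFactors = FALSE)
  ci <- match(isolates$culture_id, cultures$culture_id)
  keep <- !is.na(ci)
  if (!any(keep)) return(empty)
  iso <- isolates[keep, , drop = FALSE]
  ci <- ci[keep]
  iso$admission_id <- cultures$admission_id[ci]
  iso$date <- cultures$collection_date[ci]
  iso$site <- cultures$site[ci]
  iso$organism_class <- species_classes$organism_class[
    match(iso$species, species_classes$species)]

  ai <- match(iso$admission_id, admissions$admission_id)
  sdd_start <- admissions$sdd_start_time[ai]
  if (anyNA(sdd_start)) {
    skipped <- unique(iso$admission_id[is.na(sdd_start)])
    warning("skipping admission(s) without sdd_start_time: ",
            paste(skipped, collapse = ", "), call. = FALSE)
    ok <- !is.na(sdd_start)
    iso <- iso[ok, , drop = FALSE]
    sdd_start <- sdd_start[ok]
  }
  if (!nrow(iso)) return(empty)
  iso$sdd_day <- sdd_day(sdd_start, iso$date)

  hits <- list()
  for (r in seq_len(nrow(rules))) {
    sites <- strsplit(rules$sites[r], ";", fixed = TRUE)[[1]]
    sel <- iso$organism_class %in% rules$organism_class[r] &
      iso$site %in% sites &
      iso$sdd_day >= rules$min_sdd_day[r]
    if (any(sel)) {
      h <- iso[sel, c("admission_id", "date", "sdd_day", "organism_class",
                      "isolate_id"), drop = FALSE]
      h$rule_id <- rules$rule_id[r]
      hits[[length(hits) + 1L]] <- h
    }
  }
  if (!length(hits)) return(empty)
  ev <- do.call(rbind, hits)
  ev <- ev[order(ev$admission_id, ev$date, ev$organism_class, ev$isolate_id,
                 method = "radix"), , drop = FALSE]
  # one event per (admission, class, day)
  key <- paste(ev$admission_id, ev$organism_class, ev$date, sep = "\r")
  ev <- ev[!duplicated(key), , drop = FALSE]
  rownames(ev) <- NULL
  ev
}

#' Concordance of trigger detection between scenarios
#'
#' For each reference-scenario event (matched by admission and organism
#' class), the reduced scenario detects it on the same date (same-day), on a
#' later date (delayed; delay = days to the nearest later event of that
#' admission/class), or not at all (missed). The three fractions sum to 1
#' over reference events.
#'
#' @param events_reference,events_reduced event tables from
#'   [detect_triggers()] on the same cohort.
#' @return list with \code{same_day_fraction}, \code{delayed_fraction},
#'   \code{missed_fraction}, \code{delays}, \code{median_delay},
#'   \code{iqr_delay} and a per-event \code{detail} data.frame.
#' @export
trigger_concordance <- function(events_reference, events_reduced) {
  n <- nrow(events_reference)
  if (!n) stop("no reference events", call. = FALSE)
  status <- character(n)
  delay <- rep(NA_integer_, n)
  red_key <- paste(events_reduced$admission_id,
                   events_reduced$organism_class, sep = "\r")
  for (i in seq_len(n)) {
    k <- paste(events_reference$admission_id[i],
               events_reference$organism_class[i], sep = "\r")
    dates <- events_reduced$date[red_key == k]
    if (any(dates == events_reference$date[i])) {
      status[i] <- "same_day"
    } else if (any(dates > events_reference$date[i])) {
      delay[i] <- as.integer(min(dates[dates > events_reference$date[i]]) -
                             events_reference$date[i])
      status[i] <- "delayed"
    } else {
      status[i] <- "missed"
    }
  }
  delays <- delay[!is.na(delay)]
  list(same_day_fraction = mean(status == "same_day"),
       delayed_fraction = mean(status == "delayed"),
       missed_fraction = mean(status == "missed"),
       delays = delays,
       median_delay = if (length(delays)) stats::median(delays) else NA_real_,
       iqr_delay = if (length(delays)) quant8(delays, c(0.25, 0.75))
                   else c(NA_real_, NA_real_),
       detail = cbind(events_reference,
                      data.frame(status = status, delay_days = delay,
                                 stringsAsFactors = FALSE)))
}

#' Trigger capture of a reduced scenario, in percent
#'
#' @param n_reduced,n_reference trigger counts (or rates) in the reduced and
#'   reference scenarios.
#' @return integer percent, rounded half away from zero.
#' @export
#' @examples
#' trigger_capture_percent(43, 56)  # 77
trigger_capture_percent <- function(n_reduced, n_reference) {
  if (any(n_reference <= 0))
    stop("reference count must be positive", call. = FALSE)
  round_half_up(100 * n_reduced / n_reference)
}
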