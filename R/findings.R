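#' Parse a susceptibility string into a named map
#'
#' Susceptibility test results travel as semicolon-joined
#' \code{agent:category} pairs (e.g. \code{"CTX:R;TOB:S"}), categories
#' restricted to S (susceptible), I (intermediate) and R (resistant). Agents
#' absent from the map were not tested.
#'
#' @param s a single susceptibility string; \code{""} means no agent tested.
#' @return named character vector mapping agent code to category.
#' @export
parse_susceptibility <- function(s) {
  if (is.na(s) || !nzchar(s)) return(stats::setNames(character(0), character(0)))
  parts <- strsplit(s, ";", fixed = TRUE)[[1]]
  kv <- strsplit(parts, ":", fixed = TRUE)
  if (any(lengths(kv) != 2))
    stop("malformed susceptibility pair in: ", s, call. = FALSE)
  agents <- vapply(kv, `[[`, "", 1)
  cats <- vapply(kv, `[[`, "", 2)
  if (!all(cats %in% c("S", "I", "R")))
    stop("susceptibility category outside {S,I,R} in: ", s, call. = FALSE)
  stats::setNames(cats, agents)
}

#' Canonical susceptibility profile key
#'
#' Canonicalizes a susceptibility map to a string with agents sorted
#' lexicographically and joined as \code{agent:category}, so that two panels
#' equal as sets produce identical keys. The empty map yields \code{""}.
#'
#' @param susceptibility named character vector (agent -> S/I/R), or a raw
#'   profile string which is parsed first.
#' @return canonical profile string.
#' @export
#' @examples
#' profile_key(c(TOB = "S", CTX = "R"))  # "CTX:R;TOB:S"
profile_key <- function(susceptibility) {
  if (is.character(susceptibility) && is.null(names(susceptibility)) &&
      length(susceptibility) == 1)
    susceptibility <- parse_susceptibility(susceptibility)
  if (!length(susceptibility)) return("")
  if (!all(susceptibility %in% c("S", "I", "R")))
    stop("susceptibility category outside {S,I,R}", call. = FALSE)
  ord <- order(names(susceptibility), method = "radix")
  paste(paste0(names(susceptibility)[ord], ":", susceptibility[ord]),
        collapse = ";")
}

#' Do two susceptibility profiles differ?
#'
#' Two profiles are considered different only if some agent tested in BOTH
#' maps has different categories; agents tested in only one panel are
#' ignored. This shared-agent rule prevents panel composition differences
#' (which agents a lab happened to test) from generating spurious "new"
#' findings. Intermediate (I) differs from both S and R.
#'
#' @param profile_a,profile_b named character vectors or raw profile strings.
#' @return TRUE if the profiles disagree on at least one shared agent.
#' @export
profiles_differ <- function(profile_a, profile_b) {
  a <- if (is.null(names(profile_a)) && length(profile_a) <= 1)
    parse_susceptibility(if (length(profile_a)) profile_a else "") else profile_a
  b <- if (is.null(names(profile_b)) && length(profile_b) <= 1)
    parse_susceptibility(if (length(profile_b)) profile_b else "") else profile_b
  shared <- intersect(names(a), names(b))
  any(a[shared] != b[shared])
}

#' Classify the clinical relevance of an isolate
#'
#' Three mutually exclusive levels, by precedence:
#' \describe{
#'   \item{direct}{multidrug-resistant organisms (MRSA, VRE, ESBL producers,
#'     other MDRO) requiring immediate barrier precautions;}
#'   \item{high}{organisms resistant to third-generation cephalosporins or
#'     fluconazole (intrinsic or acquired), compromising standard empirical
#'     therapy;}
#'   \item{infection_related}{organisms adjudicated as the causative pathogen
#'     of an ICU-acquired infection.}
#' }
#' Everything else is \code{none}. The precedence direct > high >
#' infection_related makes relevance counts mutually exclusive so the three
#' levels partition the relevant findings.
#'
#' @param mdro,resistant_standard,infection_related logical vectors (recycled
#'   to common length).
#' @return character vector of levels in
#'   \{\code{"direct"}, \code{"high"}, \code{"infection_related"},
#'   \code{"none"}\}.
#' @export
classify_relevance <- function(mdro, resistant_standard, infection_related) {
  n <- max(length(mdro), length(resistant_standard),
           length(infection_related))
  mdro <- rep_len(mdro, n)
  resistant_standard <- rep_len(resistant_standard, n)
  infection_related <- rep_len(infection_related, n)
  ifelse(mdro, "direct",
         ifelse(resistant_standard, "high",
                ifelse(infection_related, "infection_related", "none")))
}

#' Extract deduplicated new findings from scenario cultures
#'
#' A "new finding" is an organism-susceptibility combination not previously
#' cultured during the same ICU admission. The rules, applied in a
#' chronological sweep per admission:
#' \itemize{
#'   \item an isolate opens a finding iff no earlier (or same-day
#'     already-attributed) isolate of the same species in this admission has a
#'     non-differing profile (see [profiles_differ()]);
#'   \item the same species with a differing susceptibility profile is a new
#'     finding;
#'   \item repeated detections at multiple surveillance sites, or in
#'     surveillance and clinical cultures on the same day, collapse to one
#'     finding; if any same-day source is a clinical culture the finding is
#'     attributed to the clinical culture (the SDD culture is
#'     non-informative), else to SDD.
#' }
#'
#' @param cultures culture table already filtered by [apply_scenario()].
#' @param isolates isolate table; isolates whose culture is outside the
#'   scenario subset are ignored.
#' @return data.frame of findings: \code{admission_id}, \code{species},
#'   \code{profile_key}, \code{first_date}, \code{relevance},
#'   \code{source_category} (\code{"sdd"} or \code{"clinical"}),
#'   \code{source_culture_ids} (pipe-joined ids of same-day sources).
#' @export
extract_new_findings <- function(cultures, isolates) {
  empty <- data.frame(admission_id = character(), species = character(),
                      profile_key = character(),
                      first_date = as.Date(character()),
                      relevance = character(), source_category = character(),
                      source_culture_ids = character(),
                      stringsAsFactors = FALSE)
  ci <- match(isolates$culture_id, cultures$culture_id)
  keep <- !is.na(ci)
  if (!any(keep)) return(empty)
  iso <- isolates[keep, , drop = FALSE]
  ci <- ci[keep]
  iso$admission_id <- cultures$admission_id[ci]
  iso$date <- cultures$collection_date[ci]
  iso$category <- cultures$category[ci]
  iso$pkey <- vapply(iso$susceptibility,
                     function(s) profile_key(parse_susceptibility(s)),
                     "", USE.NAMES = FALSE)
  # deterministic sweep order: date, then clinical before SDD within a day so
  # same-day attribution needs no rewrite, then stable ids
  ord <- order(iso$admission_id, iso$date, iso$category != "clinical",
               iso$culture_id, iso$isolate_id, method = "radix")
  iso <- iso[ord, , drop = FALSE]

  res <- vector("list", nrow(iso))
  nres <- 0L
  for (adm in unique(iso$admission_id)) {
    rows <- which(iso$admission_id == adm)
    findings <- list()  # each: species, prof (named vec), pkey, date,
                        # relevance flags, source_category, culture_ids
    for (r in rows) {
      sp <- iso$species[r]
      prof <- parse_susceptibility(iso$susceptibility[r])
      matched <- NULL
      for (k in seq_along(findings)) {
        f <- findings[[k]]
        if (f$species == sp && !profiles_differ(f$prof, prof)) {
          matched <- k
          break
        }
      }
      if (is.null(matched)) {
        findings[[length(findings) + 1L]] <- list(
          species = sp, prof = prof, pkey = iso$pkey[r], date = iso$date[r],
          mdro = iso$mdro[r], resistant_standard = iso$resistant_standard[r],
          infection_related = iso$infection_related[r],
          source_category = if (iso$category[r] == "clinical") "clinical"
                            else "sdd",
          culture_ids = iso$culture_id[r])
      } else if (iso$date[r] == findings[[matched]]$date) {
        # same-day duplicate: collapse, recording the extra source
        f <- findings[[matched]]
        f$culture_ids <- union(f$culture_ids, iso$culture_id[r])
        if (iso$category[r] == "clinical") f$source_category <- "clinical"
        findings[[matched]] <- f
      }
      # later-day repeat of a known organism: not a new finding, not recorded
    }
    for (f in findings) {
      nres <- nres + 1L
      res[[nres]] <- data.frame(
        admission_id = adm, species = f$species, profile_key = f$pkey,
        first_date = f$date,
        relevance = classify_relevance(f$mdro, f$resistant_standard,
                                       f$infection_related),
        source_category = f$source_category,
        source_culture_ids = paste(f$culture_ids, collapse = "|"),
        stringsAsFactors = FALSE)
    }
  }
  if (!nres) return(empty)
  out <- do.call(rbind, res[seq_len(nres)])
  rownames(out) <- NULL
  out
}

#' Detection rate per 1,000 ICU days
#'
#' @param n_events number of events (findings, triggers, ...).
#' @param total_icu_days cohort denominator: summed fractional length of stay
#'   of all analysed admissions.
#' @return unrounded rate per 1,000 ICU days; round only at reporting.
#' @export
#' @examples
#' detection_rate(70103, 76964)  # ~910.85, reported as 911
detection_rate <- function(n_events, total_icu_days) {
  if (any(total_icu_days <= 0))
    stop("total_icu_days must be positive", call. = FALSE)
  n_events / total_icu_days * 1000
}

#' Relative yield of a reduced scenario, in percent
#'
#' @param rate_scenario,rate_reference detection rates in the same units.
#' @return integer percent, rounded half away from zero.
#' @export
#' @examples
#' relative_yield(85, 90)  # 94
relative_yield <- function(rate_scenario, rate_reference) {
  if (any(rate_reference <= 0))
    stop("reference rate must be positive", call. = FALSE)
  round_half_up(100 * rate_scenario / rate_reference)
}

#' Missed and delayed detections relative to a reference scenario
#'
#' Matches findings between the reference (full surveillance) and a reduced
#' scenario by (admission_id, species, profile_key). A reference finding is
#' \emph{missed} if absent from the reduced scenario, \emph{delayed} if
#' present with a later first detection date (delay in whole days), and
#' \emph{same_day} otherwise. Median and IQR are computed over delayed
#' findings only (median-unbiased quantiles).
#'
#' @param findings_reference,findings_reduced finding tables from
#'   [extract_new_findings()] on the same cohort.
#' @return list with \code{n_missed}, \code{n_delayed}, \code{n_same_day},
#'   \code{delays} (integer vector, one per delayed finding),
#'   \code{median_delay}, \code{iqr_delay} (length-2), and \code{detail}
#'   (one row per reference finding with status and delay_days).
#' @export
delay_analysis <- function(findings_reference, findings_reduced) {
  key <- function(f) paste(f$admission_id, f$species, f$profile_key,
                           sep = "\r")
  ref_key <- key(findings_reference)
  red_key <- key(findings_reduced)
  m <- match(ref_key, red_key)
  status <- ifelse(is.na(m), "missed", NA)
  delay <- rep(NA_integer_, length(ref_key))
  hit <- !is.na(m)
  d <- as.integer(findings_reduced$first_date[m[hit]] -
                  findings_reference$first_date[hit])
  status[hit] <- ifelse(d > 0, "delayed", "same_day")
  delay[hit][d > 0] <- d[d > 0]
  delays <- delay[!is.na(delay)]
  list(
    n_missed = sum(status == "missed"),
    n_delayed = sum(status == "delayed"),
    n_same_day = sum(status == "same_day"),
    delays = delays,
    median_delay = if (length(delays)) stats::median(delays) else NA_real_,
    iqr_delay = if (length(delays)) quant8(delays, c(0.25, 0.75))
                else c(NA_real_, NA_real_),
    detail = data.frame(
      admission_id = findings_reference$admission_id,
      species = findings_reference$species,
      profile_key = findings_reference$profile_key,
      status = status, delay_days = delay, stringsAsFactors = FALSE))
}
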