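#' Cohort container for SDD surveillance data
#'
#' An \code{sdd_cohort} bundles the three linked tables the pipeline operates
#' on: one row per ICU admission, one row per culture (sampling event), and
#' one row per isolate (organism recovered from a culture). Admissions are the
#' unit of analysis: readmitted patients contribute one independent record per
#' ICU stay.
#'
#' @param admissions data.frame with columns \code{admission_id},
#'   \code{patient_id}, \code{admit_time}, \code{discharge_time},
#'   \code{sdd_start_time} (POSIXct), \code{icu_days} (fractional days;
#'   recomputed if absent), \code{admission_type} (one of \code{"medical"},
#'   \code{"surgical_elective"}, \code{"surgical_emergency"}),
#'   and logical flags \code{immunocompromised}, \code{covid},
#'   \code{gi_surgery}, \code{readmission}.
#' @param cultures data.frame with columns \code{culture_id},
#'   \code{admission_id}, \code{collection_date} (Date), \code{site} (one of
#'   \code{"throat"}, \code{"rectum"}, \code{"sputum"}, \code{"other"}),
#'   \code{category} (one of \code{"sdd_admission"}, \code{"sdd_surveillance"},
#'   \code{"clinical"}), and cost components \code{order_fee},
#'   \code{plate_cost}, \code{id_cost}, \code{susceptibility_cost} (numeric;
#'   all-NA marks a missing cost record, never zero).
#' @param isolates data.frame with columns \code{isolate_id},
#'   \code{culture_id}, \code{species}, \code{susceptibility}
#'   (semicolon-joined \code{agent:category} pairs, categories S/I/R), and
#'   logical flags \code{mdro}, \code{resistant_standard},
#'   \code{infection_related}, \code{topical_target}.
#' @return an object of class \code{sdd_cohort}: a list with elements
#'   \code{admissions}, \code{cultures}, \code{isolates}.
#' @seealso [validate_cohort()], [load_cohort()], [write_cohort()],
#'   [generate_cohort()]
#' @export
sdd_cohort <- function(admissions, cultures, isolates) {
  stopifnot(is.data.frame(admissions), is.data.frame(cultures),
            is.data.frame(isolates))
  need <- function(df, cols, what) {
    miss <- setdiff(cols, names(df))
    if (length(miss))
      stop(sprintf("%s table is missing column(s): %s", what,
                   paste(miss, collapse = ", ")), call. = FALSE)
  }
  need(admissions, c("admission_id", "patient_id", "admit_time",
                     "discharge_time", "sdd_start_time", "admission_type",
                     "immunocompromised", "covid", "gi_surgery",
                     "readmission"), "admissions")
  need(cultures, c("culture_id", "admission_id", "collection_date", "site",
                   "category", "order_fee", "plate_cost", "id_cost",
                   "susceptibility_cost"), "cultures")
  need(isolates, c("isolate_id", "culture_id", "species", "susceptibility",
                   "mdro", "resistant_standard", "infection_related",
                   "topical_target"), "isolates")
  if (!"icu_days" %in% names(admissions)) {
    admissions$icu_days <- as.numeric(difftime(admissions$discharge_time,
                                               admissions$admit_time,
                                               units = "days"))
  }
  structure(list(admissions = admissions, cultures = cultures,
                 isolates = isolates),
            class = "sdd_cohort")
}

#' @export
print.sdd_cohort <- function(x, ...) {
  cat(sprintf(
    "<sdd_cohort> %d admissions, %d cultures (%d SDD), %d isolates, %.0f ICU days\n",
    nrow(x$admissions), nrow(x$cultures),
    sum(x$cultures$category != "clinical"),
    nrow(x$isolates), sum(x$admissions$icu_days)))
  invisible(x)
}

ADMISSION_TYPES <- c("medical", "surgical_elective", "surgical_emergency")
CULTURE_SITES <- c("throat", "rectum", "sputum", "other")
SDD_SITES <- c("throat", "rectum", "sputum")
CULTURE_CATEGORIES <- c("sdd_admission", "sdd_surveillance", "clinical")
COST_COMPONENTS <- c("order_fee", "plate_cost", "id_cost",
                     "susceptibility_cost")

#' Validate a cohort against the domain invariants
#'
#' Checks referential integrity, temporal ordering, controlled vocabularies,
#' the SDD-site rule (SDD cultures only at throat/rectum/sputum), cost-record
#' completeness (components all present or all missing), and susceptibility
#' string syntax. Violations are returned as data, not raised: an empty report
#' certifies every invariant holds. The function is side-effect free and
#' idempotent.
#'
#' @param cohort an [sdd_cohort()].
#' @return data.frame with columns \code{record} (offending id),
#'   \code{rule} (short rule name), and \code{detail}; zero rows if valid.
#' @export
validate_cohort <- function(cohort) {
  adm <- cohort$admissions; cul <- cohort$cultures; iso <- cohort$isolates
  out <- list()
  add <- function(record, rule, detail) {
    out[[length(out) + 1L]] <<- data.frame(record = as.character(record),
                                           rule = rule, detail = detail,
                                           stringsAsFactors = FALSE)
  }

  if (anyDuplicated(adm$admission_id))
    for (id in unique(adm$admission_id[duplicated(adm$admission_id)]))
      add(id, "unique_admission_id", "duplicate admission_id")
  if (anyDuplicated(cul$culture_id))
    for (id in unique(cul$culture_id[duplicated(cul$culture_id)]))
      add(id, "unique_culture_id", "duplicate culture_id")
  if (anyDuplicated(iso$isolate_id))
    for (id in unique(iso$isolate_id[duplicated(iso$isolate_id)]))
      add(id, "unique_isolate_id", "duplicate isolate_id")

  bad <- which(as.numeric(difftime(adm$discharge_time, adm$admit_time,
                                   units = "days")) <= 0)
  for (i in bad) add(adm$admission_id[i], "temporal_ordering",
                     "discharge_time not after admit_time")
  dev <- abs(adm$icu_days - as.numeric(difftime(adm$discharge_time,
                                                adm$admit_time,
                                                units = "days")))
  for (i in which(dev > 1e-8))
    add(adm$admission_id[i], "icu_days_consistent",
        "icu_days != discharge - admit in days")
  for (i in which(adm$sdd_start_time < adm$admit_time |
                  adm$sdd_start_time > adm$discharge_time))
    add(adm$admission_id[i], "sdd_start_within_stay",
        "sdd_start_time outside [admit_time, discharge_time]")
  for (i in which(!adm$admission_type %in% ADMISSION_TYPES))
    add(adm$admission_id[i], "admission_type_vocab",
        paste("unknown admission_type:", adm$admission_type[i]))

  dangling <- !cul$admission_id %in% adm$admission_id
  for (i in which(dangling))
    add(cul$culture_id[i], "culture_admission_fk",
        paste("unknown admission_id:", cul$admission_id[i]))
  for (i in which(!cul$site %in% CULTURE_SITES))
    add(cul$culture_id[i], "site_vocab", paste("unknown site:", cul$site[i]))
  for (i in which(!cul$category %in% CULTURE_CATEGORIES))
    add(cul$culture_id[i], "category_vocab",
        paste("unknown category:", cul$category[i]))
  sdd <- cul$category %in% c("sdd_admission", "sdd_surveillance")
  for (i in which(sdd & !cul$site %in% SDD_SITES))
    add(cul$culture_id[i], "sdd_site",
        "SDD culture at a non-SDD site (must be throat/rectum/sputum)")

  ai <- match(cul$admission_id, adm$admission_id)
  ok <- !is.na(ai)
  lo <- as.Date(adm$admit_time[ai[ok]])
  hi <- as.Date(adm$discharge_time[ai[ok]])
  inside <- cul$collection_date[ok] >= lo & cul$collection_date[ok] <= hi
  for (i in which(ok)[!inside])
    add(cul$culture_id[i], "culture_within_stay",
        "collection_date outside the admission stay")

  comp <- as.matrix(cul[COST_COMPONENTS])
  n_na <- rowSums(is.na(comp))
  for (i in which(n_na > 0 & n_na < 4))
    add(cul$culture_id[i], "cost_all_or_none",
        "cost components must be all present or all missing")
  for (i in which(n_na == 0 & apply(comp, 1, function(r) any(r < 0))))
    add(cul$culture_id[i], "cost_nonnegative", "negative cost component")

  for (i in which(!iso$culture_id %in% cul$culture_id))
    add(iso$isolate_id[i], "isolate_culture_fk",
        paste("unknown culture_id:", iso$culture_id[i]))
  for (i in seq_len(nrow(iso))) {
    prof <- tryCatch(parse_susceptibility(iso$susceptibility[i]),
                     error = function(e) NULL)
    if (is.null(prof))
      add(iso$isolate_id[i], "susceptibility_syntax",
          paste("unparseable susceptibility:", iso$susceptibility[i]))
  }

  if (!length(out))
    return(data.frame(record = character(), rule = character(),
                      detail = character(), stringsAsFactors = FALSE))
  do.call(rbind, out)
}

#' Load a cohort from three CSV files
#'
#' Reads the admissions, cultures and isolates tables (UTF-8 CSV with
#' headers), parses timestamps/dates, and fails fast on schema errors
#' (missing columns), unparseable dates (with row number) and dangling
#' foreign keys (with the offending id). \code{icu_days} is derived from the
#' admission timestamps as fractional days.
#'
#' @param admissions_path,cultures_path,isolates_path paths to CSV files
#'   following the schemas documented in [sdd_cohort()].
#' @return a validated [sdd_cohort()].
#' @export
load_cohort <- function(admissions_path, cultures_path, isolates_path) {
  adm <- utils::read.csv(admissions_path, stringsAsFactors = FALSE,
                         colClasses = "character")
  cul <- utils::read.csv(cultures_path, stringsAsFactors = FALSE,
                         colClasses = "character")
  iso <- utils::read.csv(isolates_path, stringsAsFactors = FALSE,
                         colClasses = "character")

  need <- function(df, cols, file) {
    miss <- setdiff(cols, names(df))
    if (length(miss))
      stop(sprintf("schema error in %s: missing column(s) %s", file,
                   paste(miss, collapse = ", ")), call. = FALSE)
  }
  need(adm, c("admission_id", "patient_id", "admit_time", "discharge_time",
              "sdd_start_time", "admission_type", "immunocompromised",
              "covid", "gi_surgery", "readmission"), admissions_path)
  need(cul, c("culture_id", "admission_id", "collection_date", "site",
              "category", "order_fee", "plate_cost", "id_cost",
              "susceptibility_cost"), cultures_path)
  need(iso, c("isolate_id", "culture_id", "species", "susceptibility",
              "mdro", "resistant_standard", "infection_related",
              "topical_target"), isolates_path)

  parse_ts <- function(x, col, file) {
    out <- as.POSIXct(x, tz = "UTC",
                      tryFormats = c("%Y-%m-%dT%H:%M:%S", "%Y-%m-%d %H:%M:%S",
                                     "%Y-%m-%d"))
    if (anyNA(out))
      stop(sprintf("parse error in %s, column %s, row %d: %s", file, col,
                   which(is.na(out))[1], x[which(is.na(out))[1]]),
           call. = FALSE)
    out
  }
  parse_date <- function(x, col, file) {
    out <- as.Date(x, format = "%Y-%m-%d")
    if (anyNA(out))
      stop(sprintf("parse error in %s, column %s, row %d: %s", file, col,
                   which(is.na(out))[1], x[which(is.na(out))[1]]),
           call. = FALSE)
    out
  }
  flag <- function(x) as.logical(as.integer(x))
  money <- function(x) {
    x[x == ""] <- NA_character_
    as.numeric(x)
  }

  adm$admit_time <- parse_ts(adm$admit_time, "admit_time", admissions_path)
  adm$discharge_time <- parse_ts(adm$discharge_time, "discharge_time",
                                 admissions_path)
  adm$sdd_start_time <- parse_ts(adm$sdd_start_time, "sdd_start_time",
                                 admissions_path)
  for (f in c("immunocompromised", "covid", "gi_surgery", "readmission"))
    adm[[f]] <- flag(adm[[f]])

  cul$collection_date <- parse_date(cul$collection_date, "collection_date",
                                    cultures_path)
  for (f in COST_COMPONENTS) cul[[f]] <- money(cul[[f]])

  for (f in c("mdro", "resistant_standard", "infection_related",
              "topical_target"))
    iso[[f]] <- flag(iso[[f]])

  dangle <- setdiff(cul$admission_id, adm$admission_id)
  if (length(dangle))
    stop(sprintf("integrity error: cultures reference unknown admission_id %s",
                 paste(unique(dangle), collapse = ", ")), call. = FALSE)
  dangle <- setdiff(iso$culture_id, cul$culture_id)
  if (length(dangle))
    stop(sprintf("integrity error: isolates reference unknown culture_id %s",
                 paste(unique(dangle), collapse = ", ")), call. = FALSE)

  sdd_cohort(adm, cul, iso)
}

#' Write a cohort to three CSV files
#'
#' Inverse of [load_cohort()]: writes \code{admissions.csv},
#' \code{cultures.csv} and \code{isolates.csv} under \code{dir} in the
#' documented schemas (ISO-8601 timestamps/dates, 0/1 flags, blank for
#' missing cost components). \code{write_cohort} then \code{load_cohort}
#' round-trips any valid cohort field-by-field.
#'
#' @param cohort an [sdd_cohort()].
#' @param dir output directory (created if absent).
#' @return invisibly, the three file paths.
#' @export
write_cohort <- function(cohort, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  adm <- cohort$admissions
  out_adm <- data.frame(
    admission_id = adm$admission_id,
    patient_id = adm$patient_id,
    admit_time = format(adm$admit_time, "%Y-%m-%dT%H:%M:%S", tz = "UTC"),
    discharge_time = format(adm$discharge_time, "%Y-%m-%dT%H:%M:%S",
                            tz = "UTC"),
    sdd_start_time = format(adm$sdd_start_time, "%Y-%m-%dT%H:%M:%S",
                            tz = "UTC"),
    admission_type = adm$admission_type,
    immunocompromised = as.integer(adm$immunocompromised),
    covid = as.integer(adm$covid),
    gi_surgery = as.integer(adm$gi_surgery),
    readmission = as.integer(adm$readmission),
    stringsAsFactors = FALSE)
  cul <- cohort$cultures
  fmt_money <- function(x) ifelse(is.na(x), "", format(x, trim = TRUE,
                                                       scientific = FALSE))
  out_cul <- data.frame(
    culture_id = cul$culture_id,
    admission_id = cul$admission_id,
    collection_date = format(cul$collection_date, "%Y-%m-%d"),
    site = cul$site,
    category = cul$category,
    order_fee = fmt_money(cul$order_fee),
    plate_cost = fmt_money(cul$plate_cost),
    id_cost = fmt_money(cul$id_cost),
    susceptibility_cost = fmt_money(cul$susceptibility_cost),
    stringsAsFactors = FALSE)
  iso <- cohort$isolates
  out_iso <- data.frame(
    isolate_id = iso$isolate_id,
    culture_id = iso$culture_id,
    species = iso$species,
    susceptibility = iso$susceptibility,
    mdro = as.integer(iso$mdro),
    resistant_standard = as.integer(iso$resistant_standard),
    infection_related = as.integer(iso$infection_related),
    topical_target = as.integer(iso$topical_target),
    stringsAsFactors = FALSE)
  paths <- file.path(dir, c("admissions.csv", "cultures.csv", "isolates.csv"))
  utils::write.csv(out_adm, paths[1], row.names = FALSE, quote = FALSE)
  utils::write.csv(out_cul, paths[2], row.names = FALSE, quote = FALSE)
  utils::write.csv(out_iso, paths[3], row.names = FALSE, quote = FALSE)
  invisible(paths)
}
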