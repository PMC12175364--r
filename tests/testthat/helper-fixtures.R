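# Hand-built micro-cohorts and independent brute-force oracles used across
# the suite. Fixtures are constructed in code; nothing is read from disk.

ts <- function(x) as.POSIXct(x, tz = "UTC")

# a two-admission cohort covering both weekday patterns:
#  A1 admitted Mon 2021-01-04 (day0 Mon), 10-day stay -> surveillance on
#  Thu 7th, Mon 11th, Thu 14th; A2 admitted Tue 2021-01-05, 4-day stay.
tiny_admissions <- function() {
  data.frame(
    admission_id = c("A1", "A2"),
    patient_id = c("P1", "P2"),
    admit_time = ts(c("2021-01-04 08:00:00", "2021-01-05 20:00:00")),
    discharge_time = ts(c("2021-01-14 10:00:00", "2021-01-09 09:00:00")),
    sdd_start_time = ts(c("2021-01-04 09:00:00", "2021-01-05 21:00:00")),
    admission_type = c("medical", "surgical_emergency"),
    immunocompromised = c(FALSE, TRUE),
    covid = c(FALSE, FALSE),
    gi_surgery = c(FALSE, TRUE),
    readmission = c(FALSE, FALSE),
    stringsAsFactors = FALSE)
}

tiny_culture <- function(culture_id, admission_id, date, site, category,
                         order_fee = 30, plate_cost = 24, id_cost = 0,
                         susceptibility_cost = 0) {
  data.frame(culture_id = culture_id, admission_id = admission_id,
             collection_date = as.Date(date), site = site,
             category = category, order_fee = order_fee,
             plate_cost = plate_cost, id_cost = id_cost,
             susceptibility_cost = susceptibility_cost,
             stringsAsFactors = FALSE)
}

tiny_isolate <- function(isolate_id, culture_id, species, susceptibility,
                         mdro = FALSE, resistant_standard = FALSE,
                         infection_related = FALSE, topical_target = TRUE) {
  data.frame(isolate_id = isolate_id, culture_id = culture_id,
             species = species, susceptibility = susceptibility,
             mdro = mdro, resistant_standard = resistant_standard,
             infection_related = infection_related,
             topical_target = topical_target, stringsAsFactors = FALSE)
}

tiny_cohort <- function() {
  cultures <- rbind(
    tiny_culture("C1", "A1", "2021-01-04", "throat", "sdd_admission"),
    tiny_culture("C2", "A1", "2021-01-04", "rectum", "sdd_admission"),
    tiny_culture("C3", "A1", "2021-01-07", "rectum", "sdd_surveillance"),
    tiny_culture("C4", "A1", "2021-01-11", "throat", "sdd_surveillance"),
    tiny_culture("C5", "A1", "2021-01-11", "other", "clinical"),
    tiny_culture("C6", "A2", "2021-01-06", "sputum", "sdd_admission"),
    tiny_culture("C7", "A2", "2021-01-07", "sputum", "sdd_surveillance"))
  isolates <- rbind(
    tiny_isolate("I1", "C2", "ECO", "C3G:S;TOB:S"),
    tiny_isolate("I2", "C3", "ECO", "C3G:S;TOB:S"),
    tiny_isolate("I3", "C4", "ECO", "C3G:R;TOB:S", resistant_standard = TRUE),
    tiny_isolate("I4", "C6", "CAL", "FLU:S"))
  sdd_cohort(tiny_admissions(), cultures, isolates)
}

# ------------------------------------------------------------------------
# independent brute-force oracle for new-finding extraction: a direct
# transcription of the dedup rules with its own parser and nested loops,
# sharing no code with the implementation
oracle_parse <- function(s) {
  if (is.na(s) || !nzchar(s)) return(list(agents = character(),
                                          cats = character()))
  pieces <- unlist(strsplit(s, ";", fixed = TRUE))
  list(agents = sub(":.*", "", pieces), cats = sub(".*:", "", pieces))
}

oracle_differ <- function(pa, pb) {
  for (i in seq_along(pa$agents)) {
    j <- which(pb$agents == pa$agents[i])
    if (length(j) && pb$cats[j[1]] != pa$cats[i]) return(TRUE)
  }
  FALSE
}

oracle_findings <- function(cultures, isolates) {
  rows <- merge(isolates, cultures[c("culture_id", "admission_id",
                                     "collection_date", "category")],
                by = "culture_id")
  rows <- rows[order(rows$admission_id, rows$collection_date,
                     rows$category != "clinical", rows$culture_id,
                     rows$isolate_id), , drop = FALSE]
  found <- list()
  for (i in seq_len(nrow(rows))) {
    p <- oracle_parse(rows$susceptibility[i])
    dup <- FALSE
    for (f in found) {
      if (f$admission_id == rows$admission_id[i] &&
          f$species == rows$species[i] &&
          !oracle_differ(f$profile, p) && !oracle_differ(p, f$profile)) {
        dup <- TRUE
        break
      }
    }
    if (!dup)
      found[[length(found) + 1L]] <- list(
        admission_id = rows$admission_id[i], species = rows$species[i],
        profile = p, date = rows$collection_date[i])
  }
  if (!length(found))
    return(data.frame(admission_id = character(), species = character(),
                      first_date = as.Date(character())))
  out <- data.frame(
    admission_id = vapply(found, `[[`, "", "admission_id"),
    species = vapply(found, `[[`, "", "species"),
    first_date = as.Date(vapply(found, function(f) as.character(f$date), "")),
    stringsAsFactors = FALSE)
  out[order(out$admission_id, out$first_date, out$species), , drop = FALSE]
}

# brute-force trigger oracle: scan every (isolate, rule) pair
oracle_triggers <- function(cultures, isolates, admissions, rules,
                            species_classes) {
  keys <- character()
  for (i in seq_len(nrow(isolates))) {
    ci <- which(cultures$culture_id == isolates$culture_id[i])
    if (!length(ci)) next
    adm <- which(admissions$admission_id == cultures$admission_id[ci])
    cls <- species_classes$organism_class[
      species_classes$species == isolates$species[i]]
    day <- as.integer(cultures$collection_date[ci] -
                      as.Date(admissions$sdd_start_time[adm]))
    for (r in seq_len(nrow(rules))) {
      rule_sites <- unlist(strsplit(rules$sites[r], ";"))
      if (length(cls) && cls == rules$organism_class[r] &&
          cultures$site[ci] %in% rule_sites &&
          day >= rules$min_sdd_day[r]) {
        keys <- c(keys, paste(admissions$admission_id[adm], cls,
                              cultures$collection_date[ci]))
      }
    }
  }
  sort(unique(keys))
}

# random small cohort for property tests (uses the generator at small n)
random_small_cohort <- function(seed, n = 5) {
  generate_cohort(generator_params(n_admissions = n, seed = seed))
}
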