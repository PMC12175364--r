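#' Parameters for the synthetic cohort generator
#'
#' Returns the default generator configuration, optionally overridden. The
#' defaults are calibrated once to the marginals a mixed Dutch ICU cohort
#' under SDD exhibits: length of stay lognormal with median 5.0 days and IQR
#' 2.3-10.6; ~87\% of admissions colonised with at least one potentially
#' pathogenic microorganism (PPM) detectable on admission; admission-culture
#' positivity ~62\%, surveillance ~38\%, clinical ~26\%; ~9.9\% of new PPM
#' findings clinically relevant (split ~10:76:14 between direct, high and
#' infection-related relevance); fixed laboratory tariffs of EUR 30 order
#' fee + EUR 24 plates per culture, EUR 14 species identification per
#' isolate and EUR 66 susceptibility testing per bacterial isolate, so a
#' negative SDD culture costs EUR 54 and positives EUR 68-134+.
#'
#' @param n_admissions number of ICU admissions to simulate.
#' @param seed master seed; per-admission substreams are derived from
#'   (seed, admission id) so output is reproducible and independent of
#'   simulation order.
#' @param ... overrides for any default listed below.
#' @return a validated list of class \code{sdd_generator_params} with
#'   elements: \code{n_admissions}, \code{seed}, \code{window_start},
#'   \code{window_days}, \code{los_log_mean}, \code{los_log_sd},
#'   \code{los_min}, \code{los_fixed} (NULL unless forcing a fixed stay),
#'   \code{admission_type_probs}, \code{p_immunocompromised},
#'   \code{p_covid}, \code{p_gi_surgery}, \code{p_readmission},
#'   \code{organism_classes} (per-class prevalence, daily clearance under
#'   SDD, daily acquisition, per-site culture sensitivity),
#'   \code{species_table} (species, class, within-class weight),
#'   \code{p_relevant_direct}, \code{p_relevant_high},
#'   \code{p_relevant_infection}, \code{clinical_culture_daily_rate},
#'   \code{p_clinical_sputum}, \code{cost_params}, \code{p_cost_missing}.
#' @export
generator_params <- function(n_admissions = 2000L, seed = 42L, ...) {
  p <- list(
    n_admissions = as.integer(n_admissions),
    seed = as.integer(seed),
    window_start = as.Date("2021-01-04"),
    window_days = 364L,
    los_log_mean = 1.609,   # median exp(1.609) ~ 5.0 days
    los_log_sd = 1.133,     # quartiles ~ 2.3 / 10.7 days
    los_min = 0.30,
    los_fixed = NULL,
    admission_type_probs = c(medical = 0.56, surgical_elective = 0.15,
                             surgical_emergency = 0.29),
    p_immunocompromised = 0.16,
    p_covid = 0.06,
    p_gi_surgery = 0.05,
    p_readmission = 0.12,
    organism_classes = data.frame(
      class = c("gram_negative", "s_aureus", "yeast", "other_respiratory"),
      prevalence = c(0.73, 0.26, 0.35, 0.14),
      clearance = c(0.11, 0.085, 0.10, 0.14),
      acquisition = c(0.015, 0.010, 0.012, 0.005),
      sens_throat = c(0.50, 0.65, 0.55, 0.55),
      sens_rectum = c(0.73, 0.25, 0.65, 0.02),
      sens_sputum = c(0.55, 0.60, 0.50, 0.65),
      sens_clinical = c(0.27, 0.20, 0.14, 0.13),
      stringsAsFactors = FALSE),
    species_table = data.frame(
      species = c("ECO", "KPN", "PAE", "ECL", "PMI", "SAU", "CAL", "CGL",
                  "HIN", "SPN", "MCA"),
      class = c(rep("gram_negative", 5), "s_aureus", "yeast", "yeast",
                rep("other_respiratory", 3)),
      weight = c(0.40, 0.20, 0.15, 0.15, 0.10, 1, 0.80, 0.20,
                 0.50, 0.30, 0.20),
      stringsAsFactors = FALSE),
    p_relevant_direct = 0.010,
    p_relevant_high = 0.075,
    p_relevant_infection = 0.014,
    clinical_culture_daily_rate = 0.68,
    p_clinical_sputum = 0.35,
    cost_params = list(order_fee = 30, plate_cost = 24, id_unit = 14,
                       ast_unit = 66),
    p_cost_missing = 0.002)
  dots <- list(...)
  unknown <- setdiff(names(dots), names(p))
  if (length(unknown))
    stop("unknown generator parameter(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  p[names(dots)] <- dots
  p$n_admissions <- as.integer(p$n_admissions)

  probs <- c(p$p_immunocompromised, p$p_covid, p$p_gi_surgery,
             p$p_readmission, p$p_relevant_direct, p$p_relevant_high,
             p$p_relevant_infection, p$p_cost_missing,
             p$admission_type_probs,
             p$organism_classes$prevalence, p$organism_classes$clearance,
             p$organism_classes$acquisition,
             unlist(p$organism_classes[c("sens_throat", "sens_rectum",
                                         "sens_sputum", "sens_clinical")]))
  if (any(probs < 0 | probs > 1))
    stop("generator probabilities must lie in [0, 1]", call. = FALSE)
  if (p$p_relevant_direct + p$p_relevant_high + p$p_relevant_infection > 1)
    stop("relevance probabilities must sum to at most 1", call. = FALSE)
  if (p$n_admissions < 1)
    stop("n_admissions must be at least 1", call. = FALSE)
  class(p) <- "sdd_generator_params"
  p
}

# one colonisation episode: fresh species + susceptibility profile +
# relevance label, drawn when a class flips clear -> carried
draw_episode <- function(cls, params) {
  sp_tab <- params$species_table[params$species_table$class == cls, ,
                                 drop = FALSE]
  species <- sample(sp_tab$species, 1, prob = sp_tab$weight)
  u <- stats::runif(1)
  label <- if (u < params$p_relevant_direct) "direct"
    else if (u < params$p_relevant_direct + params$p_relevant_high) "high"
    else if (u < params$p_relevant_direct + params$p_relevant_high +
               params$p_relevant_infection) "infection_related"
    else "none"
  panel <- switch(cls,
    gram_negative = c("C3G", "TOB", "CIP", "COL"),
    s_aureus = c("OXA", "CLI", "TOB"),
    yeast = c("FLU", "AMB"),
    other_respiratory = c("PEN", "C3G"))
  marker <- switch(cls, gram_negative = "C3G", s_aureus = "OXA",
                   yeast = "FLU", other_respiratory = "C3G")
  cats <- stats::setNames(rep("S", length(panel)), panel)
  minor <- setdiff(panel, marker)
  r <- stats::runif(length(minor))
  cats[minor][r < 0.05] <- "R"
  cats[minor][r >= 0.05 & r < 0.07] <- "I"
  if (label %in% c("direct", "high")) {
    cats[marker] <- "R"
    if (label == "direct" && length(minor)) cats[minor[1]] <- "R"
  }
  list(species = species,
       susceptibility = profile_key(cats),
       mdro = label == "direct",
       resistant_standard = label %in% c("direct", "high"),
       infection_related = label == "infection_related",
       topical_target = cls %in% c("gram_negative", "s_aureus", "yeast"),
       relevance = label)
}

#' Simulate a colonisation trajectory for one admission
#'
#' Colonisation is modelled per organism class as an independent two-state
#' daily Markov chain over the calendar days of the stay: initial carriage
#' with the class's admission prevalence, carried-to-clear with the daily
#' clearance probability under SDD, clear-to-carried with the daily
#' acquisition probability. Each carriage episode (maximal run of carried
#' days) draws a fresh species, susceptibility profile and relevance label,
#' so repeated detections of one episode agree in species, profile and
#' relevance.
#'
#' Uses the current RNG state; callers seed a per-admission substream.
#'
#' @param n_days integer: last calendar day index of the stay (day 0 =
#'   admission day), must be \eqn{\ge} 0.
#' @param params an [generator_params()] object.
#' @return data.frame of episodes: \code{class}, \code{start_day},
#'   \code{end_day}, \code{species}, \code{susceptibility}, \code{mdro},
#'   \code{resistant_standard}, \code{infection_related},
#'   \code{topical_target}, \code{relevance}.
#' @export
simulate_carriage <- function(n_days, params) {
  stopifnot(n_days >= 0)
  oc <- params$organism_classes
  eps <- list()
  for (k in seq_len(nrow(oc))) {
    carried <- stats::runif(1) < oc$prevalence[k]
    start <- if (carried) 0L else NA_integer_
    d <- 0L
    while (d < n_days) {
      d <- d + 1L
      if (carried) {
        if (stats::runif(1) < oc$clearance[k]) {
          eps[[length(eps) + 1L]] <- c(list(class = oc$class[k],
                                            start_day = start,
                                            end_day = d - 1L),
                                       draw_episode(oc$class[k], params))
          carried <- FALSE
        }
      } else if (stats::runif(1) < oc$acquisition[k]) {
        carried <- TRUE
        start <- d
      }
    }
    if (carried)
      eps[[length(eps) + 1L]] <- c(list(class = oc$class[k],
                                        start_day = start,
                                        end_day = n_days),
                                   draw_episode(oc$class[k], params))
  }
  if (!length(eps))
    return(data.frame(class = character(), start_day = integer(),
                      end_day = integer(), species = character(),
                      susceptibility = character(), mdro = logical(),
                      resistant_standard = logical(),
                      infection_related = logical(),
                      topical_target = logical(), relevance = character(),
                      stringsAsFactors = FALSE))
  do.call(rbind, lapply(eps, function(e)
    data.frame(e, stringsAsFactors = FALSE)))
}

sens_col <- c(throat = "sens_throat", rectum = "sens_rectum",
              sputum = "sens_sputum", other = "sens_clinical")

#' Generate a synthetic SDD surveillance cohort
#'
#' Forward-simulates ICU admissions under the SDD culturing protocol:
#' admission cultures of throat, rectum and sputum on day 0, surveillance
#' cultures of the three sites on every Monday and Thursday from day 1 until
#' discharge, and clinical cultures at a configurable daily rate throughout
#' the stay. Isolates are sampled from each admission's colonisation
#' trajectory (see [simulate_carriage()]) through per-site culture
#' sensitivities, so admission cultures are more often positive than later
#' surveillance cultures (decontamination clears carriage over days).
#' Per-culture costs follow fixed laboratory tariffs, with a small fraction
#' of cost records missing.
#'
#' Output is deterministic for a fixed seed and invariant to simulation
#' order: every admission draws from its own substream seeded by
#' (master seed, admission id).
#'
#' @param params an [generator_params()] object.
#' @return a valid [sdd_cohort()].
#' @export
#' @examples
#' coh <- generate_cohort(generator_params(n_admissions = 50, seed = 1))
#' coh
generate_cohort <- function(params = generator_params()) {
  if (!inherits(params, "sdd_generator_params"))
    params <- do.call(generator_params, params)
  n <- params$n_admissions
  adm_list <- vector("list", n)
  cul_list <- vector("list", n)
  iso_list <- vector("list", n)

  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))

  for (i in seq_len(n)) {
    aid <- sprintf("A%05d", i)
    set.seed(hash31(aid, seed = params$seed))

    admit_date <- params$window_start +
      sample.int(params$window_days, 1) - 1L
    admit_time <- as.POSIXct(admit_date, tz = "UTC") +
      stats::runif(1, 0, 24) * 3600
    los <- if (!is.null(params$los_fixed)) params$los_fixed
      else max(params$los_min,
               stats::rlnorm(1, params$los_log_mean, params$los_log_sd))
    discharge_time <- admit_time + los * 86400
    sdd_start_time <- min(admit_time + stats::runif(1, 0, 6) * 3600,
                          discharge_time)
    n_days <- as.integer(as.Date(discharge_time) - admit_date)

    is_readm <- i > 1 && stats::runif(1) < params$p_readmission
    adm_list[[i]] <- data.frame(
      admission_id = aid,
      patient_id = sprintf("P%05d", if (is_readm) i - 1L else i),
      admit_time = admit_time,
      discharge_time = discharge_time,
      sdd_start_time = sdd_start_time,
      admission_type = sample(names(params$admission_type_probs), 1,
                              prob = params$admission_type_probs),
      immunocompromised = stats::runif(1) < params$p_immunocompromised,
      covid = stats::runif(1) < params$p_covid,
      gi_surgery = stats::runif(1) < params$p_gi_surgery,
      readmission = is_readm,
      stringsAsFactors = FALSE)

    episodes <- simulate_carriage(n_days, params)

    # culture schedule
    days <- integer(); sites <- character(); cats <- character()
    days <- c(days, rep(0L, 3)); sites <- c(sites, SDD_SITES)
    cats <- c(cats, rep("sdd_admission", 3))
    if (n_days >= 1) {
      for (d in 1:n_days) {
        wd <- wday_num(admit_date + d)
        if (wd %in% c(1L, 4L)) {  # Monday or Thursday
          days <- c(days, rep(d, 3)); sites <- c(sites, SDD_SITES)
          cats <- c(cats, rep("sdd_surveillance", 3))
        }
      }
    }
    for (d in 0:n_days) {
      k <- stats::rpois(1, params$clinical_culture_daily_rate)
      if (k > 0) {
        days <- c(days, rep(d, k))
        sites <- c(sites, ifelse(stats::runif(k) < params$p_clinical_sputum,
                                 "sputum", "other"))
        cats <- c(cats, rep("clinical", k))
      }
    }

    n_cul <- length(days)
    cids <- sprintf("%s-C%03d", aid, seq_len(n_cul))
    n_iso_per_cul <- integer(n_cul)
    iso_rows <- list()
    for (j in seq_len(n_cul)) {
      if (!nrow(episodes)) break
      live <- episodes[episodes$start_day <= days[j] &
                       episodes$end_day >= days[j], , drop = FALSE]
      if (!nrow(live)) next
      oc <- params$organism_classes
      sens <- oc[[sens_col[[sites[j]]]]][match(live$class, oc$class)]
      hit <- stats::runif(nrow(live)) < sens
      if (any(hit)) {
        h <- live[hit, , drop = FALSE]
        h$culture_id <- cids[j]
        iso_rows[[length(iso_rows) + 1L]] <- h
        n_iso_per_cul[j] <- nrow(h)
      }
    }

    cp <- params$cost_params
    # susceptibility testing is done for bacterial isolates only, which is
    # what makes positive cultures (EUR 68 yeast-only, EUR 134+ bacterial)
    # costlier than negatives (EUR 54)
    n_ast <- integer(n_cul)
    n_id <- n_iso_per_cul
    if (length(iso_rows)) {
      allh <- do.call(rbind, iso_rows)
      bact <- allh$class != "yeast"
      t_ast <- table(allh$culture_id[bact])
      n_ast[match(names(t_ast), cids)] <- as.integer(t_ast)
    }
    order_fee <- rep(cp$order_fee, n_cul)
    plate_cost <- rep(cp$plate_cost, n_cul)
    id_cost <- cp$id_unit * n_id
    ast_cost <- cp$ast_unit * n_ast
    miss <- stats::runif(n_cul) < params$p_cost_missing
    order_fee[miss] <- NA; plate_cost[miss] <- NA
    id_cost[miss] <- NA; ast_cost[miss] <- NA

    cul_list[[i]] <- data.frame(
      culture_id = cids,
      admission_id = aid,
      collection_date = admit_date + days,
      site = sites,
      category = cats,
      order_fee = order_fee,
      plate_cost = plate_cost,
      id_cost = id_cost,
      susceptibility_cost = ast_cost,
      stringsAsFactors = FALSE)

    if (length(iso_rows)) {
      allh <- do.call(rbind, iso_rows)
      iso_list[[i]] <- data.frame(
        isolate_id = sprintf("%s-I%04d", aid, seq_len(nrow(allh))),
        culture_id = allh$culture_id,
        species = allh$species,
        susceptibility = allh$susceptibility,
        mdro = allh$mdro,
        resistant_standard = allh$resistant_standard,
        infection_related = allh$infection_related,
        topical_target = allh$topical_target,
        stringsAsFactors = FALSE)
    }
  }

  iso_list <- iso_list[!vapply(iso_list, is.null, TRUE)]
  iso_df <- if (length(iso_list)) do.call(rbind, iso_list) else
    data.frame(isolate_id = character(), culture_id = character(),
               species = character(), susceptibility = character(),
               mdro = logical(), resistant_standard = logical(),
               infection_related = logical(), topical_target = logical(),
               stringsAsFactors = FALSE)
  sdd_cohort(do.call(rbind, adm_list), do.call(rbind, cul_list), iso_df)
}
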