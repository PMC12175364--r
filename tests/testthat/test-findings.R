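test_that("profile keys are canonical", {
  expect_equal(profile_key(c(TOB = "S", C3G = "R")), "C3G:R;TOB:S")
  expect_equal(profile_key(character(0)), "")
  expect_equal(profile_key("TOB:S;C3G:R"), "C3G:R;TOB:S")
  # two maps equal as sets give identical keys
  expect_equal(profile_key(c(A = "S", B = "R", C = "I")),
               profile_key(c(C = "I", A = "S", B = "R")))
  expect_error(profile_key(c(A = "X")), "S,I,R")
})

test_that("profiles differ only on shared-agent disagreement", {
  expect_false(profiles_differ(c(CTX = "R"), c(CTX = "R", TOB = "S")))
  expect_true(profiles_differ(c(CTX = "R"), c(CTX = "S")))
  expect_false(profiles_differ(character(0), c(CTX = "R")))
  # intermediate differs from both S and R
  expect_true(profiles_differ(c(CTX = "I"), c(CTX = "S")))
  expect_true(profiles_differ(c(CTX = "I"), c(CTX = "R")))
  # string inputs are parsed
  expect_true(profiles_differ("CTX:R;TOB:S", "CTX:S"))
})

test_that("relevance classification follows direct > high > infection precedence", {
  expect_equal(classify_relevance(TRUE, TRUE, FALSE), "direct")
  expect_equal(classify_relevance(FALSE, TRUE, TRUE), "high")
  expect_equal(classify_relevance(FALSE, FALSE, TRUE), "infection_related")
  expect_equal(classify_relevance(FALSE, FALSE, FALSE), "none")
  expect_equal(classify_relevance(c(TRUE, FALSE), c(TRUE, FALSE),
                                  c(FALSE, TRUE)),
               c("direct", "infection_related"))
})

test_that("multi-site and same-day repeats collapse to one finding", {
  adm <- tiny_admissions()
  cultures <- rbind(
    tiny_culture("R2", "A1", "2021-01-06", "rectum", "sdd_surveillance"),
    tiny_culture("T2", "A1", "2021-01-06", "throat", "sdd_surveillance"),
    tiny_culture("S5", "A1", "2021-01-09", "sputum", "sdd_surveillance"))
  isolates <- rbind(
    tiny_isolate("i1", "R2", "ECO", "C3G:S"),
    tiny_isolate("i2", "T2", "ECO", "C3G:S"),
    tiny_isolate("i3", "S5", "ECO", "C3G:S"))
  coh <- sdd_cohort(adm, cultures, isolates)
  f <- extract_new_findings(coh$cultures, coh$isolates)
  expect_equal(nrow(f), 1)
  expect_equal(f$first_date, as.Date("2021-01-06"))
  expect_equal(f$source_category, "sdd")
  expect_setequal(strsplit(f$source_culture_ids, "|", fixed = TRUE)[[1]],
                  c("R2", "T2"))
})

test_that("a differing susceptibility profile is a new finding", {
  adm <- tiny_admissions()
  cultures <- rbind(
    tiny_culture("c1", "A1", "2021-01-06", "rectum", "sdd_surveillance"),
    tiny_culture("c2", "A1", "2021-01-10", "rectum", "sdd_surveillance"))
  isolates <- rbind(
    tiny_isolate("i1", "c1", "ECO", "C3G:S"),
    tiny_isolate("i2", "c2", "ECO", "C3G:R", resistant_standard = TRUE))
  coh <- sdd_cohort(adm, cultures, isolates)
  f <- extract_new_findings(coh$cultures, coh$isolates)
  expect_equal(nrow(f), 2)
  expect_setequal(f$relevance, c("none", "high"))
})

test_that("same-day clinical source wins over the SDD culture", {
  adm <- tiny_admissions()
  cultures <- rbind(
    tiny_culture("sdd1", "A1", "2021-01-07", "sputum", "sdd_surveillance"),
    tiny_culture("cli1", "A1", "2021-01-07", "other", "clinical"))
  isolates <- rbind(
    tiny_isolate("i1", "sdd1", "SAU", "OXA:S"),
    tiny_isolate("i2", "cli1", "SAU", "OXA:S"))
  coh <- sdd_cohort(adm, cultures, isolates)
  f <- extract_new_findings(coh$cultures, coh$isolates)
  expect_equal(nrow(f), 1)
  expect_equal(f$source_category, "clinical")
})

test_that("finding extraction matches the brute-force oracle on random cohorts", {
  for (seed in 1:25) {
    coh <- random_small_cohort(seed, n = 4)
    f <- extract_new_findings(coh$cultures, coh$isolates)
    o <- oracle_findings(coh$cultures, coh$isolates)
    f2 <- f[order(f$admission_id, f$first_date, f$species), ]
    expect_equal(nrow(f), nrow(o), info = paste("seed", seed))
    expect_equal(paste(f2$admission_id, f2$species, f2$first_date),
                 paste(o$admission_id, o$species, o$first_date),
                 info = paste("seed", seed))
  }
})

test_that("dedup is idempotent on its own source cultures", {
  coh <- random_small_cohort(101, n = 8)
  f1 <- extract_new_findings(coh$cultures, coh$isolates)
  src <- unique(unlist(strsplit(f1$source_culture_ids, "|", fixed = TRUE)))
  cul2 <- coh$cultures[coh$cultures$culture_id %in% src, , drop = FALSE]
  f2 <- extract_new_findings(cul2, coh$isolates)
  key <- function(f) sort(paste(f$admission_id, f$species, f$profile_key,
                                f$first_date))
  expect_equal(key(f2), key(f1))
})

test_that("relevance counts partition the findings", {
  coh <- random_small_cohort(7, n = 40)
  f <- extract_new_findings(coh$cultures, coh$isolates)
  tab <- table(factor(f$relevance, levels = c("direct", "high",
                                              "infection_related", "none")))
  expect_equal(sum(tab), nrow(f))
})

test_that("detection rates are per 1,000 days and duplication-invariant", {
  expect_equal(detection_rate(90, 1000), 90)
  expect_equal(round_half_up(detection_rate(70103, 76964)), 911)
  expect_equal(detection_rate(0, 500), 0)
  expect_error(detection_rate(1, 0), "positive")
  expect_equal(detection_rate(2 * 90, 2 * 1000), detection_rate(90, 1000))
})

test_that("relative yield reproduces worked percentages", {
  expect_equal(relative_yield(85, 90), 94)
  expect_equal(relative_yield(77, 90), 86)
  expect_equal(relative_yield(42, 42), 100)
  expect_error(relative_yield(1, 0), "positive")
})

test_that("delay analysis classifies missed, delayed and same-day findings", {
  ref <- data.frame(admission_id = c("A1", "A1", "A2"),
                    species = c("ECO", "KPN", "SAU"),
                    profile_key = c("", "", ""),
                    first_date = as.Date(c("2021-01-02", "2021-01-02",
                                           "2021-01-03")),
                    stringsAsFactors = FALSE)
  red <- ref[-2, ]
  red$first_date[1] <- as.Date("2021-01-05")
  d <- delay_analysis(ref, red)
  expect_equal(d$n_missed, 1)
  expect_equal(d$n_delayed, 1)
  expect_equal(d$n_same_day, 1)
  expect_equal(d$median_delay, 3)
  expect_equal(d$n_missed + d$n_delayed + d$n_same_day, nrow(ref))

  ident <- delay_analysis(ref, ref)
  expect_equal(ident$n_missed, 0)
  expect_equal(ident$n_delayed, 0)
  expect_equal(ident$n_same_day, 3)
})
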