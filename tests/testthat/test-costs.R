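test_that("culture totals are exact component sums", {
  expect_equal(culture_total_cost(30, 24, 0, 0), 54)
  expect_equal(culture_total_cost(30, 24, 10, 70), 134)
  expect_equal(culture_total_cost(0, 0, 0, 0), 0)
  expect_error(culture_total_cost(30, NA, 0, 0), "missing")
  expect_error(culture_total_cost(-1, 24, 0, 0), "negative")
})

test_that("missing costs are imputed with the stratum median", {
  adm <- tiny_admissions()
  cul <- rbind(
    tiny_culture("n1", "A1", "2021-01-04", "throat", "sdd_admission",
                 26, 24, 0, 0),
    tiny_culture("n2", "A1", "2021-01-04", "rectum", "sdd_admission",
                 30, 30, 0, 0),
    tiny_culture("n3", "A1", "2021-01-07", "rectum", "sdd_surveillance",
                 40, 30, 0, 0),
    tiny_culture("n4", "A2", "2021-01-06", "sputum", "sdd_admission",
                 NA, NA, NA, NA),
    tiny_culture("p1", "A1", "2021-01-11", "throat", "sdd_surveillance",
                 30, 24, 14, 66),
    tiny_culture("p2", "A2", "2021-01-07", "sputum", "sdd_surveillance",
                 NA, NA, NA, NA))
  iso <- tiny_isolate("i1", "p1", "ECO", "C3G:S")
  iso <- rbind(iso, tiny_isolate("i2", "p2", "ECO", "C3G:S"))
  out <- impute_missing_costs(cul, iso)
  # negative donors 50, 60, 70 -> imputed 60; positive donor 134
  expect_equal(out$cost_total[out$culture_id == "n4"], 60)
  expect_equal(out$cost_total[out$culture_id == "p2"], 134)
  expect_equal(sum(out$cost_imputed), 2)
  # non-missing untouched
  expect_equal(out$cost_total[out$culture_id == "n1"], 50)

  # no missing -> identity
  full <- impute_missing_costs(cul[1:3, ], iso)
  expect_false(any(full$cost_imputed))
  expect_equal(full$cost_total, c(50, 60, 70))

  # a stratum with missing values but no donors fails loudly
  only_missing_pos <- cul[cul$culture_id %in% c("n1", "p2"), ]
  expect_error(impute_missing_costs(only_missing_pos, iso), "positive")
})

test_that("imputation preserves stratum medians on randomized fixtures", {
  withr::local_seed(31)
  for (rep in 1:20) {
    n <- 60
    pos <- runif(n) < 0.4
    totals <- ifelse(pos, 54 + sample(c(14, 80), n, replace = TRUE), 54)
    totals <- totals + sample(0:25, n, replace = TRUE)
    miss <- runif(n) < 0.15
    # keep at least one donor per stratum
    miss[which(pos)[1]] <- FALSE
    miss[which(!pos)[1]] <- FALSE
    cul <- tiny_culture(sprintf("c%03d", 1:n), "A1", "2021-01-04",
                        "throat", "sdd_admission",
                        order_fee = ifelse(miss, NA, totals),
                        plate_cost = ifelse(miss, NA, 0),
                        id_cost = ifelse(miss, NA, 0),
                        susceptibility_cost = ifelse(miss, NA, 0))
    iso <- do.call(rbind, lapply(which(pos), function(i)
      tiny_isolate(paste0("i", i), sprintf("c%03d", i), "ECO", "")))
    out <- impute_missing_costs(cul, iso)
    for (stratum in c(TRUE, FALSE)) {
      donors <- totals[!miss & pos == stratum]
      expect_equal(median(out$cost_total[pos == stratum]),
                   median(c(donors, rep(median(donors),
                                        sum(miss & pos == stratum)))))
    }
    expect_equal(sum(out$cost_imputed), sum(miss))
  }
})

test_that("cost summaries aggregate totals, medians and per-finding cost", {
  adm <- tiny_admissions()
  cul <- rbind(
    tiny_culture("c1", "A1", "2021-01-04", "throat", "sdd_admission",
                 30, 24, 0, 0),
    tiny_culture("c2", "A1", "2021-01-07", "rectum", "sdd_surveillance",
                 30, 24, 14, 66),
    tiny_culture("c3", "A2", "2021-01-06", "sputum", "sdd_admission",
                 30, 24, 14, 0))
  cul <- impute_missing_costs(cul, tiny_cohort()$isolates[0, ])
  cs <- cost_summary(cul, adm, n_relevant_findings = 2,
                     total_icu_days = 100)
  expect_equal(cs$total_cost, 54 + 134 + 68)
  expect_equal(cs$cost_per_1000_days, 2560)
  expect_equal(cs$cost_per_relevant_finding, 128)
  expect_equal(cs$median_per_culture, 68)
  expect_equal(cs$n_cultures, 3)
  # zero relevant findings: undefined, not infinite
  cs0 <- cost_summary(cul, adm, 0, 100)
  expect_true(is.na(cs0$cost_per_relevant_finding))

  single <- cost_summary(cul[1, ], adm[1, ], 1, 10)
  expect_equal(single$total_cost, 54)
  expect_equal(single$mean_per_culture, 54)
  expect_equal(single$median_per_culture, 54)
})

test_that("scenario costs are monotone A >= B >= C", {
  coh <- generate_cohort(generator_params(n_admissions = 120, seed = 55))
  totals <- vapply(c("A", "B", "C"), function(sc) {
    cul <- apply_scenario(coh, sc, seed = 2)
    cul <- impute_missing_costs(cul[cul$category != "clinical", ],
                                coh$isolates)
    sum(cul$cost_total)
  }, numeric(1))
  expect_true(totals["A"] >= totals["B"] && totals["B"] >= totals["C"])
})

test_that("cost reduction percentages reproduce worked values", {
  expect_equal(cost_reduction_percent(55208, 78774), 30)
  expect_equal(cost_reduction_percent(31522, 78774), 60)
  expect_equal(cost_reduction_percent(5, 5), 0)
  expect_error(cost_reduction_percent(1, 0), "positive")
})
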