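scr_series <- function(days, values, origin = as.Date("2015-03-01")) {
  data.frame(date = origin + days, value = values)
}

test_that("AKI detection applies the 2 x ULN threshold inside follow-up", {
  idx <- as.Date("2015-03-01")
  # 2.4 mg/dL = 2 x ULN (1.2) triggers on its first occurrence
  s <- scr_series(c(5, 10, 20), c(1.0, 1.1, 2.4))
  expect_equal(detect_aki(s, idx), idx + 20)
  # just below threshold never triggers
  s2 <- scr_series(c(5, 30, 59), c(2.3, 2.39, 2.3))
  expect_null(detect_aki(s2, idx))
  # day 60 is inside the window, day 61 outside
  expect_equal(detect_aki(scr_series(60, 2.4), idx), idx + 60)
  expect_null(detect_aki(scr_series(61, 2.4), idx))
  # a spike on the index date itself is not attributed to the drug
  expect_null(detect_aki(scr_series(0, 3.0), idx))
  expect_error(detect_aki(scr_series(c(10, 5), c(1, 1)), idx), "sorted")
})

test_that("observed-mean baseline policy caps the baseline at the ULN", {
  idx <- as.Date("2015-03-01")
  cr <- aki_criteria(baseline_policy = "observed_mean_capped")
  # pre-index mean 0.8 -> threshold 1.6; a 1.7 reading is an event
  s <- scr_series(c(-20, -10, 15), c(0.8, 0.8, 1.7))
  expect_equal(detect_aki(s, idx, cr), idx + 15)
  # under the fixed-ULN policy the same series is below 2.4
  expect_null(detect_aki(s, idx, aki_criteria()))
})

test_that("AKI detection is translation invariant", {
  idx <- as.Date("2015-03-01")
  s <- scr_series(c(-30, -10, 8, 25), c(1.0, 1.1, 1.3, 2.6))
  base <- detect_aki(s, idx)
  for (k in c(-40L, 11L, 365L)) {
    shifted <- s
    shifted$date <- shifted$date + k
    expect_equal(detect_aki(shifted, idx + k), base + k)
  }
})

test_that("index date is the first exposure and absent drugs yield empty maps", {
  b <- shared_bundle(n = 200, seed = 3)
  idx <- index_dates(b, "vancomycin")
  exposed <- unique(b$drug_exposure$person_id[
    b$drug_exposure$drug_label == "vancomycin"])
  expect_length(idx, length(exposed))
  # repeat exposures exist a week after index; the minimum is kept
  de <- b$drug_exposure[b$drug_exposure$drug_label == "vancomycin", ]
  for (p in names(idx)[1:5]) {
    expect_equal(unname(idx[p]), min(de$start_date[de$person_id == p]))
  }
  expect_length(index_dates(b, "no_such_drug"), 0)
})

test_that("exclusion reasons are assigned in the documented order", {
  b <- shared_bundle(n = 400, seed = 8, spoiler_frac = 0.15)
  co <- apply_eligibility(b, "vancomycin")
  tr <- attr(b, "truth")
  m <- merge(co, tr, by = "person_id")
  sp <- m$spoiler != "none"
  expect_true(all(m$exclusion_reason[sp] == m$spoiler[sp]))
  expect_true(all(is.na(m$exclusion_reason[!sp])))
  # partition: every exposed person is labelled xor excluded
  expect_equal(nrow(co), sum(!is.na(co$label)) + sum(!is.na(co$exclusion_reason)))
  expect_false(any(!is.na(co$label) & !is.na(co$exclusion_reason)))
})

test_that("spoiler-free bundles pass eligibility in full and recover the planted rate", {
  b <- shared_bundle(n = 600, seed = 42)
  co <- apply_eligibility(b, "vancomycin")
  expect_equal(sum(!is.na(co$exclusion_reason)), 0)
  # labels agree with the planted truth person by person
  tr <- attr(b, "truth")
  m <- merge(co, tr, by = "person_id")
  expect_true(all((m$label == "case") == m$is_case))
  expect_true(all(m$onset_day.x[m$label == "case"] ==
                    m$onset_day.y[m$label == "case"]))
  # case fraction within binomial error of the planted 0.12
  phat <- mean(co$label == "case")
  expect_lt(abs(phat - 0.12), 3 * sqrt(0.12 * 0.88 / nrow(co)))
})

test_that("raising the fold-change ratio never converts controls into cases", {
  b <- shared_bundle(n = 300, seed = 15)
  co2 <- apply_eligibility(b, "vancomycin", aki_criteria(ratio = 2))
  co3 <- apply_eligibility(b, "vancomycin", aki_criteria(ratio = 3))
  m <- merge(co2, co3, by = "person_id", suffixes = c("_2", "_3"))
  expect_false(any(m$label_2 == "control" & m$label_3 == "case", na.rm = TRUE))
})

test_that("pooled summary statistics reproduce direct computation", {
  set.seed(1)
  groups <- list(rnorm(40, 5), rnorm(25, 7, 2), rnorm(60, 6, 0.5))
  n <- lengths(groups)
  m <- vapply(groups, mean, numeric(1))
  s <- vapply(groups, sd, numeric(1))
  pooled <- pool_summary_stats(n, m, s)
  all_x <- unlist(groups)
  expect_equal(unname(pooled["n"]), length(all_x))
  expect_equal(unname(pooled["mean"]), mean(all_x))
  expect_equal(unname(pooled["sd"]), sd(all_x))
  pc <- pool_counts(c(10, 5), c(100, 60))
  expect_equal(unname(pc["pct"]), round(100 * 15 / 160, 2))
})

test_that("demographics table summarises groups and pools across sites", {
  b <- shared_bundle(n = 400, seed = 23)
  co <- apply_eligibility(b, "vancomycin")
  dem <- demographics_table(co, b)
  n_case <- sum(co$label == "case", na.rm = TRUE)
  expect_equal(dem$value[dem$characteristic == "n" & dem$group == "case" &
                           dem$site == "T1"], n_case)
  expect_equal(dem$value[dem$characteristic == "n" & dem$group == "case" &
                           dem$site == "pooled"], n_case)
  male_row <- dem[dem$characteristic == "male" & dem$group == "control" &
                    dem$site == "T1", ]
  expect_equal(male_row$value2, round(100 * male_row$value / male_row$n, 2))
  age_row <- dem[dem$characteristic == "age" & dem$group == "case" &
                   dem$site == "T1", ]
  expect_gt(age_row$value, 55)  # confounding makes cases older
})
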