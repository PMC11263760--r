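test_that("paired t statistic matches the formula and stats::t.test", {
  d <- c(1, 1, 2)
  res <- paired_t(d + 10, rep(10, 3))
  expect_equal(res$statistic, 4.0, tolerance = 1e-12)
  expect_equal(res$df, 2)
  set.seed(4)
  x <- rnorm(30); y <- rnorm(30)
  mine <- paired_t(x, y)
  ref <- t.test(x, y, paired = TRUE)
  expect_equal(mine$statistic, unname(ref$statistic), tolerance = 1e-12)
  expect_equal(mine$p_value, ref$p.value, tolerance = 1e-12)
  # one-sample t on differences is the same thing
  ref1 <- t.test(x - y)
  expect_equal(mine$p_value, ref1$p.value, tolerance = 1e-12)
  expect_warning(res0 <- paired_t(1:5, 1:5), "zero-variance")
  expect_equal(res0$p_value, 1)
})

test_that("McNemar statistic matches the formula and stats::mcnemar.test", {
  expect_equal(mcnemar_paired(5, 5)$statistic, 0)
  expect_equal(mcnemar_paired(5, 5)$p_value, 1)
  res <- mcnemar_paired(10, 2)
  expect_equal(res$statistic, 16 / 3, tolerance = 1e-12)
  ref <- mcnemar.test(matrix(c(30, 2, 10, 30), 2, 2), correct = FALSE)
  expect_equal(res$statistic, unname(ref$statistic), tolerance = 1e-12)
  expect_equal(res$p_value, ref$p.value, tolerance = 1e-12)
  expect_equal(mcnemar_paired(0, 0)$p_value, 1)
  expect_error(mcnemar_paired(-1, 2), "non-negative")
})

test_that("daily grids forward-fill labs and zero-fill exposures", {
  b <- shared_bundle(n = 60, seed = 19)
  co <- apply_eligibility(b, "vancomycin")
  grid <- suppressWarnings(build_grid(b, co))
  vars <- attr(grid, "variables")
  expect_true(all(vapply(grid, function(M) !anyNA(M), logical(1))))
  bin_cols <- vars$variable[vars$kind != "lab"]
  for (M in grid[1:5]) {
    expect_true(all(M[, bin_cols] %in% c(0, 1)))
    # forward fill is idempotent: re-filling observed values changes nothing
    for (v in vars$variable[vars$kind == "lab"][1:3]) {
      refill <- approx(seq_len(nrow(M)), M[, v], xout = seq_len(nrow(M)),
                       method = "constant", rule = 2)$y
      expect_equal(refill, unname(M[, v]))
    }
  }
  # target drug column: 1 exactly on exposure days (day 0 and any repeat)
  p <- co$person_id[!is.na(co$label)][1]
  de <- b$drug_exposure[b$drug_exposure$person_id == p &
                          b$drug_exposure$drug_label == "vancomycin", ]
  rel <- as.integer(de$start_date - co$index_date[co$person_id == p])
  M <- grid[[p]]
  expect_equal(unname(which(M[, "vancomycin"] == 1)) - 1L,
               sort(unique(rel[rel >= 0 & rel <= 60])))
})

test_that("explicit fill semantics on a hand-built series", {
  # lab observed on day 0 (5.0) and day 3 (7.0): days 1-2 carry 5.0
  b <- shared_bundle(n = 60, seed = 19)
  co <- apply_eligibility(b, "vancomycin")
  p <- co$person_id[!is.na(co$label)][1]
  idx <- co$index_date[co$person_id == p]
  tiny <- b
  tiny$measurement <- data.frame(
    person_id = p, variable_label = "scr",
    date = idx + c(0, 3), value = c(5, 7), unit = "mg/dL")
  g <- suppressWarnings(build_grid(tiny, co[co$person_id == p, ],
                                   variables = data.frame(variable = "scr",
                                                          kind = "lab"),
                                   day_min = 0, day_max = 6))
  expect_equal(unname(g[[p]][, "scr"]), c(5, 5, 5, 7, 7, 7, 7))
})

test_that("window slicing obeys the count formula, onset truncation and labelling", {
  # L = 56 days -> 3 windows for a control
  w <- make_windows(toy_grid(60), toy_cohort_row(), followup_days = 56)
  expect_equal(length(w$labels), 3)
  expect_true(all(w$labels == 0))
  expect_equal(w$meta$start_day, c(0, 14, 28))
  # case with onset on day 40: only the day-0 window fits, and it is positive
  cr <- toy_cohort_row(label = "case", onset_day = 40L)
  wc <- make_windows(toy_grid(60), cr)
  expect_equal(wc$meta$start_day, 0)
  expect_equal(wc$labels, 1L)
  # onset beyond the horizon: window emitted but negative
  wf <- make_windows(toy_grid(60), toy_cohort_row(label = "case", onset_day = 58L))
  expect_equal(wf$labels, c(0L, 0L, 1L))  # 58 lies in (56, 70] only
  # spans shorter than one window produce nothing
  expect_equal(length(make_windows(toy_grid(20), toy_cohort_row(),
                                   followup_days = 20)$labels), 0)
  # count formula agrees with enumeration for every span up to 120 days
  g120 <- toy_grid(120)
  for (L in 0:120) {
    emitted <- length(make_windows(g120, toy_cohort_row(),
                                   followup_days = L)$labels)
    expect_identical(emitted, as.integer(window_count(L)))
  }
})

test_that("windows never contain post-onset days", {
  b <- shared_bundle(n = 300, seed = 42)
  co <- apply_eligibility(b, "vancomycin")
  grid <- suppressWarnings(build_grid(b, co))
  w <- make_windows(grid, co)
  cases <- co[!is.na(co$label) & co$label == "case", ]
  onset <- stats::setNames(cases$onset_day, cases$person_id)
  case_meta <- w$meta[w$meta$person_id %in% cases$person_id, ]
  expect_true(all(case_meta$start_day + 28 <= onset[case_meta$person_id]))
})

test_that("planted drift variables are selected and flat ones are not", {
  b <- shared_bundle(n = 500, seed = 27)
  co <- apply_eligibility(b, "vancomycin")
  grid <- suppressWarnings(build_grid(b, co))
  sel <- suppressWarnings(select_predictors(co, grid))
  # the strongly drifted labs are picked up in a single cohort
  expect_true(all(sel$selected[sel$variable %in%
                                 c("lymphocytes", "hemoglobin",
                                   "prothrombin_time")]))
  expect_true(all(sel$p_value >= 0 & sel$p_value <= 1))
  # a variable identical at index and onset is never selected
  flat <- grid
  for (p in names(flat)) flat[[p]][, "cholesterol"] <- 3.14
  sel2 <- suppressWarnings(select_predictors(co, flat))
  expect_false(sel2$selected[sel2$variable == "cholesterol"])
})

test_that("selection power and false-positive rate behave across seeded runs", {
  drift_hits <- 0L; noise_hits <- 0L
  for (r in 1:10) {
    b <- shared_bundle(n = 600, seed = 1300 + r)
    co <- apply_eligibility(b, "vancomycin")
    grid <- suppressWarnings(build_grid(b, co))
    sel <- suppressWarnings(select_predictors(co, grid))
    drift_hits <- drift_hits + sel$selected[sel$variable == "lymphocytes"]
    noise_hits <- noise_hits + sel$selected[sel$variable == "calcium"]
  }
  expect_gte(drift_hits, 9)   # planted drift found in >= 90% of runs
  expect_lte(noise_hits, 3)   # undrifted lab selected at roughly alpha rate
})

test_that("6:2:2 split is person-level, stratified and exactly proportioned", {
  w <- make_planted_windows(400, seed = 8)
  sp <- split_622(w, seed = 3)
  pid <- lapply(sp, function(s) unique(s$meta$person_id))
  expect_length(intersect(pid$train, pid$validation), 0)
  expect_length(intersect(pid$train, pid$test), 0)
  expect_length(intersect(pid$validation, pid$test), 0)
  n <- lengths(pid)
  expect_lte(max(abs(n[c("validation", "test")] - 0.2 * sum(n))), 1)
  # stratification keeps the case mix within 10 points in every split
  frac <- vapply(sp, function(s) mean(s$labels), numeric(1))
  expect_true(all(abs(frac - mean(w$labels)) < 0.10))
  # ten persons split exactly 6/2/2
  w10 <- make_planted_windows(10, seed = 1)
  n10 <- lengths(lapply(split_622(w10, seed = 2), function(s)
    unique(s$meta$person_id)))
  expect_setequal(unname(n10), c(6, 2, 2))
})
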