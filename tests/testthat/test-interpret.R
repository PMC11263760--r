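test_that("attention aggregation matches the weighted-average oracle", {
  set.seed(51)
  N <- 10; V <- 4; Tt <- 28
  alphas <- array(0, c(N, V, Tt))
  for (s in 1:N) for (v in 1:V) {
    e <- rexp(Tt)
    alphas[s, v, ] <- e / sum(e)
  }
  betas <- matrix(rexp(N * V), N, V)
  betas <- betas / rowSums(betas)
  agg <- aggregate_attention(alphas, betas, variables = paste0("v", 1:V))
  want <- oracle_aggregate(alphas, betas)
  rownames(want) <- paste0("v", 1:V)
  expect_equal(agg$daily, want[rownames(agg$daily), ], tolerance = 1e-12)
  # permutation invariance over samples
  perm <- sample(N)
  agg2 <- aggregate_attention(alphas[perm, , , drop = FALSE],
                              betas[perm, , drop = FALSE],
                              variables = paste0("v", 1:V))
  expect_equal(agg2$daily, agg$daily, tolerance = 1e-12)
  # weekly binning preserves the per-variable mean when T is a multiple of 7
  expect_equal(rowMeans(agg$weekly), rowMeans(agg$daily), tolerance = 1e-12)
})

test_that("attention aggregation degenerate weights behave as stated", {
  a1 <- matrix(c(0.2, 0.8, 0.5, 0.5), 2, 2, byrow = TRUE)
  a2 <- matrix(c(0.9, 0.1, 0.3, 0.7), 2, 2, byrow = TRUE)
  # single sample: weights cancel
  one <- aggregate_attention(list(a1), list(c(0.6, 0.4)))
  expect_equal(unname(one$daily[order(-c(0.6, 0.4)), ][1, ]), a1[1, ])
  # two samples with beta weights 1 and 0 for a variable: first sample wins
  two <- aggregate_attention(list(a1, a2), list(c(1, 0.5), c(0, 0.5)))
  v1_row <- two$daily[which(abs(two$overall - 0.5) < 1e-9), , drop = FALSE]
  expect_equal(unname(v1_row[1, ]), a1[1, ])
  # unweighted flag takes the plain mean
  un <- aggregate_attention(list(a1, a2), list(c(1, 0.5), c(0, 0.5)),
                            weighting = "unweighted")
  expect_equal(sort(un$daily[, 1]), sort((a1[, 1] + a2[, 1]) / 2))
})

test_that("repeated-measures ANOVA matches hand sums of squares and aov", {
  # identical columns: no time effect
  flat <- matrix(rep(c(1, 5, 9), 3), 3, 3)
  r0 <- repeated_anova(flat)
  expect_equal(r0$statistic, 0)
  expect_equal(r0$p_value, 1)
  # constant within-subject differences: zero error mean square
  rinf <- repeated_anova(matrix(c(1, 2, 2, 3, 3, 4), 3, 2, byrow = TRUE))
  expect_identical(rinf$statistic, Inf)
  expect_identical(rinf$p_value, 0)
  # random matrix against aov(Error(subject))
  set.seed(61)
  n <- 12; k <- 4
  m <- matrix(rnorm(n * k), n, k) + rnorm(n)  # subject effects
  mine <- repeated_anova(m)
  df <- data.frame(y = as.vector(m),
                   subject = factor(rep(1:n, k)),
                   time = factor(rep(1:k, each = n)))
  fit <- summary(aov(y ~ time + Error(subject), data = df))
  ref <- fit[["Error: Within"]][[1]]
  expect_equal(mine$statistic, ref["time", "F value"], tolerance = 1e-10)
  expect_equal(mine$p_value, ref["time", "Pr(>F)"], tolerance = 1e-10)
  expect_error(repeated_anova(matrix(c(1, NA, 2, 3), 2, 2)), "complete")
})

test_that("onset statistics report medians, IQRs and the small-cell rule", {
  co <- toy_cohort_row()[0, ]
  add_case <- function(co, p, drug, site, onset) {
    rbind(co, data.frame(person_id = p, site_id = site, drug = drug,
                         index_date = as.Date("2015-03-01"), label = "case",
                         aki_onset_date = as.Date("2015-03-01") + onset,
                         onset_day = onset, exclusion_reason = NA))
  }
  for (i in 1:25) co <- add_case(co, paste0("a", i), "drugA", "S1",
                                 c(5, 12, 25)[1 + (i %% 3)])
  for (i in 1:5) co <- add_case(co, paste0("b", i), "drugB", "S1", 30 + i)
  st <- onset_stats(co, min_n = 20)
  expect_equal(st$by_drug$drug, "drugA")  # drugB cell dropped (< 20 cases)
  expect_equal(st$overall$n, 30)
  # odd-length median fixture
  st3 <- onset_stats(add_case(co[0, ], "x1", "d", "s", 5) |>
                       add_case("x2", "d", "s", 12) |>
                       add_case("x3", "d", "s", 25), min_n = 1)
  expect_equal(st3$overall$median, 12)
})

test_that("onset medians recover the generator's configured distribution", {
  b <- shared_bundle(n = 2000, seed = 77, drug = "vancomycin")
  co <- apply_eligibility(b, "vancomycin")
  st <- onset_stats(co)
  expect_lt(abs(st$by_drug$median[st$by_drug$drug == "vancomycin"] - 12), 2)
})

test_that("group tests reproduce Pearson chi-squared and Welch t", {
  # hand-computed 2x2: [[20,10],[10,20]] -> chi2 = 20/3
  g <- rep(c(0, 1), each = 30)
  x <- c(rep(1, 20), rep(0, 10), rep(1, 10), rep(0, 20))
  res <- group_tests(data.frame(flag = x), g)
  expect_equal(res$statistic, 20 / 3, tolerance = 1e-12)
  ref <- chisq.test(table(x, g), correct = FALSE)
  expect_equal(res$p_value, ref$p.value, tolerance = 1e-12)
  # Welch t on a planted one-SD shift is decisive at n = 100 per group
  set.seed(71)
  cont <- data.frame(lab = c(rnorm(100, 0), rnorm(100, 1)))
  res2 <- group_tests(cont, rep(c(0, 1), each = 100))
  expect_lt(res2$p_value, 1e-6)
  ref2 <- t.test(cont$lab ~ rep(c(0, 1), each = 100))
  expect_equal(res2$p_value, ref2$p.value, tolerance = 1e-12)
  # identical flag distributions in both groups: no association
  same <- data.frame(flag = rep(c(0, 1), 200))
  res3 <- group_tests(same, rep(c(0, 1), each = 200))
  expect_gt(res3$p_value, 0.9)
})

test_that("heat-map export writes a sorted CSV deterministically", {
  set.seed(81)
  alphas <- array(rexp(6 * 3 * 28), c(6, 3, 28))
  for (s in 1:6) for (v in 1:3) alphas[s, v, ] <- alphas[s, v, ] / sum(alphas[s, v, ])
  betas <- matrix(rexp(18), 6, 3)
  betas <- betas / rowSums(betas)
  agg <- aggregate_attention(alphas, betas, variables = c("lymph", "alb", "hgb"))
  dir <- withr::local_tempdir()
  files <- export_heatmap(agg, file.path(dir, "att"))
  expect_true(file.exists(file.path(dir, "att.csv")))
  expect_true(file.exists(file.path(dir, "att.png")))
  tab <- read.csv(file.path(dir, "att.csv"), check.names = FALSE)
  expect_equal(nrow(tab), 3)
  expect_equal(tab$variable[1], names(which.max(agg$overall)))
  expect_true(all(diff(tab$overall) <= 0))
  # re-export is byte-identical
  export_heatmap(agg, file.path(dir, "att2"))
  expect_identical(readLines(file.path(dir, "att.csv")),
                   readLines(file.path(dir, "att2.csv")))
})
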