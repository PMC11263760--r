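# Attention aggregation into the temporal feature-importance surface,
# within-subject and group statistics, and onset-time summaries.

#' Aggregate attention across windows
#'
#' Pools per-window temporal attention `alpha` (V x T) and variable
#' attention `beta` (V) into one surface. The default `"beta_weighted"`
#' aggregation is `S[v,t] = sum_s beta_s[v] alpha_s[v,t] / sum_s beta_s[v]`
#' (each window's temporal profile weighted by how much that window's
#' prediction relied on the variable); `"unweighted"` is the plain mean of
#' `alpha` over windows. Daily scores are then binned into 4 weekly means
#' (weeks -4..-1 before the window end).
#'
#' @param alphas N x V x T array (or list of V x T matrices).
#' @param betas N x V matrix (or list of length-V vectors).
#' @param variables Optional variable names.
#' @param weighting `"beta_weighted"` or `"unweighted"`.
#' @return An `attention_summary`: `daily` (V x T), `weekly` (V x weeks),
#'   `overall` (per-variable mean beta), sorted by `overall` descending.
#' @export
aggregate_attention <- function(alphas, betas, variables = NULL,
                                weighting = c("beta_weighted", "unweighted")) {
  weighting <- match.arg(weighting)
  if (is.list(alphas)) {
    Tt <- ncol(alphas[[1]]); V <- nrow(alphas[[1]])
    arr <- array(0, c(length(alphas), V, Tt))
    for (i in seq_along(alphas)) arr[i, , ] <- alphas[[i]]
    alphas <- arr
    betas <- do.call(rbind, betas)
  }
  N <- dim(alphas)[1]; V <- dim(alphas)[2]; Tt <- dim(alphas)[3]
  if (!all(dim(betas) == c(N, V))) stop_contract("alpha/beta dimensions differ")
  daily <- matrix(0, V, Tt)
  drop_rows <- logical(V)
  for (v in seq_len(V)) {
    if (weighting == "beta_weighted") {
      w <- betas[, v]
      if (sum(w) == 0) {
        warning("all-zero beta for variable ", v, "; row omitted")
        drop_rows[v] <- TRUE
        next
      }
      daily[v, ] <- colSums(w * matrix(alphas[, v, ], N, Tt)) / sum(w)
    } else {
      daily[v, ] <- colMeans(matrix(alphas[, v, ], N, Tt))
    }
  }
  overall <- colMeans(betas)
  if (!is.null(variables)) {
    rownames(daily) <- variables
    names(overall) <- variables
  }
  n_week <- Tt %/% 7L
  wk_names <- if (n_week > 0L) paste0("week_", seq(-n_week, -1L)) else character(0)
  weekly <- matrix(0, V, n_week, dimnames = list(rownames(daily), wk_names))
  for (wk in seq_len(n_week)) {
    cols <- ((wk - 1L) * 7L + 1L):(wk * 7L)
    weekly[, wk] <- rowMeans(daily[, cols, drop = FALSE])
  }
  keep <- !drop_rows
  ord <- order(-overall[keep])
  structure(list(daily = daily[keep, , drop = FALSE][ord, , drop = FALSE],
                 weekly = weekly[keep, , drop = FALSE][ord, , drop = FALSE],
                 overall = overall[keep][ord], n_windows = N),
            class = "attention_summary")
}

#' One-way repeated-measures ANOVA
#'
#' Within-subject decomposition of a complete subject x timepoint matrix:
#' `F = MS_time / MS_error` with `(k - 1, (n - 1)(k - 1))` degrees of
#' freedom. A zero error mean square with a nonzero time effect is reported
#' as `F = Inf, p = 0`; identical columns give `F = 0, p = 1`.
#'
#' @param values Numeric matrix, one row per subject, one column per
#'   timepoint; no missing cells.
#' @return List `statistic`, `p_value`, `df1`, `df2`.
#' @export
repeated_anova <- function(values) {
  values <- as.matrix(values)
  if (anyNA(values)) stop_contract("matrix must be complete")
  n <- nrow(values); k <- ncol(values)
  if (n < 2L || k < 2L) stop_contract("need >= 2 subjects and >= 2 timepoints")
  gm <- mean(values)
  col_m <- colMeans(values); row_m <- rowMeans(values)
  ss_time <- n * sum((col_m - gm)^2)
  ss_subj <- k * sum((row_m - gm)^2)
  ss_tot <- sum((values - gm)^2)
  ss_err <- ss_tot - ss_time - ss_subj
  df1 <- k - 1L; df2 <- (n - 1L) * (k - 1L)
  ms_time <- ss_time / df1
  ms_err <- ss_err / df2
  if (ms_err <= 1e-12) {
    if (ms_time <= 1e-12) return(list(statistic = 0, p_value = 1,
                                      df1 = df1, df2 = df2))
    return(list(statistic = Inf, p_value = 0, df1 = df1, df2 = df2))
  }
  f <- ms_time / ms_err
  list(statistic = f, p_value = stats::pf(f, df1, df2, lower.tail = FALSE),
       df1 = df1, df2 = df2)
}

#' Onset-day statistics per drug and per site
#'
#' Medians and IQRs (linear-interpolation quantiles) of AKI onset days among
#' cases, per drug, per site and overall; cells with fewer than `min_n`
#' cases are dropped. Pairwise two-sided Welch t tests compare onset-day
#' distributions between drugs and between sites.
#'
#' @param cohort A labelled `cohort_table` (possibly multi-site).
#' @param min_n Minimum cases for a reported cell.
#' @return An `onset_stats` list: `by_drug`, `by_site`, `overall`,
#'   `drug_pairs`, `site_pairs`.
#' @export
onset_stats <- function(cohort, min_n = 20L) {
  cases <- cohort[!is.na(cohort$label) & cohort$label == "case", , drop = FALSE]
  if (nrow(cases) == 0L) {
    return(structure(list(by_drug = NULL, by_site = NULL, overall = NULL,
                          drug_pairs = NULL, site_pairs = NULL),
                     class = "onset_stats"))
  }
  summarise <- function(days) {
    q <- stats::quantile(days, c(0.25, 0.5, 0.75), names = FALSE)
    data.frame(n = length(days), q1 = q[1], median = q[2], q3 = q[3])
  }
  cell_table <- function(split_var) {
    groups <- split(cases$onset_day, cases[[split_var]])
    groups <- groups[vapply(groups, length, integer(1)) >= min_n]
    if (!length(groups)) return(NULL)
    out <- do.call(rbind, lapply(groups, summarise))
    out <- cbind(stats::setNames(data.frame(names(groups)), split_var), out)
    rownames(out) <- NULL
    out
  }
  pair_tests <- function(split_var) {
    groups <- split(cases$onset_day, cases[[split_var]])
    groups <- groups[vapply(groups, length, integer(1)) >= max(2L, min_n)]
    nm <- names(groups)
    if (length(nm) < 2L) return(NULL)
    P <- matrix(NA_real_, length(nm), length(nm), dimnames = list(nm, nm))
    for (i in seq_along(nm)) for (j in seq_along(nm)) {
      if (i < j) {
        p <- stats::t.test(groups[[i]], groups[[j]])$p.value
        P[i, j] <- P[j, i] <- p
      }
    }
    P
  }
  structure(list(
    by_drug = cell_table("drug"), by_site = cell_table("site_id"),
    overall = summarise(cases$onset_day),
    drug_pairs = pair_tests("drug"), site_pairs = pair_tests("site_id")),
    class = "onset_stats")
}

#' Group-comparison tests for demographic characteristics
#'
#' Pearson chi-squared (no continuity correction) on 2x2 counts for binary
#' characteristics; Welch two-sample two-sided t test for continuous ones.
#'
#' @param data Data frame of per-person values.
#' @param group Binary grouping vector aligned with `data` rows.
#' @return Data frame `characteristic, type, statistic, p_value`, with a
#'   `warning` column flagging expected cell counts below 1.
#' @export
group_tests <- function(data, group) {
  group <- as.factor(group)
  if (nlevels(group) != 2L) stop_contract("exactly two groups required")
  rows <- list()
  for (cv in names(data)) {
    x <- data[[cv]]
    if (all(x %in% c(0, 1))) {
      tab <- table(factor(x, levels = c(0, 1)), group)
      exp_min <- min(outer(rowSums(tab), colSums(tab)) / sum(tab))
      ct <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
      rows[[length(rows) + 1L]] <- data.frame(
        characteristic = cv, type = "categorical",
        statistic = unname(ct$statistic), p_value = ct$p.value,
        warning = if (exp_min < 1) "expected cell < 1" else NA_character_)
    } else {
      tt <- stats::t.test(x ~ group)
      rows[[length(rows) + 1L]] <- data.frame(
        characteristic = cv, type = "continuous",
        statistic = unname(tt$statistic), p_value = tt$p.value,
        warning = NA_character_)
    }
  }
  do.call(rbind, rows)
}

#' Export an attention summary as CSV and heat map
#'
#' Writes the weekly matrix (rows sorted by overall score descending, as
#' returned by [aggregate_attention()]) to `<path>.csv` and renders a
#' simple heat map to `<path>.png`.
#'
#' @param summary An `attention_summary`.
#' @param path Output path stem (extensions are appended).
#' @return Invisible character vector of the files written.
#' @export
export_heatmap <- function(summary, path) {
  if (length(summary$overall) == 0L) stop_contract("empty attention summary")
  csv <- paste0(path, ".csv")
  png <- paste0(path, ".png")
  wk <- summary$weekly
  df <- data.frame(variable = rownames(wk), wk,
                   overall = summary$overall, check.names = FALSE)
  utils::write.csv(df, csv, row.names = FALSE)
  grDevices::png(png, width = 720, height = 120 + 40 * nrow(wk))
  op <- graphics::par(mar = c(4, 10, 2, 1))
  on.exit({ graphics::par(op); grDevices::dev.off() }, add = TRUE)
  m <- wk[rev(seq_len(nrow(wk))), , drop = FALSE]
  graphics::image(t(m), axes = FALSE,
                  col = grDevices::hcl.colors(64, "YlOrRd", rev = TRUE),
                  main = "Aggregated temporal attention")
  graphics::axis(1, at = seq(0, 1, length.out = ncol(m)), labels = colnames(m))
  graphics::axis(2, at = seq(0, 1, length.out = nrow(m)), labels = rownames(m),
                 las = 2, cex.axis = 0.8)
  invisible(c(csv, png))
}
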