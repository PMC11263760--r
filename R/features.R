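# Candidate-predictor selection and time-series featurization: paired tests
# between index and onset values, fill-imputed daily grids, 28-day windows
# at 14-day stride with a 14-day prediction horizon, and person-level
# stratified 6:2:2 splits.

#' Two-tailed paired t test
#'
#' `t = mean(d) / (sd(d) / sqrt(n))` on the paired differences `d = x - y`
#' (sample SD), with a two-sided p value from the t distribution on `n - 1`
#' degrees of freedom. Zero-variance differences yield `p = 1` with a
#' warning.
#'
#' @param x,y Paired numeric vectors of equal length (n >= 2).
#' @return List with `statistic`, `p_value`, `df`.
#' @export
paired_t <- function(x, y) {
  if (length(x) != length(y)) stop_contract("x and y must have equal length")
  n <- length(x)
  if (n < 2L) stop_contract("need at least 2 pairs")
  d <- x - y
  sdd <- stats::sd(d)
  if (sdd == 0) {
    warning("zero-variance differences; p = 1")
    return(list(statistic = 0, p_value = 1, df = n - 1L))
  }
  tval <- mean(d) / (sdd / sqrt(n))
  list(statistic = tval, p_value = 2 * stats::pt(-abs(tval), df = n - 1L),
       df = n - 1L)
}

#' McNemar test on discordant counts
#'
#' `chisq = (b - c)^2 / (b + c)` (no continuity correction), p from the
#' chi-squared distribution with 1 df. `b + c = 0` yields `p = 1`.
#'
#' @param b,c Discordant pair counts.
#' @return List with `statistic`, `p_value`.
#' @export
mcnemar_paired <- function(b, c) {
  if (b < 0 || c < 0) stop_contract("counts must be non-negative")
  if (b + c == 0) return(list(statistic = 0, p_value = 1))
  x2 <- (b - c)^2 / (b + c)
  list(statistic = x2, p_value = stats::pchisq(x2, df = 1, lower.tail = FALSE))
}

#' Build fill-imputed daily grids
#'
#' Pivots a person's events into a day-by-variable matrix at daily
#' resolution from `day_min` to `day_max` relative to the index date (day
#' 0 = index). Laboratory values: same-day duplicates averaged, then carried
#' forward from the last observation; days before the first observation take
#' the last pre-`day_min` value if any, else the cohort median of the
#' variable (flagged in the `imputed_baseline` attribute). Conditions are
#' 0/1 and carried forward from first occurrence. Drugs and procedures are
#' zero-filled binary: 1 on event days only.
#'
#' @param bundle A `cdm_bundle`.
#' @param cohort A labelled `cohort_table`.
#' @param variables Data frame with columns `variable`, `kind`
#'   (`lab`, `condition`, `drug`, `procedure`); defaults to all laboratory
#'   variables plus conditions, co-medications and procedures in the bundle.
#' @param day_min,day_max Grid span in days relative to index.
#' @return A `daily_grid`: named list of person matrices
#'   (days x variables, rownames = day), with attributes `variables` and
#'   `days`.
#' @export
build_grid <- function(bundle, cohort, variables = NULL,
                       day_min = 0L, day_max = 60L) {
  lab_rows <- cohort[!is.na(cohort$label), , drop = FALSE]
  if (is.null(variables)) {
    variables <- rbind(
      data.frame(variable = unique(bundle$measurement$variable_label), kind = "lab"),
      data.frame(variable = unique(bundle$condition_occurrence$condition_label),
                 kind = "condition"),
      data.frame(variable = unique(bundle$drug_exposure$drug_label), kind = "drug"),
      data.frame(variable = unique(bundle$procedure_occurrence$procedure_label),
                 kind = "procedure"))
  }
  days <- day_min:day_max
  nd <- length(days)
  idx <- stats::setNames(date_to_sim_day(lab_rows$index_date), lab_rows$person_id)
  persons <- lab_rows$person_id

  # long event table with relative day, per variable kind
  meas <- bundle$measurement[bundle$measurement$person_id %in% persons, , drop = FALSE]
  meas$day <- date_to_sim_day(meas$date) - idx[meas$person_id]
  cond <- bundle$condition_occurrence[bundle$condition_occurrence$person_id %in% persons, , drop = FALSE]
  cond$day <- date_to_sim_day(cond$date) - idx[cond$person_id]
  drg <- bundle$drug_exposure[bundle$drug_exposure$person_id %in% persons, , drop = FALSE]
  drg$day <- date_to_sim_day(drg$start_date) - idx[drg$person_id]
  proc <- bundle$procedure_occurrence[bundle$procedure_occurrence$person_id %in% persons, , drop = FALSE]
  proc$day <- date_to_sim_day(proc$date) - idx[proc$person_id]

  keep <- logical(nrow(variables))
  for (vi in seq_len(nrow(variables))) {
    v <- variables$variable[vi]
    n_obs <- switch(variables$kind[vi],
      lab = sum(meas$variable_label == v),
      condition = sum(cond$condition_label == v),
      drug = sum(drg$drug_label == v),
      procedure = sum(proc$procedure_label == v))
    keep[vi] <- n_obs > 0L
    if (!keep[vi]) warning("variable with no observations dropped: ", v)
  }
  variables <- variables[keep, , drop = FALSE]
  vnames <- variables$variable

  # cohort-median fallback per lab (from pre-index observations)
  lab_vars <- variables$variable[variables$kind == "lab"]
  med <- vapply(lab_vars, function(v) {
    pre <- meas$value[meas$variable_label == v & meas$day < 0]
    if (length(pre)) stats::median(pre) else
      stats::median(meas$value[meas$variable_label == v])
  }, numeric(1))

  grids <- vector("list", length(persons))
  names(grids) <- persons
  imputed_baseline <- character(0)
  meas_by <- split(meas[, c("variable_label", "day", "value")], meas$person_id)
  cond_by <- split(cond[, c("condition_label", "day")], cond$person_id)
  drg_by <- split(drg[, c("drug_label", "day")], drg$person_id)
  proc_by <- split(proc[, c("procedure_label", "day")], proc$person_id)

  for (p in persons) {
    M <- matrix(0, nrow = nd, ncol = length(vnames),
                dimnames = list(days, vnames))
    pm <- meas_by[[p]]
    for (vi in seq_len(nrow(variables))) {
      v <- variables$variable[vi]
      kind <- variables$kind[vi]
      if (kind == "lab") {
        obs <- pm[pm$variable_label == v, , drop = FALSE]
        daily <- if (nrow(obs)) tapply(obs$value, obs$day, mean) else numeric(0)
        obs_days <- as.integer(names(daily))
        in_span <- obs_days >= day_min & obs_days <= day_max
        col <- rep(NA_real_, nd)
        col[match(obs_days[in_span], days)] <- daily[in_span]
        # seed value for days before the first in-span observation
        pre <- daily[obs_days < day_min]
        seed_val <- if (length(pre)) pre[[length(pre)]] else {
          imputed_baseline <- c(imputed_baseline, paste0(p, ":", v))
          med[[v]]
        }
        if (is.na(col[1L])) col[1L] <- seed_val
        filled <- which(!is.na(col))
        M[, vi] <- if (length(filled) == 1L) rep(col[filled], nd) else
          stats::approx(filled, col[filled], xout = seq_len(nd),
                        method = "constant", rule = 2, f = 0)$y
      } else if (kind == "condition") {
        ev <- cond_by[[p]]
        d1 <- if (is.null(ev)) integer(0) else ev$day[ev$condition_label == v]
        if (length(d1) && min(d1) <= day_max)
          M[days >= min(d1), vi] <- 1
      } else {
        ev <- if (kind == "drug") drg_by[[p]] else proc_by[[p]]
        dv <- if (is.null(ev)) integer(0) else
          ev$day[(if (kind == "drug") ev$drug_label else ev$procedure_label) == v]
        dv <- dv[dv >= day_min & dv <= day_max]
        if (length(dv)) M[match(dv, days), vi] <- 1
      }
    }
    grids[[p]] <- M
  }
  structure(grids, class = "daily_grid", variables = variables, days = days,
            imputed_baseline = imputed_baseline)
}

#' Select candidate predictors by paired index-vs-onset tests
#'
#' For each variable, pairs its value at the index date with its value at
#' the AKI onset date across case patients: continuous (lab) variables are
#' tested with [paired_t()], binary variables with [mcnemar_paired()] on the
#' discordant counts. A variable is selected when `p < alpha`.
#'
#' @param cohort A labelled `cohort_table` (cases provide onset days).
#' @param grid A `daily_grid` covering index (day 0) and onset days.
#' @param alpha Selection level.
#' @param min_pairs Variables with fewer complete pairs are skipped.
#' @param fdr Apply Benjamini-Hochberg correction before thresholding.
#' @return Data frame `variable, kind, statistic, p_value, n_pairs, selected`.
#' @export
select_predictors <- function(cohort, grid, alpha = 0.05, min_pairs = 10L,
                              fdr = FALSE) {
  cases <- cohort[!is.na(cohort$label) & cohort$label == "case", , drop = FALSE]
  if (nrow(cases) == 0L) stop_contract("no labelled cases with onset dates")
  variables <- attr(grid, "variables")
  days <- attr(grid, "days")
  rows <- list()
  for (vi in seq_len(nrow(variables))) {
    v <- variables$variable[vi]
    kind <- variables$kind[vi]
    x0 <- x1 <- numeric(0)
    for (ri in seq_len(nrow(cases))) {
      p <- cases$person_id[ri]
      od <- cases$onset_day[ri]
      M <- grid[[p]]
      if (is.null(M) || !(0 %in% days) || !(od %in% days)) next
      x0 <- c(x0, M[match(0L, days), v])
      x1 <- c(x1, M[match(od, days), v])
    }
    if (length(x0) < min_pairs) {
      warning("variable skipped (", length(x0), " pairs): ", v)
      next
    }
    if (kind == "lab") {
      if (stats::sd(x0 - x1) == 0) {
        res <- list(statistic = 0, p_value = 1)
      } else res <- paired_t(x1, x0)
    } else {
      b <- sum(x0 == 1 & x1 == 0)
      cc <- sum(x0 == 0 & x1 == 1)
      res <- mcnemar_paired(b, cc)
    }
    rows[[length(rows) + 1L]] <- data.frame(
      variable = v, kind = kind, statistic = res$statistic,
      p_value = res$p_value, n_pairs = length(x0), stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  padj <- if (fdr) stats::p.adjust(out$p_value, "BH") else out$p_value
  out$selected <- padj < alpha
  out
}

#' Slice daily grids into labelled prediction windows
#'
#' Windows of `T_days` start at day 0 and advance by `stride`. A window is
#' emitted only if it fits inside the person's available span: for cases the
#' span ends at the onset day (no window contains or crosses onset), for
#' controls at the follow-up end. A window is labelled 1 iff the person is a
#' case with `onset_day` in `(window_end, window_end + horizon]`.
#'
#' @param grid A `daily_grid`.
#' @param cohort Labelled `cohort_table` matching the grid's persons.
#' @param T_days Window length in days.
#' @param stride Shift between successive windows in days.
#' @param horizon Prediction horizon after the window end in days.
#' @param followup_days Follow-up end for controls.
#' @param variables Optional character vector restricting window variables.
#' @return A `window_tensor`: list with `data` (array windows x T x V),
#'   `labels`, and `meta` (person, start day, site, drug per window).
#' @export
make_windows <- function(grid, cohort, T_days = 28L, stride = 14L,
                         horizon = 14L, followup_days = 60L,
                         variables = NULL) {
  days <- attr(grid, "days")
  vars <- attr(grid, "variables")$variable
  if (!is.null(variables)) vars <- intersect(variables, vars)
  lab <- cohort[!is.na(cohort$label), , drop = FALSE]
  slices <- list()
  labels <- integer(0)
  meta <- list()
  for (ri in seq_len(nrow(lab))) {
    p <- lab$person_id[ri]
    M <- grid[[p]]
    if (is.null(M)) next
    is_case <- lab$label[ri] == "case"
    span_end <- if (is_case) lab$onset_day[ri] else followup_days
    span_end <- min(span_end, max(days) + 1L)
    s <- 0L
    while (s + T_days <= span_end) {
      rows <- match(s:(s + T_days - 1L), days)
      win_end <- s + T_days
      lbl <- as.integer(is_case && lab$onset_day[ri] > win_end &&
                          lab$onset_day[ri] <= win_end + horizon)
      slices[[length(slices) + 1L]] <- M[rows, vars, drop = FALSE]
      labels <- c(labels, lbl)
      meta[[length(meta) + 1L]] <- data.frame(
        person_id = p, start_day = s, site_id = lab$site_id[ri],
        drug = lab$drug[ri], label = lbl, stringsAsFactors = FALSE)
      s <- s + stride
    }
  }
  nw <- length(slices)
  data <- array(0, dim = c(nw, T_days, length(vars)),
                dimnames = list(NULL, NULL, vars))
  for (w in seq_len(nw)) data[w, , ] <- slices[[w]]
  structure(list(data = data, labels = labels,
                 meta = if (nw) do.call(rbind, meta) else
                   data.frame(person_id = character(0), start_day = integer(0),
                              site_id = character(0), drug = character(0),
                              label = integer(0))),
            class = "window_tensor")
}

#' Expected window count for an observation span
#'
#' `floor((L - T) / stride) + 1` for spans of at least one window, else 0.
#' @param L Span length in days.
#' @param T_days Window length.
#' @param stride Window shift.
#' @return Integer window count.
#' @export
window_count <- function(L, T_days = 28L, stride = 14L) {
  ifelse(L < T_days, 0L, (L - T_days) %/% stride + 1L)
}

#' Person-level stratified 6:2:2 split
#'
#' Persons (not windows) are shuffled within case/control strata and
#' allocated 60/20/20 to train/validation/test, so all windows of a person
#' share one split. With a single class present the split is unstratified
#' with a warning.
#'
#' @param windows A `window_tensor`.
#' @param seed Integer seed for the shuffle.
#' @return List of three `window_tensor`s: `train`, `validation`, `test`.
#' @export
split_622 <- function(windows, seed = 1L) {
  meta <- windows$meta
  pers <- unique(meta$person_id)
  if (length(pers) < 5L) stop_contract("need at least 5 distinct persons")
  person_case <- tapply(meta$label, meta$person_id, max)[pers]
  set.seed(seed)
  assign_split <- function(ids) {
    ids <- sample(ids)
    n <- length(ids)
    n_val <- round(0.2 * n)
    n_test <- round(0.2 * n)
    parts <- split(ids, rep(c("train", "validation", "test"),
                            c(n - n_val - n_test, n_val, n_test)))
    for (nm in c("train", "validation", "test"))
      if (is.null(parts[[nm]])) parts[[nm]] <- character(0)
    parts
  }
  if (length(unique(person_case)) < 2L) {
    warning("single class present; unstratified split")
    parts <- assign_split(pers)
  } else {
    p1 <- assign_split(pers[person_case == 1])
    p0 <- assign_split(pers[person_case == 0])
    parts <- list(train = c(p1$train, p0$train),
                  validation = c(p1$validation, p0$validation),
                  test = c(p1$test, p0$test))
  }
  subset_tensor <- function(ids) {
    sel <- which(meta$person_id %in% ids)
    structure(list(data = windows$data[sel, , , drop = FALSE],
                   labels = windows$labels[sel],
                   meta = meta[sel, , drop = FALSE]),
              class = "window_tensor")
  }
  lapply(parts, subset_tensor)
}

#' Standardize window tensors per variable
#'
#' Continuous variables are scaled by the training split's per-variable mean
#' and SD (computed over all window cells); the scaler is reused on new
#' splits. Binary variables (all values 0/1) are left untouched.
#'
#' @param windows A `window_tensor`.
#' @param scaler Optional scaler from a previous call.
#' @return List `windows` (standardized) and `scaler`.
#' @export
standardize_windows <- function(windows, scaler = NULL) {
  vars <- dimnames(windows$data)[[3]]
  if (is.null(scaler)) {
    scaler <- lapply(seq_along(vars), function(v) {
      x <- windows$data[, , v]
      if (all(x %in% c(0, 1))) return(c(mean = 0, sd = 1))
      s <- stats::sd(x)
      c(mean = mean(x), sd = if (s > 0) s else 1)
    })
    names(scaler) <- vars
  }
  for (v in vars) {
    windows$data[, , v] <- (windows$data[, , v] - scaler[[v]][["mean"]]) /
      scaler[[v]][["sd"]]
  }
  list(windows = windows, scaler = scaler)
}
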