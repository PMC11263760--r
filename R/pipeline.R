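# End-to-end runner: per (site, drug) cohort -> matching -> features ->
# model -> evaluation, plus pooled demographics, onset statistics and
# aggregated attention, with a JSON run manifest.

#' Assemble and validate a pipeline run configuration
#'
#' @param sites List of [site_sim_config()]s (or lists coercible to them),
#'   or character paths to directories written by [write_bundle()].
#' @param drugs Target drug labels to model.
#' @param criteria An [aki_criteria()].
#' @param match_ratio Controls per case for matching.
#' @param alpha Predictor-selection level.
#' @param window List with `T_days`, `stride`, `horizon`.
#' @param hyper An [imv_hyperparams()].
#' @param output_dir Directory for artifacts; `NULL` for none.
#' @param seed Global seed; per-stage seeds are derived with [derive_seed()].
#' @param min_cases Minimum cases for a (site, drug) cell to be modelled.
#' @return A `run_config` list.
#' @export
run_config <- function(sites, drugs = target_drugs(),
                       criteria = aki_criteria(), match_ratio = 3L,
                       alpha = 0.05,
                       window = list(T_days = 28L, stride = 14L, horizon = 14L),
                       hyper = imv_hyperparams(), output_dir = NULL,
                       seed = 1L, min_cases = 20L) {
  if (length(sites) == 0L || length(drugs) == 0L)
    stop_config("sites and drugs must be non-empty")
  if (match_ratio < 1L) stop_config("match_ratio must be >= 1")
  assert_prob(alpha, "alpha")
  for (k in c("T_days", "stride", "horizon"))
    if (is.null(window[[k]]) || window[[k]] < 1L)
      stop_config("window$", k, " must be a positive integer")
  structure(list(sites = sites, drugs = drugs, criteria = criteria,
                 match_ratio = as.integer(match_ratio), alpha = alpha,
                 window = window, hyper = hyper, output_dir = output_dir,
                 seed = as.integer(seed), min_cases = as.integer(min_cases)),
            class = "run_config")
}

#' Parse a YAML run configuration
#'
#' Schema: top-level keys `sites` (list of site blocks or directory paths),
#' `drugs`, `criteria`, `match_ratio`, `alpha`, `window`, `hyper`,
#' `output_dir`, `seed`, `min_cases`. Unknown keys are rejected with the
#' offending name; omitted keys take the documented defaults.
#'
#' @param path Path to a YAML file.
#' @return A validated `run_config`.
#' @export
parse_config <- function(path) {
  raw <- yaml::read_yaml(path)
  allowed <- c("sites", "drugs", "criteria", "match_ratio", "alpha", "window",
               "hyper", "output_dir", "seed", "min_cases")
  unknown <- setdiff(names(raw), allowed)
  if (length(unknown)) stop_config("unknown config key: ", unknown[1])
  args <- list()
  if (is.null(raw$sites)) stop_config("config requires sites")
  args$sites <- lapply(raw$sites, function(s) {
    if (is.character(s)) return(s)
    do.call(site_sim_config, s)
  })
  if (!is.null(raw$drugs)) args$drugs <- unlist(raw$drugs)
  if (!is.null(raw$criteria)) args$criteria <- do.call(aki_criteria, raw$criteria)
  if (!is.null(raw$hyper)) args$hyper <- do.call(imv_hyperparams, raw$hyper)
  for (k in c("match_ratio", "alpha", "window", "output_dir", "seed", "min_cases"))
    if (!is.null(raw[[k]])) args[[k]] <- raw[[k]]
  do.call(run_config, args)
}

#' Write a run configuration to YAML
#' @param config A `run_config` with simulated sites.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_config <- function(config, path) {
  serialize_site <- function(s) {
    if (is.character(s)) return(s)
    s <- unclass(s)
    # named vectors must become maps to survive YAML
    for (k in c("drug_mix", "comorbidity_prev", "drift_effects"))
      s[[k]] <- as.list(s[[k]])
    s$onset_lognormal <- lapply(s$onset_lognormal, as.vector)
    s
  }
  obj <- list(
    sites = lapply(config$sites, serialize_site),
    drugs = config$drugs, criteria = unclass(config$criteria),
    match_ratio = config$match_ratio, alpha = config$alpha,
    window = config$window, hyper = unclass(config$hyper),
    seed = config$seed, min_cases = config$min_cases)
  if (!is.null(config$output_dir)) obj$output_dir <- config$output_dir
  yaml::write_yaml(obj, path)
  invisible(path)
}

.log_stage <- function(verbose, ...) if (verbose) message(format(Sys.time(), "%H:%M:%S "), ...)

#' Run the full pipeline
#'
#' For every (site, drug) cell: build the case/control cohort, propensity
#' match 1:`match_ratio`, select predictors, featurize matched persons into
#' 4-week windows, train the IMV-LSTM on a person-level 6:2:2 split, and
#' evaluate on the held-out windows. Cells with fewer than `min_cases`
#' cases are skipped with a recorded reason. Pooled outputs: demographics
#' table, onset statistics, and attention aggregated over the test-split
#' case windows of completed cells.
#'
#' @param config A `run_config`.
#' @param verbose Log per-stage progress to stderr.
#' @return A `pipeline_result`: `manifest` (counts, seeds, skips per cell),
#'   `cells` (per completed cell: metrics, attention summary, balance),
#'   `demographics`, `onset`, `pooled_attention`.
#' @export
run_pipeline <- function(config, verbose = FALSE) {
  stopifnot(inherits(config, "run_config"))
  bundles <- lapply(config$sites, function(s) {
    if (is.character(s)) read_bundle(s) else generate_site(s)
  })
  names(bundles) <- vapply(bundles, `[[`, character(1), "site_id")
  if (anyDuplicated(names(bundles))) stop_config("duplicate site_id among sites")

  manifest <- list(seed = config$seed, cells = list())
  cells <- list()
  cohorts <- list()
  att_pool <- list()
  wcfg <- config$window

  for (si in seq_along(bundles)) {
    site <- names(bundles)[si]
    bundle <- bundles[[si]]
    for (di in seq_along(config$drugs)) {
      drug <- config$drugs[di]
      cell_id <- paste(site, drug, sep = ":")
      .log_stage(verbose, "cell ", cell_id, ": cohort")
      rec <- list(site = site, drug = drug)
      res <- tryCatch({
        cohort <- apply_eligibility(bundle, drug, config$criteria)
        cohorts[[cell_id]] <- cohort
        lab <- cohort[!is.na(cohort$label), , drop = FALSE]
        rec$exposed <- nrow(cohort)
        rec$excluded <- as.list(table(cohort$exclusion_reason))
        rec$cases <- sum(lab$label == "case")
        rec$controls <- sum(lab$label == "control")
        if (rec$cases < config$min_cases) {
          rec$skipped <- paste0("cases (", rec$cases, ") below minimum (",
                                config$min_cases, ")")
          manifest$cells[[cell_id]] <- rec
          next
        }
        .log_stage(verbose, "cell ", cell_id, ": matching")
        mt <- match_cohort(cohort, bundle, k = config$match_ratio)
        rec$matched_controls <- nrow(mt$matched$pairs)
        rec$achieved_ratio <- mt$achieved_ratio

        matched_ids <- c(unique(mt$matched$pairs$case_id),
                         mt$matched$pairs$control_id)
        mcohort <- cohort[cohort$person_id %in% matched_ids, , drop = FALSE]
        .log_stage(verbose, "cell ", cell_id, ": features")
        grid <- build_grid(bundle, mcohort,
                           day_max = config$criteria$followup_days)
        sel <- select_predictors(mcohort, grid, alpha = config$alpha)
        vars <- sel$variable[sel$selected]
        vars <- setdiff(vars, "scr")  # the label is derived from SCr
        if (length(vars) < 2L) vars <- setdiff(sel$variable[sel$kind == "lab"], "scr")
        rec$selected_variables <- vars
        windows <- make_windows(grid, mcohort, T_days = wcfg$T_days,
                                stride = wcfg$stride, horizon = wcfg$horizon,
                                followup_days = config$criteria$followup_days,
                                variables = vars)
        rec$windows <- length(windows$labels)
        rec$window_positives <- sum(windows$labels)
        split_seed <- derive_seed(config$seed, si, di, 1L)
        splits <- split_622(windows, seed = split_seed)
        rec$split_windows <- vapply(splits, function(s) length(s$labels), integer(1))
        std <- standardize_windows(splits$train)
        train <- std$windows
        validation <- standardize_windows(splits$validation, std$scaler)$windows
        test <- standardize_windows(splits$test, std$scaler)$windows
        .log_stage(verbose, "cell ", cell_id, ": training")
        hyper <- config$hyper
        hyper$seed <- derive_seed(config$seed, si, di, 2L)
        model <- imv_train(train, validation, hyper)
        model$scaler <- std$scaler
        .log_stage(verbose, "cell ", cell_id, ": evaluation")
        pv <- predict(model, validation)
        pt <- predict(model, test)
        metrics <- list(
          validation = metrics_report(pv$probabilities, validation$labels,
                                      threshold = hyper$threshold,
                                      seed = derive_seed(config$seed, si, di, 3L)),
          test = metrics_report(pt$probabilities, test$labels,
                                threshold = hyper$threshold,
                                seed = derive_seed(config$seed, si, di, 4L)))
        rec$auroc_test <- metrics$test$auroc
        # attention over test-split case windows
        case_w <- which(test$labels == 1)
        att <- NULL
        if (length(case_w) >= 2L) {
          att <- aggregate_attention(pt$alpha[case_w, , , drop = FALSE],
                                     pt$beta[case_w, , drop = FALSE],
                                     variables = model$variables)
          att_pool[[cell_id]] <- list(alpha = pt$alpha[case_w, , , drop = FALSE],
                                      beta = pt$beta[case_w, , drop = FALSE],
                                      variables = model$variables)
        }
        cells[[cell_id]] <- list(site = site, drug = drug, cohort = cohort,
                                 matching = mt, selection = sel,
                                 model = model, metrics = metrics,
                                 attention = att)
        rec$completed <- TRUE
        rec
      }, error = function(e) {
        rec$error <- conditionMessage(e)
        rec
      })
      manifest$cells[[cell_id]] <- res
    }
  }

  all_cohort <- do.call(rbind, cohorts)
  demographics <- if (!is.null(all_cohort) && any(!is.na(all_cohort$label)))
    demographics_table(all_cohort, bundles) else NULL
  onset <- if (!is.null(all_cohort)) onset_stats(all_cohort, min_n = config$min_cases)
    else NULL

  pooled_attention <- NULL
  if (length(att_pool)) {
    sigs <- vapply(att_pool, function(a) paste(a$variables, collapse = "|"),
                   character(1))
    top <- names(sort(table(sigs), decreasing = TRUE))[1]
    use <- att_pool[sigs == top]
    alphas <- do.call(abind_1, lapply(use, `[[`, "alpha"))
    betas <- do.call(rbind, lapply(use, `[[`, "beta"))
    pooled_attention <- aggregate_attention(alphas, betas,
                                            variables = use[[1]]$variables)
  }

  manifest$n_completed <- length(cells)
  result <- structure(list(manifest = manifest, cells = cells,
                           demographics = demographics, onset = onset,
                           pooled_attention = pooled_attention),
                      class = "pipeline_result")
  if (!is.null(config$output_dir)) {
    dir.create(config$output_dir, recursive = TRUE, showWarnings = FALSE)
    jsonlite::write_json(manifest, file.path(config$output_dir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE, force = TRUE)
    if (!is.null(demographics))
      utils::write.csv(demographics,
                       file.path(config$output_dir, "demographics.csv"),
                       row.names = FALSE)
    if (!is.null(pooled_attention))
      export_heatmap(pooled_attention,
                     file.path(config$output_dir, "attention_pooled"))
  }
  result
}

# bind 3D arrays along the first dimension
abind_1 <- function(...) {
  arrs <- list(...)
  d <- dim(arrs[[1]])
  n <- sum(vapply(arrs, function(a) dim(a)[1], integer(1)))
  out <- array(0, c(n, d[2], d[3]))
  at <- 0L
  for (a in arrs) {
    out[at + seq_len(dim(a)[1]), , ] <- a
    at <- at + dim(a)[1]
  }
  out
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat("<pipeline_result>", x$manifest$n_completed, "completed cells\n")
  for (nm in names(x$manifest$cells)) {
    rec <- x$manifest$cells[[nm]]
    status <- if (isTRUE(rec$completed)) {
      sprintf("AUROC(test) %.3f", rec$auroc_test)
    } else if (!is.null(rec$skipped)) paste("skipped:", rec$skipped)
    else if (!is.null(rec$error)) paste("error:", rec$error)
    else "?"
    cat(sprintf("  %-28s cases %5s  %s\n", nm,
                rec$cases %||% "-", status))
  }
  invisible(x)
}
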