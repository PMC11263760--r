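# Propensity score matching: standard scaling, ridge-stabilised
# Newton-Raphson logistic regression, greedy 1:k nearest-neighbour matching
# on the propensity score without replacement, and covariate balance
# diagnostics.

#' Standardize covariate columns
#'
#' Centres and scales each column to mean 0 and population SD 1 (divisor n),
#' storing the scaler for reuse on new data.
#'
#' @param covariates Numeric data frame or matrix.
#' @param scaler Optional scaler from a previous call; when supplied its
#'   means/SDs are applied instead of refitting.
#' @return List with `data` (standardized matrix) and `scaler`
#'   (per-column `mean` and `sd`).
#' @export
standardize_covariates <- function(covariates, scaler = NULL) {
  X <- as.matrix(covariates)
  if (!is.numeric(X)) stop_contract("covariates must be numeric")
  if (is.null(scaler)) {
    if (nrow(X) < 2L) stop_contract("need at least 2 rows to standardize")
    m <- colMeans(X)
    s <- sqrt(colMeans(sweep(X, 2, m)^2))  # population SD
    bad <- which(s <= 0)
    if (length(bad))
      stop_contract("zero-variance column: ", paste(colnames(X)[bad], collapse = ", "))
    scaler <- list(mean = m, sd = s)
  }
  Z <- sweep(sweep(X, 2, scaler$mean), 2, scaler$sd, "/")
  list(data = Z, scaler = scaler)
}

#' Fit a propensity model by logistic regression
#'
#' Newton-Raphson maximisation of the Bernoulli log-likelihood with a small
#' L2 penalty (`ridge`, default 1e-6) that leaves well-posed fits unchanged
#' but keeps the solution bounded under perfect separation (a warning is
#' raised when separation is detected). Iterates until the gradient norm
#' falls below `tol`.
#'
#' @param X Standardized covariate matrix (see [standardize_covariates()]).
#' @param y Binary labels (0/1 or logical), 1 = case.
#' @param ridge L2 penalty on the coefficients (not the intercept).
#' @param tol Convergence tolerance on the gradient norm.
#' @param max_iter Iteration cap.
#' @return A `propensity_model`: `coefficients`, `intercept`, `scaler`
#'   (attached by [match_cohort()]), `converged`, `n_iter`.
#' @export
fit_propensity <- function(X, y, ridge = 1e-6, tol = 1e-8, max_iter = 100L) {
  X <- as.matrix(X)
  y <- as.numeric(y)
  if (!all(y %in% c(0, 1))) stop_contract("labels must be binary")
  if (length(unique(y)) < 2L) stop_contract("both classes must be present")
  Xi <- cbind(intercept = 1, X)
  p <- ncol(Xi)
  beta <- numeric(p)
  pen <- c(0, rep(ridge, p - 1L))
  converged <- FALSE
  it <- 0L
  for (it in seq_len(max_iter)) {
    eta <- drop(Xi %*% beta)
    mu <- stats::plogis(eta)
    grad <- drop(crossprod(Xi, y - mu)) - pen * beta
    if (sqrt(sum(grad^2)) < tol) { converged <- TRUE; break }
    w <- pmax(mu * (1 - mu), 1e-12)
    H <- crossprod(Xi * w, Xi) + diag(pen, p)
    step <- solve(H, grad)
    # damped Newton: halve until the penalised log-likelihood does not drop
    ll <- sum(y * eta - log1p(exp(eta))) - sum(pen * beta^2) / 2
    for (h in 0:20) {
      cand <- beta + step / 2^h
      eta_c <- drop(Xi %*% cand)
      ll_c <- sum(y * eta_c - log1p(exp(eta_c))) - sum(pen * cand^2) / 2
      if (ll_c >= ll - 1e-12) { beta <- cand; break }
    }
  }
  eta <- drop(Xi %*% beta)
  mu <- stats::plogis(eta)
  if (max(abs(beta[-1])) > 15 || all(abs(mu - y) < 1e-6))
    warning("possible separation: coefficients bounded by the L2 penalty")
  structure(list(coefficients = stats::setNames(beta[-1], colnames(X)),
                 intercept = beta[1], scaler = NULL,
                 converged = converged, n_iter = it),
            class = "propensity_model")
}

#' Predicted propensity scores
#' @param object A `propensity_model`.
#' @param newdata Covariate matrix on the scale the model was fitted on
#'   (standardized if the model was fitted on standardized data), or raw
#'   covariates when the model carries a scaler.
#' @param ... Unused.
#' @return Vector of probabilities in (0, 1).
#' @export
predict.propensity_model <- function(object, newdata, ...) {
  X <- as.matrix(newdata)
  if (!is.null(object$scaler)) X <- standardize_covariates(X, object$scaler)$data
  stats::plogis(object$intercept + drop(X %*% object$coefficients))
}

#' Greedy 1:k nearest-neighbour matching on propensity scores
#'
#' Cases are processed in descending propensity-score order; each takes its
#' `k` nearest controls by absolute score difference, without replacement.
#' Distance ties are broken in favour of the smaller `person_id`. Cases with
#' a depleted pool keep whatever they matched.
#'
#' @param scores Named numeric vector of propensity scores (names =
#'   person ids) covering all labelled persons.
#' @param labels Named binary vector (1 = case) aligned with `scores` names.
#' @param k Controls per case.
#' @return A `matched_cohort`: `pairs` data frame
#'   (`case_id, control_id, rank, case_score, control_score`), `k`, `scores`.
#' @export
match_knn <- function(scores, labels, k = 3L) {
  ids <- names(scores)
  if (is.null(ids) || is.null(names(labels)))
    stop_contract("scores and labels must be named by person id")
  labels <- labels[ids]
  case_ids <- ids[labels == 1]
  ctrl_ids <- ids[labels == 0]
  if (length(ctrl_ids) == 0L) {
    warning("no controls available; empty matching")
    return(structure(list(pairs = data.frame(
      case_id = character(0), control_id = character(0), rank = integer(0),
      case_score = numeric(0), control_score = numeric(0)),
      k = k, scores = scores), class = "matched_cohort"))
  }
  # Controls live in a doubly-linked list over ascending score. Equal-score
  # runs are tracked as groups: every member of a run sits at the same
  # distance from a case, so distance ties are broken by the smallest person
  # id across the full run (and across both sides when left and right
  # distances coincide).
  ord <- order(scores[ctrl_ids], ctrl_ids)
  cs <- unname(scores[ctrl_ids][ord])
  cid <- ctrl_ids[ord]
  m <- length(cid)
  nxt <- c(seq_len(m)[-1L], NA_integer_)
  prv <- c(NA_integer_, seq_len(m)[-m])
  alive <- rep(TRUE, m)
  run_of <- cumsum(!duplicated(cs))
  runs <- split(seq_len(m), run_of)
  alive_run <- function(idx) { mem <- runs[[run_of[idx]]]; mem[alive[mem]] }

  case_ord <- order(-scores[case_ids], case_ids)
  case_ids <- case_ids[case_ord]
  pairs <- vector("list", length(case_ids))
  n_alive <- m
  for (ci in seq_along(case_ids)) {
    if (n_alive == 0L) break
    s <- scores[[case_ids[ci]]]
    # frontiers: nearest alive controls at or below / strictly above s
    left <- findInterval(s, cs)
    while (left >= 1L && !alive[left]) left <- left - 1L
    if (left < 1L) left <- NA_integer_
    right <- findInterval(s, cs) + 1L
    while (right <= m && !alive[right]) right <- right + 1L
    if (right > m) right <- NA_integer_
    take <- integer(0)
    for (r in seq_len(min(k, n_alive))) {
      dl <- if (!is.na(left)) s - cs[left] else Inf
      dr <- if (!is.na(right)) cs[right] - s else Inf
      if (is.infinite(dl) && is.infinite(dr)) break
      dmin <- min(dl, dr)
      cand <- integer(0)
      if (dl == dmin) cand <- alive_run(left)
      if (dr == dmin) cand <- c(cand, alive_run(right))
      pick <- cand[order(cid[cand])[1L]]  # tie: smaller person id
      alive[pick] <- FALSE                # unlink immediately
      if (!is.na(prv[pick])) nxt[prv[pick]] <- nxt[pick]
      if (!is.na(nxt[pick])) prv[nxt[pick]] <- prv[pick]
      if (!is.na(left) && pick == left) left <- prv[pick]
      if (!is.na(right) && pick == right) right <- nxt[pick]
      take <- c(take, pick)
    }
    if (length(take)) {
      n_alive <- n_alive - length(take)
      pairs[[ci]] <- data.frame(
        case_id = case_ids[ci], control_id = cid[take],
        rank = seq_along(take), case_score = s, control_score = cs[take],
        stringsAsFactors = FALSE)
    }
  }
  pairs <- do.call(rbind, pairs)
  if (is.null(pairs)) pairs <- data.frame(
    case_id = character(0), control_id = character(0), rank = integer(0),
    case_score = numeric(0), control_score = numeric(0))
  rownames(pairs) <- NULL
  structure(list(pairs = pairs, k = k, scores = scores),
            class = "matched_cohort")
}

#' Absolute standardized mean difference
#'
#' `SMD = |m1 - m0| / sqrt((s1^2 + s0^2) / 2)` with sample SDs.
#'
#' @param x1,x0 Covariate values in the case and control groups.
#' @return Scalar SMD (0 when both groups are constant and equal).
#' @export
smd <- function(x1, x0) {
  denom <- sqrt((stats::var(x1) + stats::var(x0)) / 2)
  d <- abs(mean(x1) - mean(x0))
  if (denom == 0) return(if (d == 0) 0 else Inf)
  d / denom
}

#' Covariate balance before and after matching
#'
#' @param covariates Data frame of covariates with rownames = person ids.
#' @param labels Named binary vector (1 = case).
#' @param matched A `matched_cohort` from [match_knn()].
#' @return Data frame, one row per covariate and phase (`before`/`after`),
#'   with case mean, control mean, raw difference, and absolute SMD.
#' @export
balance_report <- function(covariates, labels, matched) {
  X <- as.data.frame(covariates)
  ids <- rownames(X)
  labels <- labels[ids]
  report <- list()
  phases <- list(
    before = list(case = ids[labels == 1], control = ids[labels == 0]),
    after = list(case = unique(matched$pairs$case_id),
                 control = matched$pairs$control_id))
  for (ph in names(phases)) {
    g1 <- phases[[ph]]$case; g0 <- phases[[ph]]$control
    if (length(g1) == 0L || length(g0) == 0L) {
      warning("empty group in phase ", ph, "; report row omitted")
      next
    }
    for (cv in names(X)) {
      x1 <- X[g1, cv]; x0 <- X[g0, cv]
      report[[length(report) + 1L]] <- data.frame(
        covariate = cv, phase = ph,
        case_mean = mean(x1), control_mean = mean(x0),
        difference = mean(x1) - mean(x0), smd = smd(x1, x0),
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, report)
}

#' Propensity-match a labelled cohort
#'
#' Convenience wrapper running the whole matching stage on one site's
#' cohort: assembles age, sex and baseline SCr per labelled person,
#' standardizes, fits the propensity model, matches 1:`k`, and reports
#' balance.
#'
#' @param cohort A labelled `cohort_table` for one site.
#' @param bundle The site's `cdm_bundle`.
#' @param k Controls per case.
#' @return List: `matched` (`matched_cohort`), `model`, `balance`,
#'   `covariates`, `achieved_ratio`.
#' @export
match_cohort <- function(cohort, bundle, k = 3L) {
  lab <- cohort[!is.na(cohort$label), , drop = FALSE]
  yob <- stats::setNames(bundle$person$year_of_birth, bundle$person$person_id)
  gender <- stats::setNames(bundle$person$gender, bundle$person$person_id)
  scr <- bundle$measurement[bundle$measurement$variable_label == "scr", , drop = FALSE]
  scr <- scr[scr$person_id %in% lab$person_id, , drop = FALSE]
  idx <- stats::setNames(lab$index_date, lab$person_id)
  pre <- scr[scr$date < idx[scr$person_id], , drop = FALSE]
  pre <- pre[order(pre$person_id, pre$date), , drop = FALSE]
  base_scr <- tapply(pre$value, pre$person_id, mean)
  covs <- data.frame(
    age = as.numeric(format(lab$index_date, "%Y")) - yob[lab$person_id],
    sex = as.numeric(gender[lab$person_id] == "M"),
    baseline_scr = as.numeric(base_scr[lab$person_id]),
    row.names = lab$person_id)
  covs$baseline_scr[is.na(covs$baseline_scr)] <- stats::median(covs$baseline_scr, na.rm = TRUE)
  y <- stats::setNames(as.numeric(lab$label == "case"), lab$person_id)
  std <- standardize_covariates(covs)
  model <- fit_propensity(std$data, y)
  model$scaler <- std$scaler
  scores <- stats::setNames(predict(model, covs), lab$person_id)
  matched <- match_knn(scores, y, k = k)
  bal <- balance_report(covs, y, matched)
  n_cases_matched <- length(unique(matched$pairs$case_id))
  list(matched = matched, model = model, balance = bal, covariates = covs,
       achieved_ratio = if (n_cases_matched) nrow(matched$pairs) / n_cases_matched else NA_real_)
}
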