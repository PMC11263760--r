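# Serum-creatinine AKI phenotyping: index dates, the doubling criterion with
# a fixed ULN surrogate baseline, eligibility rules, and Table-1-style
# demographic summaries.

#' AKI labelling criteria
#'
#' The AKI event is a serum creatinine (SCr) rise to `ratio` times baseline
#' within `followup_days` after the index date. Under the default
#' `baseline_policy = "uln_fixed"` the baseline is replaced by the upper
#' limit of normal (`uln`, 1.2 mg/dL), giving a fixed event threshold of
#' `ratio * uln` = 2.4 mg/dL; this is self-consistent with the exclusion of
#' patients whose pre-index SCr ever exceeds the ULN. The alternative
#' `"observed_mean_capped"` policy uses `min(mean(pre-observation SCr), uln)`
#' as baseline.
#'
#' @param uln Upper limit of normal SCr in mg/dL.
#' @param ratio Fold-increase over baseline defining AKI.
#' @param followup_days Follow-up window after index (days).
#' @param preobs_days Pre-observation window before index (days).
#' @param min_preobs_scr Minimum number of pre-observation SCr tests.
#' @param min_prior_visit_days Required lead time of the earliest visit
#'   record before index (days).
#' @param baseline_policy `"uln_fixed"` or `"observed_mean_capped"`.
#' @return An `aki_criteria` object.
#' @export
aki_criteria <- function(uln = 1.2, ratio = 2.0, followup_days = 60L,
                         preobs_days = 60L, min_preobs_scr = 2L,
                         min_prior_visit_days = 30L,
                         baseline_policy = c("uln_fixed", "observed_mean_capped")) {
  baseline_policy <- match.arg(baseline_policy)
  if (ratio <= 1) stop_config("ratio must exceed 1")
  for (v in c(followup_days, preobs_days, min_prior_visit_days))
    if (v <= 0) stop_config("day spans must be positive")
  structure(list(uln = uln, ratio = ratio,
                 followup_days = as.integer(followup_days),
                 preobs_days = as.integer(preobs_days),
                 min_preobs_scr = as.integer(min_preobs_scr),
                 min_prior_visit_days = as.integer(min_prior_visit_days),
                 baseline_policy = baseline_policy),
            class = "aki_criteria")
}

#' First-exposure index dates for a drug
#'
#' @param bundle A `cdm_bundle`.
#' @param drug Drug label.
#' @return Named `Date` vector: earliest `start_date` of `drug` per exposed
#'   person. Persons without exposure are absent; an unknown drug yields an
#'   empty vector.
#' @export
index_dates <- function(bundle, drug) {
  de <- bundle$drug_exposure
  de <- de[de$drug_label == drug, , drop = FALSE]
  if (nrow(de) == 0L) return(stats::setNames(as.Date(character(0)), character(0)))
  agg <- tapply(de$start_date, de$person_id, min)
  stats::setNames(as.Date(agg, origin = "1970-01-01"), names(agg))
}

#' Detect AKI onset in one SCr series
#'
#' Scans the half-open follow-up interval `(index, index + followup_days]`
#' for the first SCr at or above the criterion threshold.
#'
#' @param scr Data frame with columns `date` (sorted ascending) and `value`
#'   (mg/dL), the person's full SCr series.
#' @param index Index date (first exposure).
#' @param criteria An [aki_criteria()].
#' @return The onset `Date`, or `NULL` if no event within follow-up.
#' @export
detect_aki <- function(scr, index, criteria = aki_criteria()) {
  if (nrow(scr) == 0L) return(NULL)
  if (is.unsorted(scr$date)) stop_contract("SCr series must be sorted by date")
  if (any(scr$value <= 0)) stop_contract("SCr values must be positive")
  index <- as.Date(index)
  if (criteria$baseline_policy == "uln_fixed") {
    baseline <- criteria$uln
  } else {
    pre <- scr$value[scr$date < index & scr$date >= index - criteria$preobs_days]
    baseline <- if (length(pre)) min(mean(pre), criteria$uln) else criteria$uln
  }
  threshold <- criteria$ratio * baseline
  fu <- scr$date > index & scr$date <= index + criteria$followup_days
  hit <- which(fu & scr$value >= threshold)
  if (length(hit) == 0L) return(NULL)
  scr$date[hit[1L]]
}

.event_days <- function(bundle) {
  # All recorded event dates per person across the four event tables, used
  # for the prior-visit inclusion rule.
  rbind(
    data.frame(person_id = bundle$measurement$person_id,
               date = bundle$measurement$date),
    data.frame(person_id = bundle$drug_exposure$person_id,
               date = bundle$drug_exposure$start_date),
    data.frame(person_id = bundle$condition_occurrence$person_id,
               date = bundle$condition_occurrence$date),
    data.frame(person_id = bundle$procedure_occurrence$person_id,
               date = bundle$procedure_occurrence$date))
}

#' Build the case/control cohort for one drug
#'
#' Applies, in fixed order, the inclusion/exclusion rules to every person
#' exposed to `drug`: (1) a visit record at least `min_prior_visit_days`
#' before index, (2) at least `min_preobs_scr` SCr tests in the
#' pre-observation window `[index - preobs_days, index)`, (3) no
#' pre-observation SCr above the ULN. Survivors are labelled case/control by
#' [detect_aki()] over the 60-day follow-up.
#'
#' @param bundle A `cdm_bundle`.
#' @param drug Target drug label.
#' @param criteria An [aki_criteria()].
#' @return A `cohort_table` data frame: one row per exposed person with
#'   columns `person_id, site_id, drug, index_date, label, aki_onset_date,
#'   onset_day, exclusion_reason`. Excluded rows have `label = NA` and a
#'   reason; labelled rows have `exclusion_reason = NA`.
#' @export
apply_eligibility <- function(bundle, drug, criteria = aki_criteria()) {
  idx <- index_dates(bundle, drug)
  n <- length(idx)
  out <- data.frame(
    person_id = names(idx), site_id = bundle$site_id, drug = drug,
    index_date = as.Date(unname(idx)),
    label = rep(NA_character_, n),
    aki_onset_date = as.Date(rep(NA, n)),
    onset_day = rep(NA_integer_, n),
    exclusion_reason = rep(NA_character_, n),
    stringsAsFactors = FALSE)
  if (n == 0L) return(structure(out, class = c("cohort_table", "data.frame")))

  ev <- .event_days(bundle)
  ev <- ev[ev$person_id %in% names(idx), , drop = FALSE]
  first_ev <- tapply(ev$date, ev$person_id, min)
  first_ev <- as.Date(first_ev[names(idx)], origin = "1970-01-01")

  scr_all <- bundle$measurement[bundle$measurement$variable_label == "scr", ,
                                drop = FALSE]
  scr_all <- scr_all[order(scr_all$person_id, scr_all$date), , drop = FALSE]
  scr_by <- split(scr_all[, c("date", "value")], scr_all$person_id)

  for (i in seq_len(n)) {
    p <- out$person_id[i]
    index <- out$index_date[i]
    scr <- scr_by[[p]]
    pre <- if (is.null(scr)) scr_all[0, c("date", "value")] else
      scr[scr$date < index & scr$date >= index - criteria$preobs_days, , drop = FALSE]
    if (is.na(first_ev[i]) || first_ev[i] > index - criteria$min_prior_visit_days) {
      out$exclusion_reason[i] <- "no_prior_visit"
    } else if (nrow(pre) < criteria$min_preobs_scr) {
      out$exclusion_reason[i] <- "insufficient_preobs_scr"
    } else if (any(pre$value > criteria$uln)) {
      out$exclusion_reason[i] <- "preobs_scr_above_uln"
    } else {
      onset <- if (is.null(scr)) NULL else detect_aki(scr, index, criteria)
      if (is.null(onset)) {
        out$label[i] <- "control"
      } else {
        out$label[i] <- "case"
        out$aki_onset_date[i] <- onset
        out$onset_day[i] <- as.integer(onset - index)
      }
    }
  }
  structure(out, class = c("cohort_table", "data.frame"))
}

# ---- demographic summaries ------------------------------------------------

#' Pool per-site summary statistics exactly
#'
#' Exact pooling of per-site `(n, mean, sd)` triples: the pooled mean is the
#' n-weighted mean and the pooled variance combines within-site and
#' between-site sums of squares.
#'
#' @param n,mean,sd Vectors of per-site sizes, means and SDs.
#' @return `c(n, mean, sd)` for the pooled group.
#' @export
pool_summary_stats <- function(n, mean, sd) {
  N <- sum(n)
  M <- sum(n * mean) / N
  if (N > 1) {
    ss <- sum((n - 1) * sd^2) + sum(n * (mean - M)^2)
    S <- sqrt(ss / (N - 1))
  } else S <- 0
  c(n = N, mean = M, sd = S)
}

#' Pool per-site event counts into a count and percentage
#'
#' @param count Per-site event counts.
#' @param n Per-site group sizes.
#' @return `c(count, n, pct)` with the percentage rounded to 2 decimals.
#' @export
pool_counts <- function(count, n) {
  ct <- sum(count); N <- sum(n)
  c(count = ct, n = N, pct = round(100 * ct / N, 2))
}

.sd0 <- function(x) if (length(x) < 2L) 0 else stats::sd(x)

#' Demographic and clinical characteristics table
#'
#' Summarises a labelled cohort per group (case/control) per site, plus
#' pooled totals: group size, age mean (SD), sex counts (%), comorbidity
#' counts (%), and pre-medication laboratory means (SD) (the mean of each
#' person's last value before the index date). Percentages are
#' `count / group n * 100` rounded to 2 decimals; pooled counts equal the
#' sum of site counts.
#'
#' @param cohort A `cohort_table` (possibly row-bound across sites).
#' @param bundles A single `cdm_bundle` or a list of bundles keyed by site.
#' @return Long-format data frame with columns
#'   `characteristic, statistic, group, site, n, value, value2` where
#'   `value`/`value2` hold mean/SD or count/pct.
#' @export
demographics_table <- function(cohort, bundles) {
  if (inherits(bundles, "cdm_bundle")) bundles <- list(bundles)
  names(bundles) <- vapply(bundles, `[[`, character(1), "site_id")
  lab <- cohort[!is.na(cohort$label), , drop = FALSE]
  lab <- lab[!duplicated(paste(lab$site_id, lab$person_id)), , drop = FALSE]
  rows <- list()
  add <- function(char, stat, group, site, n, value, value2) {
    rows[[length(rows) + 1L]] <<- data.frame(
      characteristic = char, statistic = stat, group = group, site = site,
      n = n, value = value, value2 = value2, stringsAsFactors = FALSE)
  }
  labs_wanted <- c("scr", "glucose", "potassium", "sodium", "bun")

  per_site <- list()
  for (site in unique(lab$site_id)) {
    b <- bundles[[site]]
    if (is.null(b)) next
    sl <- lab[lab$site_id == site, , drop = FALSE]
    yob <- stats::setNames(b$person$year_of_birth, b$person$person_id)
    gender <- stats::setNames(b$person$gender, b$person$person_id)
    cond <- b$condition_occurrence
    meas <- b$measurement
    for (grp in c("case", "control")) {
      g <- sl[sl$label == grp, , drop = FALSE]
      ng <- nrow(g)
      add("n", "count", grp, site, ng, ng, NA)
      if (ng == 0L) next
      age <- as.numeric(format(g$index_date, "%Y")) - yob[g$person_id]
      add("age", "mean_sd", grp, site, ng, mean(age), .sd0(age))
      male <- sum(gender[g$person_id] == "M")
      add("male", "count_pct", grp, site, ng, male, round(100 * male / ng, 2))
      add("female", "count_pct", grp, site, ng, ng - male,
          round(100 * (ng - male) / ng, 2))
      pre_cond <- cond[cond$person_id %in% g$person_id, , drop = FALSE]
      for (cc in sort(unique(bundles[[site]]$condition_occurrence$condition_label))) {
        ct <- length(unique(pre_cond$person_id[pre_cond$condition_label == cc]))
        add(cc, "count_pct", grp, site, ng, ct, round(100 * ct / ng, 2))
      }
      idx_by <- stats::setNames(g$index_date, g$person_id)
      mm <- meas[meas$person_id %in% g$person_id &
                   meas$variable_label %in% labs_wanted, , drop = FALSE]
      mm <- mm[mm$date < idx_by[mm$person_id], , drop = FALSE]
      mm <- mm[order(mm$person_id, mm$date), , drop = FALSE]
      for (lv in labs_wanted) {
        ml <- mm[mm$variable_label == lv, , drop = FALSE]
        if (nrow(ml) == 0L) next
        lastv <- tapply(ml$value, ml$person_id, function(v) v[length(v)])
        add(lv, "mean_sd", grp, site, ng, mean(lastv), .sd0(lastv))
      }
    }
  }
  out <- do.call(rbind, rows)
  # pooled rows across sites, by exact pooling arithmetic
  pooled <- list()
  for (grp in c("case", "control")) {
    for (char in unique(out$characteristic)) {
      sub <- out[out$group == grp & out$characteristic == char, , drop = FALSE]
      if (nrow(sub) == 0L) next
      stat <- sub$statistic[1L]
      if (stat == "count") {
        pooled[[length(pooled) + 1L]] <- data.frame(
          characteristic = char, statistic = stat, group = grp, site = "pooled",
          n = sum(sub$n), value = sum(sub$value), value2 = NA)
      } else if (stat == "count_pct") {
        pc <- pool_counts(sub$value, sub$n)
        pooled[[length(pooled) + 1L]] <- data.frame(
          characteristic = char, statistic = stat, group = grp, site = "pooled",
          n = pc[["n"]], value = pc[["count"]], value2 = pc[["pct"]])
      } else {
        ps <- pool_summary_stats(sub$n, sub$value, sub$value2)
        pooled[[length(pooled) + 1L]] <- data.frame(
          characteristic = char, statistic = stat, group = grp, site = "pooled",
          n = ps[["n"]], value = ps[["mean"]], value2 = ps[["sd"]])
      }
    }
  }
  rbind(out, do.call(rbind, pooled))
}
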