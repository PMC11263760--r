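# Seeded multi-site synthetic EHR generator.
#
# Emits OMOP-CDM-style event tables (person, measurement, drug_exposure,
# condition_occurrence, procedure_occurrence) with planted case/control
# structure: confounded AKI assignment, drug-specific right-skewed onset-day
# distributions, prodromal laboratory drift in the case group, and guaranteed
# cohort eligibility for a configurable majority of patients.

# Laboratory catalog: population mean/SD of the per-patient baseline,
# within-patient measurement noise SD, mean sampling gap in days, and unit.
.lab_catalog <- data.frame(
  variable = c("scr", "lymphocytes", "calcium", "albumin", "hemoglobin",
               "cholesterol", "urine_ph", "prothrombin_time", "glucose",
               "potassium", "sodium", "bun", "wbc", "platelets", "alt"),
  mean  = c(0.78, 28, 9.3, 4.0, 12.5, 180, 6.0, 12.5, 120, 4.1, 138.5, 15.5, 7.5, 250, 28),
  sd    = c(0.12, 6, 0.45, 0.4, 1.7, 35, 0.55, 1.1, 38, 0.45, 3.6, 5.5, 2.4, 65, 14),
  noise = c(0.05, 2.0, 0.2, 0.15, 0.4, 10, 0.3, 0.4, 15, 0.15, 1.2, 2.0, 0.8, 20, 5),
  gap   = c(4, 5, 5, 5, 5, 7, 6, 6, 4, 4, 4, 4, 5, 5, 6),
  unit  = c("mg/dL", "%", "mg/dL", "g/dL", "g/dL", "mg/dL", "pH", "s", "mg/dL",
            "mmol/L", "mmol/L", "mg/dL", "10^3/uL", "10^3/uL", "U/L"),
  stringsAsFactors = FALSE
)

.condition_catalog <- c(
  sepsis = 0.03, diabetes_mellitus = 0.16, chronic_kidney_disease = 0.015,
  chronic_liver_disease = 0.08, hypertension = 0.25, neoplasm = 0.52,
  heart_failure = 0.035, anemia = 0.06, hypotension = 0.002, obesity = 0.003)

.comedication_catalog <- c(
  furosemide = 0.10, omeprazole = 0.20, metformin = 0.12, aspirin = 0.15,
  atorvastatin = 0.12, amlodipine = 0.10, cisplatin = 0.08,
  piperacillin_tazobactam = 0.06)

.procedure_catalog <- c(contrast_ct = 0.25, major_surgery = 0.10, hemodialysis = 0.01)

#' Target nephrotoxic drugs covered by the pipeline
#' @return Character vector of the five target drug labels.
#' @export
target_drugs <- function() {
  c("acetaminophen", "vancomycin", "naproxen", "celecoxib", "acyclovir")
}

# Default onset-day distributions: lognormal (log-median, log-sd) per drug,
# parameterised from published median/IQR summaries of drug-induced AKI onset
# (log-sd = log(q3/q1) / (2 * qnorm(0.75))).
.default_onset_lognormal <- function() {
  med <- c(acetaminophen = 19, vancomycin = 12, naproxen = 18,
           celecoxib = 22, acyclovir = 23)
  q1  <- c(acetaminophen = 9,  vancomycin = 5,  naproxen = 8,
           celecoxib = 10, acyclovir = 10)
  q3  <- c(acetaminophen = 34, vancomycin = 25, naproxen = 34,
           celecoxib = 41, acyclovir = 41)
  out <- lapply(names(med), function(d) {
    c(log_median = log(med[[d]]), log_sd = log(q3[[d]] / q1[[d]]) / (2 * stats::qnorm(0.75)))
  })
  names(out) <- names(med)
  out
}

# Default case-group prodromal drift, units per week over the 28 days before
# AKI onset: lymphocytes, albumin and hemoglobin decline; urine pH and
# prothrombin time rise.
.default_drift_effects <- function() {
  c(lymphocytes = -1.5, albumin = -0.12, hemoglobin = -0.35,
    urine_ph = 0.12, prothrombin_time = 0.5)
}

#' Configuration for one synthetic hospital site
#'
#' Defines the simulated study conditions for a single site: cohort size,
#' drug mix, demographics, comorbidity prevalences, the planted AKI rate and
#' per-drug onset distributions, the strength of confounding between case
#' status and age/sex/baseline creatinine, and the prodromal drift applied to
#' case trajectories.
#'
#' @param site_id Site label (e.g. `"SH"`).
#' @param n_patients Number of exposed patients to simulate.
#' @param drug_mix Named probability vector over target drugs; must sum to 1.
#' @param age_mean,age_sd Age distribution in years.
#' @param male_frac Proportion of male patients.
#' @param comorbidity_prev Named vector of condition prevalences.
#' @param aki_frac Proportion of exposed patients who develop AKI.
#' @param onset_lognormal Named list, per drug, of `c(log_median, log_sd)` for
#'   the AKI onset-day distribution after the index date. The sampler is
#'   calibrated so that the 60-day-truncated distribution keeps its median at
#'   `exp(log_median)`.
#' @param confound_strength Log-odds scale multiplier coupling standardized
#'   age, male sex and baseline serum creatinine to case status.
#' @param drift_effects Named vector of per-week slopes applied to case-group
#'   laboratory trajectories over the 28 days before onset.
#' @param uln Upper limit of normal for serum creatinine (mg/dL).
#' @param spoiler_frac Proportion of patients deliberately generated to fail
#'   one eligibility rule, to exercise the cohort module's exclusions.
#' @param seed Integer seed; the bundle is deterministic given the config.
#' @return A `site_sim_config` object (validated list).
#' @export
site_sim_config <- function(site_id, n_patients,
                            drug_mix = NULL,
                            age_mean = 60, age_sd = 15.5,
                            male_frac = 0.58,
                            comorbidity_prev = .condition_catalog,
                            aki_frac = 0.12,
                            onset_lognormal = .default_onset_lognormal(),
                            confound_strength = 1,
                            drift_effects = .default_drift_effects(),
                            uln = 1.2,
                            spoiler_frac = 0,
                            seed = 1L) {
  if (!is.character(site_id) || length(site_id) != 1L || !nzchar(site_id))
    stop_config("site_id must be a non-empty string")
  assert_count(n_patients, "n_patients")
  # accept list forms (as produced by YAML round trips)
  if (is.list(drug_mix)) drug_mix <- unlist(drug_mix)
  if (is.list(comorbidity_prev)) comorbidity_prev <- unlist(comorbidity_prev)
  if (is.list(drift_effects)) drift_effects <- unlist(drift_effects)
  onset_lognormal <- lapply(onset_lognormal, function(x) unname(unlist(x)))
  if (is.null(drug_mix)) {
    # default exposure mix: common analgesics/antibiotics dominate, the
    # antiviral is rarest; under the default per-drug onset distributions
    # this mix pools to the published overall onset profile (median 17 d)
    drug_mix <- c(acetaminophen = 0.30, vancomycin = 0.30, naproxen = 0.15,
                  celecoxib = 0.15, acyclovir = 0.10)
  }
  assert_prob(drug_mix, "drug_mix")
  if (abs(sum(drug_mix) - 1) > 1e-8)
    stop_config("drug_mix must sum to 1")
  if (is.null(names(drug_mix)) || !all(names(drug_mix) %in% target_drugs()))
    stop_config("drug_mix names must be target drugs")
  assert_prob(male_frac, "male_frac")
  assert_prob(comorbidity_prev, "comorbidity_prev")
  assert_prob(aki_frac, "aki_frac")
  assert_prob(spoiler_frac, "spoiler_frac")
  for (d in names(drug_mix)) {
    ol <- onset_lognormal[[d]]
    if (is.null(ol) || length(ol) != 2L || !is.finite(ol[1]) || ol[2] <= 0)
      stop_config("onset_lognormal must give (log_median, log_sd) for drug ", d)
    if (exp(ol[1]) <= 0 || exp(ol[1]) >= 55)
      stop_config("onset median for ", d, " must be positive and well below 60 days")
  }
  if (uln <= 0) stop_config("uln must be positive")
  structure(list(
    site_id = site_id, n_patients = as.integer(n_patients), drug_mix = drug_mix,
    age_mean = age_mean, age_sd = age_sd, male_frac = male_frac,
    comorbidity_prev = comorbidity_prev, aki_frac = aki_frac,
    onset_lognormal = onset_lognormal, confound_strength = confound_strength,
    drift_effects = drift_effects, uln = uln, spoiler_frac = spoiler_frac,
    seed = as.integer(seed)), class = "site_sim_config")
}

# Shift meanlog so the 60-day-truncated lognormal has median `target_median`.
# Without this correction the truncation drags long-onset drugs (median 22-23
# days, heavy right tail) several days early.
.calibrate_onset_meanlog <- function(target_median, sdlog, cap = 60) {
  trunc_median <- function(m) {
    exp(m + sdlog * stats::qnorm(0.5 * stats::pnorm((log(cap) - m) / sdlog)))
  }
  f <- function(m) trunc_median(m) - target_median
  stats::uniroot(f, lower = log(target_median), upper = log(cap) + 3 * sdlog,
                 tol = 1e-10)$root
}

.sample_onset_days <- function(n, log_median, log_sd, cap = 60) {
  if (n == 0L) return(integer(0))
  meanlog <- .calibrate_onset_meanlog(exp(log_median), log_sd, cap)
  out <- numeric(0)
  while (length(out) < n) {
    draw <- stats::rlnorm(2 * (n - length(out)) + 10, meanlog, log_sd)
    draw <- draw[draw <= cap]
    out <- c(out, draw)
  }
  pmax(1L, as.integer(round(out[seq_len(n)])))
}

#' Generate one synthetic site bundle
#'
#' Produces a `cdm_bundle`: the five OMOP-subset event tables for one site,
#' deterministic given the config seed. Every non-spoiler patient has at
#' least two pre-index serum creatinine measurements at or below the ULN
#' within the 60 days before index and an event record at least 30 days
#' before index, so the cohort module's inclusion rules pass by construction.
#' Planted cases reach `2 * uln` serum creatinine on their drawn onset day
#' and carry prodromal drift in the configured laboratory variables over the
#' 28 days before onset.
#'
#' The planted ground truth (case status, onset day, spoiler type) is
#' attached as `attr(bundle, "truth")` for calibration checks; the pipeline
#' itself never reads it.
#'
#' @param config A [site_sim_config()].
#' @return A `cdm_bundle` (list of five data frames plus `site_id`).
#' @export
generate_site <- function(config) {
  if (!inherits(config, "site_sim_config")) config <- do.call(site_sim_config, config)
  set.seed(config$seed)
  n <- config$n_patients
  uln <- config$uln
  pid <- sprintf("%s-%05d", config$site_id, seq_len(n))

  age <- pmin(95, pmax(18, round(stats::rnorm(n, config$age_mean, config$age_sd))))
  male <- stats::rbinom(n, 1, config$male_frac)
  drug <- sample(names(config$drug_mix), n, replace = TRUE, prob = config$drug_mix)
  index_day <- sample(70:120, n, replace = TRUE)
  scr_base <- pmin(1.05, pmax(0.4, stats::rnorm(n, 0.78, 0.12)))

  # Confounded case assignment: logistic in standardized age, sex, baseline
  # SCr, with the intercept calibrated so the expected case fraction equals
  # aki_frac under the realized covariates.
  if (config$aki_frac == 0) {
    is_case <- rep(FALSE, n)
  } else if (config$aki_frac == 1) {
    is_case <- rep(TRUE, n)
  } else {
    z_age <- (age - config$age_mean) / config$age_sd
    z_scr <- (scr_base - 0.78) / 0.12
    eta <- config$confound_strength * (0.5 * z_age + 0.4 * male + 0.5 * z_scr)
    a0 <- stats::uniroot(function(a) mean(stats::plogis(a + eta)) - config$aki_frac,
                         lower = -30, upper = 30, tol = 1e-10)$root
    is_case <- stats::runif(n) < stats::plogis(a0 + eta)
  }

  onset_day <- rep(NA_integer_, n)
  for (d in unique(drug[is_case])) {
    sel <- is_case & drug == d
    ol <- config$onset_lognormal[[d]]
    onset_day[sel] <- .sample_onset_days(sum(sel), ol[1], ol[2])
  }

  # Spoilers deliberately fail one eligibility rule each (cycled).
  spoiler <- rep("none", n)
  if (config$spoiler_frac > 0) {
    ns <- round(config$spoiler_frac * n)
    if (ns > 0) {
      idx <- sample(n, ns)
      spoiler[idx] <- rep(c("no_prior_visit", "insufficient_preobs_scr",
                            "preobs_scr_above_uln"), length.out = ns)
    }
  }

  person <- data.frame(person_id = pid, gender = ifelse(male == 1, "M", "F"),
                       year_of_birth = 2015L - age, stringsAsFactors = FALSE)

  # --- measurements -------------------------------------------------------
  drift <- config$drift_effects
  meas_list <- vector("list", nrow(.lab_catalog))
  for (li in seq_len(nrow(.lab_catalog))) {
    lab <- .lab_catalog[li, ]
    base_i <- stats::rnorm(n, lab$mean, lab$sd)
    # Irregular sampling: cumulative 1 + Poisson gaps across the observation
    # span [index - 60, index + 60], per patient.
    max_draws <- ceiling(130 / lab$gap) + 6
    gaps <- matrix(1L + stats::rpois(n * max_draws, lab$gap - 1), nrow = n)
    start <- index_day - 60 + sample.int(lab$gap, n, replace = TRUE) - 1L
    days <- start + t(apply(gaps, 1, cumsum)) - gaps # first draw at `start`
    keep <- days <= index_day + 60
    pidx <- row(days)[keep]
    day <- days[keep]
    val <- base_i[pidx] + stats::rnorm(length(day), 0, lab$noise)
    if (lab$variable == "scr") {
      # Forced pre-index SCr draws guarantee eligibility (>= 2 pre-obs tests
      # and a visit record >= 30 days before index).
      pidx <- c(pidx, seq_len(n), seq_len(n))
      day <- c(day, index_day - 50L, index_day - 10L)
      val <- c(val, scr_base + stats::rnorm(n, 0, 0.03),
               scr_base + stats::rnorm(n, 0, 0.03))
      pre <- day < index_day[pidx]
      val[pre] <- pmin(val[pre], uln)          # eligibility by construction
      post <- !pre
      val[post] <- pmin(val[post], 1.6 * uln)  # controls never reach 2 x ULN
      # Case SCr: ramp over the final 7 pre-onset days, spike >= 2 x ULN at
      # onset, sustained elevation after.
      od <- onset_day[pidx]
      rel <- day - index_day[pidx]
      ramp <- is_case[pidx] & !is.na(od) & rel > 0 & rel >= od - 7 & rel < od
      val[ramp] <- pmin(scr_base[pidx[ramp]] +
                          (rel[ramp] - (od[ramp] - 7)) / 7 * 0.8, 1.9 * uln)
      elev <- is_case[pidx] & !is.na(od) & rel > od
      val[elev] <- 2 * uln + abs(stats::rnorm(sum(elev), 0.3, 0.2))
      # onset-day measurement added below as a forced row
    } else if (lab$variable %in% names(drift)) {
      od <- onset_day[pidx]
      rel <- day - index_day[pidx]
      dr <- is_case[pidx] & !is.na(od) & rel >= od - 28 & rel < od
      val[dr] <- val[dr] + drift[[lab$variable]] * (rel[dr] - (od[dr] - 28)) / 7
    }
    meas_list[[li]] <- data.frame(
      person_id = pid[pidx], variable_label = lab$variable,
      day = as.integer(day), value = round(val, 3), unit = lab$unit,
      stringsAsFactors = FALSE)
  }
  # Forced onset-day SCr spike for every planted case.
  ci <- which(is_case)
  if (length(ci)) {
    meas_list[[length(meas_list) + 1L]] <- data.frame(
      person_id = pid[ci], variable_label = "scr",
      day = as.integer(index_day[ci] + onset_day[ci]),
      value = round(2 * uln * (1 + abs(stats::rnorm(length(ci), 0.05, 0.05))), 3),
      unit = "mg/dL", stringsAsFactors = FALSE)
  }
  measurement <- do.call(rbind, meas_list)

  # Apply spoilers.
  sp1 <- spoiler[match(measurement$person_id, pid)] == "no_prior_visit"
  early <- measurement$day <= (index_day[match(measurement$person_id, pid)] - 30L)
  measurement <- measurement[!(sp1 & early), , drop = FALSE]
  sp2 <- which(spoiler == "insufficient_preobs_scr")
  if (length(sp2)) {
    drop <- logical(nrow(measurement))
    mp <- match(measurement$person_id, pid)
    pre_scr <- measurement$variable_label == "scr" &
      measurement$day < index_day[mp] & measurement$day >= index_day[mp] - 60L
    for (i in sp2) {
      rows <- which(pre_scr & mp == i)
      if (length(rows) > 1L) drop[rows[-length(rows)]] <- TRUE
    }
    measurement <- measurement[!drop, , drop = FALSE]
  }
  sp3 <- which(spoiler == "preobs_scr_above_uln")
  if (length(sp3)) {
    mp <- match(measurement$person_id, pid)
    pre_scr <- measurement$variable_label == "scr" &
      measurement$day < index_day[mp] & measurement$day >= index_day[mp] - 60L
    for (i in sp3) {
      rows <- which(pre_scr & mp == i)
      if (length(rows)) {
        measurement$value[rows[1L]] <- round(uln + stats::runif(1, 0.1, 0.8), 3)
      }
    }
  }

  # --- drug exposures -----------------------------------------------------
  target <- data.frame(person_id = pid, drug_label = drug, day = index_day,
                       stringsAsFactors = FALSE)
  repeat1 <- stats::runif(n) < 0.6
  repeats <- data.frame(person_id = pid[repeat1], drug_label = drug[repeat1],
                        day = index_day[repeat1] + 7L, stringsAsFactors = FALSE)
  co_list <- lapply(names(.comedication_catalog), function(cm) {
    has <- stats::runif(n) < .comedication_catalog[[cm]]
    data.frame(person_id = pid[has], drug_label = rep(cm, sum(has)),
               day = index_day[has] + sample(-25:40, sum(has), replace = TRUE),
               stringsAsFactors = FALSE)
  })
  drug_exposure <- do.call(rbind, c(list(target, repeats), co_list))

  # --- conditions (prevalent before index) --------------------------------
  cond_list <- lapply(names(config$comorbidity_prev), function(cc) {
    has <- stats::runif(n) < config$comorbidity_prev[[cc]]
    off <- ifelse(spoiler == "no_prior_visit",
                  sample(10:28, n, replace = TRUE),
                  sample(10:90, n, replace = TRUE))
    data.frame(person_id = pid[has], condition_label = rep(cc, sum(has)),
               day = index_day[has] - off[has], stringsAsFactors = FALSE)
  })
  condition_occurrence <- do.call(rbind, cond_list)

  # --- procedures ---------------------------------------------------------
  proc_list <- lapply(names(.procedure_catalog), function(pp) {
    has <- stats::runif(n) < .procedure_catalog[[pp]]
    data.frame(person_id = pid[has], procedure_label = rep(pp, sum(has)),
               day = index_day[has] + sample(-20:40, sum(has), replace = TRUE),
               stringsAsFactors = FALSE)
  })
  procedure_occurrence <- do.call(rbind, proc_list)

  to_date <- function(df) {
    df$date <- sim_day_to_date(df$day)
    df$day <- NULL
    rownames(df) <- NULL
    df
  }
  measurement <- to_date(measurement)
  measurement <- measurement[, c("person_id", "variable_label", "date", "value", "unit")]
  drug_exposure <- to_date(drug_exposure)
  names(drug_exposure)[names(drug_exposure) == "date"] <- "start_date"
  condition_occurrence <- to_date(condition_occurrence)
  procedure_occurrence <- to_date(procedure_occurrence)

  bundle <- structure(list(
    person = person, measurement = measurement, drug_exposure = drug_exposure,
    condition_occurrence = condition_occurrence,
    procedure_occurrence = procedure_occurrence,
    site_id = config$site_id), class = "cdm_bundle")
  attr(bundle, "truth") <- data.frame(
    person_id = pid, drug = drug, index_day = index_day,
    is_case = is_case, onset_day = onset_day, spoiler = spoiler,
    age = age, male = male, scr_baseline = scr_base, stringsAsFactors = FALSE)
  attr(bundle, "seed") <- config$seed
  bundle
}

#' @export
print.cdm_bundle <- function(x, ...) {
  cat("<cdm_bundle> site", x$site_id, "\n")
  for (tb in c("person", "measurement", "drug_exposure", "condition_occurrence",
               "procedure_occurrence")) {
    cat(sprintf("  %-22s %7d rows\n", tb, nrow(x[[tb]])))
  }
  invisible(x)
}

#' Generate bundles for several sites
#'
#' @param configs List of [site_sim_config()] objects with distinct site ids.
#' @return List of `cdm_bundle` objects, one per config.
#' @export
generate_multisite <- function(configs) {
  if (length(configs) < 1L) stop_config("at least one site config required")
  ids <- vapply(configs, function(cf) cf$site_id, character(1))
  if (anyDuplicated(ids)) stop_config("duplicate site_id: ", ids[duplicated(ids)][1])
  lapply(configs, generate_site)
}

.bundle_tables <- c("person", "measurement", "drug_exposure",
                    "condition_occurrence", "procedure_occurrence")

#' Write a bundle to CSV files
#'
#' One CSV per CDM table plus a JSON manifest recording files, row counts,
#' site and the generating seed.
#'
#' @param bundle A `cdm_bundle`.
#' @param directory Output directory (created if missing).
#' @return The manifest, invisibly.
#' @export
write_bundle <- function(bundle, directory) {
  dir.create(directory, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(directory)) stop("cannot create directory: ", directory)
  files <- list()
  for (tb in .bundle_tables) {
    path <- file.path(directory, paste0(tb, ".csv"))
    utils::write.csv(bundle[[tb]], path, row.names = FALSE)
    files[[tb]] <- list(file = paste0(tb, ".csv"), rows = nrow(bundle[[tb]]))
  }
  manifest <- list(site_id = bundle$site_id, tables = files,
                   seed = attr(bundle, "seed"))
  jsonlite::write_json(manifest, file.path(directory, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(manifest)
}

#' Read a bundle written by [write_bundle()]
#' @param directory Directory containing the five CSV tables and manifest.
#' @return A `cdm_bundle`.
#' @export
read_bundle <- function(directory) {
  manifest <- jsonlite::read_json(file.path(directory, "manifest.json"))
  out <- list()
  for (tb in .bundle_tables) {
    df <- utils::read.csv(file.path(directory, paste0(tb, ".csv")),
                          stringsAsFactors = FALSE,
                          colClasses = c(person_id = "character"))
    for (dc in intersect(c("date", "start_date"), names(df))) df[[dc]] <- as.Date(df[[dc]])
    out[[tb]] <- df
  }
  out$site_id <- manifest$site_id
  structure(out, class = "cdm_bundle")
}
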