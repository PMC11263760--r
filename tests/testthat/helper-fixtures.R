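# Shared fixtures: all data is generated in code at test time.

# Planted-signal window tensor: standard-normal noise everywhere, with a
# mean shift added to variable `k` over the final week of positive windows.
make_planted_windows <- function(n, V = 6L, Tt = 28L, k = 3L, shift = 1.5,
                                 seed = 1L) {
  set.seed(seed)
  x <- array(stats::rnorm(n * Tt * V), c(n, Tt, V),
             dimnames = list(NULL, NULL, paste0("v", seq_len(V))))
  y <- stats::rbinom(n, 1, 0.5)
  for (i in which(y == 1)) x[i, (Tt - 6):Tt, k] <- x[i, (Tt - 6):Tt, k] + shift
  meta <- data.frame(person_id = sprintf("p%05d", seq_len(n)), start_day = 0L,
                     site_id = "S", drug = "d", label = y,
                     stringsAsFactors = FALSE)
  structure(list(data = x, labels = y, meta = meta), class = "window_tensor")
}

# Minimal hand-built daily grid for window tests: one control person with a
# span of L days and a single constant variable.
toy_grid <- function(L, person = "p1") {
  days <- 0:L
  g <- list(matrix(1, nrow = length(days), ncol = 1,
                   dimnames = list(days, "x")))
  names(g) <- person
  structure(g, class = "daily_grid",
            variables = data.frame(variable = "x", kind = "lab"),
            days = days)
}

toy_cohort_row <- function(person = "p1", label = "control",
                           onset_day = NA_integer_, site = "S", drug = "d") {
  structure(data.frame(
    person_id = person, site_id = site, drug = drug,
    index_date = as.Date("2015-03-01"), label = label,
    aki_onset_date = as.Date(NA), onset_day = onset_day,
    exclusion_reason = NA_character_, stringsAsFactors = FALSE),
    class = c("cohort_table", "data.frame"))
}

# A small single-drug site used by several files; memoised per options key.
shared_bundle <- local({
  cache <- list()
  function(n = 600L, seed = 42L, spoiler_frac = 0, drug = "vancomycin") {
    key <- paste(n, seed, spoiler_frac, drug)
    if (is.null(cache[[key]])) {
      cfg <- site_sim_config("T1", n, drug_mix = stats::setNames(1, drug),
                             seed = seed, spoiler_frac = spoiler_frac)
      cache[[key]] <<- generate_site(cfg)
    }
    cache[[key]]
  }
})
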