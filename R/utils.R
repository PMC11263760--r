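# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_config <- function(...) {
  stop(structure(class = c("akitrace_config_error", "error", "condition"),
                 list(message = paste0(...), call = sys.call(-1))))
}

stop_contract <- function(...) {
  stop(structure(class = c("akitrace_contract_error", "error", "condition"),
                 list(message = paste0(...), call = sys.call(-1))))
}

assert_prob <- function(x, what) {
  if (!is.numeric(x) || anyNA(x) || any(x < 0) || any(x > 1))
    stop_config(what, " must be a probability in [0, 1]")
  invisible(x)
}

assert_count <- function(x, what) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x <= 0 || x != floor(x))
    stop_config(what, " must be a positive integer")
  invisible(x)
}

#' Derive a reproducible sub-seed from a global seed
#'
#' Stage seeds are derived from the global seed and a small set of integer
#' indices by a fixed linear-congruential fold, so partial reruns of a
#' pipeline stage see the same stream as the full run. The result is always
#' in `[1, 2^31 - 2]`.
#'
#' @param seed Global integer seed.
#' @param ... Integer indices identifying the stage (site index, drug index,
#'   stage number, replicate, ...).
#' @return A single integer seed.
#' @export
derive_seed <- function(seed, ...) {
  idx <- c(...)
  h <- as.double(seed) %% 2147483647
  for (k in seq_along(idx)) {
    h <- (h * 48271 + as.double(idx[k]) * 9973 + 101 * k) %% 2147483647
  }
  as.integer(h %% 2147483645 + 1)
}

# Simulation day <-> calendar date. Day 0 of every simulated site is anchored
# at a fixed epoch so date arithmetic is reproducible across runs.
.akitrace_epoch <- as.Date("2015-01-01")

sim_day_to_date <- function(day) .akitrace_epoch + as.integer(round(day))

date_to_sim_day <- function(date) as.integer(as.Date(date) - .akitrace_epoch)
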