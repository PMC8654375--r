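#' @importFrom rlang .data abort warn
#' @importFrom ggplot2 autoplot
#' @importFrom tibble tibble as_tibble
#' @import Rcpp
#' @useDynLib vhgate, .registration = TRUE
NULL

# Run code with a temporary RNG seed, restoring the caller's RNG state.
local_seed <- function(seed, code) {
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    stats::runif(1)
  }
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  force(code)
}

#' Derive a reproducible child seed from a master seed
#'
#' Child seeds are drawn from the master-seeded RNG stream by counter
#' position, so a grid of runs can be extended (new counters appended)
#' without reshuffling the seeds of runs already performed.
#'
#' @param master_seed Integer master seed.
#' @param counter Positive integer counter (1-based position of the run).
#' @return An integer seed in `[1, 2^31 - 2]`.
#' @export
child_seed <- function(master_seed, counter) {
  stopifnot(length(counter) == 1, counter >= 1)
  local_seed(master_seed, sample.int(.Machine$integer.max - 1L, counter)[counter])
}

check_fraction <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1 || is.na(x) || x < 0 || x > 1) {
    abort(sprintf("`%s` must be a single value in [0, 1], got %s",
                  name, paste(format(x), collapse = ", ")))
  }
  as.numeric(x)
}
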