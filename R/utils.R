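# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Evaluate code under a temporary RNG seed
#'
#' Runs `code` with the RNG seeded at `seed` and restores the caller's RNG
#' state afterwards, so simulator stages are reproducible without clobbering
#' the session stream.
#' @noRd
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  }, add = TRUE)
  set.seed(seed)
  code
}

# Fixed fan-out from the single global seed to per-stage child seeds, so any
# stage can be re-run independently. Stage offsets: 1 baselines, 2 planted
# effects, 3 panel counts, 4 causal network, 5 trial cohort, 6 survival.
child_seed <- function(seed, stage) {
  as.integer(seed) * 101L + as.integer(stage)
}

geo_mean <- function(x) exp(mean(log(x)))

is_count <- function(x) {
  is.numeric(x) && length(x) == 1L && is.finite(x) && x >= 0 && x == round(x)
}
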