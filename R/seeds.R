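#' Derive reproducible stage seeds from a master seed
#'
#' All stochastic stages of a build or simulation (FSI placement, lateral
#' wiring, feedforward wiring, cortical assignment, input generation, ...)
#' draw their own sub-seed from a single master seed, so each stage is
#' independently reproducible and stages do not share RNG state.
#'
#' Sub-seeds are produced by a fixed multiplicative congruential map over the
#' Mersenne prime 2^31 - 1, keeping every seed a valid 32-bit R integer.
#'
#' @param master integer master seed.
#' @param stage  integer stage index (>= 0) or one of the named stages in
#'   [stage_index()].
#' @return a single integer seed in `[1, 2^31 - 2]`.
#' @export
#' @examples
#' derive_seed(42, 0)
#' derive_seed(42, "lateral")
derive_seed <- function(master, stage) {
  if (is.character(stage)) stage <- stage_index(stage)
  stopifnot(is.numeric(master), length(master) == 1, is.finite(master),
            is.numeric(stage), stage >= 0)
  m <- 2147483647 # 2^31 - 1
  x <- (abs(as.numeric(master)) %% m)
  # a few rounds of a Lehmer-style mix keyed by the stage index
  a <- 48271
  x <- (x + 104729 * (stage + 1)) %% m
  for (i in 1:3) x <- (a * x + 12345) %% m
  s <- as.integer(x %% (m - 2)) + 1L
  s
}

#' Named stage indices for seed streaming
#'
#' @param name one of `"fsi_placement"`, `"lateral"`, `"feedforward"`,
#'   `"cortical"`, `"inputs"`, `"drive"`, `"noise"`.
#' @return integer index used by [derive_seed()].
#' @export
stage_index <- function(name) {
  stages <- c(fsi_placement = 0L, lateral = 1L, feedforward = 2L,
              cortical = 3L, inputs = 4L, drive = 5L, noise = 6L)
  if (!name %in% names(stages)) stop("unknown seed stage: ", name)
  stages[[name]]
}

# run expr with a temporary RNG state seeded by `seed`; restores global state
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}
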