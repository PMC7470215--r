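#' Derive a stage-specific sub-seed from a global seed
#'
#' Combines the global seed with a polynomial hash of the stage name so that
#' inserting or reordering stages never shifts another stage's random stream.
#' The result is always a positive integer below 2^31.
#'
#' @param seed integer global seed.
#' @param stage character stage name.
#' @return an integer seed.
#' @export
derive_seed <- function(seed, stage) {
  stopifnot(is.numeric(seed), length(seed) == 1, is.character(stage))
  m <- 2147483647 # 2^31 - 1, kept in double precision throughout
  h <- 0
  for (k in utf8ToInt(stage)) h <- (h * 131 + k) %% m
  as.integer((abs(seed) %% m * 2654435761 %% m + h) %% m + 1)
}

# Evaluate code with a private RNG stream; restores .Random.seed on exit.
with_seed <- function(seed, code) {
  env <- globalenv()
  had <- exists(".Random.seed", envir = env, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = env) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = env)
    else if (exists(".Random.seed", envir = env, inherits = FALSE))
      rm(".Random.seed", envir = env)
  })
  set.seed(seed)
  force(code)
}

# Column means / sds with zero-variance guard (sd 0 -> 1 so z-scores stay 0).
feature_scaling <- function(x) {
  x <- as.matrix(x)
  ctr <- colMeans(x)
  scl <- apply(x, 2, stats::sd)
  scl[!is.finite(scl) | scl == 0] <- 1
  list(center = ctr, scale = scl)
}

apply_scaling <- function(x, scaling) {
  x <- as.matrix(x)
  sweep(sweep(x, 2, scaling$center, "-"), 2, scaling$scale, "/")
}

`%||%` <- function(a, b) if (is.null(a)) b else a
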