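# Internal helpers shared across modules.

# Clipping floor applied before any log transform of sleepiness scores or
# theta/alpha ratios (both can be ~0). Shared between the simulator and the
# trajectory-fit code so that recovery tests are sharp.
LOG_FLOOR <- 1e-3

#' Evaluate code under a temporary RNG seed
#'
#' Saves and restores `.Random.seed` so that seeded helpers do not disturb
#' the caller's RNG stream.
#' @noRd
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Derive a per-session seed from a study seed and session indices
#'
#' Deterministic integer hash of (participant, day, session) indices, kept
#' below 2^31 so it is a valid R seed. All session-level randomness flows
#' from the study seed through this derivation.
#' @noRd
derive_seed <- function(study_seed, participant, day, session) {
  m <- 2147483647
  h <- as.double(study_seed %% m)
  for (k in c(participant, day, session)) {
    h <- (h * 69069 + as.double(k) * 10007 + 1) %% m
  }
  as.integer(h)
}

#' Parse "HH:MM" clock labels to minutes since midnight
#' @noRd
clock_to_min <- function(x) {
  if (is.numeric(x)) return(x)
  parts <- strsplit(as.character(x), ":", fixed = TRUE)
  vapply(parts, function(p) {
    if (length(p) != 2L) stop("clock time must be 'HH:MM', got: ", paste(p, collapse = ":"))
    as.numeric(p[1]) * 60 + as.numeric(p[2])
  }, numeric(1))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stopifnot_finite <- function(x, name) {
  if (!all(is.finite(x))) stop("non-finite value in ", name)
  invisible(x)
}
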