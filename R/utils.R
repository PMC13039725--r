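# Internal helpers shared across modules.

#' Evaluate an expression under a temporary RNG state
#'
#' Sets the seed, runs `expr`, and restores the caller's RNG state, so
#' generators are bit-reproducible without disturbing the session.
#' @noRd
with_seed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed)) {
    stop("`seed` must be a single integer", call. = FALSE)
  }
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  }, add = TRUE)
  set.seed(as.integer(seed))
  expr
}

#' Derive a stage-specific seed from a global seed
#'
#' Deterministic hash of the stage name folded into the global seed so each
#' pipeline stage has its own reproducible stream. Result is kept below 2^31.
#' @param seed integer global seed.
#' @param stage character stage label.
#' @return integer seed.
#' @export
stage_seed <- function(seed, stage) {
  stopifnot(is.character(stage), length(stage) == 1L)
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  as.integer((as.numeric(seed) * 48271 + h * 16807) %% 2147483587)
}

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

# Population (divisor n) standard deviation.
pop_sd <- function(x) {
  m <- mean(x)
  sqrt(mean((x - m)^2))
}

# Row-wise minimum Manhattan distance from each row of `a` to the rows of `b`.
# Used by the disappearing/novel bioclimate scans; exact, no subsampling.
min_cross_manhattan <- function(a, b) {
  a <- as.matrix(a); b <- as.matrix(b)
  stopifnot(ncol(a) == ncol(b), nrow(b) >= 1L)
  bt <- t(b)
  out <- numeric(nrow(a))
  for (i in seq_len(nrow(a))) {
    out[i] <- min(colSums(abs(bt - a[i, ])))
  }
  out
}

# Full cross Manhattan distance matrix (rows of a x rows of b).
cross_manhattan <- function(a, b) {
  a <- as.matrix(a); b <- as.matrix(b)
  stopifnot(ncol(a) == ncol(b))
  bt <- t(b)
  out <- matrix(0, nrow(a), nrow(b))
  for (i in seq_len(nrow(a))) {
    out[i, ] <- colSums(abs(bt - a[i, ]))
  }
  out
}
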