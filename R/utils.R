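# Internal helpers shared across modules.

#' Derive a reproducible substream seed
#'
#' Maps a master seed and a stream label to a deterministic integer seed
#' strictly below 2^31, so that independent simulation components (MAF
#' sampling, genotype sampling, per-replicate cohorts) each get their own
#' reproducible stream from one master seed.
#'
#' @param seed master integer seed.
#' @param stream character label naming the stream.
#' @return an integer seed.
#' @examples
#' substream_seed(1, "replicate_001")
#' @export
substream_seed <- function(seed, stream) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  h <- sum(utf8ToInt(stream) * seq_along(utf8ToInt(stream)))
  as.integer((abs(seed) * 48271 + h * 16807) %% 2147483587)
}

# Evaluate expr with the RNG seeded at `seed`, restoring the caller's RNG
# state afterwards.
with_seed <- function(seed, expr) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_coxscan <- function(msg, class) {
  stop(structure(class = c(class, "coxscan_error", "error", "condition"),
                 list(message = msg, call = sys.call(-1))))
}
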