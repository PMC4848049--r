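# Internal helpers: classed conditions and local RNG scope.

stopWithClass <- function(class, msg) {
  stop(errorCondition(msg, class = c(class, "mapgap_error")))
}

abortArgument    <- function(msg) stopWithClass("mapgap_argument_error", msg)
abortDegenerate  <- function(msg) stopWithClass("mapgap_degenerate_error", msg)
abortMismatch    <- function(msg) stopWithClass("mapgap_calibration_mismatch", msg)
abortNoBeats     <- function(msg) stopWithClass("mapgap_no_beats_error", msg)
abortWindow      <- function(msg) stopWithClass("mapgap_window_error", msg)
abortLookup      <- function(msg) stopWithClass("mapgap_lookup_error", msg)
abortReference   <- function(msg) stopWithClass("mapgap_reference_error", msg)

# Evaluate `code` under a given seed without disturbing the caller's RNG
# stream. Seeds are plain integers so identical (seed, config) inputs give
# bit-identical output.
withSeed <- function(seed, code) {
  if (!is.null(seed) && !is.na(seed)) {
    had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    if (had) old <- get(".Random.seed", envir = globalenv(), inherits = FALSE)
    on.exit({
      if (had) {
        assign(".Random.seed", old, envir = globalenv())
      } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    })
    set.seed(as.integer(seed))
  }
  force(code)
}

# Derive a per-unit child seed from a master seed, kept within 32-bit range.
childSeed <- function(seed, i) {
  as.integer((as.numeric(seed) * 1009 + i) %% 2147483647L)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

isScalarNumber <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)

utils::globalVariables(c("col", "row", "status", "siteId"))

# Sample indices i with a <= t[i] <= b for the implicit axis t[i] = (i-1)/fs.
idxRange <- function(a, b, fs, n) {
  i0 <- max(1L, as.integer(ceiling(a * fs + 1 - 1e-9)))
  i1 <- min(n, as.integer(floor(b * fs + 1 + 1e-9)))
  if (i1 < i0) integer(0) else i0:i1
}
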