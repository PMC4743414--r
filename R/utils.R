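#' Round a ratio to a whole-number percentage
#'
#' Converts a count out of a total into a percentage rounded to the nearest
#' integer, rounding halves away from zero. All percentage reporting in the
#' package goes through this one function so that tables are internally
#' consistent.
#'
#' @param k Numerator count (numeric, may be a vector).
#' @param n Denominator count; must be positive.
#' @return Integer percentage(s), e.g. \code{percentOf(183, 205)} is 89.
#' @examples
#' percentOf(1105, 2029)  # 54
#' percentOf(24, 36)      # 67
#' @export
percentOf <- function(k, n) {
  if (any(n <= 0)) stop("percentOf(): total must be positive")
  x <- 100 * k / n
  as.integer(sign(x) * floor(abs(x) + 0.5))
}

#' @noRd
roundHalfAway <- function(x) sign(x) * floor(abs(x) + 0.5)

# 32-bit FNV-1a hash of a character scalar; cheap content fingerprint used
# to key per-generator RNG streams and to stamp pipeline outputs.
#' @noRd
fnv1a <- function(s) {
  bytes <- utf8ToInt(enc2utf8(s))
  h <- 2166136261
  for (b in bytes) {
    # xor only touches the low byte since b < 256; keeps h a double in
    # [0, 2^32) without integer overflow
    low <- h %% 256
    h <- h - low + bitwXor(as.integer(low), as.integer(b %% 256))
    # 32-bit modular multiply by the FNV prime 16777619; h is split into
    # 16-bit halves so every intermediate stays exactly representable
    h0 <- h %% 65536
    h1 <- (h - h0) / 65536
    h <- (h0 * 16777619 + ((h1 * 16777619) %% 65536) * 65536) %% 4294967296
  }
  h
}

# Derive a deterministic 31-bit seed from a base seed and a stream label, so
# each generator draws from its own stream and adding generators never
# perturbs existing outputs.
#' @noRd
deriveSeed <- function(seed, stream) {
  as.integer((fnv1a(paste0(stream, ":", seed)) + as.numeric(seed)) %% 2147483647)
}

# Evaluate expr with a locally-seeded RNG, restoring global RNG state after.
#' @noRd
withLocalSeed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' @noRd
DNA_BASES4 <- c("A", "C", "G", "T")

# Map a DNA character string to integer codes 1..4 (A,C,G,T); anything else
# (N and friends) becomes NA.
#' @noRd
dnaCodes <- function(seq) {
  m <- match(strsplit(toupper(seq), "")[[1]], DNA_BASES4)
  m
}

#' @noRd
revCompString <- function(seq) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(seq)))
}

#' @noRd
flipStrand <- function(s) ifelse(s == "+", "-", "+")
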