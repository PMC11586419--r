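# Small numeric helpers shared across modules.

#' Round half away from zero
#'
#' Table-style rounding: .5 always moves away from zero, unlike base
#' [round()]'s round-half-even. Used whenever values are rounded to a
#' printed report precision.
#'
#' @param x numeric vector.
#' @param digits integer number of decimal places.
#' @return rounded numeric vector.
#' @export
round_half_up <- function(x, digits = 0) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5) / m
}

#' Log-odds (logit) of a probability
#'
#' @param p probability strictly inside (0, 1).
#' @return log(p / (1 - p)).
#' @export
logit <- function(p) {
  stopifnot(is.numeric(p))
  if (any(!is.finite(p)) || any(p <= 0) || any(p >= 1)) {
    stop("logit() requires probabilities strictly inside (0, 1)", call. = FALSE)
  }
  log(p / (1 - p))
}

# Sample skewness (population definition, as used for simulated-path summaries)
sample_skewness <- function(x) {
  m <- mean(x)
  s2 <- mean((x - m)^2)
  if (s2 == 0) return(0)
  mean((x - m)^3) / s2^1.5
}

# Sample kurtosis, NOT excess (Gaussian -> 3)
sample_kurtosis <- function(x) {
  m <- mean(x)
  s2 <- mean((x - m)^2)
  if (s2 == 0) return(0)
  mean((x - m)^4) / s2^2
}

# 32-bit FNV-1a hash of a character scalar, reported as 8 hex digits.
# Used to stamp output files with a reproducible config fingerprint.
fnv1a32 <- function(s) {
  # XOR of 32-bit values carried as doubles, via 16-bit halves
  xor32 <- function(a, b) {
    bitwXor(a %% 65536, b %% 65536) +
      65536 * bitwXor(a %/% 65536, b %/% 65536)
  }
  bytes <- utf8ToInt(enc2utf8(paste(s, collapse = "\n")))
  h <- 2166136261
  for (b in bytes) {
    h <- xor32(h, b)
    # 32-bit modular multiply by the FNV prime 16777619 = 2^24 + 403,
    # split to stay inside the 2^53 exact-double range
    h <- (h * 403 + (h %% 256) * 16777216) %% 4294967296
  }
  sprintf("%04x%04x", as.integer(h %/% 65536), as.integer(h %% 65536))
}

# derive a reproducible 31-bit child seed from a master seed and a stream tag
derive_seed <- function(seed, tag) {
  stopifnot(is.numeric(seed), length(seed) == 1)
  h <- fnv1a32(paste(format(seed, scientific = FALSE), tag, sep = "/"))
  as.integer(strtoi(substr(h, 1, 7), base = 16L))
}

stop_invalid <- function(...) stop(..., call. = FALSE)

check_finite_scalar <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1 || !is.finite(x)) {
    stop_invalid(sprintf("`%s` must be a finite numeric scalar", name))
  }
  invisible(x)
}
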