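# internal numeric helpers shared across modules

# Draw from a normal truncated at zero by rejection. Used for per-cell
# substrate affinity; rejection is exact (no boundary pile-up, unlike
# pmax(0, rnorm(...))).
rtruncnorm_pos <- function(n, mean, sd, max_tries = 1000L) {
  if (sd == 0) {
    if (mean <= 0) stop("truncated normal with sd = 0 requires mean > 0")
    return(rep(mean, n))
  }
  out <- numeric(n)
  for (i in seq_len(n)) {
    ok <- FALSE
    for (tr in seq_len(max_tries)) {
      x <- stats::rnorm(1L, mean, sd)
      if (x > 0) { out[i] <- x; ok <- TRUE; break }
    }
    if (!ok) stop("no positive draw from truncated normal after ",
                  max_tries, " tries (mean = ", mean, ", sd = ", sd, ")")
  }
  out
}

# Lognormal multiplier with unit median and coefficient of variation cv.
# Median 1 keeps geometric-mean statistics of downstream estimators unbiased.
rlnorm_cv <- function(n, cv) {
  if (cv == 0) return(rep(1, n))
  sdlog <- sqrt(log(1 + cv^2))
  stats::rlnorm(n, meanlog = 0, sdlog = sdlog)
}

# Weighted standard deviation with frequency weights and (sum(w) - 1)
# denominator; weights here are 0/1 admissibility flags.
weighted_sd <- function(x, w) {
  sw <- sum(w)
  if (sw <= 1) return(NA_real_)
  xbar <- sum(w * x) / sw
  sqrt(sum(w * (x - xbar)^2) / (sw - 1))
}

# Derive a stream-specific 32-bit seed from a base seed so that independent
# stages driven by one user seed do not share random streams.
derive_seed <- function(seed, stream) {
  (as.integer(seed) * 48271L + as.integer(stream) * 7919L) %% 2147483629L
}

stopifnot_scalar_pos <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x <= 0)
    stop("'", name, "' must be a single positive finite number", call. = FALSE)
  invisible(x)
}
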