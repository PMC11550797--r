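# RNG discipline: every exported generator takes an explicit integer seed
# (usually via its spec), seeds R's RNG locally, and restores the caller's
# RNG state on exit, so no package function leaks global RNG side effects.

local_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

# Deterministic child seeds, kept inside 32-bit integer range.
derive_seed <- function(seed, key) {
  as.integer((as.double(seed) * 1009 + key) %% 2147483629)
}

# Skew-normal draws (Azzalini construction), used for the age distribution.
rskewnorm <- function(n, location, scale, shape) {
  delta <- shape / sqrt(1 + shape^2)
  u0 <- abs(rnorm(n))
  u1 <- rnorm(n)
  location + scale * (delta * u0 + sqrt(1 - delta^2) * u1)
}

# Skew-normal truncated to [lo, hi] by resampling.
rskewnorm_trunc <- function(n, location, scale, shape, lo = 18, hi = 105) {
  out <- numeric(0)
  while (length(out) < n) {
    x <- rskewnorm(2 * (n - length(out)) + 10, location, scale, shape)
    out <- c(out, x[x >= lo & x <= hi])
  }
  out[seq_len(n)]
}
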