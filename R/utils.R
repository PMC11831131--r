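# Internal numerical helpers shared across the trend and null-model code.

# Decimal time used for trend fitting on sub-annual records: mid-month
# convention, so July of year y is y + 6.5/12.
decimal_year <- function(year, month) {
  year + (month - 0.5) / 12
}

# Closed-form OLS slopes per group. `g` must be an integer group index
# (1..k); x and y numeric with no NAs. Returns a list with per-group slope,
# intercept, n, and the number of distinct x values. Used in permutation and
# simulation inner loops where calling lm() per group would dominate the
# runtime; equivalence with lm() is asserted in the test suite.
group_ols <- function(g, x, y, k = max(g)) {
  n  <- tabulate(g, nbins = k)
  sx <- rowsum_vec(x, g, k)
  sy <- rowsum_vec(y, g, k)
  sxx <- rowsum_vec(x * x, g, k)
  sxy <- rowsum_vec(x * y, g, k)
  denom <- sxx - sx^2 / n
  slope <- (sxy - sx * sy / n) / denom
  slope[denom <= 0 | n < 2] <- NA_real_
  intercept <- sy / n - slope * sx / n
  list(slope = slope, intercept = intercept, n = n, denom = denom)
}

rowsum_vec <- function(v, g, k) {
  out <- numeric(k)
  agg <- rowsum(v, g, reorder = FALSE)
  out[as.integer(rownames(agg))] <- agg[, 1]
  out
}

# Permute x within each group. Requires rows sorted by g; order(g, runif(n))
# then yields, within every group block, a uniformly random arrangement.
permute_within <- function(x, g) {
  x[order(g, runif(length(g)))]
}

# Draw n sub-seeds from one master seed, keeping them valid 32-bit integers.
derive_seeds <- function(seed, n) {
  set.seed(seed)
  sample.int(.Machine$integer.max - 1L, n)
}

with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  }
  on.exit({
    if (is.null(old)) {
      rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

# Round half away from zero (base round() rounds half to even).
round_half_away <- function(x) {
  sign(x) * floor(abs(x) + 0.5)
}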