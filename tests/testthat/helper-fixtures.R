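# Shared fixtures: all synthetic, built in code at test time.

# fast bootstrap settings for unit tests
fast_cfg <- function(seed = 1L, n = 100L) {
  bootstrap_config(n_boot_deciles = n, n_boot_overlap = n,
                   n_boot_u3 = n, n_boot_moments = n, seed = seed)
}

# tiny 3-region cohort with known structure
tiny_cohort <- function(n_per_sex = 30, seed = 42, ...) {
  generate_cohort(generator_spec(
    n_per_sex = n_per_sex, roi_labels = c("r1", "r2", "r3"),
    a = c(0.01, 0.02, 0.03), b = c(0.6, 0.8, 1.0),
    noise_sd = 0.1, seed = seed, ...))
}

# brute-force Cliff delta / PS by explicit double loop (independent oracle)
cliff_oracle <- function(a, b) {
  gt <- lt <- eq <- 0L
  for (x in a) for (y in b) {
    if (x > y) gt <- gt + 1L else if (x < y) lt <- lt + 1L else eq <- eq + 1L
  }
  np <- length(a) * length(b)
  list(delta = (gt - lt) / np, ps = (gt + 0.5 * eq) / np)
}

# Harrell-Davis oracle: beta-CDF weights computed by numeric integration of
# the beta density (independent of pbeta)
hd_oracle <- function(x, q) {
  n <- length(x)
  a <- (n + 1) * q; b <- (n + 1) * (1 - q)
  ib <- function(u) {
    if (u <= 0) return(0)
    if (u >= 1) return(1)
    stats::integrate(function(t) stats::dbeta(t, a, b), 0, u,
                     rel.tol = 1e-13, subdivisions = 2000L)$value
  }
  w <- vapply(seq_len(n), function(i) ib(i / n) - ib((i - 1) / n), numeric(1))
  sum(w * sort(x))
}
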