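# Shared fixtures and independent oracles used across the test files.

# Build a quadratic_fit object directly from known coefficients.
quad_fit <- function(a, b, c, n_points = 5L) {
  structure(list(a = a, b = b, c = c, rss = 0, n_points = n_points,
                 converged = TRUE),
            class = "quadratic_fit")
}

# Well-formed measurement table for the full 8 x 9 x 5 design, built from
# known concave-down curves (toy-free: realistic [H+] magnitudes).
make_full_design <- function(seed = 1, noise_cv = 0) {
  generate_cohort(generator_params(seed = seed, meas_noise_cv = noise_cv))
}

# Independent scoring oracle: direct transcription of the quadrant rule,
# the per-day Euclidean weight and the step sum, kept free of package code.
oracle_global_index <- function(v0, A, offsets, include_first = FALSE) {
  n <- length(v0)
  d <- numeric(n - 1)
  for (i in seq_len(n - 1)) {
    dv <- v0[i + 1] - v0[i]
    dA <- A[i + 1] - A[i]
    s <- if (dv <= 0 && dA <= 0) 2
    else if (dv > 0 && dA <= 0) 1
    else if (dv <= 0 && dA > 0) -1
    else -2
    omega <- sqrt(dv^2 + dA^2) / (offsets[i + 1] - offsets[i])
    d[i] <- s * omega
  }
  if (include_first) sum(d) else sum(d[-1])
}

# Normal-equations oracle for the quadratic OLS fit.
oracle_quadratic_ols <- function(times, y) {
  X <- cbind(1, times, times^2)
  as.numeric(solve(t(X) %*% X, t(X) %*% y))  # (c, b, a)
}

# Temporary CSV helper.
write_temp_csv <- function(df) {
  path <- tempfile(fileext = ".csv")
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  path
}
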