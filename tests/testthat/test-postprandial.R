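test_that("fit_quadratic interpolates exact data and matches the OLS oracle", {
  t5 <- c(0, 1, 2, 4, 6)
  y <- -1 * t5^2 + 6 * t5 + 10
  f <- fit_quadratic(t5, y)
  expect_equal(c(f$a, f$b, f$c), c(-1, 6, 10), tolerance = 1e-12)
  expect_lt(f$rss, 1e-18)

  # 3 points, 3 parameters: exact interpolation of anything
  f3 <- fit_quadratic(c(0, 1, 2), c(4.2, -1, 7))
  expect_lt(f3$rss, 1e-18)

  # noisy instances agree with the normal-equations oracle
  set.seed(101)
  for (i in 1:50) {
    y <- runif(1, -2, 2) * t5^2 + runif(1, -5, 5) * t5 + runif(1, 5, 15) +
      rnorm(5, 0, 0.5)
    f <- fit_quadratic(t5, y)
    cf <- oracle_quadratic_ols(t5, y)
    expect_equal(c(f$c, f$b, f$a), cf, tolerance = 1e-9)
  }

  expect_error(fit_quadratic(c(0, 1), c(1, 2)), "3 distinct")
  expect_error(fit_quadratic(c(2, 2, 2), c(1, 2, 3)), "3 distinct")
})

test_that("reparametrise yields baseline, amplitude, recovery and peak location", {
  # symmetric parabola returning exactly to baseline: full recovery
  sv <- reparametrise(quad_fit(-1, 6, 10))
  expect_equal(sv$v0, 10)
  expect_equal(sv$t_peak, 3)
  expect_equal(sv$A, 9)
  expect_equal(sv$v_last, 10)
  expect_equal(sv$R, 100)

  # early peak with overshoot below baseline at the window end
  sv <- reparametrise(quad_fit(-1, 4, 10))
  expect_equal(sv$t_peak, 2)
  expect_equal(sv$A, 4)
  expect_equal(sv$v_last, -2)
  expect_equal(sv$R, 25)  # 4 / 16 * 100

  # upward parabola: maximising endpoint, recovery undefined
  expect_warning(sv <- reparametrise(quad_fit(1, -2, 10)), "undefined")
  expect_equal(sv$t_peak, 6)
  expect_equal(sv$A, 24)
  expect_equal(sv$v_last, 34)
  expect_true(is.na(sv$R))

  # complement definition is the reciprocal convention
  svc <- reparametrise(quad_fit(-1, 4, 10),
                       recovery_definition = "complement")
  expect_equal(svc$R, 16 / 4 * 100)

  # amplitude ignores a constant shift of the whole curve
  sv1 <- reparametrise(quad_fit(-1, 5, 10))
  sv2 <- reparametrise(quad_fit(-1, 5, 17))
  expect_equal(sv1$A, sv2$A)
  expect_equal(sv2$v0 - sv1$v0, 7)
})

test_that("inverse_reparametrise round-trips through the forward map", {
  expect_equal(unlist(inverse_reparametrise(10, 9, 100)),
               c(a = -1, b = 6, c = 10), tolerance = 1e-12)
  expect_equal(unlist(inverse_reparametrise(10, 4, 25)),
               c(a = -1, b = 4, c = 10), tolerance = 1e-12)

  set.seed(202)
  for (i in 1:200) {
    v0 <- runif(1, 1e-7, 1e-6)
    A <- v0 * runif(1, 0.1, 5)
    R <- runif(1, 5, 100)
    cf <- inverse_reparametrise(v0, A, R)
    sv <- reparametrise(quad_fit(cf$a, cf$b, cf$c))
    expect_equal(sv$v0, v0, tolerance = 1e-9)
    expect_equal(sv$A, A, tolerance = 1e-9)
    expect_equal(sv$R, R, tolerance = 1e-9)
    expect_gt(sv$t_peak, 0)
    expect_lt(sv$t_peak, 6)
  }

  expect_error(inverse_reparametrise(10, 0, 50), "infeasible")
  expect_error(inverse_reparametrise(10, 1, -5), "infeasible")
})

test_that("threshold descriptors follow the quadratic roots and are monotone in theta", {
  # concentration-scale curve -1e-7 t^2 + 6e-7 t crosses 5e-7 at t = 1, 5
  f <- quad_fit(-1e-7, 6e-7, 0)
  tv <- derive_threshold_vars(f, theta_ph = -log10(5e-7))
  expect_equal(tv$theta_h, 5e-7)
  expect_equal(tv$dur, 4)
  expect_equal(tv$amp_ac, 4e-7)  # peak 9e-7 minus threshold 5e-7

  # entirely below threshold
  tv <- derive_threshold_vars(f, theta_ph = -log10(2e-6))
  expect_equal(tv$dur, 0)
  expect_lt(tv$amp_ac, 0)

  # raising the threshold never increases duration or exceedance
  thetas <- -log10(seq(2e-7, 12e-7, by = 5e-8))  # increasing theta_h
  durs <- vapply(thetas, function(th)
    derive_threshold_vars(f, th)$dur, numeric(1))
  amps <- vapply(thetas, function(th)
    derive_threshold_vars(f, th)$amp_ac, numeric(1))
  expect_true(all(diff(durs) <= 1e-12))
  expect_true(all(diff(amps) <= 1e-12))

  # pH scale: acidosis is time below the threshold
  # pH curve dipping below 5.5: 6.5 - t + t^2/6 has min 5 at t = 3
  tvp <- derive_threshold_vars(quad_fit(1 / 6, -1, 6.5), theta_ph = 5.5,
                               scale = "ph")
  expect_gt(tvp$dur, 0)
  expect_equal(tvp$amp_ac, 0.5, tolerance = 1e-12)
})

test_that("fit_all tabulates one row per animal-day and recovers noise-free truth", {
  co <- make_full_design(seed = 5, noise_cv = 0)
  vt <- fit_all(co$measurements)
  expect_identical(nrow(vt), 72L)  # 8 goats x 9 days
  expect_true(all(vt$A >= 0))

  # zero measurement noise: descriptor recovery to generator ground truth
  key <- paste(vt$animal_id, vt$day_label)
  tkey <- paste(co$truth$animal_id, co$truth$day_label)
  m <- match(key, tkey)
  expect_equal(vt$v0, co$truth$v0[m], tolerance = 1e-9)
  expect_equal(vt$A, co$truth$A[m], tolerance = 1e-9)
  expect_equal(vt$R, co$truth$R[m], tolerance = 1e-9)

  # an animal-day reduced to 3 points is excluded with a warning
  meas <- co$measurements
  drop_rows <- which(meas$animal_id == "g01" & meas$day_label == 1)[1:2]
  expect_warning(vt2 <- fit_all(meas[-drop_rows, ]), "excluded")
  expect_identical(nrow(vt2), 71L)
})

test_that("spearman_matrix matches the rank-based oracle and flags constants", {
  set.seed(77)
  n <- 30
  tab <- data.frame(x = rnorm(n))
  tab$y <- exp(tab$x)             # monotone transform: rho = 1
  tab$z <- -tab$x                 # rho = -1
  tab$w <- rnorm(n)
  sm <- spearman_matrix(tab, c("x", "y", "z", "w"))
  expect_equal(sm$rho["x", "y"], 1)
  expect_equal(sm$rho["x", "z"], -1)
  expect_equal(diag(sm$rho), rep(1, 4), ignore_attr = TRUE)
  expect_equal(sm$rho, t(sm$rho))
  # oracle: Pearson correlation of midranks
  expect_equal(sm$rho["x", "w"], cor(rank(tab$x), rank(tab$w)),
               tolerance = 1e-12)

  tab$const <- 1
  expect_warning(sm2 <- spearman_matrix(tab, c("x", "w", "const")),
                 "constant")
  expect_true(is.na(sm2$rho["x", "const"]))
})
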