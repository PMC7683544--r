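test_that("Box-Cox profile selects the normalising exponent", {
  set.seed(31)
  # data whose 0.2-th power is Gaussian: recovery in expectation
  lams <- replicate(20, boxcox_lambda(rnorm(500, 5, 0.5)^(1 / 0.2)))
  expect_lt(abs(mean(lams) - 0.2), 0.05)
  # Gaussian data: identity transform optimal
  expect_lt(abs(boxcox_lambda(rnorm(2000, 4, 1)) - 1), 0.2)
  # lognormal data: log optimal
  expect_lt(abs(boxcox_lambda(exp(rnorm(2000, 0, 0.5)))), 0.1)
  expect_error(boxcox_lambda(c(-1, rep(2, 20))), "positive")
})

test_that("apply_boxcox is the plain power transform with a log limit", {
  expect_equal(apply_boxcox(4, 0.5), 2)
  expect_equal(apply_boxcox(exp(1), 0), 1)
  x <- sort(runif(20, 0.1, 10))
  expect_true(all(diff(apply_boxcox(x, 0.3)) > 0))  # monotone for lambda > 0
  expect_error(apply_boxcox(c(1, -2), 1), "positive")
})

test_that("fit_mixed recovers generating parameters in the no-noise limit", {
  alpha <- c(5, 4.6, 4.9, 4.7, 5.4) * 1e-2
  truth <- list(alpha = alpha, beta = 3e-4, sigma_A2 = 2.5e-5,
                sigma2 = 1e-18)
  set.seed(41)
  tab <- simulate_mixed(truth, n_animals = 8)
  fm <- fit_mixed(tab, "value", lambda = 1)
  # estimated week means equal the truth shifted by the realised average
  # animal intercept; week contrasts and the slope are recovered exactly
  expect_equal(unname(diff(fm$alpha)), diff(alpha), tolerance = 1e-6)
  expect_equal(fm$beta, 3e-4, tolerance = 1e-6)
  expect_gte(fm$sigma_A2, 0)
  expect_equal(icc(fm), 1, tolerance = 1e-6)  # all variance between animals

  # permuting animal labels leaves a well-conditioned fit invariant
  truth2 <- list(alpha = alpha, beta = 0, sigma_A2 = 5e-6, sigma2 = 4e-6)
  tabm <- simulate_mixed(truth2, 8)
  fmm <- fit_mixed(tabm, "value", lambda = 1)
  perm <- sample(unique(tabm$animal_id))
  tab2 <- tabm
  tab2$animal_id <- perm[match(tabm$animal_id, unique(tabm$animal_id))]
  fm2 <- fit_mixed(tab2, "value", lambda = 1)
  expect_equal(fm2$alpha, fmm$alpha, tolerance = 1e-6)
  expect_equal(fm2$sigma_A2, fmm$sigma_A2, tolerance = 1e-4)

  expect_error(fit_mixed(tab[tab$animal_id == tab$animal_id[1], ],
                         "value", 1), "single animal")
})

test_that("likelihood-ratio tests are nested, chi-squared and scale-invariant", {
  truth <- list(alpha = rep(0.05, 5), beta = 0, sigma_A2 = 5e-6,
                sigma2 = 4e-6)
  set.seed(51)
  tab <- simulate_mixed(truth, 8)
  tst <- lrt_fixed_effects(tab, "value", lambda = 1)
  expect_identical(tst$effect, c("week", "days"))
  expect_identical(tst$df, c(4L, 1L))
  expect_true(all(tst$chi2 >= 0))       # nesting
  expect_true(all(tst$p_value >= 0 & tst$p_value <= 1))

  # affine rescaling of the response (e.g. the 1e7 display scale) leaves
  # the statistic unchanged
  tab2 <- tab
  tab2$value <- tab2$value * 1e7
  tst2 <- lrt_fixed_effects(tab2, "value", lambda = 1)
  expect_equal(tst2$chi2, tst$chi2, tolerance = 1e-4)

  # a strong week-5 shift is detected
  truth5 <- truth
  truth5$alpha[5] <- truth$alpha[5] + 10 * sqrt(truth$sigma2)
  tab5 <- simulate_mixed(truth5, 8)
  tst5 <- lrt_fixed_effects(tab5, "value", lambda = 1, effects = "week")
  expect_lt(tst5$p_value, 1e-6)
})

test_that("post-hoc week contrasts separate a shifted week and respect BH", {
  set.seed(61)
  truth <- list(alpha = rep(0.05, 5), beta = 0, sigma_A2 = 1e-6,
                sigma2 = 4e-6)
  truth$alpha[5] <- truth$alpha[5] + 10 * sqrt(truth$sigma2)
  tab <- simulate_mixed(truth, 8)
  fm <- fit_mixed(tab, "value", lambda = 1)
  ph <- posthoc_weeks(fm)
  expect_identical(nrow(ph$contrasts), 10L)
  # BH never lowers a p-value
  expect_true(all(ph$contrasts$p_adj >= ph$contrasts$p_value - 1e-15))
  w5 <- grepl("W5", ph$contrasts$contrast)
  expect_true(all(ph$contrasts$p_adj[w5] < 0.05))
  # week 5 shares no letter with the others
  others <- setdiff(names(ph$letters), "W5")
  shared <- vapply(others, function(w) {
    any(strsplit(ph$letters[["W5"]], "")[[1]] %in%
          strsplit(ph$letters[[w]], "")[[1]])
  }, logical(1))
  expect_false(any(shared))

  # equal weeks, tiny noise relative to spread: single shared letter
  set.seed(62)
  tab0 <- simulate_mixed(list(alpha = rep(0.05, 5), beta = 0,
                              sigma_A2 = 1e-6, sigma2 = 4e-6), 8)
  ph0 <- posthoc_weeks(fit_mixed(tab0, "value", lambda = 1))
  expect_true(length(unique(ph0$letters)) <= 2)
})

test_that("icc is the between-animal variance share", {
  fake <- structure(list(sigma_A2 = 0, sigma2 = 1),
                    class = "mixed_model_result")
  expect_equal(icc(fake), 0)
  fake$sigma_A2 <- 1
  expect_equal(icc(fake), 0.5)
  # recovery at rho = 0.56 with 8 animals, averaged over replicates
  set.seed(71)
  truth <- list(alpha = rep(0.05, 5), beta = 0,
                sigma_A2 = 0.56 / 0.44 * 4e-6, sigma2 = 4e-6)
  rhos <- replicate(60, {
    icc(fit_mixed(simulate_mixed(truth, 8), "value", lambda = 1))
  })
  expect_lt(abs(mean(rhos) - 0.56), 0.10)
})

test_that("power_simulation is calibrated at the null and grows with effect size", {
  truth0 <- list(alpha = rep(0.05, 5), beta = 0, sigma_A2 = 5e-6,
                 sigma2 = 4e-6)
  p0 <- power_simulation(truth0, n_animals = 8, n_sims = 400,
                         effect = "days", seed = 81)
  expect_gt(p0$power, 0.01)
  expect_lt(p0$power, 0.12)

  # a huge slope is always detected
  truth_big <- truth0
  truth_big$beta <- 50 * sqrt(truth0$sigma2)
  p_big <- power_simulation(truth_big, n_animals = 8, n_sims = 100,
                            effect = "days", seed = 82)
  expect_gt(p_big$power, 0.99)

  expect_error(power_simulation(truth0, n_sims = 10), ">= 100")
  bad <- truth0; bad$sigma2 <- -1
  expect_error(power_simulation(bad, n_sims = 100), "invalid truth")
})

test_that("simulate_mixed honours the design and is reproducible", {
  truth <- list(alpha = 1:5, beta = 0.5, sigma_A2 = 1, sigma2 = 0)
  set.seed(91); a <- simulate_mixed(truth, 4)
  set.seed(91); b <- simulate_mixed(truth, 4)
  expect_identical(a, b)
  expect_identical(nrow(a), 36L)  # 4 animals x 9 days
  # with zero residual noise the week/day structure is exact per animal
  one <- a[a$animal_id == a$animal_id[1], ]
  expect_equal(one$value - (truth$alpha[one$week] +
                              0.5 * one$days_since_change),
               rep(one$value[1] - truth$alpha[1], 9), tolerance = 1e-12)
})
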