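test_that("score_step implements the quadrant rule and its symmetries", {
  expect_identical(score_step(-1e-7, -1e-7), 2L)
  expect_identical(score_step(1e-7, 1e-7), -2L)
  expect_identical(score_step(1e-7, -1e-7), 1L)   # effort of adaptation
  expect_identical(score_step(-1e-7, 1e-7), -1L)

  # antisymmetry for strict signs
  set.seed(12)
  dv <- runif(50, -1, 1); dA <- runif(50, -1, 1)
  expect_identical(score_step(-dv, -dA), -score_step(dv, dA))

  # zero deltas credited as non-deterioration by default, configurable
  expect_identical(score_step(0, -1), 2L)
  expect_identical(score_step(0, 1), -1L)
  expect_identical(score_step(0, 1, zero_as = "increase"), -2L)
  expect_identical(score_step(0, 0), 2L)
})

test_that("step_weight is Euclidean distance per calendar day", {
  expect_equal(step_weight(c(0, 0), c(3, 4), 1), 5)
  expect_equal(step_weight(c(0, 0), c(3, 4), 5), 1)
  expect_equal(step_weight(c(2, 7), c(2, 7), 3), 0)
  expect_error(step_weight(c(0, 0), c(1, 1), 0), "positive")
  expect_error(step_weight(c(0, 0), c(1, 1, 1), 1), "dimension")
})

test_that("daily_scores matches the hand-computed step table", {
  traj <- data.frame(day_label = 1:4, day_offset = c(0, 3, 7, 8),
                     v0 = c(10, 8, 9, 5), A = c(4, 3, 5, 2))
  st <- daily_scores(traj)
  expect_identical(st$s, c(2L, -2L, 2L))
  expect_equal(st$omega,
               c(sqrt(4 + 1) / 3, sqrt(1 + 4) / 4, sqrt(16 + 9) / 1))
  expect_equal(st$d, st$s * st$omega)

  # monotone decrease in both coordinates: all +2, all d >= 0
  mono <- data.frame(day_label = 1:5, day_offset = c(0, 2, 5, 6, 9),
                     v0 = 10:6, A = 5:1)
  expect_true(all(daily_scores(mono)$s == 2L))
  expect_true(all(daily_scores(mono)$d >= 0))

  # reversing a strictly monotone trajectory flips every score
  rev_traj <- mono
  rev_traj$v0 <- rev(mono$v0); rev_traj$A <- rev(mono$A)
  expect_identical(daily_scores(rev_traj)$s, -daily_scores(mono)$s)

  expect_error(daily_scores(mono[c(1, 1, 2), ]), "duplicate")
  bad <- mono; bad$day_offset <- rev(bad$day_offset)
  expect_error(daily_scores(bad), "sorted")
})

test_that("global_index sums the post-change steps and matches the oracle", {
  set.seed(22)
  for (i in 1:100) {
    v0 <- runif(9, 1e-7, 1e-6)
    A <- runif(9, 1e-7, 2e-6)
    off <- sampling_schedule()$day_offsets
    traj <- data.frame(day_label = 1:9, day_offset = off, v0 = v0, A = A)
    gi <- global_index(daily_scores(traj))
    expect_equal(gi$gi, oracle_global_index(v0, A, off), tolerance = 1e-12)
    gi_all <- global_index(daily_scores(traj), include_first_step = TRUE)
    expect_equal(gi_all$gi,
                 oracle_global_index(v0, A, off, include_first = TRUE),
                 tolerance = 1e-12)
    # |GI| bounded by twice the summed weights of included steps
    st <- daily_scores(traj)
    expect_lte(abs(gi$gi), 2 * sum(st$omega[-1]) + 1e-15)
  }
  expect_equal(global_index(rep(0, 8))$gi, 0)
})

test_that("joint rescaling of the phase plane rescales GI and preserves ranks", {
  set.seed(32)
  off <- sampling_schedule()$day_offsets
  tabs <- lapply(1:5, function(i) {
    data.frame(animal_id = paste0("g", i), day_label = 1:9,
               day_offset = off,
               v0 = runif(9, 1e-7, 1e-6), A = runif(9, 1e-7, 2e-6))
  })
  vt <- do.call(rbind, tabs)
  sc1 <- score_cohort(vt)
  vt2 <- vt
  vt2$v0 <- vt$v0 * 1e7
  vt2$A <- vt$A * 1e7
  sc2 <- score_cohort(vt2)
  expect_equal(sc2$indices$gi, sc1$indices$gi * 1e7, tolerance = 1e-9)
  expect_identical(sc2$ranking$animal_id, sc1$ranking$animal_id)
})

test_that("rank_animals orders by descending index with stable tie handling", {
  idx <- data.frame(animal_id = c("b", "a", "c"), gi = c(1, 3, 1))
  r <- rank_animals(idx)
  expect_identical(r$animal_id, c("a", "b", "c"))
  expect_identical(r$rank, 1:3)
  expect_identical(r$tied, c(FALSE, TRUE, TRUE))
  # adding a constant leaves the order unchanged
  idx2 <- idx; idx2$gi <- idx2$gi + 100
  expect_identical(rank_animals(idx2)$animal_id, r$animal_id)
  expect_identical(rank_animals(data.frame(animal_id = "x", gi = 0))$rank, 1L)
})

test_that("the unweighted index sums raw quadrant scores", {
  mono <- data.frame(day_label = 1:8, day_offset = c(0, 3, 7, 8, 9, 10, 14, 20),
                     v0 = 8:1, A = 8:1)
  gi <- unweighted_global_index(mono)
  expect_equal(gi$gi, 2 * 6)  # 7 steps, first excluded, all +2
  expect_true(all(gi$steps$omega == 1))
})
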