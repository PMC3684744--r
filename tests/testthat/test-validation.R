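test_that("partition sizes follow the 75-25 half-up rule", {
  d <- recovery_dataset(n = 29, noise_sd = 0.2, seed = 2)
  terms <- model_terms(linear = c("voltinism", "ovigeny_index"))
  cv <- cross_validate(d, terms, n_partitions = 10, seed = 1)
  # n = 29 -> 22 train, 7 test: each partition holds out 7 species
  expect_equal(sum(cv$n_heldout), 10 * 7)
  expect_equal(floor(0.75 * 29 + 0.5), 22)
  expect_equal(floor(0.75 * 28 + 0.5), 21)
  expect_equal(floor(0.75 * 26 + 0.5), 20)  # half-up, not banker's
})

test_that("cross-validation is reproducible and exact on noise-free data", {
  d <- recovery_dataset(n = 20, noise_sd = 0, seed = 3)
  terms <- model_terms(linear = c("voltinism", "ovigeny_index"))
  cv1 <- cross_validate(d, terms, n_partitions = 30, seed = 9)
  cv2 <- cross_validate(d, terms, n_partitions = 30, seed = 9)
  expect_identical(cv1$pred_mean, cv2$pred_mean)
  held <- !is.na(cv1$pred_mean)
  expect_true(any(held))
  expect_equal(cv1$pred_mean[held], cv1$observed[held], tolerance = 1e-8)
})

test_that("rightness is the OLS slope of observed on predicted", {
  expect_equal(rightness(c(1, 2, 3), c(1, 1, 2)), 1.5)
  x <- c(0.3, 1.1, 2.2, 3.1)
  expect_equal(rightness(x, x), 1)
  expect_error(rightness(c(1, 2, 3), c(2, 2, 2)), "constant")
  expect_error(rightness(1:2, 1:2), ">= 3")
})

test_that("imprecision is the (optionally relative) mean absolute error", {
  expect_equal(imprecision(c(1, 2, 3), c(1, 1, 2)), 2 / 3)
  expect_equal(imprecision(c(2, 4), c(1, 2), relative = TRUE), 0.5)
  expect_equal(imprecision(c(1, 2), c(1, 2)), 0)
  expect_error(imprecision(c(0, 1), c(1, 1), relative = TRUE), "zero")
  # relative imprecision is scale-invariant
  obs <- c(1.5, 2.5, 4); pred <- c(1, 3, 3.5)
  for (c_scale in c(0.01, 1, 250)) {
    expect_equal(imprecision(obs * c_scale, pred * c_scale, relative = TRUE),
                 imprecision(obs, pred, relative = TRUE), tolerance = 1e-12)
  }
})

test_that("repeat-level performance has near-zero spread on noise-free data", {
  d <- recovery_dataset(n = 20, noise_sd = 0, seed = 13)
  terms <- model_terms(linear = c("voltinism", "ovigeny_index"))
  perf <- assess_performance(d, terms, n_repeats = 4, n_partitions = 20,
                             seed = 5)
  expect_equal(perf$rightness, 1, tolerance = 0.01)
  expect_lt(perf$imprecision, 1e-6)
  expect_lt(perf$rightness_se, 1e-6)
  # a single repeat cannot yield a standard error
  p1 <- assess_performance(d, terms, n_repeats = 1, n_partitions = 10,
                           seed = 6)
  expect_true(is.na(p1$rightness_se))
})

test_that("different seeds give different but compatible estimates", {
  d <- recovery_dataset(n = 24, noise_sd = 0.3, seed = 19)
  terms <- model_terms(linear = c("voltinism", "ovigeny_index"))
  pa <- assess_performance(d, terms, n_repeats = 5, n_partitions = 30,
                           seed = 1)
  pb <- assess_performance(d, terms, n_repeats = 5, n_partitions = 30,
                           seed = 2)
  expect_false(identical(pa$rightness, pb$rightness))
  # estimates of the same quantity should agree within a few joint SEs
  joint_se <- sqrt(pa$rightness_se^2 + pb$rightness_se^2)
  expect_lt(abs(pa$rightness - pb$rightness), 6 * joint_se + 0.05)
})

test_that("comparing a model against itself reports null gains", {
  d <- recovery_dataset(n = 24, noise_sd = 0.3, seed = 29)
  terms <- model_terms(linear = c("voltinism", "ovigeny_index"))
  perf <- assess_performance(d, terms, n_repeats = 5, n_partitions = 20,
                             seed = 3)
  rep <- compare_models(perf, perf)
  expect_equal(rep$gain_rightness, 0)
  expect_equal(rep$gain_precision, 1)
  expect_equal(rep$p_rightness, 1, tolerance = 1e-9)
  expect_equal(rep$p_precision, 1, tolerance = 1e-9)
  td <- tidy(rep)
  expect_equal(td$gain_precision, 1)
})

test_that("trait syndromes out-predict a pure-noise wing-size reference", {
  # response driven by two traits; wing length is independent noise
  withr::local_seed(37)
  traits <- simulate_trait_table(29)
  tm <- recovery_true_model(noise_sd = 0.25)
  disp <- simulate_responses(traits, tm)
  d <- syndrome_data(traits, disp, "mean_distance",
                     candidates = c(recovery_candidates(),
                                    "log_wing_length"))
  trait_perf <- assess_performance(
    d, model_terms(linear = c("voltinism", "ovigeny_index")),
    n_repeats = 5, n_partitions = 30, relative = FALSE)
  ref_perf <- assess_performance(
    d, model_terms(linear = "log_wing_length"),
    n_repeats = 5, n_partitions = 30, relative = FALSE)
  rep <- compare_models(trait_perf, ref_perf)
  expect_gt(rep$gain_precision, 1)
  expect_lt(rep$p_precision, 0.05)
})
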