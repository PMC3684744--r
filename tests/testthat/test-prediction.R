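fit_propensity_model <- function(n = 25, seed = 1, noise_sd = 0.05) {
  traits <- simulate_trait_table(n, seed = seed)
  tm <- true_model("propensity",
                   model_terms(linear = c("voltinism", "ovigeny_index")),
                   coefficients = c(0.12, -0.1), intercept = -0.45,
                   noise_sd = noise_sd)
  disp <- simulate_responses(traits, tm, seed = seed + 100L)
  d <- syndrome_data(traits, disp, "propensity",
                     candidates = c("voltinism", "ovigeny_index"))
  list(traits = traits,
       disp = disp,
       fit = fit_dispersal_glm(
         d, model_terms(linear = c("voltinism", "ovigeny_index"))))
}

test_that("back-transformation of predictions follows the element rules", {
  fx <- fit_propensity_model()
  preds <- predict_species(fx$fit, fx$traits, "propensity")
  # natural values recomputed by hand from the transformed scale
  ok <- !preds$truncated
  expect_equal(preds$pred_natural[ok], preds$pred_transformed[ok]^2,
               tolerance = 1e-10)
  expect_true(all(preds$pred_natural >= 0 & preds$pred_natural <= 1,
                  na.rm = TRUE))
  # a propensity prediction of -0.5 means 25% emigration
  expect_equal(dispersal_back_transform("propensity", -0.5), 0.25)
  # mean-distance predictions at 0 on the log scale are 1 km
  expect_equal(dispersal_back_transform("mean_distance", 0), 1)
})

test_that("out-of-domain transformed predictions are truncated and flagged", {
  fx <- fit_propensity_model()
  # force predictions outside [-1, 0] by extreme trait values
  new_traits <- fx$traits[1:3, ]
  new_traits$species_id <- c("hi1", "hi2", "hi3")
  new_traits$voltinism <- c(3, 3, 3)
  new_traits$ovigeny_index <- c(0, 0, 0)
  preds <- predict_species(fx$fit, new_traits, "propensity",
                           extrapolate = TRUE)
  out_dom <- preds$pred_transformed > 0 | preds$pred_transformed < -1
  expect_equal(preds$truncated, out_dom)
  if (any(out_dom)) {
    expect_true(all(preds$pred_natural[out_dom] %in% c(0, 1)))
  }
})

test_that("the applicability mask uses closed training ranges", {
  fx <- fit_propensity_model()
  rng <- fx$fit$training_ranges$voltinism
  probe <- fx$traits[1:3, ]
  probe$species_id <- c("inside", "at_max", "above")
  probe$voltinism <- c(mean(rng), rng[2], min(rng[2] * 1.1, 3))
  mask <- applicability_mask(fx$fit, probe)
  expect_true(mask$in_range[1])
  expect_true(mask$in_range[2])  # boundary value counts as in range
  if (probe$voltinism[3] > rng[2]) expect_false(mask$in_range[3])
  # suppressed natural-scale values for out-of-range species by default
  preds <- predict_species(fx$fit, probe, "propensity")
  if (probe$voltinism[3] > rng[2]) {
    expect_true(is.na(preds$pred_natural[preds$species_id == "above"]))
    expect_false(is.na(preds$pred_transformed[preds$species_id == "above"]))
  }
  # when all species sit inside the training ranges nothing is flagged
  mask_all <- applicability_mask(fx$fit, fx$traits)
  expect_true(all(mask_all$in_range))
})

test_that("species with missing model traits are skipped with a record", {
  fx <- fit_propensity_model()
  tr <- fx$traits
  tr$voltinism[2] <- NA
  preds <- predict_species(fx$fit, tr, "propensity")
  expect_false(tr$species_id[2] %in% preds$species_id)
  expect_equal(attr(preds, "skipped"), tr$species_id[2])
})

test_that("distribution summaries match order-statistics quantiles", {
  s <- summarize_distribution(as.numeric(1:10), observed = as.numeric(1:10))
  pred_row <- s$stats[s$stats$group == "predicted", ]
  # type-7 quantile oracle: sort and interpolate at 1 + 0.9*(n-1)
  expect_equal(pred_row$q90, 1 + 0.9 * 9)
  expect_equal(pred_row$q50, 5.5)
  expect_equal(pred_row$mean, 5.5)
  # identical inputs give identical summaries
  obs_row <- s$stats[s$stats$group == "observed", ]
  expect_equal(pred_row[-1], obs_row[-1])
  # two values suffice
  s2 <- summarize_distribution(c(0.1, 0.3))
  expect_equal(s2$stats$mean, 0.2)
  expect_true(nrow(s2$densities) > 0)
  expect_error(summarize_distribution(0.5), ">= 2")
})

test_that("prediction round trip respects domains on every element", {
  withr::local_seed(11)
  traits <- simulate_trait_table(40)
  for (el in dispersal_elements()) {
    tm <- true_model(el, model_terms(linear = "voltinism"),
                     coefficients = 2, intercept = 0, noise_sd = 0.8)
    disp <- simulate_responses(traits, tm)
    d <- syndrome_data(traits, disp, el, candidates = "voltinism")
    fit <- fit_dispersal_glm(d, model_terms(linear = "voltinism"))
    preds <- predict_species(fit, traits, el, extrapolate = TRUE)
    v <- preds$pred_natural
    ok <- switch(el,
      mean_distance = all(v > 0),
      ldd_frequency = all(v > 0 & v <= 1),
      propensity = all(v >= 0 & v <= 1),
      gene_flow = all(v >= 0 & v <= 1))
    expect_true(ok, info = el)
  }
})

test_that("autoplot methods return ggplot objects", {
  fx <- fit_propensity_model()
  d <- syndrome_data(fx$traits, fx$disp, "propensity",
                     candidates = c("voltinism", "ovigeny_index"))
  sel <- select_dispersal_model(d)
  expect_s3_class(autoplot(sel), "ggplot")
  cv <- cross_validate(d, sel$chosen$terms, n_partitions = 10, seed = 2)
  expect_s3_class(autoplot(cv), "ggplot")
  expect_s3_class(autoplot(r2_partition(sel$chosen)), "ggplot")
  preds <- predict_species(sel$chosen, fx$traits, "propensity")
  expect_s3_class(autoplot(summarize_distribution(preds, fx$disp)), "ggplot")
})
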