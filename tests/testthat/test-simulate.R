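test_that("trait simulation is reproducible and respects trait ranges", {
  a <- simulate_trait_table(20, seed = 7)
  b <- simulate_trait_table(20, seed = 7)
  expect_identical(a, b)
  big <- simulate_trait_table(2000, seed = 8)
  defs <- trait_definitions()
  for (i in seq_len(nrow(defs))) {
    v <- big[[defs$trait[i]]]
    expect_true(all(v >= defs$min[i] & v <= defs$max[i]), info = defs$trait[i])
    if (defs$type[i] != "continuous") expect_true(all(v == round(v)))
  }
  expect_true(all(big$ovigeny_index >= 0 & big$ovigeny_index <= 1))
  expect_true(all(big$voltinism >= 0.5 & big$voltinism <= 3))
  expect_error(simulate_trait_table(1), "n_species")
})

test_that("responses are exactly linear in the stated terms at zero noise", {
  tr <- simulate_trait_table(15, seed = 3)
  tm <- true_model("mean_distance",
                   model_terms(linear = c("voltinism", "fecundity")),
                   coefficients = c(2, -1), intercept = 1, noise_sd = 0)
  d <- simulate_responses(tr, tm, seed = 1)
  z <- function(x) (x - mean(x)) / sd(x)
  eta <- 1 + 2 * z(tr$voltinism) - 1 * z(tr$fecundity)
  got <- d$transformed_value[match(tr$species_id, d$species_id)]
  expect_equal(got, eta, tolerance = 1e-10)
})

test_that("two seeds differ only through the noise draws", {
  tr <- simulate_trait_table(15, seed = 3)
  tm <- true_model("mean_distance", model_terms(linear = "voltinism"),
                   coefficients = 1, noise_sd = 0.5)
  d1 <- simulate_responses(tr, tm, seed = 1)
  d2 <- simulate_responses(tr, tm, seed = 2)
  eta <- attr(d1, "linear_predictor")
  expect_identical(eta, attr(d2, "linear_predictor"))
  expect_false(identical(d1$raw_value, d2$raw_value))
  expect_identical(simulate_responses(tr, tm, seed = 1)$raw_value,
                   d1$raw_value)
})

test_that("simulated raw values stay inside their element domains", {
  tr <- simulate_trait_table(200, seed = 5)
  for (el in dispersal_elements()) {
    tm <- true_model(el, model_terms(linear = "voltinism"),
                     coefficients = 3, intercept = 0, noise_sd = 1)
    d <- simulate_responses(tr, tm, seed = 6)
    ok <- switch(el,
      mean_distance = all(d$raw_value > 0),
      ldd_frequency = all(d$raw_value > 0 & d$raw_value <= 1),
      propensity = all(d$raw_value >= 0 & d$raw_value <= 1),
      gene_flow = all(d$raw_value >= 0 & d$raw_value <= 1))
    expect_true(ok, info = el)
    if (el != "mean_distance") {
      # bounded elements must clip under a wide linear predictor
      expect_true(any(d$clipped), info = el)
    }
  }
})

test_that("distance samples follow their kernel laws", {
  d <- simulate_mrr_distances(1e5, "negexp", alpha = 5, seed = 1)
  se <- (1 / 5) / sqrt(1e5)
  expect_lt(abs(mean(d) - 0.2), 3 * se)
  dp <- simulate_mrr_distances(1e5, "invpower", b = 2, d_min = 1, seed = 2)
  p5 <- mean(dp > 5)
  expect_lt(abs(p5 - 0.2), 3 * sqrt(0.2 * 0.8 / 1e5))
  expect_true(all(dp >= 1))
  expect_length(simulate_mrr_distances(1, "negexp", alpha = 5, seed = 3), 1)
  expect_error(simulate_mrr_distances(10, "invpower", b = 0.5), "b")
})

test_that("residency simulation matches its binomial propensity", {
  r <- simulate_residency(0.3, totals = rep(50, 200), seed = 4)
  expect_true(all(r$residents <= r$total))
  est <- propensity_from_recaptures(r)
  expect_lt(abs(est - 0.3), 3 * sqrt(0.3 * 0.7 / 50) / sqrt(200))
})

test_that("lambda controls the phylogenetic covariance of simulated traits", {
  # lambda = 0: tip values i.i.d. -> off-diagonal sample covariance ~ 0
  withr::local_seed(10)
  n_rep <- 300
  sims0 <- replicate(n_rep, simulate_tree_and_trait(8, lambda = 0)$trait)
  cmat <- cov(t(sims0))
  off <- cmat[upper.tri(cmat)]
  expect_lt(mean(abs(off)) / mean(diag(cmat)), 0.15)

  # lambda = 1: E[(t_i - t_j)^2] equals the patristic distance under BM,
  # so squared tip differences should track cophenetic distances
  withr::local_seed(11)
  cors <- replicate(60, {
    tt <- simulate_tree_and_trait(64, lambda = 1)
    D <- ape::cophenetic.phylo(tt$tree)[names(tt$trait), names(tt$trait)]
    sqdiff <- outer(tt$trait, tt$trait, function(a, b) (a - b)^2)
    cor(sqdiff[upper.tri(sqdiff)], D[upper.tri(D)])
  })
  expect_gt(mean(cors), 0.2)
  expect_gt(mean(cors > 0), 0.9)

  # reproducibility
  expect_identical(simulate_tree_and_trait(16, lambda = 0.5, seed = 12)$trait,
                   simulate_tree_and_trait(16, lambda = 0.5, seed = 12)$trait)
})

test_that("simulate_study writes readable CSV pairs", {
  dir <- withr::local_tempdir()
  tm <- recovery_true_model(noise_sd = 0.1)
  paths <- simulate_study(dir, 12, tm, seed = 20)
  tr <- read_trait_table(paths["traits"])
  d <- read_dispersal_table(paths["dispersal"])
  expect_equal(nrow(tr), 12)
  expect_equal(nrow(d), 12)
})
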