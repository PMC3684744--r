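#' Simulate a species-by-trait table
#'
#' Draws each of the 18 traits independently and uniformly within its
#' defined range ([trait_definitions()]): continuous traits uniform over
#' the interval, ordinal and binary traits uniform over their integer
#' levels. Independence across traits is the default so that model-recovery
#' tests stay interpretable; real trait tables are more structured.
#'
#' @param n_species Number of species (>= 2).
#' @param seed Integer seed; draws are reproducible for a fixed seed.
#' @param ranges Optional named list of `c(min, max)` overrides per trait.
#' @return A validated trait table (tibble) with species ids `sp001`, ...
#' @examples
#' simulate_trait_table(5, seed = 1)
#' @export
simulate_trait_table <- function(n_species, seed = NULL, ranges = NULL) {
  if (n_species < 2) stop("`n_species` must be >= 2", call. = FALSE)
  if (!is.null(seed)) withr::local_seed(seed)
  defs <- trait_definitions()
  out <- tibble::tibble(
    species_id = sprintf("sp%03d", seq_len(n_species))
  )
  for (i in seq_len(nrow(defs))) {
    lim <- c(defs$min[i], defs$max[i])
    if (!is.null(ranges) && defs$trait[i] %in% names(ranges)) {
      lim <- ranges[[defs$trait[i]]]
    }
    out[[defs$trait[i]]] <- if (defs$type[i] == "continuous") {
      stats::runif(n_species, lim[1], lim[2])
    } else {
      sample(seq(lim[1], lim[2]), n_species, replace = TRUE)
    }
  }
  validate_trait_table(out)
}

#' Define a generating syndrome model
#'
#' Ground truth for simulation: a dispersal element, a term set, one
#' coefficient per term unit (two for a quadratic unit) on standardized
#' trait scales, an intercept and a Gaussian noise standard deviation on
#' the transformed response scale.
#'
#' @param element One of [dispersal_elements()].
#' @param terms A term tibble from [model_terms()].
#' @param coefficients Numeric vector, one value per slope coefficient
#'   (quadratic units take two: linear then squared part), in term order.
#' @param intercept Intercept on the transformed scale.
#' @param noise_sd Residual standard deviation (>= 0) on the transformed
#'   scale.
#' @return A `true_model` object.
#' @export
true_model <- function(element, terms, coefficients, intercept = 0,
                       noise_sd = 0.25) {
  check_element(element)
  if (length(coefficients) != sum(terms$ncoef)) {
    stop("need one coefficient per slope (", sum(terms$ncoef),
         "), got ", length(coefficients), call. = FALSE)
  }
  if (noise_sd < 0) stop("`noise_sd` must be >= 0", call. = FALSE)
  structure(
    list(element = element, terms = terms, coefficients = coefficients,
         intercept = intercept, noise_sd = noise_sd),
    class = "true_model"
  )
}

#' Simulate dispersal responses under a generating syndrome model
#'
#' Builds the transformed-scale response `intercept + X beta + noise` where
#' `X` is the model design on internally standardized traits (each trait
#' column centered and scaled to unit variance before term construction, so
#' coefficients are per-SD effects), then back-transforms to the natural
#' scale of the element, clipping into its valid domain. Clipping events
#' are recorded in a `clipped` column.
#'
#' @param traits A trait table.
#' @param model A [true_model()].
#' @param seed Integer seed for the noise draws.
#' @return A `dispersal_data` tibble with the extra columns `clipped` and
#'   (attribute `"linear_predictor"`) the noiseless transformed values.
#' @export
simulate_responses <- function(traits, model, seed = NULL) {
  stopifnot(inherits(model, "true_model"))
  if (!is.null(seed)) withr::local_seed(seed)
  traits <- validate_trait_table(traits)
  vars <- term_variables(model$terms)
  miss <- setdiff(vars, names(traits))
  if (length(miss)) {
    stop("true model references unknown trait(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  }
  std <- traits
  for (v in vars) {
    x <- traits[[v]]
    s <- stats::sd(x)
    std[[v]] <- if (s > 0) (x - mean(x)) / s else x - mean(x)
  }
  des <- build_design(model$terms, std)
  eta <- model$intercept + drop(des$X %*% model$coefficients)
  yt <- eta + stats::rnorm(nrow(traits), 0, model$noise_sd)
  dom <- transformed_domain(model$element)
  clipped <- yt < dom[1] | yt > dom[2]
  yt_clip <- pmin(pmax(yt, dom[1]), dom[2])
  raw <- dispersal_back_transform(model$element, yt_clip)
  # raw values at an open boundary (zero distance / zero LDD frequency)
  # cannot be represented; nudge into the open domain
  if (model$element %in% c("mean_distance", "ldd_frequency")) {
    raw <- pmax(raw, .Machine$double.xmin)
  }
  out <- dispersal_data(tibble::tibble(
    species_id = traits$species_id,
    element = model$element,
    raw_value = raw
  ))
  out$clipped <- clipped[match(out$species_id, traits$species_id)]
  attr(out, "linear_predictor") <-
    stats::setNames(eta, traits$species_id)
  out
}

#' Simulate mark-release-recapture movement distances
#'
#' Draws a distance sample (km) from one of the two kernel families:
#' `negexp` is exponential with rate `alpha` (mean `1/alpha`), `invpower`
#' is Pareto with survival `(d / d_min)^-(b - 1)` for `d >= d_min`.
#'
#' @param n Sample size (>= 1).
#' @param family `"negexp"` or `"invpower"`.
#' @param alpha Rate of the negative exponential, per km (> 0).
#' @param b Inverse-power exponent (> 1).
#' @param d_min Reference distance of the power law, km (> 0).
#' @param seed Integer seed.
#' @return Numeric vector of `n` distances in km.
#' @examples
#' simulate_mrr_distances(5, "negexp", alpha = 5, seed = 1)
#' @export
simulate_mrr_distances <- function(n, family = c("negexp", "invpower"),
                                   alpha = 5, b = 2, d_min = 1, seed = NULL) {
  family <- match.arg(family)
  if (n < 1) stop("`n` must be >= 1", call. = FALSE)
  if (!is.null(seed)) withr::local_seed(seed)
  if (family == "negexp") {
    if (alpha <= 0) stop("`alpha` must be > 0", call. = FALSE)
    stats::rexp(n, rate = alpha)
  } else {
    if (b <= 1) stop("`b` must be > 1", call. = FALSE)
    if (d_min <= 0) stop("`d_min` must be > 0", call. = FALSE)
    # inverse-CDF draw: S(d) = (d/d_min)^-(b-1)
    d_min * stats::runif(n)^(-1 / (b - 1))
  }
}

#' Simulate per-patch residency counts for a propensity
#'
#' Given a true propensity to leave, draws the number of resident
#' recaptures per patch as Binomial(total, 1 - propensity).
#'
#' @param propensity True probability of leaving the patch, in \[0, 1\].
#' @param totals Integer vector of total recaptures per patch.
#' @param seed Integer seed.
#' @return A tibble with columns `residents` and `total`, one row per
#'   patch, usable with [propensity_from_recaptures()].
#' @export
simulate_residency <- function(propensity, totals, seed = NULL) {
  if (propensity < 0 || propensity > 1) {
    stop("`propensity` must be in [0, 1]", call. = FALSE)
  }
  if (any(totals < 1)) stop("patch totals must be >= 1", call. = FALSE)
  if (!is.null(seed)) withr::local_seed(seed)
  tibble::tibble(
    residents = stats::rbinom(length(totals), totals, 1 - propensity),
    total = as.integer(totals)
  )
}

#' Simulate a pure-birth tree and a trait with tunable phylogenetic signal
#'
#' Grows a pure-birth (Yule) tree on `n_tips` species, rescales its
#' phylogenetic covariance by Pagel's lambda (off-diagonal shared branch
#' lengths multiplied by `lambda`, tip variances untouched) and draws one
#' Brownian-motion trait from the resulting multivariate normal. At
#' `lambda = 0` trait values are i.i.d. across tips; at `lambda = 1` they
#' follow plain Brownian motion on the tree.
#'
#' @param n_tips Number of tips (>= 3).
#' @param lambda Pagel's lambda in \[0, 1\].
#' @param sigma Brownian-motion rate (SD per unit branch length).
#' @param seed Integer seed.
#' @return A list with `tree` (an `ape::phylo` with tip labels `sp001`,
#'   ...) and `trait` (named numeric vector).
#' @export
simulate_tree_and_trait <- function(n_tips, lambda = 1, sigma = 1,
                                    seed = NULL) {
  if (n_tips < 3) stop("`n_tips` must be >= 3", call. = FALSE)
  if (lambda < 0 || lambda > 1) stop("`lambda` must be in [0, 1]",
                                     call. = FALSE)
  if (!is.null(seed)) withr::local_seed(seed)
  tree <- ape::rphylo(n_tips, birth = 1, death = 0)
  tree$tip.label <- sprintf("sp%03d", seq_len(n_tips))
  C <- ape::vcv.phylo(tree)
  Cl <- lambda_scale(C, lambda)
  L <- chol(Cl)
  trait <- drop(crossprod(L, stats::rnorm(n_tips))) * sigma
  names(trait) <- rownames(Cl)
  list(tree = tree, trait = trait)
}

# Pagel transform: multiply off-diagonal phylogenetic covariance by lambda.
lambda_scale <- function(C, lambda) {
  Cl <- C * lambda
  diag(Cl) <- diag(C)
  Cl
}

#' Write a simulated study to CSV files
#'
#' Convenience wrapper generating a trait table and one dispersal response
#' under a generating model, written in the package's CSV formats.
#'
#' @param dir Output directory (created if needed).
#' @param n_species Number of species.
#' @param model A [true_model()].
#' @param seed Integer seed.
#' @return Invisibly, the paths written (`traits.csv`, `dispersal.csv`).
#' @export
simulate_study <- function(dir, n_species, model, seed = NULL) {
  if (!is.null(seed)) withr::local_seed(seed)
  traits <- simulate_trait_table(n_species)
  disp <- simulate_responses(traits, model)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  p1 <- file.path(dir, "traits.csv")
  p2 <- file.path(dir, "dispersal.csv")
  write_trait_table(traits, p1)
  readr::write_csv(tibble::as_tibble(disp)[c("species_id", "element",
                                             "raw_value")], p2)
  invisible(c(traits = p1, dispersal = p2))
}
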