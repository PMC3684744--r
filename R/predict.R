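#' Predict a dispersal element for a table of species
#'
#' Applies a fitted syndrome model to every species of a trait table with
#' complete values for the model's traits. Transformed-scale predictions
#' are back-transformed to the natural scale with element-specific
#' truncation: long-distance dispersal frequency is clipped into (0, 1\],
#' propensity and gene flow into \[0, 1\]; mean dispersal distance needs
#' none (its back-transform is always positive). Each species is also
#' flagged for applicability: a prediction is an extrapolation when any
#' retained trait lies outside the (closed) range observed in the model's
#' training species, and its natural-scale value is suppressed unless
#' `extrapolate = TRUE`.
#'
#' @param fit A `dispersal_fit` (e.g. `selection$chosen`).
#' @param traits Trait table of the species to predict (any species also
#'   used in training are predicted like the others).
#' @param element Dispersal element the response represents; needed for
#'   back-transformation.
#' @param extrapolate Keep natural-scale predictions for out-of-range
#'   species.
#' @return A `prediction_set` tibble: `species_id`, `pred_transformed`,
#'   `pred_natural`, `truncated`, `in_range`; attribute
#'   `"training_ranges"` records the per-trait ranges used.
#' @export
predict_species <- function(fit, traits, element, extrapolate = FALSE) {
  stopifnot(inherits(fit, "dispersal_fit"))
  check_element(element)
  preds <- prepare_predictors(traits)
  vars <- term_variables(fit$terms)
  miss <- setdiff(vars, names(preds))
  if (length(miss)) {
    stop("trait table lacks model trait(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  complete <- stats::complete.cases(preds[vars])
  skipped <- preds$species_id[!complete]
  preds <- preds[complete, ]
  des <- build_design(fit$terms, preds, centers = fit$centers)
  X <- cbind(1, des$X)
  eta <- drop(X %*% fit$coef)
  dom <- transformed_domain(element)
  truncated <- eta < dom[1] | eta > dom[2]
  natural <- dispersal_back_transform(element, eta, truncate = TRUE)
  in_range <- rep(TRUE, nrow(preds))
  for (v in vars) {
    rg <- fit$training_ranges[[v]]
    in_range <- in_range & preds[[v]] >= rg[1] & preds[[v]] <= rg[2]
  }
  if (!extrapolate) natural[!in_range] <- NA_real_
  out <- tibble::tibble(
    species_id = preds$species_id,
    element = element,
    pred_transformed = eta,
    pred_natural = natural,
    truncated = truncated,
    in_range = in_range
  )
  attr(out, "training_ranges") <- fit$training_ranges[vars]
  attr(out, "skipped") <- skipped
  class(out) <- c("prediction_set", class(out))
  out
}

#' Flag species outside the training trait ranges
#'
#' A prediction is only trusted for species whose values of every retained
#' trait fall within the closed \[min, max\] interval observed in the
#' species the model was fitted on.
#'
#' @param fit A `dispersal_fit`.
#' @param traits Trait table of species to check.
#' @return A tibble with `species_id` and logical `in_range`.
#' @export
applicability_mask <- function(fit, traits) {
  stopifnot(inherits(fit, "dispersal_fit"))
  preds <- prepare_predictors(traits)
  vars <- term_variables(fit$terms)
  in_range <- rep(TRUE, nrow(preds))
  for (v in vars) {
    rg <- fit$training_ranges[[v]]
    v_ok <- !is.na(preds[[v]]) & preds[[v]] >= rg[1] & preds[[v]] <= rg[2]
    in_range <- in_range & v_ok
  }
  tibble::tibble(species_id = preds$species_id, in_range = in_range)
}

#' Summarize predicted and observed dispersal distributions
#'
#' Distributional summaries (mean, standard deviation, min, max and
#' quantiles by the type-7 linear-interpolation rule, including the 90th
#' percentile) for natural-scale predictions and, when supplied, the
#' observed values, plus kernel density estimates for plotting.
#'
#' @param predictions A `prediction_set` (or numeric vector).
#' @param observed Optional `dispersal_data` restricted to the same
#'   element, or numeric vector of observed natural-scale values.
#' @param probs Quantile probabilities (default includes 0.1, 0.5, 0.9).
#' @return A `dispersal_summary` list with a `stats` tibble (one row per
#'   group) and a `densities` tibble (`group`, `x`, `density`).
#' @export
summarize_distribution <- function(predictions, observed = NULL,
                                   probs = c(0.1, 0.5, 0.9)) {
  vals <- list()
  if (is.numeric(predictions)) {
    vals$predicted <- predictions
  } else {
    vals$predicted <- predictions$pred_natural[!is.na(predictions$pred_natural)]
  }
  if (!is.null(observed)) {
    vals$observed <- if (is.numeric(observed)) observed else
      observed$raw_value
  }
  stats_tab <- purrr::imap_dfr(vals, function(v, nm) {
    if (length(v) < 2) stop("need >= 2 values per group", call. = FALSE)
    q <- stats::quantile(v, probs, type = 7, names = FALSE)
    tibble::tibble(
      group = nm, n = length(v), mean = mean(v), sd = stats::sd(v),
      min = min(v), max = max(v),
      !!!stats::setNames(as.list(q), paste0("q", probs * 100))
    )
  })
  dens_tab <- purrr::imap_dfr(vals, function(v, nm) {
    d <- stats::density(v)
    tibble::tibble(group = nm, x = d$x, density = d$y)
  })
  structure(list(stats = stats_tab, densities = dens_tab),
            class = "dispersal_summary")
}

#' @export
print.dispersal_summary <- function(x, ...) {
  print(x$stats)
  invisible(x)
}
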