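#' Cross-validated per-species predictions
#'
#' Random 75-25 partitioning of the species: in each partition the model
#' is refit on the training fraction and used to predict the held-out
#' species. The training size is `round(frac * n)` (half-up). Over
#' `n_partitions` partitions, each species accumulates predictions from
#' the partitions in which it was held out; their mean and standard error
#' are returned. Partitions with a rank-deficient training design are
#' redrawn (and counted).
#'
#' @param data Analysis table (`response` + trait columns, complete cases).
#' @param terms Term tibble of the model under assessment.
#' @param response Name of the response column.
#' @param frac Training fraction (default 0.75).
#' @param n_partitions Number of random partitions (default 100).
#' @param seed Integer seed.
#' @return A tibble with `species_id`, `observed`, `pred_mean`, `pred_se`
#'   and `n_heldout`; attribute `"n_resampled"` counts redrawn partitions.
#'   Species never held out get `NA` predictions.
#' @export
cross_validate <- function(data, terms, response = "response", frac = 0.75,
                           n_partitions = 100, seed = NULL) {
  if (!is.null(seed)) withr::local_seed(seed)
  data <- tibble::as_tibble(data)
  vars <- term_variables(terms)
  data <- data[stats::complete.cases(data[c(response, vars)]), ]
  n <- nrow(data)
  if (n < 8) stop("need at least 8 species for 75-25 cross-validation",
                  call. = FALSE)
  m <- floor(frac * n + 0.5)  # half-up rounding of the training size
  if (m < sum(terms$ncoef) + 2 || m >= n) {
    stop("training size ", m, " cannot fit ", sum(terms$ncoef),
         " coefficients and leave a test set", call. = FALSE)
  }
  y <- data[[response]]
  des <- build_design(terms, data)  # shared centers: columns are fixed transforms
  X <- cbind(1, des$X)
  k <- ncol(X)
  sums <- sumsq <- counts <- numeric(n)
  n_resampled <- 0L
  for (part in seq_len(n_partitions)) {
    repeat {
      train <- sort(sample.int(n, m))
      qrX <- qr(X[train, , drop = FALSE])
      if (qrX$rank == k) break
      n_resampled <- n_resampled + 1L
      if (n_resampled > 100 * n_partitions) {
        stop("training designs persistently rank-deficient", call. = FALSE)
      }
    }
    beta <- qr.coef(qrX, y[train])
    test <- setdiff(seq_len(n), train)
    pred <- drop(X[test, , drop = FALSE] %*% beta)
    sums[test] <- sums[test] + pred
    sumsq[test] <- sumsq[test] + pred^2
    counts[test] <- counts[test] + 1
  }
  pred_mean <- ifelse(counts > 0, sums / counts, NA_real_)
  pred_var <- ifelse(counts > 1,
                     pmax(sumsq - counts * pred_mean^2, 0) / (counts - 1),
                     NA_real_)
  out <- tibble::tibble(
    species_id = data$species_id %||% sprintf("sp%03d", seq_len(n)),
    observed = y,
    pred_mean = pred_mean,
    pred_se = sqrt(pred_var / counts),
    n_heldout = as.integer(counts)
  )
  attr(out, "n_resampled") <- n_resampled
  class(out) <- c("cv_predictions", class(out))
  out
}

#' Rightness: calibration slope of observed on predicted
#'
#' The slope of the ordinary least-squares regression of observations on
#' (mean) predictions, intercept included. A well-calibrated predictor has
#' slope close to +1.
#'
#' @param observed,predicted Paired numeric vectors (>= 3 pairs;
#'   predictions must vary).
#' @return The regression slope.
#' @examples
#' rightness(c(1, 2, 3), c(1, 1, 2))  # 1.5
#' @export
rightness <- function(observed, predicted) {
  ok <- stats::complete.cases(observed, predicted)
  observed <- observed[ok]; predicted <- predicted[ok]
  if (length(observed) < 3) stop("need >= 3 pairs", call. = FALSE)
  if (stats::var(predicted) == 0) {
    stop("predictions are constant: calibration slope undefined",
         call. = FALSE)
  }
  unname(stats::cov(observed, predicted) / stats::var(predicted))
}

#' Imprecision: mean absolute prediction error
#'
#' Mean absolute difference between observed and predicted values; with
#' `relative = TRUE` each difference is divided by its observed value to
#' remove scale dependency (used for mean dispersal distance and
#' long-distance dispersal frequency).
#'
#' @param observed,predicted Paired numeric vectors.
#' @param relative Divide each absolute error by `|observed|`.
#' @return A non-negative scalar.
#' @examples
#' imprecision(c(1, 2, 3), c(1, 1, 2))                 # 2/3
#' imprecision(c(2, 4), c(1, 2), relative = TRUE)      # 0.5
#' @export
imprecision <- function(observed, predicted, relative = FALSE) {
  ok <- stats::complete.cases(observed, predicted)
  observed <- observed[ok]; predicted <- predicted[ok]
  if (!length(observed)) stop("no complete pairs", call. = FALSE)
  err <- abs(observed - predicted)
  if (relative) {
    if (any(observed == 0)) {
      stop("relative imprecision undefined with a zero observation",
           call. = FALSE)
    }
    err <- err / abs(observed)
  }
  mean(err)
}

#' Cross-validated performance with repeat-to-repeat standard errors
#'
#' Runs the full cross-validation (`n_partitions` random 75-25 partitions)
#' `n_repeats` times independently; each repeat yields one rightness and
#' one imprecision value from its per-species mean predictions. Their
#' means and standard errors over repeats summarize the model's predictive
#' quality.
#'
#' @inheritParams cross_validate
#' @param n_repeats Number of independent cross-validation repeats.
#' @param relative Use observation-relative imprecision.
#' @param label Model label carried into reports.
#' @return A `cv_performance` object: per-repeat tibble plus summary.
#' @export
assess_performance <- function(data, terms, response = "response",
                               n_repeats = 20, n_partitions = 100,
                               frac = 0.75, relative = FALSE, seed = NULL,
                               label = "model") {
  if (!is.null(seed)) withr::local_seed(seed)
  per_repeat <- purrr::map_dfr(seq_len(n_repeats), function(r) {
    cv <- cross_validate(data, terms, response = response, frac = frac,
                         n_partitions = n_partitions)
    tibble::tibble(
      repeat_id = r,
      rightness = rightness(cv$observed, cv$pred_mean),
      imprecision = imprecision(cv$observed, cv$pred_mean,
                                relative = relative)
    )
  })
  se <- function(x) if (length(x) > 1) stats::sd(x) / sqrt(length(x)) else NA_real_
  structure(
    list(
      label = label,
      per_repeat = per_repeat,
      rightness = mean(per_repeat$rightness),
      rightness_se = se(per_repeat$rightness),
      imprecision = mean(per_repeat$imprecision),
      imprecision_se = se(per_repeat$imprecision),
      relative = relative,
      n_repeats = n_repeats,
      n_partitions = n_partitions
    ),
    class = "cv_performance"
  )
}

#' @export
print.cv_performance <- function(x, ...) {
  cat("Cross-validated performance (", x$label, "): ",
      x$n_repeats, " repeats x ", x$n_partitions, " partitions\n", sep = "")
  cat(sprintf("rightness   %.4f +/- %.4f\n", x$rightness, x$rightness_se))
  cat(sprintf("imprecision %.4g +/- %.4g%s\n", x$imprecision,
              x$imprecision_se, if (x$relative) " (relative)" else ""))
  invisible(x)
}

#' Compare a trait model against the wing-size-only reference
#'
#' Gain in rightness is the difference of calibration slopes (trait model
#' minus reference); gain in precision is the ratio of the reference's
#' imprecision to the trait model's (values above 1 mean the trait model
#' is more precise). Significance of each difference comes from a
#' regression of the per-repeat performance values on the model-type
#' indicator.
#'
#' @param trait_perf,reference_perf `cv_performance` objects computed on
#'   the same response with the same number of repeats.
#' @return A `gain_report` list: `gain_rightness`, `gain_precision`,
#'   `p_rightness`, `p_precision`.
#' @export
compare_models <- function(trait_perf, reference_perf) {
  stopifnot(inherits(trait_perf, "cv_performance"),
            inherits(reference_perf, "cv_performance"))
  if (trait_perf$n_repeats != reference_perf$n_repeats) {
    stop("repeat counts differ between the two performances", call. = FALSE)
  }
  both <- dplyr::bind_rows(
    dplyr::mutate(trait_perf$per_repeat, type = 1),
    dplyr::mutate(reference_perf$per_repeat, type = 0)
  )
  p_of <- function(metric) {
    v <- both[[metric]]
    if (stats::var(v) == 0) return(1)
    fit <- stats::lm(v ~ both$type)
    stats::summary.lm(fit)$coefficients[2, 4]
  }
  structure(
    list(
      gain_rightness = trait_perf$rightness - reference_perf$rightness,
      gain_precision = reference_perf$imprecision / trait_perf$imprecision,
      p_rightness = p_of("rightness"),
      p_precision = p_of("imprecision"),
      trait = trait_perf, reference = reference_perf
    ),
    class = "gain_report"
  )
}

#' @export
print.gain_report <- function(x, ...) {
  cat(sprintf("gain in rightness: %+.4f (p = %.3g)\n",
              x$gain_rightness, x$p_rightness))
  cat(sprintf("gain in precision: x%.3f (p = %.3g)\n",
              x$gain_precision, x$p_precision))
  invisible(x)
}
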