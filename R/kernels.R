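#' Fit a negative-exponential dispersal kernel
#'
#' The negative-exponential kernel has density
#' `P(D) = alpha * exp(-alpha * D)` for distances D > 0 (km). The maximum
#' likelihood estimate is the closed form `alpha = 1 / mean(D)`, so the
#' kernel's mean dispersal distance `1/alpha` equals the sample mean
#' exactly.
#'
#' @param distances Numeric vector of movement distances in km; at least
#'   two strictly positive values.
#' @return A `kernel_fit` object: family, parameter estimates, number of
#'   observations, log-likelihood and the implied mean distance (km).
#' @examples
#' fit_negexp(c(0.1, 0.2, 0.3))
#' @export
fit_negexp <- function(distances) {
  distances <- as.numeric(distances)
  if (length(distances) < 2) {
    stop("need at least 2 distances to fit a kernel", call. = FALSE)
  }
  if (any(!is.finite(distances)) || any(distances <= 0)) {
    stop("all distances must be finite and > 0 km", call. = FALSE)
  }
  alpha <- 1 / mean(distances)
  n <- length(distances)
  loglik <- n * log(alpha) - alpha * sum(distances)
  new_kernel_fit(
    family = "negexp",
    params = c(alpha = alpha),
    n = n,
    loglik = loglik,
    mean_distance = 1 / alpha
  )
}

#' Fit an inverse-power dispersal kernel
#'
#' The inverse-power kernel has density `P(D) = a * D^-b` for distances
#' `D >= d_min` (km), i.e. a Pareto law with tail exponent `b - 1`. The
#' maximum-likelihood tail estimate is the closed form
#' `b = 1 + n / sum(log(D / d_min))`; the normalizing constant is
#' `a = (b - 1) * d_min^(b - 1)`. A finite tail mass requires `b > 1`,
#' which the MLE guarantees whenever some distance exceeds `d_min`.
#'
#' @param distances Numeric vector of movement distances in km, all
#'   `>= d_min`; at least two values, not all equal to `d_min`.
#' @param d_min Reference (minimum) distance of the power law, km; > 0.
#' @return A `kernel_fit` object.
#' @examples
#' fit_invpower(c(1, exp(1), exp(2)), d_min = 1)  # b = 2
#' @export
fit_invpower <- function(distances, d_min) {
  distances <- as.numeric(distances)
  if (length(distances) < 2) {
    stop("need at least 2 distances to fit a kernel", call. = FALSE)
  }
  if (!is.numeric(d_min) || length(d_min) != 1 || d_min <= 0) {
    stop("`d_min` must be a single positive distance (km)", call. = FALSE)
  }
  if (any(!is.finite(distances)) || any(distances < d_min)) {
    stop("all distances must be finite and >= d_min", call. = FALSE)
  }
  slog <- sum(log(distances / d_min))
  if (slog == 0) {
    stop("all distances equal d_min; tail exponent is unidentifiable",
         call. = FALSE)
  }
  n <- length(distances)
  b <- 1 + n / slog
  a <- (b - 1) * d_min^(b - 1)
  loglik <- n * log(b - 1) + n * (b - 1) * log(d_min) - b * sum(log(distances))
  new_kernel_fit(
    family = "invpower",
    params = c(a = a, b = b, d_min = d_min),
    n = n,
    loglik = loglik,
    mean_distance = if (b > 2) (b - 1) / (b - 2) * d_min else Inf
  )
}

#' Fit a kernel to a binned dispersal kernel (density vs distance class)
#'
#' Alternative fitting path for data published as a dispersal kernel, i.e.
#' a probability density per distance class rather than raw distances. The
#' kernel is linearized on the log-density scale (`log p = log alpha -
#' alpha d` for the negative exponential, `log p = log a - b log d` for the
#' inverse power) and fitted by least squares, optionally weighted.
#'
#' @param distance Numeric vector of class midpoints (km).
#' @param density Positive probability density at each midpoint.
#' @param family `"negexp"` or `"invpower"`.
#' @param weights Optional least-squares weights (e.g. class counts).
#' @return A `kernel_fit` object (log-likelihood is `NA`: no raw sample).
#' @export
fit_kernel_binned <- function(distance, density,
                              family = c("negexp", "invpower"),
                              weights = NULL) {
  family <- match.arg(family)
  if (length(distance) != length(density) || length(distance) < 2) {
    stop("need >= 2 (distance, density) pairs of equal length", call. = FALSE)
  }
  if (any(density <= 0) || any(distance <= 0)) {
    stop("distances and densities must be > 0", call. = FALSE)
  }
  y <- log(density)
  if (family == "negexp") {
    fit <- stats::lm(y ~ distance, weights = weights)
    alpha <- -unname(stats::coef(fit)[2])
    if (alpha <= 0) stop("fitted rate is not positive; density does not decay",
                         call. = FALSE)
    new_kernel_fit("negexp", c(alpha = alpha), n = length(distance),
                   loglik = NA_real_, mean_distance = 1 / alpha)
  } else {
    lx <- log(distance)
    fit <- stats::lm(y ~ lx, weights = weights)
    b <- -unname(stats::coef(fit)[2])
    if (b <= 1) stop("fitted exponent b <= 1: infinite tail mass", call. = FALSE)
    d_min <- min(distance)
    a <- (b - 1) * d_min^(b - 1)
    new_kernel_fit("invpower", c(a = a, b = b, d_min = d_min),
                   n = length(distance), loglik = NA_real_,
                   mean_distance = if (b > 2) (b - 1) / (b - 2) * d_min else Inf)
  }
}

new_kernel_fit <- function(family, params, n, loglik, mean_distance) {
  structure(
    list(family = family, params = params, n = n, loglik = loglik,
         mean_distance = mean_distance),
    class = "kernel_fit"
  )
}

#' @export
print.kernel_fit <- function(x, ...) {
  cat("Dispersal kernel fit (", x$family, "), n = ", x$n, "\n", sep = "")
  print(round(x$params, 6))
  cat("mean distance:", signif(x$mean_distance, 6), "km\n")
  invisible(x)
}

#' Tail probability of a fitted dispersal kernel
#'
#' Probability that a movement exceeds `threshold` km, computed as the
#' integrated tail mass of the fitted density (not a point evaluation):
#' `exp(-alpha * t)` for the negative exponential and
#' `(t / d_min)^-(b - 1)` for the inverse power. Used with `threshold = 5`
#' to obtain the frequency of long-distance dispersal.
#'
#' @param fit A `kernel_fit`.
#' @param threshold Distance threshold in km (> 0; `>= d_min` for the
#'   inverse-power family).
#' @return A probability in \[0, 1\].
#' @examples
#' fit <- fit_invpower(c(1, exp(1), exp(2)), d_min = 1)
#' tail_probability(fit, 5)  # 0.2
#' @export
tail_probability <- function(fit, threshold) {
  stopifnot(inherits(fit, "kernel_fit"))
  if (!is.numeric(threshold) || length(threshold) != 1 || threshold <= 0) {
    stop("`threshold` must be a single positive distance (km)", call. = FALSE)
  }
  if (fit$family == "negexp") {
    p <- exp(-fit$params[["alpha"]] * threshold)
  } else {
    b <- fit$params[["b"]]
    d_min <- fit$params[["d_min"]]
    if (b <= 1) stop("b <= 1: tail mass is not finite", call. = FALSE)
    if (threshold < d_min) {
      stop("`threshold` must be >= d_min for the inverse-power family",
           call. = FALSE)
    }
    p <- (threshold / d_min)^(-(b - 1))
  }
  min(max(unname(p), 0), 1)
}

#' Dispersal propensity from mark-release-recapture residency
#'
#' Per patch, the propensity to leave is one minus the proportion of
#' recaptures that occurred in the patch of initial capture (residents);
#' the species value is the unweighted mean over patches, so patches of
#' different size count equally.
#'
#' @param patches A data frame with columns `residents` and `total`
#'   (recapture counts per patch), or a numeric vector of residents with
#'   `total` given separately.
#' @param total Optional numeric vector of total recaptures per patch when
#'   `patches` is a numeric vector.
#' @return A single propensity in \[0, 1\].
#' @examples
#' propensity_from_recaptures(data.frame(residents = c(8, 6), total = c(10, 10)))
#' @export
propensity_from_recaptures <- function(patches, total = NULL) {
  if (is.data.frame(patches)) {
    residents <- patches$residents
    total <- patches$total
  } else {
    residents <- patches
  }
  if (is.null(residents) || is.null(total) || length(residents) == 0) {
    stop("need per-patch `residents` and `total` recapture counts",
         call. = FALSE)
  }
  if (length(residents) != length(total)) {
    stop("`residents` and `total` must have equal length", call. = FALSE)
  }
  if (any(total < 1) || any(residents < 0) || any(residents > total)) {
    stop("counts must satisfy 0 <= residents <= total and total >= 1",
         call. = FALSE)
  }
  mean(1 - residents / total)
}

#' Gene-flow observation from an F_ST value
#'
#' Wraps a per-species fixation index into a dispersal observation carrying
#' both the raw F_ST and its transformed analysis value (by default
#' `1 - sqrt(F_ST)`, which increases with gene flow).
#'
#' @param fst F_ST value(s) in \[0, 1\].
#' @param species_id Optional species identifier(s).
#' @inheritParams dispersal_data
#' @return A `dispersal_data` tibble with element `gene_flow`.
#' @examples
#' geneflow_from_fst(0.04, "sp1")
#' @export
geneflow_from_fst <- function(fst, species_id = NULL,
                              gene_flow_convention = c("one_minus_sqrt_fst",
                                                       "sqrt_complement")) {
  if (any(!is.finite(fst)) || any(fst < 0) || any(fst > 1)) {
    stop("F_ST must lie in [0, 1]", call. = FALSE)
  }
  if (is.null(species_id)) species_id <- paste0("sp", seq_along(fst))
  dispersal_data(
    tibble::tibble(species_id = as.character(species_id),
                   element = "gene_flow", raw_value = fst),
    gene_flow_convention = match.arg(gene_flow_convention)
  )
}
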