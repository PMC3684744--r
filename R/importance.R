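#' Partition a model's R-squared among its terms (LMG decomposition)
#'
#' Averages, over all orderings of the regressors, the increase in
#' R-squared obtained when each regressor enters the model after those
#' preceding it in the ordering. The contributions are non-negative and
#' sum exactly to the full model's R-squared.
#'
#' Two grouping conventions are available: `mode = "unit"` treats a
#' quadratic polynomial (its two coefficients) as a single regressor, as
#' well as each interaction; `mode = "coefficient"` orders individual
#' design columns, giving one contribution per coefficient row. Up to
#' `exact_max` regressor groups the subset-weighted exact formula is used
#' (equivalent to enumerating all orderings); above it, a random sample of
#' orderings approximates the average.
#'
#' @param fit A `dispersal_fit` from [fit_dispersal_glm()].
#' @param mode `"unit"` or `"coefficient"`; see Details.
#' @param exact_max Largest group count computed exactly (default 10).
#' @param n_orderings Sampled orderings when above `exact_max`.
#' @param seed Seed for the sampled-orderings path.
#' @return An `r2_partition` object with a tibble `contributions`
#'   (`label`, `contribution`), the full-model `r2` and the computation
#'   mode.
#' @export
r2_partition <- function(fit, mode = c("unit", "coefficient"),
                         exact_max = 10, n_orderings = 5000, seed = NULL) {
  stopifnot(inherits(fit, "dispersal_fit"))
  mode <- match.arg(mode)
  data <- fit$training
  y <- data[[fit$response]]
  des <- build_design(fit$terms, data, centers = fit$centers)
  if (!ncol(des$X)) stop("model has no regressors to partition", call. = FALSE)
  if (mode == "unit") {
    groups <- des$unit_cols
    labels <- fit$terms$label
  } else {
    groups <- as.list(colnames(des$X))
    labels <- colnames(des$X)
  }
  gidx <- lapply(groups, function(nm) match(nm, colnames(des$X)))
  contrib <- lmg_contributions(des$X, y, gidx, exact_max = exact_max,
                               n_orderings = n_orderings, seed = seed)
  structure(
    list(
      contributions = tibble::tibble(label = labels, contribution = contrib),
      r2 = sum(contrib),
      mode = mode,
      exact = length(gidx) <= exact_max
    ),
    class = "r2_partition"
  )
}

# Core decomposition on a design matrix X (no intercept) with column
# groups `gidx`. Exact path: subset-weighted formula over all 2^p
# submodels, identical to averaging sequential increments over all p!
# orderings but exponential instead of factorial in cost.
lmg_contributions <- function(X, y, gidx, exact_max = 10,
                              n_orderings = 5000, seed = NULL) {
  p <- length(gidx)
  n <- length(y)
  Xi <- cbind(1, X)
  XtX <- crossprod(Xi)
  Xty <- drop(crossprod(Xi, y))
  tss <- sum(y^2) - n * mean(y)^2
  if (tss <= 0) stop("response has no variation", call. = FALSE)
  cols_of <- function(set) c(1L, unlist(gidx[set]) + 1L)
  r2_of <- function(set) {
    idx <- cols_of(set)
    R <- tryCatch(chol(XtX[idx, idx, drop = FALSE]), error = function(e) NULL)
    if (is.null(R)) stop("rank-deficient submodel in R2 partition",
                         call. = FALSE)
    b <- backsolve(R, forwardsolve(t(R), Xty[idx]))
    rss <- max(sum(y^2) - sum(b * Xty[idx]), 0)
    1 - rss / tss
  }
  if (p <= exact_max) {
    # cache R2 of every subset, keyed by bitmask
    r2_cache <- numeric(2^p)
    for (mask in 0:(2^p - 1)) {
      set <- which(bitwAnd(mask, bitwShiftL(1L, 0:(p - 1))) > 0)
      r2_cache[mask + 1] <- if (length(set)) r2_of(set) else 0
    }
    w <- vapply(0:(p - 1), function(s) {
      factorial(s) * factorial(p - 1 - s) / factorial(p)
    }, numeric(1))
    contrib <- numeric(p)
    for (j in seq_len(p)) {
      bit_j <- bitwShiftL(1L, j - 1L)
      for (mask in 0:(2^p - 1)) {
        if (bitwAnd(mask, bit_j) > 0) next
        s <- sum(bitwAnd(mask, bitwShiftL(1L, 0:(p - 1))) > 0)
        contrib[j] <- contrib[j] +
          w[s + 1] * (r2_cache[bitwOr(mask, bit_j) + 1] - r2_cache[mask + 1])
      }
    }
  } else {
    if (!is.null(seed)) withr::local_seed(seed)
    contrib <- numeric(p)
    for (o in seq_len(n_orderings)) {
      ord <- sample.int(p)
      prev <- 0
      set <- integer(0)
      for (j in ord) {
        set <- c(set, j)
        cur <- r2_of(set)
        contrib[j] <- contrib[j] + (cur - prev)
        prev <- cur
      }
    }
    contrib <- contrib / n_orderings
  }
  contrib
}

#' @export
print.r2_partition <- function(x, ...) {
  cat("R2 partition (", x$mode, if (x$exact) ", exact" else ", sampled",
      "): total R2 = ", round(x$r2, 4), "\n", sep = "")
  print(dplyr::arrange(x$contributions, dplyr::desc(.data$contribution)))
  invisible(x)
}
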