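#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a fitted syndrome model
#'
#' @param x A `dispersal_fit`.
#' @param ... Unused.
#' @return A tibble with one row per coefficient: `term`, `estimate`,
#'   `std.error`, `statistic`, `p.value`.
#' @method tidy dispersal_fit
#' @export
tidy.dispersal_fit <- function(x, ...) {
  sm <- stats::summary.lm(x$lm)$coefficients
  tibble::tibble(
    term = rownames(sm),
    estimate = sm[, 1],
    std.error = sm[, 2],
    statistic = sm[, 3],
    p.value = sm[, 4]
  )
}

#' @rdname tidy.dispersal_fit
#' @return `glance()` returns a one-row tibble with `r.squared`,
#'   `adj.r.squared`, `sigma`, `logLik`, `AICc`, `nobs` and `k`.
#' @method glance dispersal_fit
#' @export
glance.dispersal_fit <- function(x, ...) {
  tibble::tibble(
    r.squared = x$r2, adj.r.squared = x$adj_r2, sigma = x$sigma,
    logLik = x$loglik, AICc = x$aicc, nobs = x$n, k = x$k
  )
}

#' Tidy a two-stage model selection
#'
#' @param x A `syndrome_selection`.
#' @param stage Which AICc table to return: `"stage2"` (default),
#'   `"stage1"`, or `"top"` for the final top set.
#' @param ... Unused.
#' @return A tibble of models with `label`, `k`, `loglik`, `aicc`,
#'   `delta_aicc`, `r2`, `adj_r2`.
#' @method tidy syndrome_selection
#' @export
tidy.syndrome_selection <- function(x, stage = c("stage2", "stage1", "top"),
                                    ...) {
  stage <- match.arg(stage)
  tab <- switch(stage, stage1 = x$stage1, stage2 = x$stage2,
                top = x$stage2_top)
  dplyr::select(tab, "label", "k", "loglik", "aicc", "delta_aicc",
                "r2", "adj_r2")
}

#' @rdname tidy.syndrome_selection
#' @method glance syndrome_selection
#' @export
glance.syndrome_selection <- function(x, ...) {
  tibble::tibble(
    n = x$n,
    n_stage1 = nrow(x$stage1), n_stage1_top = nrow(x$stage1_top),
    n_stage2 = nrow(x$stage2), n_stage2_top = nrow(x$stage2_top),
    chosen = if (nrow(x$chosen$terms))
      paste(x$chosen$terms$label, collapse = " + ") else "1",
    r.squared = x$chosen$r2, adj.r.squared = x$chosen$adj_r2,
    AICc = x$chosen$aicc
  )
}

#' Tidy cross-validated performance
#'
#' @param x A `cv_performance`.
#' @param ... Unused.
#' @return The per-repeat tibble (`repeat_id`, `rightness`,
#'   `imprecision`).
#' @method tidy cv_performance
#' @export
tidy.cv_performance <- function(x, ...) x$per_repeat

#' @rdname tidy.cv_performance
#' @method glance cv_performance
#' @export
glance.cv_performance <- function(x, ...) {
  tibble::tibble(
    label = x$label,
    rightness = x$rightness, rightness_se = x$rightness_se,
    imprecision = x$imprecision, imprecision_se = x$imprecision_se,
    relative = x$relative, n_repeats = x$n_repeats,
    n_partitions = x$n_partitions
  )
}

#' Tidy an R-squared partition
#'
#' @param x An `r2_partition`.
#' @param ... Unused.
#' @return The contributions tibble.
#' @method tidy r2_partition
#' @export
tidy.r2_partition <- function(x, ...) x$contributions

#' Tidy a PGLS fit
#'
#' @param x A `pgls_fit`.
#' @param ... Unused.
#' @return A tibble of coefficient estimates.
#' @method tidy pgls_fit
#' @export
tidy.pgls_fit <- function(x, ...) {
  tibble::tibble(term = names(x$coef), estimate = unname(x$coef))
}

#' @rdname tidy.pgls_fit
#' @method glance pgls_fit
#' @export
glance.pgls_fit <- function(x, ...) {
  tibble::tibble(
    lambda = x$lambda, logLik = x$loglik, logLik0 = x$loglik0,
    logLik1 = x$loglik1, LR = x$lr_lambda0, p.value = x$p_lambda0,
    nobs = x$n
  )
}

#' Tidy a gain report
#'
#' @param x A `gain_report`.
#' @param ... Unused.
#' @return A one-row tibble with both gains and their p-values.
#' @method tidy gain_report
#' @export
tidy.gain_report <- function(x, ...) {
  tibble::tibble(
    gain_rightness = x$gain_rightness, p_rightness = x$p_rightness,
    gain_precision = x$gain_precision, p_precision = x$p_precision
  )
}
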