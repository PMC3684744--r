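#' Small-sample-corrected Akaike information criterion
#'
#' `AICc = -2 loglik + 2p + 2p(p + 1)/(n - p - 1)`, where `p` counts every
#' estimated parameter: intercept, slope coefficients and the residual
#' variance. The correction vanishes as `n` grows; it is undefined (the
#' model is saturated) when `n - p - 1 < 1`.
#'
#' @param loglik Gaussian log-likelihood at the maximum (MLE variance).
#' @param p Total parameter count including intercept and variance.
#' @param n Number of observations.
#' @return The AICc value.
#' @examples
#' aicc(-10, p = 2, n = 10)  # = 20 + 4 + 12/7
#' @export
aicc <- function(loglik, p, n) {
  if (n - p - 1 < 1) {
    stop("model saturated: n - p - 1 < 1, AICc undefined", call. = FALSE)
  }
  -2 * loglik + 2 * p + 2 * p * (p + 1) / (n - p - 1)
}

#' Screen one trait for a curvilinear dispersal relationship
#'
#' Fits `response ~ trait + trait^2` (centered powers) and inspects the
#' quadratic coefficient. Significant and marginally significant curvature
#' (p < `alpha`, default 0.1) both promote the trait to a second-degree
#' polynomial in subsequent model selection; otherwise the trait enters
#' linearly. Binary traits are never screened.
#'
#' @param response Transformed dispersal values.
#' @param trait Trait values, paired with `response`; at least 5 pairs,
#'   non-constant.
#' @param alpha p-value threshold below which curvature is retained.
#' @return A list with `form` (`"linear"` or `"quadratic"`), `p_value` of
#'   the quadratic coefficient and its `estimate`.
#' @export
screen_quadratic <- function(response, trait, alpha = 0.1) {
  ok <- stats::complete.cases(response, trait)
  response <- response[ok]; trait <- trait[ok]
  if (length(response) < 5) {
    stop("need at least 5 paired observations to screen curvature",
         call. = FALSE)
  }
  if (stats::var(trait) == 0) {
    stop("trait is constant; curvature screen undefined", call. = FALSE)
  }
  xc <- trait - mean(trait)
  fit <- stats::lm(response ~ xc + I(xc^2))
  sm <- stats::summary.lm(fit)$coefficients
  if (nrow(sm) < 3 || is.na(sm[3, 4])) {
    # squared term collinear (e.g. trait with 2 distinct values)
    return(list(form = "linear", p_value = NA_real_, estimate = NA_real_))
  }
  list(
    form = if (sm[3, 4] < alpha) "quadratic" else "linear",
    p_value = unname(sm[3, 4]),
    estimate = unname(sm[3, 1])
  )
}

#' Fit one syndrome model by ordinary least squares
#'
#' Gaussian identity-link fit of a transformed dispersal response on a
#' term set (see [model_terms()]). Returns the fit together with the
#' Gaussian log-likelihood (MLE variance), AICc (`NA` when the model is
#' too saturated for the correction), R-squared and adjusted R-squared,
#' and remembers the training data, term design and trait centers so the
#' model can predict new species.
#'
#' @param data A tibble with a response column and the trait columns the
#'   terms reference (e.g. from [syndrome_data()]).
#' @param terms A term tibble from [model_terms()].
#' @param response Name of the response column.
#' @return A `dispersal_fit` object.
#' @examples
#' d <- tibble::tibble(y = c(1, 2, 3, 4.1, 5), x = 1:5)
#' fit_dispersal_glm(d, model_terms(linear = "x"), response = "y")
#' @export
fit_dispersal_glm <- function(data, terms, response = "response") {
  data <- tibble::as_tibble(data)
  if (!response %in% names(data)) {
    stop("no column `", response, "` in data", call. = FALSE)
  }
  vars <- term_variables(terms)
  keep <- stats::complete.cases(data[c(response, vars)])
  data <- data[keep, ]
  y <- data[[response]]
  n <- length(y)
  k <- sum(terms$ncoef)
  if (n < k + 2) {
    stop("need at least k + 2 complete cases to fit ", k,
         " coefficients (have ", n, ")", call. = FALSE)
  }
  des <- build_design(terms, data)
  df <- data.frame(.y = y, des$X, check.names = FALSE)
  fml <- if (ncol(des$X)) {
    stats::reformulate(sprintf("`%s`", colnames(des$X)), response = ".y")
  } else {
    .y ~ 1
  }
  fit <- stats::lm(fml, data = df)
  if (any(is.na(stats::coef(fit)))) {
    bad <- names(stats::coef(fit))[is.na(stats::coef(fit))]
    stop("singular design; collinear term column(s): ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  rss <- sum(stats::resid(fit)^2)
  tss <- sum((y - mean(y))^2)
  rss <- max(rss, rss_floor(tss))  # treat residuals below numeric noise as exact fit
  r2 <- if (tss > 0) 1 - rss / tss else 0
  adj_r2 <- if (tss > 0) 1 - (1 - r2) * (n - 1) / (n - k - 1) else 0
  ll <- -n / 2 * (log(2 * pi * rss / n) + 1)
  p <- k + 2
  aicc_val <- if (n - p - 1 >= 1) aicc(ll, p, n) else NA_real_
  ranges <- lapply(vars, function(v) range(data[[v]]))
  names(ranges) <- vars
  structure(
    list(terms = terms, lm = fit, coef = stats::coef(fit),
         loglik = ll, aicc = aicc_val, r2 = r2, adj_r2 = adj_r2,
         sigma = sqrt(rss / n), n = n, k = k,
         centers = des$centers, response = response,
         training_ranges = ranges, training = data),
    class = "dispersal_fit"
  )
}

#' @export
print.dispersal_fit <- function(x, ...) {
  cat("Syndrome model fit: ", x$response, " ~ ",
      if (nrow(x$terms)) paste(x$terms$label, collapse = " + ") else "1",
      "\n", sep = "")
  cat(sprintf("n = %d, k = %d, R2 = %.4f, adj R2 = %.4f, AICc = %.3f\n",
              x$n, x$k, x$r2, x$adj_r2, x$aicc))
  invisible(x)
}

# --- exhaustive enumeration -------------------------------------------------

#' Enumerate all sub-models of a candidate term set
#'
#' Yields every subset of the candidate units whose total slope-coefficient
#' count does not exceed `max_coef`, including the intercept-only model,
#' in a deterministic order. Marginality is respected: an interaction unit
#' is only emitted in subsets that also contain main-effect units for both
#' of its traits.
#'
#' @param terms Candidate term tibble (see [model_terms()]).
#' @param max_coef Maximum total number of slope coefficients (intercept
#'   excluded).
#' @return A list of integer vectors, each indexing rows of `terms`
#'   (`integer(0)` is the intercept-only model).
#' @examples
#' length(enumerate_models(model_terms(linear = letters[1:10]), 8))  # 1013
#' @export
enumerate_models <- function(terms, max_coef = 8) {
  if (max_coef < 1) stop("`max_coef` must be >= 1", call. = FALSE)
  dependent <- terms$kind %in% c("interaction", "square")
  ord <- order(dependent)  # main effects first, stable
  terms_o <- terms[ord, ]
  n_units <- nrow(terms_o)
  # units that must already be present before unit i may enter
  required_of <- lapply(seq_len(n_units), function(i) {
    if (terms_o$kind[i] == "interaction") {
      mains <- which(!terms_o$kind %in% c("interaction", "square") &
                       terms_o$trait1 %in% c(terms_o$trait1[i],
                                             terms_o$trait2[i]))
      if (length(mains) < 2) return(NULL)  # a main is missing: never usable
      mains
    } else if (terms_o$kind[i] == "square") {
      main <- which(terms_o$kind == "linear" &
                      terms_o$trait1 == terms_o$trait1[i])
      if (length(main) < 1) return(NULL)
      main
    } else {
      integer(0)
    }
  })
  out <- vector("list", 0)
  recurse <- function(i, chosen, budget) {
    if (i > n_units) {
      out[[length(out) + 1]] <<- sort(ord[chosen])
      return(invisible())
    }
    req <- required_of[[i]]
    if (terms_o$ncoef[i] <= budget && !is.null(req) &&
        all(req %in% chosen)) {
      recurse(i + 1, c(chosen, i), budget - terms_o$ncoef[i])
    }
    recurse(i + 1, chosen, budget)
  }
  recurse(1L, integer(0), max_coef)
  out
}

# Residual sums of squares below this fraction of the total variation are
# numeric noise from an exact fit; flooring them makes all perfect-fit
# models tie, so AICc ordering among them reduces to the parameter penalty.
rss_floor <- function(tss) max(tss, .Machine$double.eps) * 1e-12

# Fast all-subsets OLS via cross-products of the full candidate design.
# Returns one row per enumerated model with loglik/AICc/R2 computed from
# the normal equations; singular submodels are dropped.
fit_all_subsets <- function(terms, data, response, max_coef = 8) {
  y <- data[[response]]
  n <- length(y)
  des <- build_design(terms, data)
  X <- cbind(`(Intercept)` = 1, des$X)
  XtX <- crossprod(X)
  Xty <- drop(crossprod(X, y))
  yty <- sum(y^2)
  tss <- yty - n * mean(y)^2
  # column indices (within X) per unit
  colidx <- lapply(des$unit_cols, function(nm) match(nm, colnames(X)))
  subsets <- enumerate_models(terms, max_coef)
  nm <- length(subsets)
  floor_rss <- rss_floor(tss)
  k_v <- ll_v <- aicc_v <- r2_v <- adj_v <- rep(NA_real_, nm)
  keep <- logical(nm)
  for (m in seq_len(nm)) {
    units <- subsets[[m]]
    idx <- c(1L, unlist(colidx[units], use.names = FALSE))
    k <- length(idx) - 1L
    p <- k + 2L
    if (n - p - 1 < 1) next  # saturated under AICc
    R <- tryCatch(chol(XtX[idx, idx, drop = FALSE]), error = function(e) NULL)
    if (is.null(R)) next     # singular submodel
    b <- backsolve(R, forwardsolve(t(R), Xty[idx]))
    rss <- max(yty - sum(b * Xty[idx]), 0, floor_rss)
    r2 <- if (tss > 0) 1 - rss / tss else 0
    ll <- -n / 2 * (log(2 * pi * rss / n) + 1)
    keep[m] <- TRUE
    k_v[m] <- k
    ll_v[m] <- ll
    aicc_v[m] <- -2 * ll + 2 * p + 2 * p * (p + 1) / (n - p - 1)
    r2_v[m] <- r2
    adj_v[m] <- if (tss > 0) 1 - (1 - r2) * (n - 1) / (n - k - 1) else 0
  }
  labels <- vapply(subsets, function(u) {
    if (length(u)) paste(terms$label[u], collapse = " + ") else "1"
  }, character(1))
  tibble::tibble(
    units = subsets, label = labels, k = as.integer(k_v),
    loglik = ll_v, aicc = aicc_v, r2 = r2_v, adj_r2 = adj_v
  )[keep, ]
}

rank_models <- function(tab) {
  tab |>
    dplyr::arrange(.data$aicc, dplyr::desc(.data$adj_r2), .data$k,
                   .data$label) |>
    dplyr::mutate(delta_aicc = .data$aicc - min(.data$aicc))
}

# --- two-stage selection ----------------------------------------------------

#' Two-stage exhaustive syndrome model selection
#'
#' Implements the trait-syndrome detection procedure for one dispersal
#' element. A curvature pre-screen flags, per non-binary candidate trait,
#' whether it may enter as a second-degree polynomial; flagged traits
#' contribute a squared unit on top of their linear one (the squared unit
#' can only appear alongside its linear part), so the exhaustive search
#' itself decides whether the curvature survives in the retained model.
#' Stage one searches all main-effect sub-models up to `max_coef` slope
#' coefficients and ranks them by AICc. Stage two pools the variables
#' appearing in any stage-one model within `delta` AICc points of the best,
#' adds all first-order interactions among them, and searches again under
#' the same cap. The model finally retained is the one with the highest
#' R-squared among stage-two models within `delta` of the best AICc — the
#' candidate that captures most of the deviance, hence predicts best.
#'
#' @param data Analysis table from [syndrome_data()]: `response` plus one
#'   column per candidate trait, complete cases.
#' @param candidates Candidate predictor columns (default: all columns
#'   except `species_id` and the response).
#' @param response Name of the response column.
#' @param max_coef Cap on slope coefficients per model (default 8).
#' @param delta AICc window defining the top set (default 2).
#' @param screen_alpha p-value threshold of the curvature screen.
#' @return A `syndrome_selection` object: stage-wise AICc tables, top
#'   sets, the chosen `dispersal_fit`, per-term stability frequencies and
#'   the screen decisions.
#' @export
select_dispersal_model <- function(data, candidates = NULL,
                                   response = "response", max_coef = 8,
                                   delta = 2, screen_alpha = 0.1) {
  data <- tibble::as_tibble(data)
  if (is.null(candidates)) {
    candidates <- setdiff(names(data), c("species_id", response))
  }
  if (!length(candidates)) stop("no candidate traits", call. = FALSE)
  data <- data[stats::complete.cases(data[c(response, candidates)]), ]
  n <- nrow(data)
  if (n < 4) stop("too few complete cases for model selection", call. = FALSE)

  # curvature pre-screen (non-binary candidates only)
  forms <- purrr::map_chr(candidates, function(tr) {
    v <- data[[tr]]
    if (length(unique(v)) <= 2) return("linear")
    if (n < 5) return("linear")
    screen_quadratic(data[[response]], v, alpha = screen_alpha)$form
  })
  names(forms) <- candidates

  # every candidate contributes a linear unit; screened traits additionally
  # contribute a squared unit that can only enter alongside the linear one,
  # so the search itself decides whether the curvature survives
  stage1_terms <- dplyr::bind_rows(
    model_terms(linear = candidates),
    purrr::map_dfr(candidates[forms == "quadratic"], square_term)
  )

  stage1 <- rank_models(fit_all_subsets(stage1_terms, data, response, max_coef))
  stage1_top <- dplyr::filter(stage1, .data$delta_aicc <= delta)
  pool <- unique(unlist(lapply(stage1_top$units, function(u) {
    term_variables(stage1_terms[u, ])
  })))

  if (length(pool) == 0) {
    stage2_terms <- stage1_terms[0, ]
  } else {
    pairs <- if (length(pool) >= 2) utils::combn(sort(pool), 2, simplify = FALSE)
             else list()
    stage2_terms <- dplyr::bind_rows(
      model_terms(linear = pool, interactions = pairs),
      purrr::map_dfr(pool[forms[pool] == "quadratic"], square_term)
    )
  }
  stage2 <- rank_models(fit_all_subsets(stage2_terms, data, response, max_coef))
  stage2_top <- dplyr::filter(stage2, .data$delta_aicc <= delta)

  # highest R2 within the top set; deterministic tie-breaks
  chosen_row <- stage2_top |>
    dplyr::arrange(dplyr::desc(.data$r2), dplyr::desc(.data$adj_r2),
                   .data$k, .data$label) |>
    dplyr::slice(1)
  chosen_units <- stage2_terms[chosen_row$units[[1]], ]
  chosen_terms <- collapse_square_units(chosen_units)
  chosen <- fit_dispersal_glm(data, chosen_terms, response = response)

  stability <- term_stability_tab(stage2_terms, stage2_top)

  structure(
    list(stage1_terms = stage1_terms, stage1 = stage1, stage1_top = stage1_top,
         stage2_terms = stage2_terms, stage2 = stage2, stage2_top = stage2_top,
         chosen = chosen, stability = stability, forms = forms,
         data = data, response = response, candidates = candidates,
         max_coef = max_coef, delta = delta, n = n),
    class = "syndrome_selection"
  )
}

# Report a retained (linear, square) pair as a single quadratic unit.
collapse_square_units <- function(units) {
  sq <- units$trait1[units$kind == "square"]
  lin <- units$trait1[units$kind == "linear"]
  ints <- units[units$kind == "interaction", ]
  model_terms(
    linear = setdiff(lin, sq),
    quadratic = intersect(sq, lin),
    interactions = purrr::map2(ints$trait1, ints$trait2, c)
  )
}

term_stability_tab <- function(terms, top) {
  if (!nrow(terms)) {
    return(tibble::tibble(label = character(), frequency = numeric()))
  }
  counts <- vapply(seq_len(nrow(terms)), function(i) {
    mean(vapply(top$units, function(u) i %in% u, logical(1)))
  }, numeric(1))
  tibble::tibble(label = terms$label, frequency = counts)
}

#' Term stability across the top model set
#'
#' For each candidate term, the fraction of stage-two models within the
#' AICc window that contain it — a check that the terms retained for
#' prediction are also present in the alternative models of similar fit.
#'
#' @param selection A `syndrome_selection` object.
#' @return A tibble with columns `label` and `frequency` in \[0, 1\].
#' @export
term_stability <- function(selection) {
  stopifnot(inherits(selection, "syndrome_selection"))
  selection$stability
}

#' @export
print.syndrome_selection <- function(x, ...) {
  cat("Two-stage syndrome model selection (n = ", x$n, ", cap = ",
      x$max_coef, " coefficients, window = ", x$delta, " AICc)\n", sep = "")
  cat("stage 1: ", nrow(x$stage1), " models, top set ", nrow(x$stage1_top),
      "\n", sep = "")
  cat("stage 2: ", nrow(x$stage2), " models, top set ", nrow(x$stage2_top),
      "\n", sep = "")
  cat("chosen: ")
  print(x$chosen)
  invisible(x)
}
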