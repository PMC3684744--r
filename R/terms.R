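#' Build a model term set
#'
#' A term set lists the units a dispersal model is built from. Three kinds
#' of unit exist: `linear` (one coefficient), `quadratic` (a second-degree
#' polynomial in one trait: centered linear + centered squared term, two
#' coefficients, kept together as one unit) and `interaction` (the product
#' of two traits, one coefficient). Marginality is built in: a quadratic
#' unit always carries its linear part, and interactions are only valid in
#' models that also contain both main effects.
#'
#' @param linear Character vector of trait names entering linearly.
#' @param quadratic Character vector of trait names entering as
#'   second-degree polynomials.
#' @param interactions List of length-2 character vectors (or a character
#'   vector of `"a:b"` labels) naming interacting trait pairs.
#' @return A tibble with columns `kind`, `trait1`, `trait2`, `ncoef`,
#'   `label`.
#' @examples
#' model_terms(linear = c("voltinism"), quadratic = "ovigeny_index",
#'             interactions = list(c("voltinism", "ovigeny_index")))
#' @export
model_terms <- function(linear = character(), quadratic = character(),
                        interactions = list()) {
  if (is.character(interactions)) {
    interactions <- strsplit(interactions, ":", fixed = TRUE)
  }
  rows <- list()
  for (tr in linear) {
    rows[[length(rows) + 1]] <- tibble::tibble(
      kind = "linear", trait1 = tr, trait2 = NA_character_,
      ncoef = 1L, label = tr)
  }
  for (tr in quadratic) {
    rows[[length(rows) + 1]] <- tibble::tibble(
      kind = "quadratic", trait1 = tr, trait2 = NA_character_,
      ncoef = 2L, label = paste0("poly(", tr, ",2)"))
  }
  for (pr in interactions) {
    pr <- sort(as.character(pr))
    if (length(pr) != 2 || pr[1] == pr[2]) {
      stop("interactions must name two distinct traits", call. = FALSE)
    }
    rows[[length(rows) + 1]] <- tibble::tibble(
      kind = "interaction", trait1 = pr[1], trait2 = pr[2],
      ncoef = 1L, label = paste0(pr[1], ":", pr[2]))
  }
  out <- if (length(rows)) dplyr::bind_rows(rows) else tibble::tibble(
    kind = character(), trait1 = character(), trait2 = character(),
    ncoef = integer(), label = character())
  if (anyDuplicated(out$label)) stop("duplicate terms", call. = FALSE)
  out
}

term_variables <- function(terms) {
  unique(stats::na.omit(c(terms$trait1, terms$trait2)))
}

# Internal term kind used during selection: the squared half of a screened
# polynomial as a separate one-coefficient unit, valid only alongside its
# linear main effect. The search itself then decides whether the curvature
# survives; a retained (linear, square) pair is reported as one quadratic
# polynomial unit.
square_term <- function(trait) {
  tibble::tibble(kind = "square", trait1 = trait, trait2 = NA_character_,
                 ncoef = 1L, label = paste0("I(", trait, "^2)"))
}

# Design matrix (no intercept column) for a term set. Quadratic units use
# centered powers; `centers` carries the training means so predictions for
# new species reuse the same parameterization.
build_design <- function(terms, data, centers = NULL) {
  vars <- term_variables(terms)
  miss <- setdiff(vars, names(data))
  if (length(miss)) {
    stop("data lacks trait column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  if (is.null(centers)) {
    centers <- vapply(vars, function(v) mean(data[[v]]), numeric(1))
  }
  cols <- list()
  unit_cols <- vector("list", nrow(terms))
  for (i in seq_len(nrow(terms))) {
    kind <- terms$kind[i]
    if (kind == "linear") {
      cols[[terms$label[i]]] <- data[[terms$trait1[i]]]
      unit_cols[[i]] <- terms$label[i]
    } else if (kind == "quadratic") {
      xc <- data[[terms$trait1[i]]] - centers[[terms$trait1[i]]]
      nm <- c(paste0(terms$trait1[i], ".c"), paste0(terms$trait1[i], ".c2"))
      cols[[nm[1]]] <- xc
      cols[[nm[2]]] <- xc^2
      unit_cols[[i]] <- nm
    } else if (kind == "square") {
      xc <- data[[terms$trait1[i]]] - centers[[terms$trait1[i]]]
      nm <- terms$label[i]
      cols[[nm]] <- xc^2
      unit_cols[[i]] <- nm
    } else {
      nm <- terms$label[i]
      cols[[nm]] <- data[[terms$trait1[i]]] * data[[terms$trait2[i]]]
      unit_cols[[i]] <- nm
    }
  }
  X <- if (length(cols)) do.call(cbind, cols) else
    matrix(numeric(0), nrow = nrow(data), ncol = 0)
  list(X = X, unit_cols = unit_cols, centers = centers)
}

#' Predictor table for syndrome models
#'
#' Prepares a trait table for model building: wing length is replaced by
#' its natural logarithm (`log_wing_length`), since size relationships are
#' allometric, and all other traits are passed through on their coded
#' scales.
#'
#' @param traits A validated trait table.
#' @return A tibble with `species_id`, the 17 life-history traits and
#'   `log_wing_length`.
#' @export
prepare_predictors <- function(traits) {
  traits <- validate_trait_table(traits)
  traits |>
    dplyr::mutate(log_wing_length = log(.data$wing_length)) |>
    dplyr::select(-"wing_length")
}

#' Assemble an analysis table for one dispersal element
#'
#' Joins the transformed dispersal values of one element to the predictor
#' table and keeps complete cases over the named candidate traits, giving
#' the species-by-variables table a syndrome model is selected on.
#'
#' @param traits A trait table (see [validate_trait_table()]).
#' @param dispersal A `dispersal_data` tibble.
#' @param element One of [dispersal_elements()].
#' @param candidates Candidate predictor columns to keep (default: all 17
#'   life-history traits plus `log_wing_length`).
#' @return A tibble with `species_id`, `response` (the transformed
#'   dispersal value) and one column per candidate.
#' @export
syndrome_data <- function(traits, dispersal, element, candidates = NULL) {
  check_element(element)
  preds <- prepare_predictors(traits)
  if (is.null(candidates)) candidates <- setdiff(names(preds), "species_id")
  obs <- tibble::as_tibble(dispersal) |>
    dplyr::filter(.data$element == !!element) |>
    dplyr::select("species_id", response = "transformed_value")
  out <- dplyr::inner_join(obs, preds[c("species_id", candidates)],
                           by = "species_id")
  out[stats::complete.cases(out[c("response", candidates)]), ]
}
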