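#' The four dispersal elements
#'
#' Names of the four dispersal measurements handled by the package:
#' `mean_distance` (mean dispersal distance, km, from a negative-exponential
#' movement kernel), `ldd_frequency` (probability of movements beyond 5 km,
#' from an inverse-power kernel), `propensity` (probability of leaving the
#' natal patch, from mark-release-recapture residency) and `gene_flow`
#' (derived from among-population F_ST).
#'
#' @return Character vector of the four element names.
#' @export
dispersal_elements <- function() {
  c("mean_distance", "ldd_frequency", "propensity", "gene_flow")
}

check_element <- function(element) {
  if (length(element) != 1 || !element %in% dispersal_elements()) {
    stop("`element` must be one of: ",
         paste(dispersal_elements(), collapse = ", "), call. = FALSE)
  }
  element
}

#' Normalizing transforms for the dispersal elements
#'
#' Each dispersal element is analysed on a transformed scale on which its
#' distribution across species is approximately normal:
#' \describe{
#'   \item{mean_distance}{`ln(x)` for x in km, x > 0.}
#'   \item{ldd_frequency}{`log10(x)` for x a probability in (0, 1].}
#'   \item{propensity}{`-sqrt(x)` for x a fraction in \[0, 1\].}
#'   \item{gene_flow}{`1 - sqrt(F_ST)` (default), an index that increases
#'     with gene flow; the alternative convention `sqrt_complement` applies
#'     the square-root transform to 1 - F_ST instead, giving
#'     `1 - sqrt(1 - F_ST)`.}
#' }
#'
#' `dispersal_back_transform()` inverts the transform exactly on its valid
#' domain. With `truncate = TRUE`, out-of-domain transformed values are
#' moved to the nearest domain boundary before inversion (the truncation
#' used when model predictions are mapped back to natural scale):
#' long-distance dispersal frequency is clipped to (0, 1], propensity and
#' gene flow to \[0, 1\]; mean distance needs no truncation.
#'
#' @param element One of [dispersal_elements()].
#' @param x Raw values on the natural scale.
#' @param xt Values on the transformed scale.
#' @param gene_flow_convention `"one_minus_sqrt_fst"` (default) or
#'   `"sqrt_complement"`; see Details.
#' @param truncate Logical; clip transformed values into the valid domain
#'   before back-transforming instead of erroring.
#' @return Numeric vector of transformed (or back-transformed) values.
#' @examples
#' dispersal_transform("mean_distance", 1)    # 0
#' dispersal_transform("propensity", 0.25)    # -0.5
#' dispersal_transform("gene_flow", 0.04)     # 0.8
#' dispersal_back_transform("propensity", -0.5)
#' @export
dispersal_transform <- function(element, x,
                                gene_flow_convention = c("one_minus_sqrt_fst",
                                                         "sqrt_complement")) {
  check_element(element)
  gene_flow_convention <- match.arg(gene_flow_convention)
  bad <- !is.na(x) & !element_in_domain(element, x)
  if (any(bad)) {
    stop("value out of domain for element '", element, "': ",
         paste(utils::head(x[bad], 3), collapse = ", "), call. = FALSE)
  }
  switch(element,
    mean_distance = log(x),
    ldd_frequency = log10(x),
    propensity    = -sqrt(x),
    gene_flow     = if (gene_flow_convention == "one_minus_sqrt_fst") {
      1 - sqrt(x)
    } else {
      1 - sqrt(1 - x)
    }
  )
}

#' @rdname dispersal_transform
#' @export
dispersal_back_transform <- function(element, xt,
                                     gene_flow_convention = c("one_minus_sqrt_fst",
                                                              "sqrt_complement"),
                                     truncate = FALSE) {
  check_element(element)
  gene_flow_convention <- match.arg(gene_flow_convention)
  dom <- transformed_domain(element)
  out_of_dom <- !is.na(xt) & (xt < dom[1] | xt > dom[2])
  if (any(out_of_dom)) {
    if (!truncate) {
      stop("transformed value outside the valid domain for '", element,
           "' (use truncate = TRUE to clip)", call. = FALSE)
    }
    xt <- pmin(pmax(xt, dom[1]), dom[2])
  }
  switch(element,
    mean_distance = exp(xt),
    ldd_frequency = 10^xt,
    propensity    = xt^2,
    gene_flow     = if (gene_flow_convention == "one_minus_sqrt_fst") {
      (1 - xt)^2
    } else {
      1 - (1 - xt)^2
    }
  )
}

# Natural-scale domain of each element. Zero mean distance or LDD frequency
# has no finite transform, hence the open lower bounds.
element_in_domain <- function(element, x) {
  switch(element,
    mean_distance = x > 0,
    ldd_frequency = x > 0 & x <= 1,
    propensity    = x >= 0 & x <= 1,
    gene_flow     = x >= 0 & x <= 1
  )
}

# Domain of the transformed scale (used to truncate model predictions).
transformed_domain <- function(element) {
  switch(element,
    mean_distance = c(-Inf, Inf),
    ldd_frequency = c(-Inf, 0),
    propensity    = c(-1, 0),
    gene_flow     = c(0, 1)
  )
}
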