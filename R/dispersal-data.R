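#' Build a dispersal dataset from per-species measurements
#'
#' A dispersal dataset is a long-format tibble holding, per species and
#' dispersal element, the raw measurement and its value on the normalized
#' analysis scale (see [dispersal_transform()]). One observation per
#' (species, element) pair is enforced.
#'
#' @param data A data frame with columns `species_id`, `element` and
#'   `raw_value`.
#' @param gene_flow_convention Passed to [dispersal_transform()].
#' @return A tibble with columns `species_id`, `element`, `raw_value`,
#'   `transformed_value`, of class `dispersal_data`.
#' @examples
#' dispersal_data(data.frame(
#'   species_id = c("sp1", "sp2"),
#'   element = "propensity",
#'   raw_value = c(0.25, 0.04)
#' ))
#' @export
dispersal_data <- function(data,
                           gene_flow_convention = c("one_minus_sqrt_fst",
                                                    "sqrt_complement")) {
  gene_flow_convention <- match.arg(gene_flow_convention)
  data <- tibble::as_tibble(data)
  need <- c("species_id", "element", "raw_value")
  if (!all(need %in% names(data))) {
    stop("dispersal data needs columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  unknown <- setdiff(unique(data$element), dispersal_elements())
  if (length(unknown)) {
    stop("unknown dispersal element(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  dup <- duplicated(data[c("species_id", "element")])
  if (any(dup)) {
    stop("duplicate (species_id, element) pairs: ",
         paste(unique(data$species_id[dup]), collapse = ", "), call. = FALSE)
  }
  out <- data |>
    dplyr::mutate(
      transformed_value = purrr::map2_dbl(
        .data$element, .data$raw_value,
        function(e, x) dispersal_transform(e, x, gene_flow_convention)
      )
    ) |>
    dplyr::arrange(.data$element, .data$species_id)
  structure(out, class = c("dispersal_data", class(out)),
            gene_flow_convention = gene_flow_convention)
}

#' Read a long-format dispersal CSV
#'
#' Expects columns `species_id`, `element` (one of
#' [dispersal_elements()]) and `raw_value`. Transformed analysis values are
#' computed on read.
#'
#' @inheritParams dispersal_data
#' @param path Path to a CSV file.
#' @return A `dispersal_data` tibble.
#' @export
read_dispersal_table <- function(path,
                                 gene_flow_convention = c("one_minus_sqrt_fst",
                                                          "sqrt_complement")) {
  raw <- readr::read_csv(path, col_types = readr::cols(
    species_id = readr::col_character(),
    element = readr::col_character(),
    raw_value = readr::col_double()
  ))
  dispersal_data(raw, gene_flow_convention = match.arg(gene_flow_convention))
}

#' Per-element species counts
#'
#' @param data A `dispersal_data` tibble.
#' @return A tibble with columns `element` and `n`.
#' @export
element_counts <- function(data) {
  dplyr::count(tibble::as_tibble(data), .data$element, name = "n")
}
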