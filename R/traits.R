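#' Definitions of the 18 candidate species traits
#'
#' The trait set used to detect dispersal syndromes: 17 life-history traits
#' describing demography, ecological specialization and behaviour, plus wing
#' length as a size trait. Ordinal scores are coded as integers and treated
#' as numeric throughout; binary traits are 0/1.
#'
#' @return A tibble with one row per trait: `trait` (column name used in
#'   trait tables), `type` (`"continuous"`, `"ordinal"` or `"binary"`),
#'   `min`, `max` (valid range on the coded scale) and `unit`.
#' @examples
#' trait_definitions()
#' @export
trait_definitions <- function() {
  tibble::tribble(
    ~trait,                   ~type,        ~min, ~max,  ~unit,
    "fecundity",              "ordinal",     1,    9,    "score",
    "adult_lifetime",         "continuous",  5,    60,   "days",
    "voltinism",              "continuous",  0.5,  3,    "generations/yr",
    "larval_growth_rate",     "continuous",  16,   186,  "days feeding",
    "ripe_egg_load",          "ordinal",     1,    9,    "score",
    "ovigeny_index",          "continuous",  0,    1,    "fraction",
    "female_maturation",      "ordinal",     1,    8,    "level",
    "overwintering_stage",    "ordinal",     0,    7,    "stage code",
    "life_cycle_flexibility", "binary",      0,    1,    "0/1",
    "flight_period",          "continuous",  3,    32,   "weeks",
    "thermal_tolerance",      "ordinal",     1,    9,    "level",
    "adult_habitat_range",    "ordinal",     1,    7,    "ecosystem count",
    "larval_dietary_breadth", "ordinal",     1,    4,    "level",
    "myrmecophily",           "ordinal",     0,    9,    "level",
    "female_precision",       "ordinal",     1,    9,    "level",
    "laying_strategy",        "binary",      0,    1,    "0/1",
    "mate_location",          "ordinal",     1,    7,    "level",
    "wing_length",            "continuous",  11,   37.5, "mm"
  )
}

trait_names <- function() trait_definitions()$trait

#' Validate a species-by-trait table
#'
#' Checks that every trait value lies within its defined range (see
#' [trait_definitions()]), that ordinal and binary traits take whole-number
#' codes, and that species identifiers are unique. Missing values (`NA`) are
#' allowed and simply flagged; species with incomplete traits are retained
#' and dropped later on a per-analysis basis (complete-case filtering).
#'
#' @param traits A data frame with a `species_id` column and the 18 trait
#'   columns of [trait_definitions()].
#' @return The input as a tibble, invisibly validated; attribute
#'   `"missing_mask"` holds a logical species-by-trait matrix of missing
#'   cells.
#' @export
validate_trait_table <- function(traits) {
  traits <- tibble::as_tibble(traits)
  if (!"species_id" %in% names(traits)) {
    stop("trait table must have a `species_id` column", call. = FALSE)
  }
  if (anyDuplicated(traits$species_id)) {
    stop("duplicated species_id in trait table", call. = FALSE)
  }
  defs <- trait_definitions()
  missing_traits <- setdiff(defs$trait, names(traits))
  if (length(missing_traits)) {
    stop("trait table lacks columns: ",
         paste(missing_traits, collapse = ", "), call. = FALSE)
  }
  for (i in seq_len(nrow(defs))) {
    tr <- defs$trait[i]
    v <- traits[[tr]]
    if (!is.numeric(v)) {
      stop("trait column '", tr, "' is not numeric", call. = FALSE)
    }
    bad <- !is.na(v) & (v < defs$min[i] | v > defs$max[i])
    if (defs$type[i] %in% c("ordinal", "binary")) {
      bad <- bad | (!is.na(v) & v != round(v))
    }
    if (any(bad)) {
      stop("out-of-range value for trait '", tr, "' in species ",
           paste(traits$species_id[bad], collapse = ", "),
           " (valid: ", defs$min[i], "-", defs$max[i], ")", call. = FALSE)
    }
  }
  mask <- is.na(as.matrix(traits[defs$trait]))
  rownames(mask) <- traits$species_id
  attr(traits, "missing_mask") <- mask
  traits
}

#' Read or write a species-by-trait CSV table
#'
#' The CSV has one row per species, a `species_id` column and the 18 trait
#' columns named as in [trait_definitions()]; empty cells are missing
#' values. Unknown extra columns are dropped with a warning. Values are
#' validated against the trait ranges on read.
#'
#' @param path Path to a CSV file.
#' @param traits A validated trait table (see [validate_trait_table()]).
#' @return `read_trait_table()` returns a validated tibble;
#'   `write_trait_table()` returns `path` invisibly.
#' @export
read_trait_table <- function(path) {
  raw <- readr::read_csv(path, col_types = readr::cols(
    species_id = readr::col_character(),
    .default = readr::col_double()
  ), na = c("", "NA"))
  known <- c("species_id", trait_names())
  extra <- setdiff(names(raw), known)
  if (length(extra)) {
    warning("ignoring unknown columns: ", paste(extra, collapse = ", "),
            call. = FALSE)
    raw <- raw[intersect(names(raw), known)]
  }
  validate_trait_table(raw)
}

#' @rdname read_trait_table
#' @export
write_trait_table <- function(traits, path) {
  traits <- validate_trait_table(traits)
  readr::write_csv(traits[c("species_id", trait_names())], path)
  invisible(path)
}
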