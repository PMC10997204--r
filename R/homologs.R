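#' Target PFAA homologs
#'
#' The default set of perfluoroalkyl acids (PFAAs) tracked by the package:
#' seven perfluoroalkyl carboxylic acids (PFCAs) and three perfluoroalkane
#' sulfonic acids (PFSAs), with perfluorooctane sulfonic acid (PFOS) carried
#' as separate linear and branched homologs through enrichment-factor (EF)
#' estimation. The `species` column groups isomers that are summed downstream
#' (linear + branched PFOS make up species `"PFOS"`).
#'
#' @return A tibble with columns `homolog`, `family` (`"PFCA"` or `"PFSA"`),
#'   `chain_length` (number of perfluorinated carbons), `isomer`
#'   (`"linear"`, `"branched"` or `"sum"`) and `species`.
#' @examples
#' pfaa_homologs()
#' @export
pfaa_homologs <- function() {
  out <- tibble::tribble(
    ~homolog,  ~family, ~chain_length, ~isomer,    ~species,
    "PFHxA",   "PFCA",  5L,            "sum",      "PFHxA",
    "PFHpA",   "PFCA",  6L,            "sum",      "PFHpA",
    "PFOA",    "PFCA",  7L,            "sum",      "PFOA",
    "PFNA",    "PFCA",  8L,            "sum",      "PFNA",
    "PFDA",    "PFCA",  9L,            "sum",      "PFDA",
    "PFUnDA",  "PFCA",  10L,           "sum",      "PFUnDA",
    "PFDoDA",  "PFCA",  11L,           "sum",      "PFDoDA",
    "PFBS",    "PFSA",  4L,            "sum",      "PFBS",
    "PFHxS",   "PFSA",  6L,            "sum",      "PFHxS",
    "L-PFOS",  "PFSA",  8L,            "linear",   "PFOS",
    "B-PFOS",  "PFSA",  8L,            "branched", "PFOS"
  )
  stopifnot(!anyDuplicated(out$homolog), all(out$chain_length >= 3L))
  out
}

#' Impactor size-fraction scheme
#'
#' Builds the pooling of 14 cascade-impactor stages into 8 SSA size
#' fractions. Stage cutoffs are aerodynamic d50 diameters; stages 1-6 are
#' pooled into fraction 1 and stages 7-8 into fraction 2, with the remaining
#' stages kept individually. A fraction spans from the d50 of its lowest
#' stage to the d50 of the next stage above it; the topmost fraction is
#' bounded by the impactor inlet diameter. For integration against the SSA
#' source function the outermost bounds are extended to 0 and +Inf
#' (`lower_int_um`, `upper_int_um`), while the representative diameter `dp_um`
#' of a fraction is the geometric mean of its bounding diameters.
#'
#' @param cutoffs_um Strictly increasing d50 cutoffs of the impactor stages
#'   in micrometres (length 14 by default).
#' @param pool List of integer vectors of stage indices pooled into each
#'   fraction, in increasing diameter order.
#' @param inlet_um Upper collection bound of the top stage in micrometres.
#' @return A tibble with one row per fraction: `fraction`, `stages`
#'   (list-column), `lower_um`, `upper_um`, `lower_int_um`, `upper_int_um`,
#'   `dp_um`.
#' @examples
#' size_fraction_scheme()
#' @export
size_fraction_scheme <- function(cutoffs_um = c(0.015, 0.030, 0.055, 0.094,
                                                0.155, 0.255, 0.380, 0.600,
                                                0.94, 1.60, 2.50, 3.60,
                                                5.30, 9.91),
                                 pool = c(list(1:6, 7:8),
                                          as.list(9:length(cutoffs_um))),
                                 inlet_um = 15) {
  if (any(diff(cutoffs_um) <= 0)) {
    abort("impactor stage cutoffs must be strictly increasing")
  }
  stages <- sort(unlist(pool))
  if (!identical(stages, seq_along(cutoffs_um))) {
    abort("pooling map must use every stage exactly once")
  }
  if (inlet_um <= cutoffs_um[length(cutoffs_um)]) {
    abort("inlet diameter must exceed the top stage cutoff")
  }
  upper_of_stage <- c(cutoffs_um[-1], inlet_um)
  out <- purrr::map_dfr(seq_along(pool), function(f) {
    st <- pool[[f]]
    tibble(
      fraction = f,
      stages = list(st),
      lower_um = cutoffs_um[min(st)],
      upper_um = upper_of_stage[max(st)]
    )
  })
  out %>%
    mutate(
      lower_int_um = ifelse(.data$fraction == 1L, 0, .data$lower_um),
      upper_int_um = ifelse(.data$fraction == dplyr::n(), Inf, .data$upper_um),
      dp_um = sqrt(.data$lower_um * .data$upper_um)
    )
}
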