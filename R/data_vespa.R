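#' Published microsatellite allele frequencies for *Vespa soror*
#'
#' The population allele frequencies of the eight microsatellite loci used to
#' genotype colony members of the southern giant hornet *Vespa soror* (353
#' females across three colonies, drifted workers excluded, nests pooled into
#' a single population). Seven loci are polymorphic; VMA-4 is monomorphic.
#'
#' Published summaries report allele frequencies only, not fragment lengths,
#' so the allele labels here are synthetic stable integers (base-pair-like,
#' spaced by the dinucleotide repeat unit) assigned in decreasing order of
#' frequency. All frequency-based computations are label-invariant.
#'
#' @return a [locus_panel()] with 8 loci.
#' @examples
#' panel <- vespa_soror_panel()
#' expected_heterozygosity(panel$frequencies[["VMA-3"]])
#' @export
vespa_soror_panel <- function() {
  raw <- list(
    `VMA-3`    = c(0.399, 0.340, 0.163, 0.098),
    `VMA-4`    = c(1.00),
    `VMA-6`    = c(0.579, 0.421),
    `VMA-7`    = c(0.542, 0.156, 0.153, 0.149),
    `VMA-8`    = c(0.252, 0.222, 0.137, 0.109, 0.089, 0.072, 0.067, 0.026,
                   0.026),
    LIST2003   = c(0.541, 0.433, 0.026),
    LIST2010   = c(0.433, 0.232, 0.211, 0.098, 0.013, 0.013),
    LIST2020   = c(0.646, 0.205, 0.082, 0.067)
  )
  freqs <- lapply(raw, function(f) {
    names(f) <- as.character(seq(100L, by = 2L, length.out = length(f)))
    f
  })
  locus_panel(freqs)
}

#' Comb census tables for two mature *Vespa soror* nests
#'
#' Per-comb measurements from the two excavated nests: comb position (1 =
#' oldest, top), longest and shortest axis in cm, counts of completed cells,
#' large (gyne-sized) cells, sealed pupal cells, and large sealed cells.
#'
#' @param nest `"N1"` (collected late September) or `"N2"` (early November).
#' @return a `nest_census` object (see [nest_census()]).
#' @seealso [census_summary()], [comb_area()]
#' @export
vespa_soror_combs <- function(nest = c("N1", "N2")) {
  nest <- match.arg(nest)
  combs <- if (nest == "N1") {
    data.frame(
      comb = 1:5,
      length_cm = c(38.0, 40.0, 39.5, 37.0, 20.0),
      width_cm = c(27.5, 32.5, 32.5, 31.5, 14.0),
      cells = c(483L, 1027L, 750L, 706L, 151L),
      large_cells = c(0L, 0L, 5L, 0L, 0L),
      pupae = c(68L, 199L, 180L, 144L, 2L),
      large_pupae = c(0L, 0L, 5L, 0L, 0L)
    )
  } else {
    data.frame(
      comb = 1:5,
      length_cm = c(55.8, 48.5, 39.7, 33.2, 13.3),
      width_cm = c(42.4, 36.0, 28.5, 27.6, 11.0),
      cells = c(1375L, 1376L, 744L, 554L, 122L),
      large_cells = c(168L, 201L, 231L, 0L, 0L),
      pupae = c(413L, 484L, 183L, 41L, 0L),
      large_pupae = c(105L, 143L, 96L, 0L, 0L)
    )
  }
  nest_census(combs, nest = nest)
}
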