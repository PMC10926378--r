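#' Expected heterozygosity from allele frequencies
#'
#' Gene diversity `He = 1 - sum(p^2)`. No small-sample correction is applied:
#' the plain estimator reproduces published per-locus values computed from
#' pooled colony samples.
#'
#' @param frequencies numeric vector of allele frequencies summing to 1
#'   (within `1e-6`).
#' @return `He` in `[0, 1)`.
#' @examples
#' expected_heterozygosity(c(0.5, 0.5)) # 0.5
#' @export
expected_heterozygosity <- function(frequencies) {
  if (any(frequencies < 0)) stop("allele frequencies must be nonnegative")
  if (abs(sum(frequencies) - 1) > 1e-6) {
    stop("allele frequencies sum to ", format(sum(frequencies)), ", not 1")
  }
  1 - sum(frequencies^2)
}

#' Observed heterozygosity at a locus
#'
#' Fraction of scored diploid (female) individuals carrying two distinct
#' alleles at the locus. Haploid males are ignored.
#'
#' @param dataset a [colony_dataset()].
#' @param locus locus name.
#' @param exclude individual ids to leave out (e.g. drifters).
#' @return proportion in `[0, 1]`.
#' @export
observed_heterozygosity <- function(dataset, locus, exclude = character()) {
  g <- genotypes_at(dataset, locus, sex = "female")
  g <- g[!rownames(g) %in% exclude, , drop = FALSE]
  g <- g[stats::complete.cases(g), , drop = FALSE]
  if (nrow(g) == 0) stop("no scored diploid individuals at locus ", locus)
  mean(g[, 1] != g[, 2])
}

#' Allele frequencies observed in a dataset
#'
#' Counts allele copies per locus (two per female, optionally one per male)
#' and returns them as a [locus_panel()]. Following standard practice for
#' colony samples, haploid males are excluded by default: sampled offspring
#' of a few queens dominate such datasets and the published summaries are
#' reproducible from female allele copies.
#'
#' @param dataset a [colony_dataset()].
#' @param exclude individual ids (e.g. drifters) to leave out of the counts.
#' @param include_males if `TRUE`, male allele copies (one each) enter the
#'   counts.
#' @return a [locus_panel()] whose frequencies are the observed proportions.
#' @export
allele_frequencies <- function(dataset, exclude = character(),
                               include_males = FALSE) {
  stopifnot(inherits(dataset, "colony_dataset"))
  r <- dataset$records[!dataset$records$id %in% exclude, ]
  if (!include_males) r <- r[r$sex == "female", ]
  if (nrow(r) == 0) stop("no individuals left after exclusion")
  sub <- colony_dataset(r, panel = dataset$panel)
  freqs <- lapply(dataset$loci, function(l) {
    g <- genotypes_at(sub, l)
    a <- c(g[, 1], g[, 2])
    a <- a[!is.na(a)]
    if (length(a) == 0) stop("no alleles observed at locus ", l)
    tab <- table(a)
    f <- as.numeric(tab) / sum(tab)
    names(f) <- names(tab)
    f
  })
  names(freqs) <- dataset$loci
  locus_panel(freqs)
}

#' Per-locus diversity summary
#'
#' One row per locus with allele counts for colony members (drifters
#' excluded) and for the whole sample, the member allele frequencies in
#' descending order, and expected/observed heterozygosity. Means of `He` and
#' of allele number are reported over polymorphic loci only (a monomorphic
#' locus carries no information about colony structure and published means
#' are computed this way).
#'
#' @param dataset a [colony_dataset()].
#' @param drifters ids of drifted individuals to exclude from member counts
#'   (may be empty).
#' @param include_males passed to [allele_frequencies()].
#' @return object of class `panel_summary`: a list with `table` (data frame:
#'   `locus`, `n_alleles_members`, `n_alleles_with_drifters`, `He`, `Ho`,
#'   `polymorphic`), `frequencies` (list of descending-sorted numeric
#'   vectors), `mean_He` and `mean_n_alleles` (over polymorphic loci; `NA`
#'   with a flag if there are none).
#' @export
panel_summary <- function(dataset, drifters = character(),
                          include_males = FALSE) {
  members <- allele_frequencies(dataset, exclude = drifters,
                                include_males = include_males)
  everyone <- allele_frequencies(dataset, include_males = include_males)
  loci <- dataset$loci
  n_mem <- vapply(members$alleles[loci], length, 1L)
  n_all <- vapply(everyone$alleles[loci], length, 1L)
  He <- vapply(loci, function(l)
    expected_heterozygosity(members$frequencies[[l]]), 1.0)
  Ho <- vapply(loci, function(l)
    observed_heterozygosity(dataset, l, exclude = drifters), 1.0)
  poly <- n_mem >= 2
  tab <- data.frame(
    locus = loci,
    n_alleles_members = n_mem,
    n_alleles_with_drifters = n_all,
    He = He, Ho = Ho,
    polymorphic = poly,
    row.names = NULL
  )
  structure(list(
    table = tab,
    frequencies = lapply(members$frequencies[loci],
                         function(f) sort(f, decreasing = TRUE)),
    mean_He = if (any(poly)) mean(He[poly]) else NA_real_,
    mean_n_alleles = if (any(poly)) mean(n_mem[poly]) else NA_real_,
    n_polymorphic = sum(poly)
  ), class = "panel_summary")
}

#' Diversity summary of a locus panel
#'
#' Computes per-locus expected heterozygosity from the panel's stored allele
#' frequencies (e.g. published frequency tables) plus the means over
#' polymorphic loci, without needing individual genotypes.
#'
#' @param object a [locus_panel()].
#' @param ... unused.
#' @return list with `table` (locus, n_alleles, He, polymorphic), `mean_He`
#'   and `mean_n_alleles` over polymorphic loci (`NA` if none).
#' @export
summary.locus_panel <- function(object, ...) {
  n <- vapply(object$alleles, length, 1L)
  He <- vapply(object$frequencies, expected_heterozygosity, 1.0)
  poly <- n >= 2
  list(
    table = data.frame(locus = object$loci, n_alleles = n, He = He,
                       polymorphic = poly, row.names = NULL),
    mean_He = if (any(poly)) mean(He[poly]) else NA_real_,
    mean_n_alleles = if (any(poly)) mean(n[poly]) else NA_real_,
    n_polymorphic = sum(poly)
  )
}

#' @export
print.panel_summary <- function(x, ...) {
  tab <- x$table
  tab$He <- round(tab$He, 2)
  tab$Ho <- round(tab$Ho, 2)
  print(tab, row.names = FALSE)
  if (x$n_polymorphic > 0) {
    cat(sprintf("Polymorphic loci: %d; mean alleles/locus %.1f; mean He %.2f\n",
                x$n_polymorphic, x$mean_n_alleles, x$mean_He))
  } else {
    cat("No polymorphic loci; means undefined\n")
  }
  invisible(x)
}
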