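## Analytic non-detection and non-sampling error probabilities for pedigree
## inference from colony samples.

#' Non-detection probability for an additional male mate
#'
#' The probability that a second, independent male mate went undetected
#' because his multilocus haploid genotype coincides with the inferred
#' paternal genotype: the product, over polymorphic loci with a resolved
#' paternal allele, of that allele's population frequency.
#'
#' @param father data frame with columns `locus`, `allele` and (optionally)
#'   `flag`; rows flagged `"ambiguous"` are skipped.
#' @param panel a [locus_panel()] with population frequencies (pooled across
#'   nests by convention; pass per-nest frequencies for a within-nest
#'   variant).
#' @return probability in `[0, 1]`. With no informative locus the product is
#'   empty and the value is 1 (no information).
#' @export
patriline_nondetection <- function(father, panel) {
  stopifnot(inherits(panel, "locus_panel"))
  poly <- polymorphic_loci(panel)
  p <- 1.0
  for (i in seq_len(nrow(father))) {
    l <- father$locus[i]
    if (!l %in% poly) next
    if (!is.null(father$flag) && father$flag[i] != "resolved") next
    a <- as.character(father$allele[i])
    f <- panel$frequencies[[l]]
    if (is.null(f) || !a %in% names(f)) {
      stop("father allele ", a, " at locus ", l, " absent from panel")
    }
    p <- p * f[[a]]
  }
  p
}

#' Non-sampling probability for a minority patriline
#'
#' The probability that none of the offspring of a hypothetical additional
#' father appear in a sample of `n_sampled` offspring, when that father
#' sired a fraction `minority_fraction` of the brood:
#' `(1 - minority_fraction)^n_sampled`.
#'
#' @param n_sampled number of genotyped offspring.
#' @param minority_fraction assumed proportion sired by the missed father.
#' @return probability in `[0, 1]`.
#' @export
patriline_nonsampling <- function(n_sampled, minority_fraction) {
  stopifnot(n_sampled >= 0, minority_fraction >= 0, minority_fraction <= 1)
  (1 - minority_fraction)^n_sampled
}

#' Non-detection probability for a worker-derived male
#'
#' Chance that a worker's son is genotypically indistinguishable from a
#' queen's son. At each of `k_informative` loci (loci where the paternal
#' allele is absent from the queen's genotype) a worker's son inherits his
#' mother's paternal allele — the giveaway — with probability 1/2, so he
#' passes as queen-derived with probability `(1/2)^k_informative`.
#'
#' @param k_informative number of informative loci.
#' @return probability in `[0, 1]`.
#' @examples
#' worker_male_nondetection(4)  # 0.0625, i.e. 6.3%
#' @export
worker_male_nondetection <- function(k_informative) {
  stopifnot(k_informative >= 0)
  0.5^k_informative
}

#' Combined non-sampling probability for worker-derived males
#'
#' Probability that, among `n_males_sampled` genotyped males, none is both
#' worker-derived and detectable, when workers produce a proportion `rate`
#' of all males and each worker-derived male is detectable with probability
#' `1 - (1/2)^k_informative`:
#' `(1 - rate * (1 - (1/2)^k_informative))^n_males_sampled`.
#'
#' This combined form accounts for per-male detectability; pure
#' non-sampling `(1 - rate)^n` ignores it and understates the probability.
#'
#' @param rate assumed proportion of males produced by workers.
#' @param k_informative number of informative loci.
#' @param n_males_sampled number of genotyped males.
#' @return probability in `[0, 1]`.
#' @examples
#' worker_male_combined_nonsampling(0.02, 4, 30)  # ~0.567, i.e. 57%
#' worker_male_combined_nonsampling(0.10, 4, 30)  # ~0.052, i.e. 5%
#' @export
worker_male_combined_nonsampling <- function(rate, k_informative,
                                             n_males_sampled) {
  stopifnot(rate >= 0, rate <= 1, k_informative >= 0, n_males_sampled >= 0)
  (1 - rate * (1 - 0.5^k_informative))^n_males_sampled
}

#' Monte-Carlo check of the worker-male error arithmetic
#'
#' Simulates the per-locus Mendelian coin flips behind
#' [worker_male_combined_nonsampling()]: in each replicate, each of `n`
#' sampled males is worker-derived with probability `rate`; a worker-derived
#' male transmits his mother's informative paternal allele at each of `k`
#' loci independently with probability 1/2 and is detected iff at least one
#' informative allele shows. Returns the fraction of replicates in which no
#' worker-derived male was detected.
#'
#' @param rate proportion of males produced by workers.
#' @param k_informative number of informative loci.
#' @param n_males_sampled number of genotyped males per replicate.
#' @param n_rep number of replicates.
#' @return list with `estimate` (Monte-Carlo probability), `analytic`
#'   (closed form), `se` (binomial standard error) and `n_rep`.
#' @export
simulate_worker_male_detection <- function(rate, k_informative,
                                           n_males_sampled, n_rep = 10000) {
  stopifnot(n_rep >= 1)
  missed <- vapply(seq_len(n_rep), function(i) {
    nw <- stats::rbinom(1, n_males_sampled, rate)
    if (nw == 0) return(TRUE)
    ## each worker-derived male: k fair coin flips for the informative allele
    shows <- stats::rbinom(nw, k_informative, 0.5) > 0
    !any(shows)
  }, TRUE)
  est <- mean(missed)
  list(estimate = est,
       analytic = worker_male_combined_nonsampling(rate, k_informative,
                                                   n_males_sampled),
       se = sqrt(est * (1 - est) / n_rep),
       n_rep = n_rep)
}

#' Format a probability as a display percentage
#'
#' Display convention used in the reports: one decimal place below 10%,
#' integer percent at or above 10%. Rounding is half-up (so 0.0625 prints as
#' "6.3%", not the round-half-even "6.2%").
#'
#' @param p probability in `[0, 1]`.
#' @return character scalar like `"6.3%"` or `"57%"`.
#' @export
format_percent <- function(p) {
  stopifnot(length(p) == 1, p >= 0, p <= 1)
  pct <- p * 100
  if (pct < 10) {
    sprintf("%.1f%%", round_half_up(pct, 1))
  } else {
    sprintf("%.0f%%", round_half_up(pct, 0))
  }
}

## round half away from zero at `digits` decimals (R's round() is half-even)
round_half_up <- function(x, digits = 0) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5) / m
}
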