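## Desk-scale replication pipeline: simulate colonies under the study
## design, run the pedigree inference and error models, summarise locus
## diversity, run the wing-shape analysis, and compute the nest census —
## one deterministic report for a fixed seed.

#' Run the full replication pipeline
#'
#' Stages (each skippable): (1) locus diversity summary of the bundled
#' population panel; (2) simulation of three colonies mirroring the study
#' design — two monogynous, singly-mated nests and one with two unrelated
#' queens (contributions 0.85/0.15, fully disjoint at the most polymorphic
#' locus) — followed by pedigree inference and per-queen error estimates;
#' (3) the worker-male error grid for a set of assumed worker production
#' rates; (4) wing simulation, GPA, Procrustes ANOVA, shape PCA, CAC and
#' size-gap caste split; (5) census summaries of the bundled comb tables.
#'
#' @param seed integer seed governing all simulation stages.
#' @param out_dir optional directory; when given, `report.json` and
#'   `report.md` are written there.
#' @param n_perm permutations for the Procrustes ANOVA (default 199 at desk
#'   scale).
#' @param worker_rates assumed worker male-production rates for the error
#'   grid.
#' @param k_informative informative-locus count for the worker-male grid.
#' @param n_males_sampled genotyped males entering the worker-male grid.
#' @param genetics,morphometrics,census logical switches per stage.
#' @return report list (class `replication_report`) with elements
#'   `diversity`, `nests`, `worker_male_grid`, `wings`, `census`, `seed`.
#' @export
run_replication <- function(seed = 1, out_dir = NULL, n_perm = 199,
                            worker_rates = c(0.02, 0.10),
                            k_informative = 4, n_males_sampled = 30,
                            genetics = TRUE, morphometrics = TRUE,
                            census = TRUE) {
  panel <- vespa_soror_panel()
  report <- list(seed = seed)
  dv <- summary(panel)
  report$diversity <- list(
    table = dv$table,
    mean_He = dv$mean_He,
    mean_n_alleles = dv$mean_n_alleles
  )
  if (genetics) {
    designs <- list(
      N1 = list(n_females = 97, n_males = 0, n_queens = 1,
                contributions = 1, force = NULL),
      N2 = list(n_females = 140, n_males = 30, n_queens = 1,
                contributions = 1, force = NULL),
      N3 = list(n_females = 116, n_males = 0, n_queens = 2,
                contributions = c(0.85, 0.15), force = "VMA-8")
    )
    report$nests <- lapply(seq_along(designs), function(i) {
      d <- designs[[i]]
      sim <- simulate_colony(
        n_females = d$n_females, n_males = d$n_males, panel = panel,
        n_queens = d$n_queens, contributions = d$contributions,
        force_disjoint_locus = d$force, nest = names(designs)[i],
        seed = seed + i
      )
      inf <- infer_pedigree(sim$dataset, names(designs)[i], panel = panel)
      list(nest = names(designs)[i],
           n_queens = inf$partition$n_queens,
           mates = inf$errors$mates,
           contribution = inf$errors$contribution,
           nondetection = inf$errors$nondetection,
           nonsampling = inf$errors$nonsampling,
           drifters = inf$drifters,
           true_queens = d$n_queens)
    })
    names(report$nests) <- names(designs)
    grid <- expand.grid(rate = worker_rates, stringsAsFactors = FALSE)
    grid$nondetection <- worker_male_nondetection(k_informative)
    grid$combined_nonsampling <- vapply(grid$rate, function(r)
      worker_male_combined_nonsampling(r, k_informative, n_males_sampled),
      1.0)
    report$worker_male_grid <- grid
  }
  if (morphometrics) {
    sim <- simulate_wings(seed = seed + 100)
    g <- gpa(sim$landmarks)
    anova_tab <- procrustes_anova(g, n_perm = n_perm, seed = seed + 101)
    pca <- shape_pca(g)
    split <- split_castes_by_size(log(g$csize))
    cac <- common_allometric_component(g)
    report$wings <- list(
      n = length(g$id),
      anova = as.data.frame(anova_tab),
      pc_var_fraction = pca$var_fraction[1:2],
      split_threshold = split$threshold,
      split_agreement = mean(as.character(split$labels) == sim$truth$caste),
      cac_slopes = cac$slopes
    )
  }
  if (census) {
    report$census <- lapply(c("N1", "N2"), function(n) {
      s <- census_summary(vespa_soror_combs(n))
      list(nest = n, total_area_cm2 = s$total_area_cm2,
           total_cells = s$total_cells, total_pupae = s$total_pupae,
           sealed_fraction = s$sealed_fraction,
           large_sealed_fraction = s$large_sealed_fraction)
    })
    names(report$census) <- c("N1", "N2")
  }
  class(report) <- "replication_report"
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    jsonlite::write_json(unclass(report),
                         file.path(out_dir, "report.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE,
                         force = TRUE)
    writeLines(format_report_md(report), file.path(out_dir, "report.md"))
  }
  report
}

format_report_md <- function(report) {
  out <- c("# Colony replication report", "",
           paste("Seed:", report$seed), "")
  dv <- report$diversity
  out <- c(out, "## Locus diversity", "",
           "| locus | n alleles | He |", "|---|---|---|",
           sprintf("| %s | %d | %.2f |", dv$table$locus, dv$table$n_alleles,
                   dv$table$He),
           "",
           sprintf("Mean over polymorphic loci: %.1f alleles, He %.2f",
                   dv$mean_n_alleles, dv$mean_He), "")
  if (!is.null(report$nests)) {
    out <- c(out, "## Queen number and mating status (simulated colonies)",
             "",
             "| nest | queen | mates | contribution | non-detection |",
             "|---|---|---|---|---|")
    for (n in report$nests) {
      for (k in seq_along(n$mates)) {
        out <- c(out, sprintf("| %s | %d | %d | %.2f | %s |", n$nest, k,
                              n$mates[k], n$contribution[k],
                              format_percent(n$nondetection[k])))
      }
    }
    out <- c(out, "", "## Worker-derived male error grid", "",
             "| rate | non-detection | combined non-sampling |",
             "|---|---|---|")
    g <- report$worker_male_grid
    out <- c(out, sprintf("| %.2f | %s | %s |", g$rate,
                          vapply(g$nondetection, format_percent, ""),
                          vapply(g$combined_nonsampling, format_percent, "")),
             "")
  }
  if (!is.null(report$wings)) {
    w <- report$wings
    out <- c(out, "## Wing shape (simulated)", "",
             sprintf("n = %d; size-gap split at ln centroid size %.3f (%.0f%% agreement with truth)",
                     w$n, w$split_threshold, 100 * w$split_agreement),
             sprintf("PC1/PC2 variance: %.0f%% / %.0f%%",
                     100 * w$pc_var_fraction[1], 100 * w$pc_var_fraction[2]),
             "")
  }
  if (!is.null(report$census)) {
    out <- c(out, "## Nest census", "",
             "| nest | area cm^2 | cells | pupae | sealed | large sealed |",
             "|---|---|---|---|---|---|")
    for (cns in report$census) {
      out <- c(out, sprintf("| %s | %.0f | %d | %d | %.0f%% | %.0f%% |",
                            cns$nest, round_half_up(cns$total_area_cm2),
                            cns$total_cells, cns$total_pupae,
                            round_half_up(100 * cns$sealed_fraction),
                            round_half_up(100 * cns$large_sealed_fraction)))
    }
    out <- c(out, "")
  }
  out
}

#' @export
print.replication_report <- function(x, ...) {
  cat(format_report_md(x), sep = "\n")
  invisible(x)
}
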