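## Ground-truth simulators: Mendelian haplodiploid colony genotypes (with
## polygyny, polyandry, worker-laid males, drifters) and wing landmarks
## with caste and allometry structure. These generators embody exactly the
## inheritance model the pedigree reconstruction assumes: diploid daughters
## receive one maternal and one paternal allele per locus; haploid sons
## receive a single maternal allele.

draw_allele <- function(freq) {
  as.integer(sample(names(freq), 1, prob = freq))
}

draw_diploid <- function(panel) {
  g <- lapply(panel$loci, function(l) {
    f <- panel$frequencies[[l]]
    sort(c(draw_allele(f), draw_allele(f)))
  })
  names(g) <- panel$loci
  g
}

draw_haploid <- function(panel) {
  g <- lapply(panel$loci, function(l) draw_allele(panel$frequencies[[l]]))
  names(g) <- panel$loci
  g
}

#' Simulate a haplodiploid colony with known pedigree
#'
#' Queens are diploid genotypes drawn from the panel frequencies
#' (`relatedness = "sisters"` draws them as daughters of a common parental
#' pair instead); each queen mates with `mates_per_queen` haploid males
#' drawn from the same frequencies. Diploid daughters receive one allele
#' from their queen and the father's allele; haploid sons receive one queen
#' allele — unless flagged worker-derived (probability `worker_male_rate`),
#' in which case the mother is a random daughter and the son receives one of
#' her alleles. Drifters are unrelated females drawn from `drifter_panel`.
#'
#' @param n_females number of diploid offspring (workers/gynes) sampled.
#' @param n_males number of haploid males sampled.
#' @param panel [locus_panel()] with allele frequencies; default the
#'   published *Vespa soror* panel, so simulations live in the study's
#'   parameter regime.
#' @param n_queens number of queens (matrilines).
#' @param mates_per_queen scalar or vector of mate counts per queen.
#' @param contributions per-queen offspring proportions (default equal),
#'   summing to 1.
#' @param relatedness `"unrelated"` (default) or `"sisters"`.
#' @param worker_male_rate probability a sampled male is worker-derived.
#' @param n_drifters number of drifter females appended.
#' @param drifter_panel [locus_panel()] for drifters (default: `panel`).
#' @param force_disjoint_locus optional locus name at which queens (and
#'   their mates) are forced to share no alleles — the guaranteed-detectable
#'   polygyny scenario. Requires enough alleles at that locus.
#' @param nest nest id label for the generated records.
#' @param seed optional integer seed (single global stream).
#' @return list with `dataset` (a [colony_dataset()]) and `truth` (class
#'   `synthetic_truth`): queen and father genotypes, per-offspring `mother`
#'   and `father` indices, `worker_derived` and `drifter` flags.
#' @export
simulate_colony <- function(n_females = 100, n_males = 0,
                            panel = vespa_soror_panel(), n_queens = 1,
                            mates_per_queen = 1, contributions = NULL,
                            relatedness = c("unrelated", "sisters"),
                            worker_male_rate = 0, n_drifters = 0,
                            drifter_panel = NULL,
                            force_disjoint_locus = NULL, nest = "N1",
                            seed = NULL) {
  relatedness <- match.arg(relatedness)
  if (!is.null(seed)) set.seed(seed)
  if (is.null(contributions)) contributions <- rep(1 / n_queens, n_queens)
  stopifnot(length(contributions) == n_queens,
            abs(sum(contributions) - 1) < 1e-9,
            worker_male_rate >= 0, worker_male_rate <= 1)
  mates_per_queen <- rep_len(mates_per_queen, n_queens)
  if (is.null(drifter_panel)) drifter_panel <- panel
  loci <- panel$loci
  ## queens
  queens <- if (relatedness == "sisters" && n_queens > 1) {
    gm <- draw_diploid(panel)   # grandmother
    gf <- draw_haploid(panel)   # grandfather
    lapply(seq_len(n_queens), function(q) {
      g <- lapply(loci, function(l) sort(c(sample(gm[[l]], 1), gf[[l]])))
      names(g) <- loci
      g
    })
  } else {
    lapply(seq_len(n_queens), function(q) draw_diploid(panel))
  }
  ## optionally force queens (and their mates) pairwise disjoint at a locus
  taken <- integer(0)
  if (!is.null(force_disjoint_locus)) {
    l <- force_disjoint_locus
    if (!l %in% loci) stop("locus '", l, "' not in panel")
    f <- panel$frequencies[[l]]
    need <- 2 * n_queens + sum(mates_per_queen)
    if (length(f) < need) {
      stop("locus ", l, " has ", length(f), " alleles; need ", need,
           " for fully disjoint queens and mates")
    }
    for (q in seq_len(n_queens)) {
      avail <- f[!names(f) %in% as.character(taken)]
      a <- as.integer(sample(names(avail), 2, prob = avail))
      queens[[q]][[l]] <- sort(a)
      taken <- c(taken, a)
    }
  }
  ## fathers per queen
  fathers <- vector("list", n_queens)
  for (q in seq_len(n_queens)) {
    fathers[[q]] <- vector("list", mates_per_queen[q])
    for (m in seq_len(mates_per_queen[q])) {
      fa <- draw_haploid(panel)
      if (!is.null(force_disjoint_locus)) {
        l <- force_disjoint_locus
        f <- panel$frequencies[[l]]
        avail <- f[!names(f) %in% as.character(taken)]
        a <- as.integer(sample(names(avail), 1, prob = avail))
        fa[[l]] <- a
        taken <- c(taken, a)
      }
      fathers[[q]][[m]] <- fa
    }
  }
  mk_row <- function(id, sex, caste, geno) {
    row <- list(id = id, nest = nest, sex = sex, caste = caste)
    for (l in loci) {
      g <- geno[[l]]
      row[[paste0(l, ".1")]] <- g[1]
      row[[paste0(l, ".2")]] <- if (sex == "female") g[2] else NA_integer_
    }
    as.data.frame(row, check.names = FALSE)
  }
  rows <- list()
  truth_mother <- integer(0); truth_father <- integer(0)
  worker_flag <- logical(0); drifter_flag <- logical(0)
  daughter_genos <- list()  # pool for worker-laid males
  ## daughters
  qs <- sample(n_queens, n_females, replace = TRUE, prob = contributions)
  for (i in seq_len(n_females)) {
    q <- qs[i]
    m <- sample.int(mates_per_queen[q], 1)
    geno <- lapply(loci, function(l)
      sort(c(sample(queens[[q]][[l]], 1), fathers[[q]][[m]][[l]])))
    names(geno) <- loci
    id <- sprintf("F%03d", i)
    rows[[length(rows) + 1L]] <- mk_row(id, "female", "worker", geno)
    daughter_genos[[length(daughter_genos) + 1L]] <- geno
    truth_mother <- c(truth_mother, q); truth_father <- c(truth_father, m)
    worker_flag <- c(worker_flag, FALSE); drifter_flag <- c(drifter_flag, FALSE)
  }
  ## males
  if (n_males > 0) {
    qm <- sample(n_queens, n_males, replace = TRUE, prob = contributions)
    for (i in seq_len(n_males)) {
      wd <- stats::runif(1) < worker_male_rate && length(daughter_genos) > 0
      if (wd) {
        mom <- daughter_genos[[sample.int(length(daughter_genos), 1)]]
        geno <- lapply(loci, function(l) sample(mom[[l]], 1))
        q <- NA_integer_
      } else {
        q <- qm[i]
        geno <- lapply(loci, function(l) sample(queens[[q]][[l]], 1))
      }
      names(geno) <- loci
      id <- sprintf("M%03d", i)
      rows[[length(rows) + 1L]] <- mk_row(id, "male", "male", geno)
      truth_mother <- c(truth_mother, q); truth_father <- c(truth_father, NA_integer_)
      worker_flag <- c(worker_flag, wd); drifter_flag <- c(drifter_flag, FALSE)
    }
  }
  ## drifters
  if (n_drifters > 0) {
    for (i in seq_len(n_drifters)) {
      geno <- draw_diploid(drifter_panel)
      id <- sprintf("D%03d", i)
      rows[[length(rows) + 1L]] <- mk_row(id, "female", "worker", geno)
      truth_mother <- c(truth_mother, NA_integer_)
      truth_father <- c(truth_father, NA_integer_)
      worker_flag <- c(worker_flag, FALSE); drifter_flag <- c(drifter_flag, TRUE)
    }
  }
  records <- do.call(rbind, rows)
  dataset <- colony_dataset(records, panel = merge_panels(panel, drifter_panel))
  truth <- structure(list(
    queens = queens, fathers = fathers,
    mother = truth_mother, father = truth_father,
    worker_derived = worker_flag, drifter = drifter_flag,
    ids = records$id
  ), class = "synthetic_truth")
  list(dataset = dataset, truth = truth)
}

## union of two panels' allele sets (frequencies from the first; alleles of
## the second added with the complement mass spread is not needed for
## validation purposes, so frequencies are re-normalised counts-free: the
## combined panel is used for allele bookkeeping only)
merge_panels <- function(a, b) {
  if (identical(a, b)) return(a)
  freqs <- lapply(a$loci, function(l) {
    fa <- a$frequencies[[l]]
    extra <- setdiff(names(b$frequencies[[l]]), names(fa))
    if (length(extra)) {
      fb <- b$frequencies[[l]][extra]
      f <- c(fa, fb) / sum(c(fa, fb))
    } else {
      f <- fa
    }
    f
  })
  names(freqs) <- a$loci
  locus_panel(freqs)
}

#' Default 19-landmark wing template
#'
#' A stylised insect forewing: landmarks along the leading and trailing
#' margins plus interior vein intersections, centred and scaled to unit
#' centroid size. Purely synthetic geometry — it emulates the landmark
#' count and rough aspect ratio of a hornet forewing, not its actual
#' venation.
#'
#' @return `19 x 2` matrix.
#' @export
wing_template <- function() {
  t_lead <- seq(0, 1, length.out = 7)
  lead <- cbind(t_lead, 0.25 * sin(pi * t_lead))
  t_trail <- seq(0.1, 0.95, length.out = 6)
  trail <- cbind(t_trail, -0.22 * sin(pi * t_trail^0.8))
  t_mid <- seq(0.15, 0.85, length.out = 6)
  mid <- cbind(t_mid, 0.05 * cos(2 * pi * t_mid) - 0.02)
  m <- rbind(lead, trail, mid)
  m <- scale(m, scale = FALSE)
  m / sqrt(sum(m^2))
}

## deterministic unit direction vectors in the 2k shape space
shape_direction <- function(k, which = c("caste", "allometry")) {
  which <- match.arg(which)
  i <- seq_len(2 * k)
  v <- if (which == "caste") sin(i * 2.3) else cos(i * 1.7)
  v <- v - mean(v)
  v / sqrt(sum(v^2))
}

#' Simulate wing landmarks with caste and allometry structure
#'
#' Each specimen's shape is the template plus a caste offset (gynes only)
#' plus an allometric term proportional to its ln centroid size deviation,
#' plus isotropic Gaussian landmark noise; the configuration is then scaled
#' to its drawn centroid size, randomly rotated and translated. Default
#' sample sizes and the worker/gyne ln-size means straddling 1.09 mirror
#' the published study design (86 workers, 45 gynes).
#'
#' @param n_workers,n_gynes specimens per caste.
#' @param template `k x 2` base configuration (default [wing_template()]).
#' @param caste_offset magnitude of the gyne shape offset (Procrustes
#'   units; 0 = no caste shape difference).
#' @param allometry_slope magnitude of shape change per unit ln centroid
#'   size (0 = no allometry).
#' @param lnCS_worker,lnCS_gyne mean ln centroid size per caste.
#' @param lnCS_sd within-caste standard deviation of ln centroid size.
#' @param noise_sd isotropic landmark noise sd (Procrustes units).
#' @param seed optional integer seed.
#' @return list with `landmarks` (a [landmarks()] collection with caste
#'   labels), `truth` (list: `caste`, `lnCS`, `caste_direction`,
#'   `allometry_direction`, parameters).
#' @export
simulate_wings <- function(n_workers = 86, n_gynes = 45,
                           template = wing_template(),
                           caste_offset = 0.01, allometry_slope = 0.05,
                           lnCS_worker = 1.04, lnCS_gyne = 1.14,
                           lnCS_sd = 0.02, noise_sd = 0.005, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  stopifnot(noise_sd > 0)
  k <- nrow(template)
  n <- n_workers + n_gynes
  caste <- c(rep("worker", n_workers), rep("gyne", n_gynes))
  lnCS <- c(stats::rnorm(n_workers, lnCS_worker, lnCS_sd),
            stats::rnorm(n_gynes, lnCS_gyne, lnCS_sd))
  dir_c <- shape_direction(k, "caste")
  dir_a <- shape_direction(k, "allometry")
  base <- as.vector(template)
  mean_lnCS <- mean(c(lnCS_worker, lnCS_gyne))
  configs <- vector("list", n)
  for (i in seq_len(n)) {
    v <- base +
      (if (caste[i] == "gyne") caste_offset * dir_c else 0) +
      allometry_slope * (lnCS[i] - mean_lnCS) * dir_a +
      stats::rnorm(2 * k, 0, noise_sd)
    m <- matrix(v, ncol = 2)
    m <- scale(m, scale = FALSE)
    m <- m / sqrt(sum(m^2)) * exp(lnCS[i])
    th <- stats::runif(1, 0, 2 * pi)
    R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2)
    configs[[i]] <- m %*% R + matrix(stats::runif(2, -5, 5), k, 2,
                                     byrow = TRUE)
  }
  ids <- sprintf("W%03d", seq_len(n))
  list(
    landmarks = landmarks(configs, id = ids, caste = caste),
    truth = list(caste = caste, lnCS = lnCS, caste_direction = dir_c,
                 allometry_direction = dir_a, caste_offset = caste_offset,
                 allometry_slope = allometry_slope, noise_sd = noise_sd)
  )
}
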