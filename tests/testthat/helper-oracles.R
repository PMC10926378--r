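## Shared fixtures and independent oracles used across the suite.

toy_panel <- function() {
  locus_panel(list(
    L1 = c(`1` = 0.4, `2` = 0.3, `3` = 0.3),
    L2 = c(`1` = 0.5, `2` = 0.5),
    L3 = c(`1` = 1.0)
  ))
}

make_dataset <- function(females = list(), males = list(), nest = "N",
                         panel = NULL) {
  loci <- if (length(females)) names(females[[1]]) else names(males[[1]])
  rows <- list()
  for (i in seq_along(females)) {
    row <- list(id = sprintf("f%02d", i), nest = nest, sex = "female",
                caste = "worker")
    for (l in loci) {
      g <- sort(females[[i]][[l]])
      row[[paste0(l, ".1")]] <- g[1]
      row[[paste0(l, ".2")]] <- g[2]
    }
    rows[[length(rows) + 1L]] <- as.data.frame(row, check.names = FALSE)
  }
  for (i in seq_along(males)) {
    row <- list(id = sprintf("m%02d", i), nest = nest, sex = "male",
                caste = "male")
    for (l in loci) {
      row[[paste0(l, ".1")]] <- males[[i]][[l]]
      row[[paste0(l, ".2")]] <- NA_integer_
    }
    rows[[length(rows) + 1L]] <- as.data.frame(row, check.names = FALSE)
  }
  colony_dataset(do.call(rbind, rows), panel = panel)
}

## Brute-force oracle for single-locus queen/father enumeration: loops over
## every queen pair of observed alleles and every per-female paternal
## choice, entirely independently of the package's search.
brute_locus_solutions <- function(females, males = integer(0)) {
  females <- as.matrix(females)
  alleles <- sort(unique(c(as.vector(females), males)))
  sols <- list()
  for (q1 in alleles) for (q2 in alleles) {
    if (q1 > q2) next
    Q <- c(q1, q2)
    if (length(males) && !all(males %in% Q)) next
    choices <- list()
    ok <- TRUE
    for (i in seq_len(nrow(females))) {
      x <- females[i, 1]; y <- females[i, 2]
      opts <- integer(0)
      if (y %in% Q) opts <- c(opts, x)  # x paternal, y maternal
      if (x %in% Q) opts <- c(opts, y)
      opts <- unique(opts)
      if (!length(opts)) { ok <- FALSE; break }
      choices[[i]] <- opts
    }
    if (!ok) next
    if (length(choices)) {
      grids <- do.call(expand.grid, choices)
      counts <- apply(grids, 1, function(v) length(unique(v)))
      best <- min(counts)
      fsets <- unique(lapply(which(counts == best), function(r)
        sort(unique(as.integer(grids[r, ])))))
    } else {
      best <- 0L
      fsets <- list(integer(0))
    }
    sols[[length(sols) + 1L]] <- list(queen = Q, n_fathers = best,
                                      father_sets = fsets)
  }
  sols
}

brute_min_fathers <- function(females, males = integer(0)) {
  sols <- brute_locus_solutions(females, males)
  if (!length(sols)) return(NA_integer_)
  min(vapply(sols, `[[`, 1L, "n_fathers"))
}

## Independent consistency verifier: every member of every matriline must be
## explainable by its inferred queen and assigned father.
verify_pedigree <- function(dataset, part) {
  for (m in part$matrilines) {
    q <- m$queen
    pat <- m$patrilines
    for (id in m$members) {
      f <- pat$fathers[[pat$assignment[[id]]]]
      for (j in seq_len(nrow(q))) {
        if (q$flag[j] == "multiple_solutions") next
        Q <- c(q$a1[j], q$a2[j])
        g <- genotypes_at(dataset, q$locus[j])[id, ]
        if (any(is.na(g))) next
        pa <- f$allele[f$locus == q$locus[j]]
        pf <- f$flag[f$locus == q$locus[j]]
        explained <- (g[1] %in% Q && (pf == "ambiguous" || g[2] == pa)) ||
                     (g[2] %in% Q && (pf == "ambiguous" || g[1] == pa))
        if (!explained) return(FALSE)
      }
    }
    for (id in m$males) {
      for (j in seq_len(nrow(q))) {
        if (q$flag[j] == "multiple_solutions") next
        a <- genotypes_at(dataset, q$locus[j])[id, 1]
        if (!is.na(a) && !a %in% c(q$a1[j], q$a2[j])) return(FALSE)
      }
    }
  }
  TRUE
}

## A drifter source pool with private alleles at every polymorphic locus.
private_panel <- function(panel) {
  freqs <- lapply(panel$loci, function(l) {
    f <- panel$frequencies[[l]]
    if (length(f) < 2) return(f)  # monomorphic locus stays shared
    stats::setNames(c(0.5, 0.5), as.character(max(as.integer(names(f))) + c(100L, 102L)))
  })
  names(freqs) <- panel$loci
  locus_panel(freqs)
}

## Small deterministic landmark noise helper for morphometrics tests.
jitter_config <- function(template, sd) {
  template + matrix(stats::rnorm(length(template), 0, sd),
                    ncol = ncol(template))
}
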