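## Pedigree reconstruction for haplodiploid colonies from codominant
## genotypes: drifter detection, matriline partitioning, queen-genotype
## inference by shared-allele identification, paternal subtraction, and
## patriline counting under a parsimony objective (fewest parents in total,
## ties resolved toward fewer queens).

#' Detect drifted workers in a nest
#'
#' A drifter is an individual carrying, at `min_unique_loci` or more
#' polymorphic loci, at least one allele found in no other member of the
#' nest (other drifters included). The rule is applied iteratively: once an
#' individual is flagged, uniqueness is re-assessed against the remaining
#' members, so two drifters from the same foreign colony cannot shield each
#' other indefinitely.
#'
#' @param dataset a [colony_dataset()].
#' @param nest nest id.
#' @param min_unique_loci minimum number of polymorphic loci with a private
#'   allele required to flag an individual (default 4).
#' @return character vector of flagged individual ids (possibly empty).
#' @export
detect_drifters <- function(dataset, nest, min_unique_loci = 4) {
  stopifnot(inherits(dataset, "colony_dataset"))
  r <- dataset$records
  if (!nest %in% r$nest) stop("nest '", nest, "' not found")
  ids <- r$id[r$nest == nest]
  if (length(ids) < 2) stop("need at least 2 individuals in nest ", nest)
  poly <- intersect(polymorphic_loci(dataset$panel), dataset$loci)
  ## allele sets per individual per locus
  sets <- lapply(poly, function(l) {
    g <- genotypes_at(dataset, l, nest = nest)
    lapply(seq_len(nrow(g)), function(i) unique(g[i, ][!is.na(g[i, ])]))
  })
  names(sets) <- poly
  n_private <- function(i, against) {
    sum(vapply(poly, function(l) {
      mine <- sets[[l]][[i]]
      others <- unlist(sets[[l]][against], use.names = FALSE)
      length(mine) > 0 && any(!mine %in% others)
    }, TRUE))
  }
  idx <- seq_along(ids)
  flagged <- logical(length(ids))
  ## first pass: uniqueness against every other nestmate, drifters included
  for (i in idx) flagged[i] <- n_private(i, setdiff(idx, i)) >= min_unique_loci
  ## iterate: re-assess against non-flagged members so drifters don't shield
  repeat {
    new_flag <- flagged
    keep <- idx[!flagged]
    for (i in keep) {
      new_flag[i] <- n_private(i, setdiff(keep, i)) >= min_unique_loci
    }
    if (identical(new_flag, flagged)) break
    flagged <- new_flag
  }
  sort(ids[flagged])
}

#' Enumerate single-queen solutions at one locus
#'
#' Exhaustively enumerates queen genotypes `{q1, q2}` (over the alleles
#' observed at the locus, homozygous pairs included) and minimal father
#' allele sets such that every diploid offspring carries one queen allele
#' plus one father allele, and every haploid male carries a queen allele.
#' An empty result signals that the offspring cannot descend from a single
#' queen with at most `max_fathers` mates at this locus.
#'
#' @param females two-column matrix of diploid genotypes at the locus (one
#'   row per female; `NA`-free rows only).
#' @param males integer vector of haploid male alleles (may be empty).
#' @param max_fathers cap on fathers per queen considered (default 10).
#' @return data-frame-like list of candidate solutions, each a list with
#'   `queen` (sorted pair), `fathers` (sorted allele vector), `n_fathers`,
#'   and `father_ambiguous` (`TRUE` when more than one minimal father set
#'   exists for that queen). Candidates are sorted by `n_fathers`, then
#'   lexicographically by queen pair.
#' @export
enumerate_locus_solutions <- function(females, males = integer(0),
                                      max_fathers = 10) {
  females <- as.matrix(females)
  if (nrow(females) < 1 && length(males) < 1) stop("no offspring supplied")
  if (any(is.na(females))) stop("females must have complete genotypes")
  alleles <- sort(unique(c(as.vector(females), males)))
  pairs <- expand.grid(q1 = alleles, q2 = alleles)
  pairs <- pairs[pairs$q1 <= pairs$q2, , drop = FALSE]
  out <- list()
  for (p in seq_len(nrow(pairs))) {
    Q <- c(pairs$q1[p], pairs$q2[p])
    if (length(males) && !all(males %in% Q)) next
    forced <- integer(0)
    amb <- list()  # per ambiguous female: candidate paternal alleles
    ok <- TRUE
    for (i in seq_len(nrow(females))) {
      x <- females[i, 1]; y <- females[i, 2]
      inx <- x %in% Q; iny <- y %in% Q
      if (!inx && !iny) { ok <- FALSE; break }
      if (x == y) {
        ## homozygous offspring: queen allele and father allele are both x
        forced <- c(forced, x)
      } else if (inx && iny) {
        amb[[length(amb) + 1L]] <- c(x, y)
      } else if (inx) {
        forced <- c(forced, y)
      } else {
        forced <- c(forced, x)
      }
    }
    if (!ok) next
    forced <- unique(forced)
    ## minimal extra alleles covering ambiguous females not hit by a forced
    ## father; candidates are subsets of the queen pair
    uncovered <- Filter(function(cand) !any(cand %in% forced), amb)
    extra_options <- list(integer(0))
    if (length(uncovered)) {
      pool <- sort(unique(unlist(uncovered)))
      found <- NULL
      for (k in 1:min(length(pool), max_fathers)) {
        subs <- utils::combn(pool, k, simplify = FALSE)
        hit <- Filter(function(s)
          all(vapply(uncovered, function(cand) any(cand %in% s), TRUE)), subs)
        if (length(hit)) { found <- hit; break }
      }
      if (is.null(found)) next
      extra_options <- found
    }
    n_f <- length(forced) + length(extra_options[[1]])
    if (n_f > max_fathers) next
    father_sets <- lapply(extra_options, function(e) sort(c(forced, e)))
    father_sets <- unique(father_sets)
    out[[length(out) + 1L]] <- list(
      queen = Q,
      fathers = father_sets[[1]],
      n_fathers = length(father_sets[[1]]),
      father_ambiguous = length(father_sets) > 1
    )
  }
  if (!length(out)) return(out)
  ord <- order(
    vapply(out, function(s) s$n_fathers, 1L),
    vapply(out, function(s) s$queen[1], alleles[1]),
    vapply(out, function(s) s$queen[2], alleles[1])
  )
  out[ord]
}

#' Infer a queen genotype from a consistent matriline
#'
#' Starts from the most parsimonious single-queen solution per locus from
#' [enumerate_locus_solutions()] (fewest fathers; heterozygous solutions
#' preferred over homozygous ones at equal father count, remaining ties
#' lexicographic by queen pair). Because per-locus parsimony can be
#' globally wrong — a homozygous queen's locus admits a spurious one-father
#' solution that merges patrilines — the per-locus picks are refined
#' whenever the joint father count (via [assign_patrilines()]) exceeds the
#' per-locus lower bound, by an iterative-deepening search over the product
#' of per-locus candidate solutions. Haploid sons, when present, constrain
#' the per-locus enumeration as in the shared-allele procedure. Per-locus
#' ambiguity flags record whether the chosen solution was unique at the
#' achieved father budget.
#'
#' @param dataset a [colony_dataset()].
#' @param members ids of the matriline's diploid offspring.
#' @param males ids of haploid males attributed to the same queen.
#' @param loci loci to use; default all loci of the dataset.
#' @return object of class `queen_genotype`: data frame with columns
#'   `locus`, `a1`, `a2`, `flag` (`"resolved"`, `"homozygosity_unresolved"`
#'   or `"multiple_solutions"`) and attribute `n_fathers_by_locus`.
#' @export
infer_queen_genotype <- function(dataset, members, males = character(),
                                 loci = NULL) {
  stopifnot(inherits(dataset, "colony_dataset"))
  if (is.null(loci)) loci <- dataset$loci
  per_locus <- lapply(loci, function(l) {
    g <- genotypes_at(dataset, l)
    fem <- g[rownames(g) %in% members, , drop = FALSE]
    fem <- fem[stats::complete.cases(fem), , drop = FALSE]
    mal <- g[rownames(g) %in% males, 1]
    mal <- mal[!is.na(mal)]
    sols <- enumerate_locus_solutions(fem, mal)
    if (!length(sols)) {
      stop("matriline inconsistent with a single queen at locus ", l)
    }
    ## prefer heterozygous queen solutions at equal father count: a
    ## homozygous call is only made when no heterozygous explanation ties
    nf <- vapply(sols, `[[`, 1L, "n_fathers")
    hom <- vapply(sols, function(s) s$queen[1] == s$queen[2], TRUE)
    sols <- sols[order(nf, hom)]
    n_min <- min(nf)
    list(locus = l, candidates = sols, n_min = n_min,
         n_tied = sum(nf == n_min))
  })
  pick <- lapply(per_locus, function(pl) pl$candidates[[1]])
  n_tied <- vapply(per_locus, `[[`, 1L, "n_tied")
  ## per-locus parsimony can be globally wrong (e.g. a homozygous queen's
  ## locus admits a spurious one-father solution that merges patrilines, so
  ## several loci must be corrected simultaneously); when the joint father
  ## count exceeds the per-locus lower bound, search the product of
  ## per-locus candidates by iterative deepening on the father budget
  if (length(members) > 1) {
    joint_nf <- function(picks) {
      assign_patrilines(dataset, members,
                        queen_frame(per_locus, picks))$n_fathers
    }
    bound <- max(vapply(per_locus, `[[`, 1L, "n_min"))
    current <- joint_nf(pick)
    if (current > bound) {
      for (k in bound:(current - 1L)) {
        cand_k <- lapply(per_locus, function(pl)
          Filter(function(s) s$n_fathers <= k, pl$candidates))
        if (any(lengths(cand_k) == 0)) next
        if (prod(lengths(cand_k)) > 800) break
        grid <- as.matrix(do.call(expand.grid, lapply(cand_k, seq_along)))
        ## try combinations with the largest per-locus father counts first:
        ## spurious queen pairs absorb a father allele and sit at low
        ## counts, the true structure at the locus's real father diversity
        tot_nf <- numeric(nrow(grid))
        for (i in seq_along(cand_k)) {
          nfs <- vapply(cand_k[[i]], `[[`, 1L, "n_fathers")
          tot_nf <- tot_nf + nfs[grid[, i]]
        }
        grid <- grid[order(-tot_nf), , drop = FALSE]
        found <- FALSE
        for (r in seq_len(nrow(grid))) {
          trial <- lapply(seq_along(cand_k), function(i)
            cand_k[[i]][[grid[r, i]]])
          nf <- joint_nf(trial)
          if (nf <= k) {
            pick <- trial
            current <- nf
            found <- TRUE
            break
          }
        }
        if (found) break
      }
      ## re-assess per-locus ambiguity at the achieved father budget:
      ## a locus is multiply solved if another candidate ties jointly
      ## (candidates needing more fathers at the locus than the joint
      ## budget cannot tie and are skipped)
      for (i in seq_along(per_locus)) {
        cands <- Filter(function(s) s$n_fathers <= current,
                        per_locus[[i]]$candidates)
        if (length(cands) < 2) { n_tied[i] <- 1L; next }
        ties <- vapply(cands, function(s) {
          trial <- pick
          trial[[i]] <- s
          joint_nf(trial) <= current
        }, TRUE)
        n_tied[i] <- sum(ties)
      }
    }
  }
  qg <- queen_frame(per_locus, pick, n_tied)
  attr(qg, "n_fathers_by_locus") <-
    vapply(per_locus, `[[`, 1L, "n_min")
  qg
}

queen_frame <- function(per_locus, pick, n_tied = NULL) {
  if (is.null(n_tied)) n_tied <- vapply(per_locus, `[[`, 1L, "n_tied")
  flag <- vapply(seq_along(per_locus), function(i) {
    if (n_tied[i] > 1) "multiple_solutions"
    else if (pick[[i]]$queen[1] == pick[[i]]$queen[2]) "homozygosity_unresolved"
    else "resolved"
  }, "")
  qg <- data.frame(
    locus = vapply(per_locus, `[[`, "", "locus"),
    a1 = vapply(pick, function(s) s$queen[1], 1L),
    a2 = vapply(pick, function(s) s$queen[2], 1L),
    flag = flag,
    row.names = NULL
  )
  class(qg) <- c("queen_genotype", "data.frame")
  qg
}

#' Assign a matriline's offspring to patrilines
#'
#' Subtracts the queen's alleles from each female's genotype to obtain her
#' paternal allele per locus (a candidate set when the female's genotype is
#' contained in the queen pair), then groups females under the minimal number
#' of haploid father genotypes: females are processed in order of increasing
#' ambiguity (ties by id) and joined to the first existing father compatible
#' at every locus, narrowing that father's candidate alleles by intersection;
#' otherwise a new father is opened. Compatible fathers are merged at the
#' end. The procedure is deterministic and exact whenever each locus admits
#' its minimal father count jointly (always the case for a singly-mated
#' queen).
#'
#' @param dataset a [colony_dataset()].
#' @param members ids of the matriline's diploid offspring.
#' @param queen a `queen_genotype` from [infer_queen_genotype()].
#' @return object of class `patriline_assignment`: list with `fathers` (list
#'   of data frames `locus`/`allele`/`flag`, flag `"ambiguous"` when more
#'   than one allele remains possible), `assignment` (named vector:
#'   member id -> father index) and `n_fathers`.
#' @export
assign_patrilines <- function(dataset, members, queen) {
  stopifnot(inherits(queen, "queen_genotype"))
  loci <- queen$locus
  L <- length(loci)
  ids <- sort(as.character(members))
  n <- length(ids)
  ## candidate paternal alleles per female per locus, packed as two n x L
  ## integer matrices: (c1, NA) = forced allele, (c1, c2) = two-way
  ## ambiguity, (NA, NA) = unconstrained (missing call)
  C1 <- matrix(NA_integer_, n, L)
  C2 <- matrix(NA_integer_, n, L)
  for (j in seq_len(L)) {
    g <- dataset$geno[[loci[j]]][ids, , drop = FALSE]
    q1 <- queen$a1[j]; q2 <- queen$a2[j]
    x <- g[, 1]; y <- g[, 2]
    miss <- is.na(x) | is.na(y)
    inx <- x == q1 | x == q2
    iny <- y == q1 | y == q2
    bad <- !miss & !inx & !iny
    if (any(bad)) {
      stop("individual ", ids[which(bad)[1]],
           " incompatible with queen at locus ", loci[j])
    }
    both <- !miss & inx & iny
    C1[!miss & both, j] <- x[!miss & both]
    two <- both & x != y
    C2[two, j] <- y[two]
    only_x <- !miss & inx & !iny
    C1[only_x, j] <- y[only_x]
    only_y <- !miss & !inx & iny
    C1[only_y, j] <- x[only_y]
  }
  ## process females in order of increasing ambiguity (ties by id)
  n_amb <- rowSums(!is.na(C2)) + rowSums(is.na(C1))
  ordr <- order(n_amb, ids)
  F1 <- matrix(NA_integer_, 0, L)  # father candidate sets, same packing
  F2 <- matrix(NA_integer_, 0, L)
  assignment <- integer(n)
  compat_row <- function(k, i) {
    f1 <- F1[k, ]; f2 <- F2[k, ]
    c1 <- C1[i, ]; c2 <- C2[i, ]
    free <- is.na(f1) | is.na(c1)
    hit <- (!is.na(f1) & !is.na(c1) & f1 == c1) |
           (!is.na(f1) & !is.na(c2) & f1 == c2) |
           (!is.na(f2) & !is.na(c1) & f2 == c1) |
           (!is.na(f2) & !is.na(c2) & f2 == c2)
    all(free | hit)
  }
  narrow_row <- function(k, i) {
    f1 <- F1[k, ]; f2 <- F2[k, ]
    c1 <- C1[i, ]; c2 <- C2[i, ]
    for (j in seq_len(L)) {
      a <- c(f1[j], f2[j]); a <- a[!is.na(a)]
      b <- c(c1[j], c2[j]); b <- b[!is.na(b)]
      s <- if (!length(a)) b else if (!length(b)) a else intersect(a, b)
      f1[j] <- if (length(s)) s[1] else NA_integer_
      f2[j] <- if (length(s) > 1) s[2] else NA_integer_
    }
    F1[k, ] <<- f1
    F2[k, ] <<- f2
  }
  for (i in ordr) {
    hit <- 0L
    for (k in seq_len(nrow(F1))) {
      if (compat_row(k, i)) { hit <- k; break }
    }
    if (hit == 0L) {
      F1 <- rbind(F1, C1[i, ])
      F2 <- rbind(F2, C2[i, ])
      hit <- nrow(F1)
    } else {
      narrow_row(hit, i)
    }
    assignment[i] <- hit
  }
  ## merge fathers that remained mutually compatible
  compat_ff <- function(k, m) {
    f1 <- F1[k, ]; f2 <- F2[k, ]
    g1 <- F1[m, ]; g2 <- F2[m, ]
    free <- is.na(f1) | is.na(g1)
    hit <- (!is.na(f1) & !is.na(g1) & f1 == g1) |
           (!is.na(f1) & !is.na(g2) & f1 == g2) |
           (!is.na(f2) & !is.na(g1) & f2 == g1) |
           (!is.na(f2) & !is.na(g2) & f2 == g2)
    all(free | hit)
  }
  k <- 1L
  while (k < nrow(F1)) {
    merged <- FALSE
    for (m in seq(k + 1L, length.out = nrow(F1) - k)) {
      if (compat_ff(k, m)) {
        ## narrow k by m, drop m
        C1 <- rbind(C1, F1[m, ]); C2 <- rbind(C2, F2[m, ])
        narrow_row(k, nrow(C1))
        C1 <- C1[-nrow(C1), , drop = FALSE]
        C2 <- C2[-nrow(C2), , drop = FALSE]
        F1 <- F1[-m, , drop = FALSE]
        F2 <- F2[-m, , drop = FALSE]
        assignment[assignment == m] <- k
        assignment[assignment > m] <- assignment[assignment > m] - 1L
        merged <- TRUE
        break
      }
    }
    if (!merged) k <- k + 1L
  }
  father_df <- lapply(seq_len(nrow(F1)), function(k) {
    data.frame(
      locus = loci,
      allele = F1[k, ],
      flag = ifelse(is.na(F1[k, ]) | !is.na(F2[k, ]), "ambiguous",
                    "resolved"),
      row.names = NULL
    )
  })
  names(assignment) <- ids
  structure(list(fathers = father_df, assignment = assignment,
                 n_fathers = length(father_df)),
            class = "patriline_assignment")
}

#' Count informative loci of a queen-father pair
#'
#' A locus is informative when the paternal allele is not carried by the
#' queen, so that a male offspring carrying it cannot be the queen's son.
#' Loci where either genotype is unresolved are skipped.
#'
#' @param queen a `queen_genotype`.
#' @param father a data frame `locus`/`allele`/`flag` as returned inside
#'   [assign_patrilines()].
#' @return integer count of informative loci.
#' @export
informative_loci <- function(queen, father) {
  stopifnot(inherits(queen, "queen_genotype"))
  j <- match(father$locus, queen$locus)
  ok <- !is.na(j) & father$flag == "resolved" & queen$flag[j] != "multiple_solutions"
  sum(vapply(which(ok), function(i) {
    !father$allele[i] %in% c(queen$a1[j[i]], queen$a2[j[i]])
  }, TRUE))
}

## ---- matriline partitioning -------------------------------------------

single_matriline_fits <- function(dataset, members, males, loci) {
  for (l in loci) {
    g <- genotypes_at(dataset, l)
    fem <- g[rownames(g) %in% members, , drop = FALSE]
    fem <- fem[stats::complete.cases(fem), , drop = FALSE]
    mal <- g[rownames(g) %in% males, 1]
    mal <- mal[!is.na(mal)]
    if (nrow(fem) == 0 && length(mal) == 0) next
    if (!length(enumerate_locus_solutions(fem, mal))) return(l)
  }
  NULL
}

## connected components of the allele-sharing graph among females at a locus
allele_sharing_components <- function(g) {
  ids <- rownames(g)
  n <- length(ids)
  comp <- seq_len(n)
  find <- function(i) { while (comp[i] != i) i <- comp[i]; i }
  alleles <- sort(unique(as.vector(g)))
  for (a in alleles) {
    carriers <- which(g[, 1] == a | g[, 2] == a)
    if (length(carriers) > 1) {
      root <- find(carriers[1])
      for (i in carriers[-1]) comp[find(i)] <- root
    }
  }
  roots <- vapply(seq_len(n), find, 1L)
  split(ids, match(roots, unique(roots)))
}

## all ways to group `n` components into `m` non-empty unlabelled groups
component_groupings <- function(n, m) {
  if (m == 1) return(list(rep(1L, n)))
  out <- list()
  assign <- integer(n)
  recur <- function(i, used) {
    if (i > n) {
      if (used == m) out[[length(out) + 1L]] <<- assign
      return(invisible())
    }
    for (g in seq_len(min(used + 1L, m))) {
      assign[i] <<- g
      recur(i + 1L, max(used, g))
    }
  }
  recur(1L, 0L)
  out
}

## queen inference is re-requested for the same member sets repeatedly
## during partition search; memoise on the sorted member ids
queen_cached <- function(dataset, grp, cache) {
  key <- paste(sort(grp), collapse = "\r")
  if (!is.null(cache[[key]])) return(cache[[key]])
  q <- infer_queen_genotype(dataset, grp, character(), loci = dataset$loci)
  cache[[key]] <- q
  q
}

## fathers needed to explain a candidate matriline jointly across loci
## (queen inferred from the females alone); NULL when inconsistent
group_father_count <- function(dataset, grp, poly, cache) {
  if (!is.null(single_matriline_fits(dataset, grp, character(), poly))) {
    return(NULL)
  }
  queen <- queen_cached(dataset, grp, cache)
  assign_patrilines(dataset, grp, queen)$n_fathers
}

#' Partition a nest's offspring into matrilines
#'
#' Implements the shared-allele parsimony procedure. Candidate partitions
#' into 1, 2, ... `max_queens` matrilines are generated from the most
#' discriminating loci — those whose allele-sharing graph among offspring
#' breaks into several connected components (two unrelated queens sharing no
#' alleles at a locus are thereby always separable) — and every candidate
#' whose groups each admit a single-queen explanation at every polymorphic
#' locus is scored by the total number of parents it requires (queens plus
#' fathers, counted jointly across loci). The minimal-parent candidate wins;
#' ties go to fewer queens, then to lexicographic order of sorted member
#' ids. This formalises accounting for the offspring with as few queens and
#' male mates as possible: a colony headed by one singly-mated queen scores
#' 2, while explaining two unrelated matrilines by a single queen inflates
#' the father count and loses.
#'
#' @param dataset a [colony_dataset()].
#' @param members ids of diploid offspring to partition (drifters already
#'   removed).
#' @param males ids of haploid males from the same nest; assigned to
#'   matrilines by genotype compatibility, and used to sharpen queen
#'   inference within their matriline (a male carrying a non-queen allele is
#'   left unassigned — the worker-derived male signal — rather than being
#'   allowed to create a matriline).
#' @param max_queens maximum number of matrilines searched (default 3).
#' @return object of class `matriline_partition`: list of matrilines (each
#'   with `members`, `males`, `queen`, `patrilines`, `contribution`), plus
#'   `n_queens` and `unassigned_males`.
#' @export
partition_matrilines <- function(dataset, members, males = character(),
                                 max_queens = 3) {
  stopifnot(inherits(dataset, "colony_dataset"))
  members <- sort(as.character(members))
  males <- sort(as.character(males))
  if (length(members) < 1) stop("need at least one diploid offspring")
  poly <- intersect(polymorphic_loci(dataset$panel), dataset$loci)
  cache <- new.env(parent = emptyenv())
  candidates <- list()
  add_candidate <- function(groups) {
    groups <- lapply(groups, sort)
    groups <- groups[order(vapply(groups, `[`, "", 1))]
    key <- paste(vapply(groups, paste, "", collapse = ","), collapse = "|")
    if (!key %in% names(candidates)) candidates[[key]] <<- groups
  }
  add_candidate(list(members))
  ## seed multi-matriline candidates from allele-sharing components
  fem_g <- lapply(poly, function(l) {
    g <- genotypes_at(dataset, l)
    g <- g[rownames(g) %in% members, , drop = FALSE]
    g[stats::complete.cases(g), , drop = FALSE]
  })
  names(fem_g) <- poly
  comps <- lapply(fem_g, allele_sharing_components)
  if (max_queens >= 2) {
    for (l in poly) {
      cs <- comps[[l]]
      if (length(cs) < 2) next
      for (m in 2:min(max_queens, length(cs))) {
        for (grouping in component_groupings(length(cs), m)) {
          add_candidate(lapply(seq_len(m), function(g)
            unlist(cs[grouping == g], use.names = FALSE)))
        }
      }
    }
  }
  ## score candidates: total parents, then queens, then member order
  best <- NULL
  best_score <- c(Inf, Inf)
  keys <- sort(names(candidates))
  keys <- keys[order(vapply(candidates[keys], length, 1L))]
  for (key in keys) {
    groups <- candidates[[key]]
    fathers <- vapply(groups, function(grp) {
      n <- group_father_count(dataset, grp, poly, cache)
      if (is.null(n)) NA_integer_ else n
    }, 1L)
    if (anyNA(fathers)) next
    score <- c(length(groups) + sum(fathers), length(groups))
    if (score[1] < best_score[1] ||
        (score[1] == best_score[1] && score[2] < best_score[2])) {
      best <- groups
      best_score <- score
    }
  }
  if (is.null(best)) {
    bad <- single_matriline_fits(dataset, members, character(), poly)
    stop("no consistent matriline partition within ", max_queens,
         " queens; conflicting loci include: ",
         paste(unique(c(bad, poly[vapply(comps, length, 1L) > 1])),
               collapse = ", "))
  }
  build_partition(dataset, best, males, poly, cache)
}

## assemble queen/patriline structure for a fixed grouping
build_partition <- function(dataset, groups, males, poly,
                            cache = new.env(parent = emptyenv())) {
  all_loci <- dataset$loci
  ## provisional queens (females only) to assign males when several groups
  queens0 <- lapply(groups, function(grp)
    queen_cached(dataset, grp, cache))
  male_of <- rep(NA_integer_, length(males))
  names(male_of) <- males
  if (length(males)) {
    for (i in seq_along(males)) {
      fits <- which(vapply(seq_along(groups), function(k) {
        q <- queens0[[k]]
        ok <- TRUE
        for (j in seq_len(nrow(q))) {
          if (q$flag[j] == "multiple_solutions") next
          a <- genotypes_at(dataset, q$locus[j])[males[i], 1]
          if (is.na(a)) next
          if (!a %in% c(q$a1[j], q$a2[j])) { ok <- FALSE; break }
        }
        ok
      }, TRUE))
      if (length(fits) == 1) male_of[i] <- fits
    }
  }
  n_total <- sum(lengths(groups))
  matrilines <- lapply(seq_along(groups), function(k) {
    grp <- groups[[k]]
    mal <- males[!is.na(male_of) & male_of == k]
    ## sons disambiguate the queen where they fit; fall back to the
    ## female-only inference if the joint solve fails at some locus
    queen <- tryCatch(
      infer_queen_genotype(dataset, grp, mal, loci = all_loci),
      error = function(e) queens0[[k]]
    )
    pat <- assign_patrilines(dataset, grp, queen)
    list(members = grp, males = mal, queen = queen, patrilines = pat,
         contribution = length(grp) / n_total)
  })
  structure(list(matrilines = matrilines,
                 n_queens = length(matrilines),
                 unassigned_males = males[is.na(male_of)]),
            class = "matriline_partition")
}

#' @export
print.matriline_partition <- function(x, ...) {
  cat("Matriline partition:", x$n_queens, "queen(s)\n")
  for (k in seq_along(x$matrilines)) {
    m <- x$matrilines[[k]]
    cat(sprintf("  queen %d: %d females, %d males, %d father(s), contribution %.2f\n",
                k, length(m$members), length(m$males),
                m$patrilines$n_fathers, m$contribution))
  }
  if (length(x$unassigned_males)) {
    cat("  unassigned males:", paste(x$unassigned_males, collapse = ", "), "\n")
  }
  invisible(x)
}

#' Full pedigree inference for one nest
#'
#' Runs the whole reconstruction for a nest: drifter detection, matriline
#' partitioning of the remaining diploid offspring, queen and paternal
#' genotype inference, patriline counting, and the analytic error estimates
#' (paternal non-detection per matriline via [patriline_nondetection()],
#' non-sampling via [patriline_nonsampling()]).
#'
#' Individuals with a missing call at any polymorphic locus are excluded from
#' inference (and reported), mirroring analyses built on complete profiles.
#'
#' @param dataset a [colony_dataset()].
#' @param nest nest id.
#' @param max_queens maximum matrilines searched (default 3).
#' @param drifter_min_loci threshold for [detect_drifters()] (default 4).
#' @param panel [locus_panel()] with population frequencies for the error
#'   estimates; defaults to frequencies computed from the dataset
#'   (drifters excluded).
#' @param minority_fraction assumed proportion of offspring sired by a
#'   hypothetical undetected father, for the non-sampling error (default
#'   0.10).
#' @return object of class `pedigree_inference`: list with `nest`,
#'   `drifters`, `excluded_incomplete`, `partition`
#'   (a `matriline_partition`), and `errors` (data frame, one row per
#'   matriline: `n_sampled`, `mates`, `contribution`, `nondetection`,
#'   `nonsampling`).
#' @export
infer_pedigree <- function(dataset, nest, max_queens = 3,
                           drifter_min_loci = 4, panel = NULL,
                           minority_fraction = 0.10) {
  stopifnot(inherits(dataset, "colony_dataset"))
  r <- dataset$records
  if (!nest %in% r$nest) stop("nest '", nest, "' not found")
  drifters <- detect_drifters(dataset, nest, min_unique_loci = drifter_min_loci)
  incomplete <- intersect(incomplete_individuals(dataset),
                          r$id[r$nest == nest])
  sub <- r[r$nest == nest & !r$id %in% c(drifters, incomplete), ]
  females <- sub$id[sub$sex == "female"]
  males <- sub$id[sub$sex == "male"]
  part <- partition_matrilines(dataset, females, males,
                               max_queens = max_queens)
  if (is.null(panel)) {
    panel <- allele_frequencies(dataset, exclude = drifters)
  }
  errs <- do.call(rbind, lapply(seq_along(part$matrilines), function(k) {
    m <- part$matrilines[[k]]
    nd <- vapply(m$patrilines$fathers, function(f)
      patriline_nondetection(f, panel), 1.0)
    data.frame(
      matriline = k,
      n_sampled = length(m$members),
      mates = m$patrilines$n_fathers,
      contribution = m$contribution,
      nondetection = max(nd),
      nonsampling = patriline_nonsampling(length(m$members),
                                          minority_fraction)
    )
  }))
  structure(list(nest = nest, drifters = drifters,
                 excluded_incomplete = incomplete,
                 partition = part, errors = errs),
            class = "pedigree_inference")
}

#' @export
print.pedigree_inference <- function(x, ...) {
  cat("Pedigree inference for nest", x$nest, "\n")
  if (length(x$drifters)) {
    cat("  drifters:", paste(x$drifters, collapse = ", "), "\n")
  } else cat("  drifters: none\n")
  if (length(x$excluded_incomplete)) {
    cat("  excluded (incomplete profiles):",
        paste(x$excluded_incomplete, collapse = ", "), "\n")
  }
  print(x$partition)
  e <- x$errors
  for (k in seq_len(nrow(e))) {
    cat(sprintf("  queen %d: non-detection %s, non-sampling %s\n",
                k, format_percent(e$nondetection[k]),
                format_percent(e$nonsampling[k])))
  }
  invisible(x)
}
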