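test_that("locus solution enumeration matches the brute-force oracle", {
  cases <- list(
    list(f = rbind(c(1, 3), c(2, 3)), m = c(1L, 2L)),
    list(f = rbind(c(1, 1), c(1, 1)), m = integer(0)),
    list(f = rbind(c(1, 2)), m = integer(0)),
    list(f = rbind(c(1, 3), c(2, 3), c(1, 4)), m = integer(0)),
    list(f = rbind(c(1, 2), c(3, 4)), m = integer(0)),
    list(f = rbind(c(1, 2), c(1, 3), c(2, 3)), m = c(1L)),
    list(f = rbind(c(2, 2), c(2, 5), c(5, 5)), m = integer(0))
  )
  for (cs in cases) {
    got <- enumerate_locus_solutions(cs$f, cs$m)
    want <- brute_locus_solutions(cs$f, cs$m)
    expect_equal(length(got), length(want))
    if (length(want)) {
      ## same minimal father count per queen pair
      key <- function(s) paste(s$queen, collapse = "/")
      got_n <- setNames(vapply(got, `[[`, 1L, "n_fathers"),
                        vapply(got, key, ""))
      want_n <- setNames(vapply(want, `[[`, 1L, "n_fathers"),
                         vapply(want, key, ""))
      expect_mapequal(as.list(got_n), as.list(want_n))
    }
  }
})

test_that("canonical enumeration cases behave as documented", {
  ## unique solution pinned by sons
  s <- enumerate_locus_solutions(rbind(c(1, 3), c(2, 3)), c(1L, 2L))
  expect_length(s, 1)
  expect_equal(s[[1]]$queen, c(1L, 2L))
  expect_equal(s[[1]]$fathers, 3L)
  ## minimal-information homozygous case
  s2 <- enumerate_locus_solutions(rbind(c(1, 1), c(1, 1)))
  expect_equal(s2[[1]]$queen, c(1L, 1L))
  expect_equal(s2[[1]]$fathers, 1L)
  ## a single heterozygous female admits several one-father solutions
  s3 <- enumerate_locus_solutions(rbind(c(1, 2)))
  expect_gt(length(Filter(function(x) x$n_fathers == 1, s3)), 1)
  ## random parents at the published frequencies: recount oracle
  set.seed(404)
  for (r in 1:25) {
    sim <- simulate_colony(n_females = 12, seed = 9000 + r)
    for (l in polymorphic_loci(sim$dataset$panel)) {
      g <- genotypes_at(sim$dataset, l, sex = "female")
      expect_equal(enumerate_locus_solutions(g)[[1]]$n_fathers,
                   brute_min_fathers(g))
    }
  }
})

test_that("queen genotype inference recovers simulated queens", {
  hits <- 0; total <- 0
  for (r in 1:200) {
    sim <- simulate_colony(n_females = 30, seed = 20000 + r)
    q <- infer_queen_genotype(sim$dataset, sim$dataset$records$id)
    truth <- sim$truth$queens[[1]]
    for (j in seq_len(nrow(q))) {
      if (q$flag[j] == "multiple_solutions") next
      total <- total + 1
      if (identical(sort(c(q$a1[j], q$a2[j])), truth[[q$locus[j]]])) {
        hits <- hits + 1
      }
    }
  }
  expect_gte(hits / total, 0.99)
})

test_that("queen inference flags and error paths behave", {
  d <- make_dataset(females = list(list(L1 = c(1, 3)), list(L1 = c(2, 3)),
                                   list(L1 = c(1, 3))),
                    males = list(list(L1 = 1), list(L1 = 2)))
  q <- infer_queen_genotype(d, c("f01", "f02", "f03"), c("m01", "m02"),
                            loci = "L1")
  expect_equal(c(q$a1, q$a2), c(1L, 2L))
  expect_equal(q$flag, "resolved")
  ## monomorphic locus: trivially resolved homozygote
  dmono <- make_dataset(females = list(list(L3 = c(1, 1)), list(L3 = c(1, 1))))
  qm <- infer_queen_genotype(dmono, c("f01", "f02"), loci = "L3")
  expect_equal(c(qm$a1, qm$a2), c(1L, 1L))
  ## inconsistent matriline errors with the locus named
  dbad <- make_dataset(females = list(list(L1 = c(1, 2)), list(L1 = c(3, 4)),
                                      list(L1 = c(5, 6))))
  expect_error(infer_queen_genotype(dbad, c("f01", "f02", "f03"), loci = "L1"),
               "L1")
})

test_that("paternal subtraction groups females under minimal fathers", {
  d <- make_dataset(females = list(list(L1 = c(1, 3)), list(L1 = c(2, 3))))
  q <- infer_queen_genotype(d, c("f01", "f02"), loci = "L1")
  pat <- assign_patrilines(d, c("f01", "f02"), q)
  expect_equal(pat$n_fathers, 1)
  expect_equal(pat$fathers[[1]]$allele, 3L)
  ## two fathers forced
  d2 <- make_dataset(females = list(list(L1 = c(1, 3)), list(L1 = c(1, 4)),
                                    list(L1 = c(2, 3))))
  q2 <- infer_queen_genotype(d2, c("f01", "f02", "f03"), loci = "L1")
  pat2 <- assign_patrilines(d2, c("f01", "f02", "f03"), q2)
  expect_equal(pat2$n_fathers, 2)
  ## female contained in the queen pair is resolved to the pinned father
  d3 <- make_dataset(females = list(list(L1 = c(1, 1)), list(L1 = c(1, 2))))
  q3 <- infer_queen_genotype(d3, c("f01", "f02"), loci = "L1")
  expect_equal(sort(c(q3$a1, q3$a2)), c(1L, 2L))
  pat3 <- assign_patrilines(d3, c("f01", "f02"), q3)
  expect_equal(pat3$n_fathers, 1)
  expect_equal(pat3$fathers[[1]]$allele, 1L)
  expect_length(unique(pat3$assignment), 1)
})

test_that("informative locus counting matches a direct recount", {
  sim <- simulate_colony(n_females = 25, n_males = 10, seed = 303)
  inf <- infer_pedigree(sim$dataset, "N1")
  m <- inf$partition$matrilines[[1]]
  q <- m$queen
  for (f in m$patrilines$fathers) {
    k <- informative_loci(q, f)
    recount <- 0
    for (j in seq_len(nrow(f))) {
      if (f$flag[j] != "resolved") next
      jj <- which(q$locus == f$locus[j])
      if (q$flag[jj] == "multiple_solutions") next
      if (!f$allele[j] %in% c(q$a1[jj], q$a2[jj])) recount <- recount + 1
    }
    expect_equal(k, recount)
  }
  ## father allele always inside the queen pair -> zero
  q0 <- structure(data.frame(locus = c("L1", "L2"), a1 = c(1L, 2L),
                             a2 = c(2L, 3L), flag = "resolved"),
                  class = c("queen_genotype", "data.frame"))
  f0 <- data.frame(locus = c("L1", "L2"), allele = c(1L, 3L),
                   flag = "resolved")
  expect_equal(informative_loci(q0, f0), 0)
  f1 <- data.frame(locus = c("L1", "L2"), allele = c(4L, 5L),
                   flag = "resolved")
  expect_equal(informative_loci(q0, f1), 2)
})

test_that("drifter detection flags injected foreigners and respects the locus rule", {
  panel <- vespa_soror_panel()
  sim <- simulate_colony(n_females = 50, n_drifters = 1,
                         drifter_panel = private_panel(panel), seed = 88)
  expect_equal(detect_drifters(sim$dataset, "N1"), "D001")
  ## uniqueness at only 3 loci is not enough under the 4-locus rule
  base <- lapply(1:6, function(i) list(L1 = c(1, 2), L2 = c(1, 2),
                                       L4 = c(1, 2), L5 = c(1, 2)))
  odd <- list(list(L1 = c(8, 8), L2 = c(8, 8), L4 = c(8, 8), L5 = c(1, 2)))
  d <- make_dataset(females = c(base, odd))
  expect_length(detect_drifters(d, "N"), 0)
  expect_equal(detect_drifters(d, "N", min_unique_loci = 3), "f07")
  ## homogeneous single-family nest: empty set
  simh <- simulate_colony(n_females = 40, seed = 21)
  expect_length(detect_drifters(simh$dataset, "N1"), 0)
})

test_that("matriline partition recovers simulated structure", {
  ## monogynous, singly mated (the modal published outcome)
  sim <- simulate_colony(n_females = 100, seed = 17)
  part <- partition_matrilines(sim$dataset, sim$dataset$records$id)
  expect_equal(part$n_queens, 1)
  expect_equal(part$matrilines[[1]]$patrilines$n_fathers, 1)
  expect_true(verify_pedigree(sim$dataset, part))
  ## two unrelated queens, disjoint at the most polymorphic locus
  for (s in 1:10) {
    sim2 <- simulate_colony(n_females = 100, n_queens = 2,
                            contributions = c(0.85, 0.15),
                            force_disjoint_locus = "VMA-8", seed = 600 + s)
    part2 <- partition_matrilines(sim2$dataset, sim2$dataset$records$id)
    expect_equal(part2$n_queens, 2)
    expect_true(verify_pedigree(sim2$dataset, part2))
    ## contributions match the realised family sizes
    truth_prop <- sort(as.vector(table(sim2$truth$mother)) / 100)
    got_prop <- sort(vapply(part2$matrilines, `[[`, 1.0, "contribution"))
    expect_equal(got_prop, truth_prop, tolerance = 1e-9)
  }
  ## single offspring: one matriline, everything ambiguous or homozygous
  d1 <- make_dataset(females = list(list(L1 = c(1, 2))))
  p1 <- partition_matrilines(d1, "f01")
  expect_equal(p1$n_queens, 1)
  expect_true(all(p1$matrilines[[1]]$queen$flag != "resolved"))
})

test_that("polyandry is detected without inventing extra queens", {
  for (s in 1:5) {
    sim <- simulate_colony(n_females = 60, mates_per_queen = 2, seed = 430 + s)
    part <- partition_matrilines(sim$dataset, sim$dataset$records$id)
    expect_equal(part$n_queens, 1)
    expect_equal(part$matrilines[[1]]$patrilines$n_fathers, 2)
    expect_true(verify_pedigree(sim$dataset, part))
  }
})

test_that("inference is invariant to input row order", {
  sim <- simulate_colony(n_females = 40, n_queens = 2,
                         contributions = c(0.6, 0.4),
                         force_disjoint_locus = "VMA-8", seed = 55)
  ids <- sim$dataset$records$id
  part <- partition_matrilines(sim$dataset, ids)
  set.seed(1)
  shuffled <- colony_dataset(
    sim$dataset$records[sample(nrow(sim$dataset$records)), ],
    panel = sim$dataset$panel
  )
  part2 <- partition_matrilines(shuffled, sample(ids))
  expect_equal(lapply(part$matrilines, `[[`, "members"),
               lapply(part2$matrilines, `[[`, "members"))
})

test_that("full nest inference combines drifters, partition and errors", {
  panel <- vespa_soror_panel()
  sim <- simulate_colony(n_females = 50, n_males = 20, n_drifters = 2,
                         drifter_panel = private_panel(panel), seed = 99)
  inf <- infer_pedigree(sim$dataset, "N1", panel = panel)
  expect_equal(inf$drifters, c("D001", "D002"))
  expect_equal(inf$partition$n_queens, 1)
  expect_equal(inf$errors$mates, 1)
  expect_true(all(inf$errors$nondetection >= 0 & inf$errors$nondetection <= 1))
  ## males are attributed to the queen, not left over
  expect_length(inf$partition$unassigned_males, 0)
  expect_error(infer_pedigree(sim$dataset, "nope"), "not found")
})
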