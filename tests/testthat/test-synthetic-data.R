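test_that("simulation is reproducible and respects configuration flags", {
  a <- simulate_colony(n_females = 20, n_males = 5, seed = 3)
  b <- simulate_colony(n_females = 20, n_males = 5, seed = 3)
  expect_identical(a$dataset$records, b$dataset$records)
  expect_identical(a$truth$queens, b$truth$queens)
  ## no worker-derived males at rate 0
  expect_false(any(a$truth$worker_derived))
  ## worker-derived males appear at high rates
  c2 <- simulate_colony(n_females = 20, n_males = 40, worker_male_rate = 0.9,
                        seed = 4)
  expect_gt(sum(c2$truth$worker_derived), 20)
  w1 <- simulate_wings(n_workers = 5, n_gynes = 5, seed = 10)
  w2 <- simulate_wings(n_workers = 5, n_gynes = 5, seed = 10)
  expect_identical(w1$landmarks$coords, w2$landmarks$coords)
})

test_that("offspring genotypes are Mendelian-consistent with recorded parents", {
  sim <- simulate_colony(n_females = 60, n_males = 25, seed = 15)
  truth <- sim$truth
  d <- sim$dataset
  for (l in d$loci) {
    g <- genotypes_at(d, l)
    for (i in seq_along(truth$ids)) {
      id <- truth$ids[i]
      if (truth$drifter[i] || truth$worker_derived[i]) next
      q <- truth$queens[[truth$mother[i]]][[l]]
      if (d$records$sex[d$records$id == id] == "female") {
        f <- truth$fathers[[truth$mother[i]]][[truth$father[i]]][[l]]
        pair <- g[id, ]
        ok <- (pair[1] %in% q && pair[2] == f) ||
              (pair[2] %in% q && pair[1] == f)
        expect_true(ok, label = paste("female", id, "at", l))
      } else {
        expect_true(g[id, 1] %in% q, label = paste("male", id, "at", l))
      }
    }
  }
})

test_that("queen alleles segregate 1:1 and the father allele is universal", {
  panel <- locus_panel(list(L1 = c(`1` = 0.25, `2` = 0.25, `3` = 0.25,
                                   `4` = 0.25)))
  set.seed(8)
  sim <- simulate_colony(n_females = 400, panel = panel, seed = 19)
  q <- sim$truth$queens[[1]]$L1
  f <- sim$truth$fathers[[1]][[1]]$L1
  g <- genotypes_at(sim$dataset, "L1", sex = "female")
  maternal <- ifelse(g[, 1] == f, g[, 2], g[, 1])
  ## every daughter carries the father allele
  expect_true(all(g[, 1] == f | g[, 2] == f))
  if (q[1] != q[2] && !f %in% q) {
    p1 <- mean(maternal == q[1])
    ## binomial 3-sigma band around 1/2
    expect_lt(abs(p1 - 0.5), 3 * sqrt(0.25 / 400))
  }
})

test_that("large simulated populations converge to the configured frequencies", {
  panel <- locus_panel(list(L1 = c(`1` = 0.6, `2` = 0.3, `3` = 0.1)))
  sim <- simulate_colony(n_females = 2000, panel = panel, n_queens = 100,
                         mates_per_queen = 5, seed = 23)
  f <- allele_frequencies(sim$dataset, include_males = TRUE)$frequencies$L1
  for (a in names(f)) {
    p <- panel$frequencies$L1[[a]]
    ## allele copies are correlated within families; allow 3x iid sigma
    expect_lt(abs(f[[a]] - p), 3 * 3 * sqrt(p * (1 - p) / 4000))
  }
})

test_that("forced-disjoint polygyny is detectable by construction", {
  for (s in 1:10) {
    sim <- simulate_colony(n_females = 40, n_queens = 2,
                           force_disjoint_locus = "VMA-8", seed = 1200 + s)
    q1 <- sim$truth$queens[[1]]$`VMA-8`
    q2 <- sim$truth$queens[[2]]$`VMA-8`
    f1 <- sim$truth$fathers[[1]][[1]]$`VMA-8`
    f2 <- sim$truth$fathers[[2]][[1]]$`VMA-8`
    expect_length(intersect(c(q1, f1), c(q2, f2)), 0)
    part <- partition_matrilines(sim$dataset, sim$dataset$records$id)
    expect_equal(part$n_queens, 2)
  }
  ## not enough alleles for the construction -> explicit error
  small <- locus_panel(list(L1 = c(`1` = 0.5, `2` = 0.5)))
  expect_error(simulate_colony(n_females = 5, panel = small, n_queens = 2,
                               force_disjoint_locus = "L1", seed = 1),
               "alleles")
})

test_that("worker-derived sons carry the giveaway allele half the time", {
  ## queen (a,b), father f informative: a worker's son shows f w.p. 1/2
  panel <- locus_panel(list(L1 = c(`1` = 0.45, `2` = 0.45, `3` = 0.10)))
  set.seed(9)
  shows <- 0; total <- 0
  for (r in 1:40) {
    sim <- simulate_colony(n_females = 30, n_males = 30,
                           worker_male_rate = 1, panel = panel,
                           seed = 3000 + r)
    f <- sim$truth$fathers[[1]][[1]]$L1
    q <- sim$truth$queens[[1]]$L1
    if (f %in% q) next  # uninformative draw
    g <- genotypes_at(sim$dataset, "L1", sex = "male")
    wd <- sim$truth$worker_derived[match(rownames(g), sim$truth$ids)]
    shows <- shows + sum(g[wd, 1] == f)
    total <- total + sum(wd)
  }
  expect_gt(total, 200)
  expect_lt(abs(shows / total - 0.5), 3 * sqrt(0.25 / total))
})

test_that("wing simulator produces the intended caste and size structure", {
  sim <- simulate_wings(seed = 123)
  expect_equal(table(sim$truth$caste)[["worker"]], 86)
  expect_equal(table(sim$truth$caste)[["gyne"]], 45)
  ## realised centroid sizes match the drawn ln sizes exactly
  cs <- centroid_size(sim$landmarks)
  expect_equal(unname(log(cs)), sim$truth$lnCS, tolerance = 1e-9)
  ## caste offset at 5x the landmark noise separates groups in shape space
  ## (pooled over replicates so the binomial error of the rate is small)
  agree_n <- 0; total_n <- 0
  for (r in 1:5) {
    sim2 <- simulate_wings(n_workers = 40, n_gynes = 40, caste_offset = 0.05,
                           allometry_slope = 0, noise_sd = 0.01,
                           lnCS_worker = 1.09, lnCS_gyne = 1.09,
                           seed = 124 + r)
    g <- gpa(sim2$landmarks)
    sc <- shape_pca(g)$scores[, 1]
    lab <- ifelse(sc > mean(sc), "a", "b")
    hits <- max(sum(lab == ifelse(sim2$truth$caste == "gyne", "a", "b")),
                sum(lab == ifelse(sim2$truth$caste == "gyne", "b", "a")))
    agree_n <- agree_n + hits
    total_n <- total_n + 80
  }
  expect_gte(agree_n / total_n, 0.98)
})
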