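test_that("TPS files parse and round-trip", {
  tf <- withr::local_tempfile(fileext = ".tps")
  writeLines(c("LM=3", "0 0", "1 0", "0 1", "ID=tri1",
               "LM=3", "0.0 0.0", "2.0 0.0", "0.0 2.0", "IMAGE=tri2.jpg",
               "SCALE=0.5"), tf)
  lms <- read_tps(tf)
  expect_equal(dim(lms$coords), c(3, 2, 2))
  expect_equal(lms$id, c("tri1", "tri2.jpg"))
  ## SCALE honoured: second specimen halves to the first
  expect_equal(lms$coords[, , 2], lms$coords[, , 1], ignore_attr = TRUE)
  ## record with a missing coordinate line errors with the record named
  bad <- withr::local_tempfile(fileext = ".tps")
  writeLines(c("LM=3", "0 0", "1 0", "ID=oops"), bad)
  expect_error(read_tps(bad), "record 1")
  ## round trip through the writer
  sim <- simulate_wings(n_workers = 4, n_gynes = 3, seed = 8)
  out <- withr::local_tempfile(fileext = ".tps")
  write_tps(sim$landmarks, out)
  back <- read_tps(out)
  expect_equal(back$coords, sim$landmarks$coords, tolerance = 1e-6,
               ignore_attr = TRUE)
  expect_equal(back$id, sim$landmarks$id)
})

test_that("a study-sized TPS file parses record by record", {
  sim <- simulate_wings(seed = 77)  # 86 workers + 45 gynes, 19 landmarks
  f <- withr::local_tempfile(fileext = ".tps")
  write_tps(sim$landmarks, f)
  lms <- read_tps(f)
  expect_equal(dim(lms$coords), c(19, 2, 131))
})

test_that("centroid size: closed form, homogeneity, brute force", {
  sq <- rbind(c(1, 1), c(1, -1), c(-1, 1), c(-1, -1))
  expect_equal(centroid_size(sq), 2 * sqrt(2))
  set.seed(5)
  m <- matrix(rnorm(38), ncol = 2)
  expect_equal(centroid_size(3.7 * m), 3.7 * centroid_size(m))
  ## brute-force double loop over landmarks
  ctr <- colMeans(m)
  brute <- sqrt(sum(vapply(seq_len(nrow(m)), function(i)
    sum((m[i, ] - ctr)^2), 1.0)))
  expect_equal(centroid_size(m), brute)
  expect_error(centroid_size(matrix(1, 3, 2)), "coincide")
})

test_that("GPA removes rigid motion and scale", {
  sim <- simulate_wings(n_workers = 10, n_gynes = 10, seed = 14)
  g1 <- gpa(sim$landmarks)
  ## arbitrarily rotate/translate/scale one input configuration
  lms2 <- sim$landmarks
  th <- 1.234
  R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2)
  lms2$coords[, , 4] <- 5.5 * lms2$coords[, , 4] %*% R +
    matrix(c(30, -12), 19, 2, byrow = TRUE)
  g2 <- gpa(lms2)
  expect_lt(max(abs(g1$coords - g2$coords)), 1e-6)
  ## two identical shapes, one rotated and translated: distance 0
  a <- matrix(rnorm(20), ncol = 2)
  b <- a %*% R + 3
  expect_lt(procrustes_distance(a, b), 1e-12)
  ## aligned configurations are centred with unit centroid size
  for (i in seq_len(dim(g1$coords)[3])) {
    expect_lt(max(abs(colMeans(g1$coords[, , i]))), 1e-12)
    expect_equal(sum(g1$coords[, , i]^2), 1.0)
  }
  ## consensus is the coordinate-wise mean of the aligned shapes (up to its
  ## rescaling to unit centroid size)
  mn <- apply(g1$coords, c(1, 2), mean)
  expect_equal(mn / sqrt(sum(mn^2)), g1$consensus, tolerance = 1e-6,
               ignore_attr = TRUE)
})

test_that("two-shape alignment attains the closed-form optimum", {
  set.seed(6)
  for (r in 1:5) {
    a <- matrix(rnorm(16), ncol = 2)
    b <- matrix(rnorm(16), ncol = 2)
    ## closed form: ||A - BR||^2 = 2 - 2 * sum(singular values), with the
    ## smallest singular value sign-flipped if the rotation would reflect
    ca <- scale(a, scale = FALSE); ca <- ca / sqrt(sum(ca^2))
    cb <- scale(b, scale = FALSE); cb <- cb / sqrt(sum(cb^2))
    sv <- svd(crossprod(ca, cb))
    d <- sign(det(sv$u %*% t(sv$v)))
    traceform <- sum(sv$d * c(1, d))
    expect_equal(procrustes_distance(a, b), sqrt(2 - 2 * traceform),
                 tolerance = 1e-10)
    ## GPA of the pair reproduces the pairwise optimum
    g <- gpa(landmarks(list(a = a, b = b)))
    expect_equal(sqrt(sum((g$coords[, , 1] - g$coords[, , 2])^2)),
                 sqrt(2 - 2 * traceform), tolerance = 1e-6)
  }
})

test_that("rotation solution agrees with an independent implementation", {
  skip_if_not_installed("vegan")
  set.seed(33)
  a <- matrix(rnorm(24), ncol = 2)
  b <- matrix(rnorm(24), ncol = 2)
  ca <- scale(a, scale = FALSE); ca <- ca / sqrt(sum(ca^2))
  cb <- scale(b, scale = FALSE); cb <- cb / sqrt(sum(cb^2))
  v <- vegan::procrustes(ca, cb, scale = FALSE)
  ## vegan permits reflections; compare only when its rotation is proper
  if (det(v$rotation) > 0) {
    expect_equal(procrustes_distance(a, b), sqrt(sum(v$ss)),
                 tolerance = 1e-8)
  }
  succeed()
})

test_that("Procrustes ANOVA decomposition matches column-wise linear models", {
  sim <- simulate_wings(n_workers = 12, n_gynes = 12, caste_offset = 0.02,
                        allometry_slope = 0.2, seed = 41)
  g <- gpa(sim$landmarks)
  tab <- procrustes_anova(g, n_perm = 49, seed = 1)
  ## independent route: type-I SS summed over coordinate columns
  Y <- t(apply(g$coords, 3, as.vector))
  x <- log(g$csize) - mean(log(g$csize))
  grp <- factor(g$caste)
  ss <- c(size = 0, group = 0, `size:group` = 0, Residuals = 0)
  for (j in seq_len(ncol(Y))) {
    a <- stats::anova(stats::lm(Y[, j] ~ x * grp))
    ss <- ss + a$`Sum Sq`
  }
  expect_equal(unname(tab[c("size", "group", "size:group", "Residuals"), "SS"]),
               unname(ss), tolerance = 1e-8)
  ## sequential identity: components sum to the total; Rsq sums to 1
  expect_equal(sum(tab[1:4, "SS"]), tab["Total", "SS"])
  expect_equal(sum(tab[1:4, "Rsq"]), 1.0)
  expect_equal(sum(tab[1:4, "Df"]), tab["Total", "Df"])
})

test_that("Procrustes ANOVA is deterministic and detects injected allometry", {
  sim <- simulate_wings(n_workers = 15, n_gynes = 15, seed = 52)
  g <- gpa(sim$landmarks)
  t1 <- procrustes_anova(g, n_perm = 99, seed = 7)
  t2 <- procrustes_anova(g, n_perm = 99, seed = 7)
  expect_identical(t1, t2)
  ## strong allometry: size term at the permutation floor in every replicate
  hits <- 0
  for (r in 1:15) {
    simr <- simulate_wings(n_workers = 15, n_gynes = 15, caste_offset = 0,
                           allometry_slope = 0.5, noise_sd = 0.005,
                           seed = 700 + r)
    gr <- gpa(simr$landmarks)
    tr <- procrustes_anova(gr, n_perm = 199, seed = r)
    if (tr["size", "P"] <= 0.01) hits <- hits + 1
  }
  expect_gte(hits / 15, 0.95)
  ## Z is monotone with P across terms
  expect_error(procrustes_anova(g, sizes = rep(1, 30)), "constant")
})

test_that("common allometric component recovers an injected direction", {
  ## signal sd (slope x size spread) five times the landmark noise
  sim <- simulate_wings(n_workers = 100, n_gynes = 0, caste_offset = 0,
                        allometry_slope = 0.5, lnCS_sd = 0.05,
                        noise_sd = 0.005, seed = 61)
  g <- gpa(sim$landmarks)
  cc <- common_allometric_component(g)
  ## the GPA frame is rotated relative to the generating frame, so recovery
  ## is judged by the score-size correlation the injected axis induces
  expect_gte(abs(stats::cor(cc$scores, log(g$csize))), 0.95)
  expect_equal(sum(cc$direction^2), 1.0)
  ## zero-allometry data: the CAC score-size regression is descriptive and
  ## biased by axis selection, so the null check belongs to the ANOVA size
  ## term, which should reject at its nominal rate only
  rej <- 0
  for (r in 1:20) {
    sim0 <- simulate_wings(n_workers = 10, n_gynes = 10, caste_offset = 0,
                           allometry_slope = 0, noise_sd = 0.01,
                           seed = 6200 + r)
    g0 <- gpa(sim0$landmarks)
    p0 <- procrustes_anova(g0, sizes = stats::rnorm(20, 1, 0.05),
                           n_perm = 99, seed = r)["size", "P"]
    if (p0 <= 0.05) rej <- rej + 1
  }
  expect_lte(rej, 4)
  ## two identical copies of one group give the same axis as a single group
  sim0 <- simulate_wings(n_workers = 20, n_gynes = 0, caste_offset = 0,
                         allometry_slope = 0.2, noise_sd = 0.01, seed = 62)
  cfg <- lapply(1:20, function(i) sim0$landmarks$coords[, , i])
  dup <- landmarks(c(cfg, cfg))
  gd <- gpa(dup)
  cc_one <- common_allometric_component(gd, groups = rep("a", 40))
  cc_two <- common_allometric_component(gd, groups = rep(c("a", "b"), each = 20))
  expect_equal(cc_one$direction, cc_two$direction, tolerance = 1e-8)
})

test_that("shape PCA fractions are coherent", {
  sim <- simulate_wings(n_workers = 20, n_gynes = 20, seed = 71)
  g <- gpa(sim$landmarks)
  p <- shape_pca(g)
  expect_true(all(p$var_fraction >= 0))
  expect_lte(sum(p$var_fraction), 1 + 1e-9)
  ## fractions recomputed from scores match
  vf <- apply(p$scores, 2, stats::var)
  expect_equal(p$var_fraction, vf / sum(vf), tolerance = 1e-9,
               ignore_attr = TRUE)
  ## data confined to one direction: PC1 explains everything
  k <- 6
  base <- matrix(seq_len(2 * k), ncol = 2)
  dirv <- matrix(rnorm(2 * k), ncol = 2)
  configs <- lapply(seq(-1, 1, length.out = 8), function(t) base + 0.01 * t * dirv)
  gl <- gpa(landmarks(configs), tol = 1e-12)
  pl <- shape_pca(gl)
  expect_gt(pl$var_fraction[1], 0.99)
})

test_that("size-gap caste splitting finds the break", {
  sizes <- c(seq(1.00, 1.05, length.out = 8), seq(1.12, 1.20, length.out = 6))
  sp <- split_castes_by_size(sizes)
  expect_gt(sp$threshold, 1.05)
  expect_lt(sp$threshold, 1.12)
  expect_equal(as.character(sp$labels),
               c(rep("worker", 8), rep("gyne", 6)))
  ## consistent with the published fixed threshold
  spf <- split_castes_by_size(sizes, method = "fixed_threshold")
  expect_identical(sp$labels, spf$labels)
  ## bimodal recovery at >= 4 sigma separation
  set.seed(4)
  truth <- rep(c("worker", "gyne"), c(86, 45))
  ln <- c(rnorm(86, 1.04, 0.0125), rnorm(45, 1.14, 0.0125))
  spb <- split_castes_by_size(ln)
  expect_gte(mean(as.character(spb$labels) == truth), 0.98)
  expect_error(split_castes_by_size(rep(1, 5)), "no gap")
})
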