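## Landmark-based geometric morphometrics: TPS I/O, generalized Procrustes
## superimposition, Procrustes ANOVA with residual-randomization permutation
## (RRPP), common allometric component, shape PCA, and size-gap caste
## splitting.

#' Build a landmark collection
#'
#' @param coords either a `k x 2 x n` array of 2D landmark configurations or
#'   a list of `k x 2` matrices.
#' @param id specimen ids (default names of the list / dimnames, else
#'   `"spec1"`, ...).
#' @param caste optional caste labels per specimen.
#' @return object of class `landmarks`: list with `coords` (`k x 2 x n`
#'   array), `id`, `caste`.
#' @export
landmarks <- function(coords, id = NULL, caste = NULL) {
  if (is.list(coords)) {
    k <- unique(vapply(coords, nrow, 1L))
    if (length(k) != 1) stop("all configurations must share a landmark count")
    if (is.null(id)) id <- names(coords)
    coords <- array(unlist(lapply(coords, function(m) as.matrix(m))),
                    dim = c(k, 2, length(coords)))
  }
  stopifnot(is.array(coords), length(dim(coords)) == 3, dim(coords)[2] == 2)
  n <- dim(coords)[3]
  if (is.null(id)) id <- paste0("spec", seq_len(n))
  if (length(id) != n) stop("id length must match number of specimens")
  if (!is.null(caste) && length(caste) != n) {
    stop("caste length must match number of specimens")
  }
  if (!all(is.finite(coords))) stop("all coordinates must be finite")
  dimnames(coords) <- list(NULL, c("x", "y"), id)
  structure(list(coords = coords, id = as.character(id), caste = caste),
            class = "landmarks")
}

#' @export
print.landmarks <- function(x, ...) {
  d <- dim(x$coords)
  cat("Landmark collection:", d[3], "specimens x", d[1], "landmarks (2D)\n")
  if (!is.null(x$caste)) print(table(x$caste))
  invisible(x)
}

#' Read 2D landmark configurations from a TPS file
#'
#' Supports the standard TPS dialect: each record starts with `LM=k`,
#' followed by `k` coordinate lines (`x y`), then optional `IMAGE=`, `ID=`
#' and `SCALE=` keys. Coordinates are multiplied by `SCALE` when present.
#' The specimen id is taken from `ID=`, else `IMAGE=`, else the record
#' number.
#'
#' @param path TPS file path.
#' @return a [landmarks()] collection.
#' @export
read_tps <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- trimws(readLines(path))
  lines <- lines[nzchar(lines)]
  starts <- grep("^LM\\s*=", lines, ignore.case = TRUE)
  if (!length(starts)) stop("no LM= records found in ", path)
  ends <- c(starts[-1] - 1L, length(lines))
  configs <- vector("list", length(starts))
  ids <- character(length(starts))
  for (r in seq_along(starts)) {
    block <- lines[starts[r]:ends[r]]
    k <- as.integer(sub("^LM\\s*=\\s*", "", block[1], ignore.case = TRUE))
    body <- block[-1]
    is_key <- grepl("^[A-Za-z]+\\s*=", body)
    coord_lines <- body[!is_key]
    if (length(coord_lines) != k) {
      stop("record ", r, ": LM=", k, " but ", length(coord_lines),
           " coordinate lines")
    }
    xy <- do.call(rbind, lapply(strsplit(coord_lines, "\\s+"), function(p) {
      v <- suppressWarnings(as.numeric(p))
      if (length(v) != 2 || anyNA(v)) {
        stop("record ", r, ": malformed coordinate line")
      }
      v
    }))
    keys <- body[is_key]
    getkey <- function(name) {
      hit <- grep(paste0("^", name, "\\s*="), keys, ignore.case = TRUE,
                  value = TRUE)
      if (length(hit)) sub("^[A-Za-z]+\\s*=\\s*", "", hit[1]) else NA_character_
    }
    sc <- getkey("SCALE")
    if (!is.na(sc)) xy <- xy * as.numeric(sc)
    id <- getkey("ID")
    if (is.na(id)) id <- getkey("IMAGE")
    if (is.na(id)) id <- as.character(r)
    configs[[r]] <- xy
    ids[r] <- id
  }
  if (anyDuplicated(ids)) ids <- make.unique(ids)
  landmarks(configs, id = ids)
}

#' Write landmark configurations as a TPS file
#'
#' @param lms a [landmarks()] collection.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_tps <- function(lms, path) {
  stopifnot(inherits(lms, "landmarks"))
  k <- dim(lms$coords)[1]
  n <- dim(lms$coords)[3]
  con <- file(path, open = "wb")
  on.exit(close(con))
  for (i in seq_len(n)) {
    writeLines(paste0("LM=", k), con)
    m <- lms$coords[, , i]
    writeLines(sprintf("%.8f %.8f", m[, 1], m[, 2]), con)
    writeLines(paste0("ID=", lms$id[i]), con)
  }
  invisible(path)
}

#' Centroid size of a landmark configuration
#'
#' The square root of the summed squared distances of the landmarks from
#' their centroid — the standard geometric-morphometric size measure.
#'
#' @param m `k x 2` matrix (k >= 2), or a [landmarks()] collection (then a
#'   vector is returned).
#' @return positive numeric.
#' @examples
#' sq <- rbind(c(1, 1), c(1, -1), c(-1, 1), c(-1, -1))
#' centroid_size(sq)  # 2 * sqrt(2)
#' @export
centroid_size <- function(m) {
  if (inherits(m, "landmarks")) {
    return(apply(m$coords, 3, centroid_size))
  }
  m <- as.matrix(m)
  if (nrow(m) < 2) stop("need at least 2 landmarks")
  cs <- sqrt(sum(scale(m, scale = FALSE)^2))
  if (cs == 0) stop("all landmarks coincide; centroid size is 0")
  cs
}

## optimal rotation of centred config m onto centred target t, reflections
## disallowed (wings share chirality): determinant-corrected SVD
rotate_onto <- function(m, target) {
  s <- svd(crossprod(target, m))
  d <- sign(det(s$u %*% t(s$v)))
  R <- s$v %*% diag(c(1, d)) %*% t(s$u)
  m %*% R
}

#' Generalized Procrustes analysis
#'
#' Iterative superimposition removing location, scale and orientation: each
#' configuration is centred, scaled to unit centroid size, and rotated onto
#' the current consensus (orthogonal rotation via SVD of the
#' cross-covariance, reflections disallowed); the consensus is the mean of
#' the aligned configurations, rescaled to unit centroid size, and the loop
#' runs until the summed squared deviation about the consensus changes by
#' less than `tol`.
#'
#' @param lms a [landmarks()] collection with at least 2 specimens.
#' @param tol convergence tolerance on the Procrustes sum of squares
#'   (default 1e-8).
#' @param max_iter iteration cap; exceeding it is an error reporting the
#'   last residual change.
#' @return object of class `gpa`: list with `coords` (aligned `k x 2 x n`
#'   array, centred, unit centroid size), `consensus` (`k x 2`), `csize`
#'   (original centroid sizes), `id`, `caste`, `iterations`, `rss` (final
#'   summed squared deviation).
#' @export
gpa <- function(lms, tol = 1e-8, max_iter = 100) {
  stopifnot(inherits(lms, "landmarks"))
  n <- dim(lms$coords)[3]
  if (n < 2) stop("need at least 2 configurations")
  cs <- apply(lms$coords, 3, centroid_size)
  aligned <- lms$coords
  for (i in seq_len(n)) {
    m <- scale(lms$coords[, , i], scale = FALSE)
    aligned[, , i] <- m / cs[i]
  }
  consensus <- aligned[, , 1]
  rss_old <- Inf
  iter <- 0L
  repeat {
    iter <- iter + 1L
    for (i in seq_len(n)) {
      aligned[, , i] <- rotate_onto(aligned[, , i], consensus)
    }
    consensus <- apply(aligned, c(1, 2), mean)
    consensus <- consensus / sqrt(sum(consensus^2))
    rss <- sum(sweep(aligned, c(1, 2), consensus)^2)
    if (abs(rss_old - rss) < tol) break
    if (iter >= max_iter) {
      stop("GPA did not converge in ", max_iter,
           " iterations; last change ", format(abs(rss_old - rss)))
    }
    rss_old <- rss
  }
  structure(list(coords = aligned, consensus = consensus, csize = cs,
                 id = lms$id, caste = lms$caste, iterations = iter,
                 rss = rss),
            class = "gpa")
}

#' @export
print.gpa <- function(x, ...) {
  d <- dim(x$coords)
  cat(sprintf(
    "GPA: %d specimens x %d landmarks; %d iterations, Procrustes SS %.3g\n",
    d[3], d[1], x$iterations, x$rss))
  invisible(x)
}

#' Procrustes distance between two aligned configurations
#'
#' Square root of the summed squared coordinate differences after optimal
#' superimposition of the two configurations (centred, unit centroid size,
#' optimally rotated without reflection).
#'
#' @param a,b `k x 2` matrices.
#' @return nonnegative numeric.
#' @export
procrustes_distance <- function(a, b) {
  ca <- scale(as.matrix(a), scale = FALSE); ca <- ca / sqrt(sum(ca^2))
  cb <- scale(as.matrix(b), scale = FALSE); cb <- cb / sqrt(sum(cb^2))
  cb <- rotate_onto(cb, ca)
  sqrt(sum((ca - cb)^2))
}

## flatten aligned coords to an n x 2k matrix
shape_matrix <- function(g) {
  stopifnot(inherits(g, "gpa"))
  d <- dim(g$coords)
  t(apply(g$coords, 3, as.vector))
}

#' Procrustes ANOVA with residual randomization
#'
#' Sequential (type I) decomposition of the summed squared Procrustes
#' deviations for the model `shape ~ size + group + size:group`, testing
#' size (allometry) first and group (caste) after size has been accounted
#' for. F ratios use the residual mean square; significance comes from a
#' residual randomization permutation procedure (RRPP): for each term, the
#' residuals of the reduced model containing the preceding terms are
#' permuted across specimens, the statistic recomputed, and
#' `p = (#{F* >= F} + 1) / (n_perm + 1)`. The effect size Z is the
#' standardized location of the observed statistic in the permuted
#' distribution after a log transform of F (monotone in p by construction).
#'
#' @param g a [gpa()] fit.
#' @param sizes numeric covariate per specimen, conventionally ln centroid
#'   size (default `log(g$csize)`). Must not be constant.
#' @param groups factor of group (caste) labels per specimen (default
#'   `g$caste`).
#' @param n_perm number of permutations (default 999).
#' @param seed optional integer seed for the permutations.
#' @return object of class `procrustes_anova`: data frame with rows
#'   `size`, `group`, `size:group`, `Residuals`, `Total` and columns `Df`,
#'   `SS`, `MS`, `Rsq`, `F`, `Z`, `P`.
#' @export
procrustes_anova <- function(g, sizes = NULL, groups = NULL, n_perm = 999,
                             seed = NULL) {
  Y <- shape_matrix(g)
  n <- nrow(Y)
  if (is.null(sizes)) sizes <- log(g$csize)
  if (is.null(groups)) groups <- g$caste
  if (is.null(groups)) stop("no group labels supplied")
  groups <- factor(groups)
  if (length(sizes) != n || length(groups) != n) {
    stop("sizes and groups must match the number of specimens")
  }
  if (stats::var(sizes) == 0) stop("size covariate is constant")
  if (any(table(groups) < 3)) stop("need at least 3 specimens per group")
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
    set.seed(seed)
  }
  x <- sizes - mean(sizes)
  Xs <- list(
    size = stats::model.matrix(~x),
    group = stats::model.matrix(~ x + groups),
    `size:group` = stats::model.matrix(~ x * groups)
  )
  hat <- function(X) {
    q <- qr(X)
    tcrossprod(qr.Q(q)[, seq_len(q$rank), drop = FALSE])
  }
  H0 <- matrix(1 / n, n, n)  # intercept only
  H <- lapply(Xs, hat)
  Hprev <- c(list(H0), H[1:2])
  names(Hprev) <- names(Xs)
  Hfull <- H[["size:group"]]
  ssq <- function(M) sum(M^2)
  SS_term <- vapply(names(Xs), function(t)
    ssq((H[[t]] - Hprev[[t]]) %*% Y), 1.0)
  SS_res <- ssq(Y - Hfull %*% Y)
  SS_tot <- ssq(Y - H0 %*% Y)
  gN <- nlevels(groups)
  df <- c(size = 1L, group = gN - 1L, `size:group` = gN - 1L)
  df_res <- n - 2L * gN
  if (df_res < 1) stop("not enough specimens for the full model")
  MS <- SS_term / df
  MS_res <- SS_res / df_res
  Fobs <- MS / MS_res
  ## RRPP: permute reduced-model residuals; for nested hat matrices the
  ## reduced-model fit drops out of both numerator and denominator, so only
  ## the permuted residual matrix is needed
  P <- Z <- numeric(length(Fobs))
  names(P) <- names(Z) <- names(Fobs)
  IH <- diag(n) - Hfull
  for (t in names(Xs)) {
    A <- H[[t]] - Hprev[[t]]
    R <- Y - Hprev[[t]] %*% Y
    Fperm <- numeric(n_perm)
    for (b in seq_len(n_perm)) {
      Rp <- R[sample.int(n), , drop = FALSE]
      ssb <- ssq(A %*% Rp)
      ssr <- ssq(IH %*% Rp)
      Fperm[b] <- (ssb / df[[t]]) / (ssr / df_res)
    }
    P[t] <- (sum(Fperm >= Fobs[[t]]) + 1) / (n_perm + 1)
    lf <- log(Fperm[Fperm > 0])
    Z[t] <- (log(Fobs[[t]]) - mean(lf)) / stats::sd(lf)
  }
  tab <- data.frame(
    Df = c(df, Residuals = df_res, Total = n - 1L),
    SS = c(SS_term, Residuals = SS_res, Total = SS_tot),
    MS = c(MS, Residuals = MS_res, Total = NA),
    Rsq = c(SS_term / SS_tot, Residuals = SS_res / SS_tot, Total = 1),
    F = c(Fobs, Residuals = NA, Total = NA),
    Z = c(Z, Residuals = NA, Total = NA),
    P = c(P, Residuals = NA, Total = NA)
  )
  class(tab) <- c("procrustes_anova", "data.frame")
  attr(tab, "n_perm") <- n_perm
  tab
}

#' @export
print.procrustes_anova <- function(x, ...) {
  y <- as.data.frame(x)
  y$SS <- signif(y$SS, 5); y$MS <- signif(y$MS, 5)
  y$Rsq <- round(y$Rsq, 5); y$F <- round(y$F, 3); y$Z <- round(y$Z, 2)
  print(y)
  cat("P from", attr(x, "n_perm"), "residual-randomization permutations\n")
  invisible(x)
}

#' Common allometric component
#'
#' One-dimensional summary of allometry: the normalized direction of the
#' regression of (group-mean-centred) shape on the size covariate. Each
#' specimen's CAC score is the projection of its centred shape onto that
#' axis; per-group least-squares lines of score on size are returned for
#' plotting, and allometry shows as slopes different from zero.
#'
#' @param g a [gpa()] fit.
#' @param sizes size covariate (default ln centroid size).
#' @param groups optional group labels; when given, shape and size are
#'   centred within group before estimating the common direction.
#' @return object of class `cac`: list with `direction` (unit vector, length
#'   2k), `scores` (per specimen), `sizes`, `groups`, `slopes` (data frame
#'   with per-group intercept and slope of score ~ size).
#' @export
common_allometric_component <- function(g, sizes = NULL, groups = NULL) {
  Y <- shape_matrix(g)
  n <- nrow(Y)
  if (is.null(sizes)) sizes <- log(g$csize)
  if (is.null(groups)) groups <- g$caste
  if (stats::var(sizes) == 0) stop("size covariate has zero variance")
  if (!is.null(groups)) {
    groups <- factor(groups)
    Yc <- Y
    xc <- sizes
    for (lv in levels(groups)) {
      i <- groups == lv
      Yc[i, ] <- sweep(Y[i, , drop = FALSE], 2, colMeans(Y[i, , drop = FALSE]))
      xc[i] <- sizes[i] - mean(sizes[i])
    }
  } else {
    Yc <- sweep(Y, 2, colMeans(Y))
    xc <- sizes - mean(sizes)
  }
  b <- crossprod(Yc, xc) / sum(xc^2)
  dir <- as.vector(b) / sqrt(sum(b^2))
  scores <- as.vector(sweep(Y, 2, colMeans(Y)) %*% dir)
  slopes <- if (!is.null(groups)) {
    do.call(rbind, lapply(levels(groups), function(lv) {
      i <- groups == lv
      cf <- stats::coef(stats::lm(scores[i] ~ sizes[i]))
      data.frame(group = lv, intercept = cf[1], slope = cf[2],
                 row.names = NULL)
    }))
  } else {
    cf <- stats::coef(stats::lm(scores ~ sizes))
    data.frame(group = "all", intercept = cf[1], slope = cf[2],
               row.names = NULL)
  }
  structure(list(direction = dir, scores = scores, sizes = sizes,
                 groups = groups, slopes = slopes),
            class = "cac")
}

#' @export
plot.cac <- function(x, xlab = "ln centroid size", ylab = "CAC score", ...) {
  col <- if (!is.null(x$groups)) as.integer(factor(x$groups)) else 1
  graphics::plot(x$sizes, x$scores, col = col, pch = 19, xlab = xlab,
                 ylab = ylab, ...)
  for (i in seq_len(nrow(x$slopes))) {
    graphics::abline(x$slopes$intercept[i], x$slopes$slope[i], col = i)
  }
  invisible(x)
}

#' Principal component analysis of aligned shapes
#'
#' Eigen-decomposition of the covariance of the aligned coordinates;
#' explained-variance fractions per component sum to at most 1 (exactly 1
#' over all non-null components).
#'
#' @param g a [gpa()] fit with at least 3 specimens.
#' @return object of class `shape_pca`: list with `scores` (n x p), `sdev`,
#'   `var_fraction`, `rotation`.
#' @export
shape_pca <- function(g) {
  Y <- shape_matrix(g)
  if (nrow(Y) < 3) stop("need at least 3 specimens")
  p <- stats::prcomp(Y, center = TRUE)
  structure(list(scores = p$x, sdev = p$sdev,
                 var_fraction = p$sdev^2 / sum(p$sdev^2),
                 rotation = p$rotation),
            class = "shape_pca")
}

#' @export
print.shape_pca <- function(x, ...) {
  vf <- round(100 * x$var_fraction[seq_len(min(5, length(x$var_fraction)))])
  cat("Shape PCA:", ncol(x$scores), "components; leading variance %:",
      paste(vf, collapse = ", "), "\n")
  invisible(x)
}

#' Split females into castes by a size gap
#'
#' Workers and gynes form two clusters of ln centroid size; the split is
#' either at a supplied fixed threshold (1.09 for the published hornet
#' wings) or data-driven at the widest gap between consecutive sorted
#' values. Small specimens are labelled `"worker"`, large `"gyne"`.
#'
#' @param ln_sizes numeric vector of ln centroid sizes (>= 2 values).
#' @param method `"largest_gap"` (default) or `"fixed_threshold"`.
#' @param threshold cut point for `"fixed_threshold"` (default 1.09).
#' @return list with `labels` (factor worker/gyne), `threshold` (the cut
#'   used; for `largest_gap`, the gap midpoint), `gap` (gap width, largest
#'   gap only).
#' @export
split_castes_by_size <- function(ln_sizes,
                                 method = c("largest_gap", "fixed_threshold"),
                                 threshold = 1.09) {
  method <- match.arg(method)
  if (length(ln_sizes) < 2) stop("need at least 2 specimens")
  if (method == "largest_gap") {
    s <- sort(ln_sizes)
    gaps <- diff(s)
    if (max(gaps) == 0) stop("all sizes equal; no gap to split at")
    i <- which.max(gaps)
    threshold <- (s[i] + s[i + 1]) / 2
    gap <- gaps[i]
  } else {
    gap <- NA_real_
  }
  labels <- factor(ifelse(ln_sizes > threshold, "gyne", "worker"),
                   levels = c("worker", "gyne"))
  list(labels = labels, threshold = threshold, gap = gap)
}
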