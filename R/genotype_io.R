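#' Construct a microsatellite locus panel
#'
#' A locus panel holds the loci scored in a study together with their known
#' alleles and (optionally) population allele frequencies. Alleles are integer
#' fragment lengths in base pairs; arbitrary string labels are accepted and
#' mapped to integers stably (by sorted order of the labels).
#'
#' @param frequencies named list, one element per locus, each a named numeric
#'   vector of allele frequencies (names are allele labels). Per-locus
#'   frequencies must be nonnegative and sum to 1 within `1e-9`.
#' @return an object of class `locus_panel` with elements `loci` (character),
#'   `alleles` (named list of sorted integer vectors) and `frequencies`
#'   (named list of named numeric vectors, names are allele values).
#' @examples
#' locus_panel(list(L1 = c(`100` = 0.6, `104` = 0.4)))
#' @export
locus_panel <- function(frequencies) {
  if (!is.list(frequencies) || is.null(names(frequencies)) ||
      any(!nzchar(names(frequencies)))) {
    stop("'frequencies' must be a named list with one element per locus")
  }
  loci <- names(frequencies)
  freqs <- lapply(loci, function(l) {
    f <- frequencies[[l]]
    if (is.null(names(f)) || any(!nzchar(names(f)))) {
      stop("allele frequencies for locus '", l, "' must be named by allele")
    }
    if (any(f < 0)) stop("negative allele frequency at locus '", l, "'")
    if (abs(sum(f) - 1) > 1e-9) {
      stop("allele frequencies at locus '", l, "' sum to ", format(sum(f)),
           ", not 1")
    }
    names(f) <- as.character(as_allele(names(f)))
    f[order(as.integer(names(f)))]
  })
  names(freqs) <- loci
  structure(
    list(
      loci = loci,
      alleles = lapply(freqs, function(f) as.integer(names(f))),
      frequencies = freqs
    ),
    class = "locus_panel"
  )
}

#' @export
print.locus_panel <- function(x, ...) {
  cat("Locus panel:", length(x$loci), "loci\n")
  for (l in x$loci) {
    k <- length(x$alleles[[l]])
    cat(sprintf("  %-10s %d allele%s", l, k, if (k == 1) "" else "s"))
    cat(" (", paste(x$alleles[[l]], collapse = ", "), ")\n", sep = "")
  }
  invisible(x)
}

#' Which loci of a panel are polymorphic?
#'
#' A locus is polymorphic iff it has at least two known alleles.
#'
#' @param panel a [locus_panel()].
#' @return character vector of polymorphic locus names.
#' @export
polymorphic_loci <- function(panel) {
  stopifnot(inherits(panel, "locus_panel"))
  panel$loci[vapply(panel$alleles, length, 1L) >= 2]
}

## Map allele labels to integers: numeric labels pass through; other strings
## are mapped by rank among the sorted unique labels (stable, documented).
as_allele <- function(x) {
  x <- as.character(x)
  n <- suppressWarnings(as.integer(x))
  if (!anyNA(n[!is.na(x) & nzchar(x)])) return(n)
  u <- sort(unique(x))
  match(x, u)
}

#' Assemble a colony genotype dataset
#'
#' The central container for genotype data: one row per individual with its
#' nest, sex, caste, and two allele columns per locus (`<locus>.1`,
#' `<locus>.2`). Haploid males carry their single allele in `<locus>.1` and
#' `NA` in `<locus>.2` (this `NA` is structural, not missing data). Missing
#' calls for diploid females are `NA` in either slot and are tracked, never
#' silently dropped.
#'
#' @param records data frame with columns `id`, `nest`, `sex` (`"female"` or
#'   `"male"`), `caste` (`"worker"`, `"gyne"`, `"male"` or `"unknown"`), and
#'   two integer columns `<locus>.1`/`<locus>.2` per locus.
#' @param panel optional [locus_panel()]; if `NULL`, a panel is built from the
#'   alleles observed in `records` (without frequencies beyond observed
#'   proportions).
#' @return an object of class `colony_dataset` with elements `records`
#'   (validated data frame) and `panel`.
#' @seealso [read_genotypes()], [write_genotypes()]
#' @export
colony_dataset <- function(records, panel = NULL) {
  stopifnot(is.data.frame(records))
  meta <- c("id", "nest", "sex", "caste")
  if (!all(meta %in% names(records))) {
    stop("records must have columns ", paste(meta, collapse = ", "))
  }
  records$id <- as.character(records$id)
  records$nest <- as.character(records$nest)
  records$sex <- as.character(records$sex)
  records$caste <- as.character(records$caste)
  if (anyDuplicated(records$id)) {
    stop("duplicated individual ids: ",
         paste(unique(records$id[duplicated(records$id)]), collapse = ", "))
  }
  if (!all(records$sex %in% c("female", "male"))) {
    stop("sex must be 'female' or 'male'")
  }
  if (!all(records$caste %in% c("worker", "gyne", "male", "unknown"))) {
    stop("caste must be worker, gyne, male or unknown")
  }
  allele_cols <- setdiff(names(records), meta)
  loci <- locus_names_from_columns(allele_cols)
  for (l in loci) {
    records[[paste0(l, ".1")]] <- as.integer(records[[paste0(l, ".1")]])
    records[[paste0(l, ".2")]] <- as.integer(records[[paste0(l, ".2")]])
  }
  ## canonical order within diploid pairs
  for (l in loci) {
    a <- records[[paste0(l, ".1")]]
    b <- records[[paste0(l, ".2")]]
    fem <- records$sex == "female"
    swap <- fem & !is.na(a) & !is.na(b) & a > b
    tmp <- a[swap]; a[swap] <- b[swap]; b[swap] <- tmp
    if (any(records$sex == "male" & !is.na(b))) {
      stop("male rows must carry a single allele per locus (locus ", l, ")")
    }
    records[[paste0(l, ".1")]] <- a
    records[[paste0(l, ".2")]] <- b
  }
  if (is.null(panel)) {
    panel <- panel_from_records(records, loci)
  } else {
    stopifnot(inherits(panel, "locus_panel"))
    if (!all(loci %in% panel$loci)) {
      stop("records contain loci absent from the panel: ",
           paste(setdiff(loci, panel$loci), collapse = ", "))
    }
  }
  rownames(records) <- NULL
  ## cache per-locus genotype matrices: the inference code indexes these
  ## heavily
  geno <- lapply(loci, function(l) {
    m <- cbind(a1 = records[[paste0(l, ".1")]],
               a2 = records[[paste0(l, ".2")]])
    rownames(m) <- records$id
    m
  })
  names(geno) <- loci
  structure(list(records = records, panel = panel, loci = loci, geno = geno),
            class = "colony_dataset")
}

locus_names_from_columns <- function(cols) {
  if (length(cols) == 0) stop("no allele columns found")
  hits <- grepl("\\.[12]$", cols)
  if (!all(hits)) {
    stop("allele columns must be named <locus>.1/<locus>.2; offending: ",
         paste(cols[!hits], collapse = ", "))
  }
  loci <- unique(sub("\\.[12]$", "", cols))
  miss <- c(paste0(loci, ".1"), paste0(loci, ".2"))
  miss <- miss[!miss %in% cols]
  if (length(miss)) stop("missing allele columns: ", paste(miss, collapse = ", "))
  loci
}

panel_from_records <- function(records, loci) {
  freqs <- lapply(loci, function(l) {
    a <- c(records[[paste0(l, ".1")]], records[[paste0(l, ".2")]])
    a <- a[!is.na(a)]
    if (length(a) == 0) stop("no alleles observed at locus ", l)
    tab <- table(a)
    f <- as.numeric(tab) / sum(tab)
    names(f) <- names(tab)
    f
  })
  names(freqs) <- loci
  locus_panel(freqs)
}

#' @export
print.colony_dataset <- function(x, ...) {
  r <- x$records
  cat("Colony dataset:", nrow(r), "individuals,",
      length(unique(r$nest)), "nest(s),", length(x$loci), "loci\n")
  for (n in unique(r$nest)) {
    sub <- r[r$nest == n, ]
    cat(sprintf("  %s: %d females, %d males\n", n,
                sum(sub$sex == "female"), sum(sub$sex == "male")))
  }
  invisible(x)
}

#' Genotypes of one nest at one locus
#'
#' Internal-facing accessor used throughout the inference code.
#'
#' @param dataset a [colony_dataset()].
#' @param locus locus name.
#' @param nest optional nest id; default all nests.
#' @param sex optional `"female"`/`"male"` filter.
#' @return matrix with columns `a1`, `a2` and rownames = individual ids
#'   (males have `NA` in `a2`).
#' @export
genotypes_at <- function(dataset, locus, nest = NULL, sex = NULL) {
  stopifnot(inherits(dataset, "colony_dataset"))
  if (!locus %in% dataset$loci) stop("locus '", locus, "' not in dataset")
  m <- dataset$geno[[locus]]
  keep <- rep(TRUE, nrow(m))
  if (!is.null(nest)) {
    if (!nest %in% dataset$records$nest) stop("nest '", nest, "' not found")
    keep <- keep & dataset$records$nest == nest
  }
  if (!is.null(sex)) keep <- keep & dataset$records$sex == sex
  m[keep, , drop = FALSE]
}

#' Individuals with incomplete genotypes
#'
#' Lists individuals missing a call at any polymorphic locus. By default the
#' inference functions exclude these individuals, mirroring analyses built on
#' complete multilocus profiles.
#'
#' @param dataset a [colony_dataset()].
#' @return character vector of individual ids.
#' @export
incomplete_individuals <- function(dataset) {
  r <- dataset$records
  poly <- polymorphic_loci(dataset$panel)
  poly <- intersect(poly, dataset$loci)
  bad <- rep(FALSE, nrow(r))
  for (l in poly) {
    a1 <- r[[paste0(l, ".1")]]
    a2 <- r[[paste0(l, ".2")]]
    bad <- bad | is.na(a1) | (r$sex == "female" & is.na(a2))
  }
  r$id[bad]
}

#' Read a codominant genotype table
#'
#' Two dialects are supported. `"two_column"` is a GenAlEx-style wide layout:
#' columns `id`, `nest`, `sex`, `caste`, then two columns per locus named
#' `<locus>.1` and `<locus>.2` (a single `<locus>` column containing `"a/b"`
#' strings is also accepted). `"long"` has one row per individual x locus with
#' columns `id`, `nest`, `sex`, `caste`, `locus`, `allele1`, `allele2`.
#' Missing calls are written as `0` or left blank. Male rows may duplicate
#' their single allele across both columns or leave the second blank; they are
#' normalised to single-allele genotypes.
#'
#' @param path path to a comma- or tab-separated text file (separator sniffed
#'   from the header line).
#' @param dialect `"two_column"` (default) or `"long"`.
#' @param panel optional [locus_panel()] to validate against.
#' @return a [colony_dataset()].
#' @export
read_genotypes <- function(path, dialect = c("two_column", "long"),
                           panel = NULL) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("file not found: ", path)
  header <- readLines(path, n = 1L)
  sep <- if (grepl("\t", header)) "\t" else ","
  tab <- utils::read.table(path, header = TRUE, sep = sep,
                           colClasses = "character", check.names = FALSE,
                           stringsAsFactors = FALSE)
  meta <- c("id", "nest", "sex", "caste")
  if (dialect == "long") {
    need <- c(meta, "locus", "allele1", "allele2")
    if (!all(need %in% names(tab))) {
      stop("malformed header for long dialect; need columns ",
           paste(need, collapse = ", "))
    }
    loci <- unique(tab$locus)
    ind <- unique(tab[meta])
    wide <- ind
    for (l in loci) {
      sub <- tab[tab$locus == l, ]
      i <- match(wide$id, sub$id)
      wide[[paste0(l, ".1")]] <- sub$allele1[i]
      wide[[paste0(l, ".2")]] <- sub$allele2[i]
    }
    tab <- wide
  } else {
    if (!all(meta %in% names(tab))) {
      stop("malformed header: need columns ", paste(meta, collapse = ", "))
    }
    acols <- setdiff(names(tab), meta)
    ## single column per locus with "a/b" strings -> split
    slash <- acols[!grepl("\\.[12]$", acols)]
    for (l in slash) {
      v <- tab[[l]]
      parts <- strsplit(v, "/", fixed = TRUE)
      tab[[paste0(l, ".1")]] <- vapply(parts, function(p) if (length(p) >= 1) p[[1]] else "", "")
      tab[[paste0(l, ".2")]] <- vapply(parts, function(p) if (length(p) >= 2) p[[2]] else "", "")
      tab[[l]] <- NULL
    }
  }
  loci <- locus_names_from_columns(setdiff(names(tab), meta))
  for (l in loci) {
    for (s in c(".1", ".2")) {
      col <- paste0(l, s)
      v <- trimws(tab[[col]])
      v[v == "" | v == "0" | toupper(v) == "NA"] <- NA
      tab[[col]] <- suppressWarnings(as.integer(v))
    }
  }
  ## normalise males: duplicated allele -> single slot
  for (l in loci) {
    male <- tab$sex == "male"
    a1 <- tab[[paste0(l, ".1")]]
    a2 <- tab[[paste0(l, ".2")]]
    two <- male & !is.na(a2) & !is.na(a1) & a1 != a2
    if (any(two)) {
      stop("male row(s) with two distinct alleles at locus ", l, ": ",
           paste(tab$id[two], collapse = ", "))
    }
    a2[male] <- NA_integer_
    tab[[paste0(l, ".2")]] <- a2
    ## female with a single allele and no missing marker is a validation error
    fem_bad <- tab$sex == "female" & xor(is.na(a1), is.na(tab[[paste0(l, ".2")]]))
    if (any(fem_bad)) {
      stop("female row(s) with one allele at locus ", l, ": ",
           paste(tab$id[fem_bad], collapse = ", "))
    }
  }
  colony_dataset(tab, panel = panel)
}

#' Write a colony dataset as a canonical genotype table
#'
#' Output is the two-column-per-locus layout of [read_genotypes()], comma
#' separated, with alleles sorted within each diploid pair, males written with
#' a blank second column, and missing calls written as `0`. Byte output is
#' deterministic for a fixed dataset, so `read_genotypes(write_genotypes(x))`
#' round-trips.
#'
#' @param dataset a [colony_dataset()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_genotypes <- function(dataset, path) {
  stopifnot(inherits(dataset, "colony_dataset"))
  r <- dataset$records
  loci <- dataset$loci
  cols <- c("id", "nest", "sex", "caste",
            as.vector(rbind(paste0(loci, ".1"), paste0(loci, ".2"))))
  out <- r[cols]
  for (l in loci) {
    for (s in c(".1", ".2")) {
      v <- out[[paste0(l, s)]]
      ch <- ifelse(is.na(v), "0", as.character(v))
      ## structural NA of male second slot -> blank, not 0
      if (s == ".2") ch[r$sex == "male"] <- ""
      out[[paste0(l, s)]] <- ch
    }
  }
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(paste(cols, collapse = ","), con)
  lines <- do.call(paste, c(unname(as.list(out)), list(sep = ",")))
  if (length(lines)) writeLines(lines, con)
  invisible(path)
}
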