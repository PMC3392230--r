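## Binary-trait (sex) single-marker LOD scan on phase-known four-way
## genotype classes, with genome-wide permutation thresholds, 1.5-LOD
## support intervals, haplotype-by-sex tables and Fisher's exact test.

#' Binary-trait LOD score at one marker
#'
#' Likelihood-ratio LOD for sex (male/female) against genotype classes:
#' the alternative fits one penetrance per class,
#' `p_g = m_g / (m_g + f_g)`, the null a single pooled penetrance
#' `M / (M + F)`; `LOD = log10(L1 / L0)` with the `0 log 0 = 0`
#' convention. Missing class labels or sexes are dropped pairwise.
#'
#' @param marker_classes per-individual genotype class labels (any atomic
#'   vector; `NA` = missing).
#' @param sexes per-individual `"male"` / `"female"` labels.
#' @return list with `lod`, `penetrance` (named per-class estimates) and
#'   `counts` (class x sex matrix).
#' @export
binary_lod <- function(marker_classes, sexes) {
  check_that(length(marker_classes) == length(sexes),
             "marker_classes and sexes must have equal length")
  ok <- !is.na(marker_classes) & sexes %in% c("male", "female")
  cl <- as.character(marker_classes[ok])
  male <- sexes[ok] == "male"
  check_that(length(cl) > 0, "no informative individuals")
  m <- tapply(male, cl, sum)
  f <- tapply(!male, cl, sum)
  if (length(m) < 2) {
    warning("only one genotype class present; LOD = 0")
    return(list(lod = 0,
                penetrance = stats::setNames(sum(male) / length(male),
                                             names(m)),
                counts = cbind(male = m, female = f)))
  }
  ll1 <- sum(xlogx(m) + xlogx(f) - xlogx(m + f))
  M <- sum(m); F <- sum(f)
  ll0 <- xlogx(M) + xlogx(F) - xlogx(M + F)
  list(lod = (ll1 - ll0) / log(10),
       penetrance = stats::setNames(as.vector(m / (m + f)), names(m)),
       counts = cbind(male = m, female = f))
}

## Vectorised LOD engine: class_matrix is markers x individuals (small
## integer codes, NA = missing); sex01 is individuals x P (columns are
## 0/1 male indicator vectors, one per permutation). Returns markers x P
## LOD matrix. Same likelihood as binary_lod, evaluated with four
## indicator-matrix BLAS products per class code.
lod_engine <- function(class_matrix, sex01) {
  sex01 <- as.matrix(sex01)
  codes <- sort(unique(as.vector(class_matrix[!is.na(class_matrix)])))
  nM <- nrow(class_matrix)
  P <- ncol(sex01)
  ll1 <- matrix(0, nM, P)
  Mtot <- matrix(0, nM, P)
  Ntot <- matrix(0, nM, P)
  ones <- rep(1, nrow(sex01))
  for (k in codes) {
    I <- (class_matrix == k) & !is.na(class_matrix)
    storage.mode(I) <- "double"
    mk <- I %*% sex01                 # males in class k, per permutation
    nk <- as.vector(I %*% ones)       # class-k individuals (perm-free)
    ll1 <- ll1 + xlogx(mk) + xlogx(nk - mk) - xlogx(matrix(nk, nM, P))
    Mtot <- Mtot + mk
    Ntot <- Ntot + nk
  }
  ll0 <- xlogx(Mtot) + xlogx(Ntot - Mtot) - xlogx(Ntot)
  (ll1 - ll0) / log(10)
}

#' Genome-wide permutation thresholds for the binary LOD scan
#'
#' Shuffles the sex vector among individuals (genotype correlation
#' structure preserved), records the genome-wide maximum LOD of each
#' permutation, and returns upper quantiles (type-7 linear interpolation)
#' as significance thresholds.
#'
#' @param class_matrix markers x individuals matrix of genotype class
#'   codes (e.g. from [fourway_classes()]).
#' @param sexes per-individual `"male"` / `"female"` labels.
#' @param n_perm number of permutations (>= 100; default 10000).
#' @param quantiles quantiles to report (default 0.95 and 0.90, i.e. the
#'   5% and 10% genome-wide thresholds).
#' @param seed integer seed (required for reproducibility).
#' @param block permutations per BLAS block (memory knob).
#' @return list with `thresholds` (named numeric) and `max_lods` (the
#'   permutation null sample).
#' @export
permutation_threshold <- function(class_matrix, sexes, n_perm = 10000,
                                  quantiles = c(0.95, 0.90), seed = 1L,
                                  block = 1000L) {
  check_that(n_perm >= 100, "n_perm must be >= 100 (unstable quantiles)")
  set.seed(seed)
  sex01 <- as.numeric(sexes == "male")
  n <- length(sex01)
  max_lods <- numeric(n_perm)
  done <- 0L
  while (done < n_perm) {
    b <- min(block, n_perm - done)
    S <- vapply(seq_len(b), function(i) sex01[sample.int(n)], numeric(n))
    lods <- lod_engine(class_matrix, S)
    max_lods[done + seq_len(b)] <- apply(lods, 2, max)
    done <- done + b
  }
  thr <- stats::quantile(max_lods, probs = quantiles, type = 7)
  names(thr) <- sprintf("%g%%", 100 * (1 - quantiles))
  list(thresholds = thr, max_lods = max_lods)
}

#' 1.5-LOD support intervals around scan peaks
#'
#' For each chromosome whose peak LOD exceeds `threshold`, the interval
#' extends from the peak in both directions to the outermost marker with
#' `LOD >= peak - drop`, then one marker beyond (conservative flanking
#' marker) unless the chromosome end is reached first.
#'
#' @param scan `data.frame` with `chrom`, `cM`, `pos_bp`, `lod`, in map
#'   order.
#' @param drop LOD drop defining the support interval (default 1.5).
#' @param threshold only chromosomes with peak LOD above this enter the
#'   list (default 0).
#' @return `data.frame` of intervals: `chrom`, `peak_marker`, `peak_lod`,
#'   `cM_lo`, `cM_hi`, `bp_lo`, `bp_hi`; empty if no peak qualifies.
#' @export
lod_support_interval <- function(scan, drop = 1.5, threshold = 0) {
  out <- list()
  for (ch in unique(scan$chrom)) {
    s <- scan[scan$chrom == ch, , drop = FALSE]
    pk <- which.max(s$lod)
    if (s$lod[pk] <= threshold) next
    cut <- s$lod[pk] - drop
    keep <- s$lod >= cut
    lo <- pk
    while (lo > 1 && keep[lo - 1]) lo <- lo - 1
    hi <- pk
    while (hi < nrow(s) && keep[hi + 1]) hi <- hi + 1
    lo <- max(1L, lo - 1L)          # one flanking marker beyond
    hi <- min(nrow(s), hi + 1L)
    out[[ch]] <- data.frame(
      chrom = ch,
      peak_marker = s$marker_id[pk], peak_lod = s$lod[pk],
      cM_lo = s$cM[lo], cM_hi = s$cM[hi],
      bp_lo = s$pos_bp[lo], bp_hi = s$pos_bp[hi],
      stringsAsFactors = FALSE)
  }
  if (length(out) == 0) {
    return(data.frame(chrom = character(), peak_marker = character(),
                      peak_lod = numeric(), cM_lo = numeric(),
                      cM_hi = numeric(), bp_lo = numeric(),
                      bp_hi = numeric(), stringsAsFactors = FALSE))
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Binary-trait LOD scan with permutation thresholds
#'
#' Runs the single-marker binary LOD over every marker, determines
#' genome-wide permutation thresholds, and reports 1.5-LOD support
#' intervals for chromosomes exceeding the 5% threshold.
#'
#' @param geno a `radsex_geno` object, or a markers x individuals class
#'   matrix (then `map` is required).
#' @param sheet sample-sheet `data.frame` aligned with the genotype
#'   columns; unknown-sex individuals are dropped.
#' @param map genetic map `data.frame` (defaults to `geno$map`).
#' @param n_perm number of permutations (default 1000).
#' @param seed integer seed.
#' @param drop LOD drop for support intervals (default 1.5).
#' @return an object of class `lodscan`: list with `scan` (per-marker
#'   `marker_id`, `chrom`, `pos_bp`, `cM`, `lod`), `thresholds`,
#'   `intervals`, `max_lods`, `penetrance` (markers x classes estimates).
#' @export
run_lodscan <- function(geno, sheet, map = NULL, n_perm = 1000, seed = 1L,
                        drop = 1.5) {
  if (inherits(geno, "radsex_geno")) {
    classes <- fourway_classes(geno)
    if (is.null(map)) map <- geno$map
  } else {
    classes <- geno
    check_that(!is.null(map), "map is required with a raw class matrix")
  }
  keep <- sheet$sex %in% c("male", "female")
  sheet <- sheet[keep, , drop = FALSE]
  idx <- match(sheet$sample_id, colnames(classes))
  check_that(!anyNA(idx), "sample sheet and genotype columns disagree")
  classes <- classes[, idx, drop = FALSE]
  sexes <- sheet$sex
  sex01 <- matrix(as.numeric(sexes == "male"), ncol = 1)
  lods <- as.vector(lod_engine(classes, sex01))
  ## per-class penetrance estimates
  codes <- sort(unique(as.vector(classes[!is.na(classes)])))
  pen <- sapply(codes, function(k) {
    I <- (classes == k) & !is.na(classes)
    mk <- as.vector(I %*% sex01)
    nk <- rowSums(I)
    ifelse(nk > 0, mk / nk, NA_real_)
  })
  colnames(pen) <- paste0("class", codes)

  pt <- permutation_threshold(classes, sexes, n_perm = n_perm,
                              seed = seed)
  scan <- data.frame(
    marker_id = map$marker_id, chrom = map$chrom, pos_bp = map$pos_bp,
    cM = (map$cM_female + map$cM_male) / 2,  # sex-averaged position
    lod = lods, stringsAsFactors = FALSE)
  intervals <- lod_support_interval(scan, drop = drop,
                                    threshold = pt$thresholds[[1]])
  structure(list(scan = scan, thresholds = pt$thresholds,
                 intervals = intervals, max_lods = pt$max_lods,
                 penetrance = pen, n_perm = n_perm, seed = seed),
            class = "lodscan")
}

#' @export
print.lodscan <- function(x, ...) {
  pk <- which.max(x$scan$lod)
  cat(sprintf("Binary-trait LOD scan: %d markers, %d permutations\n",
              nrow(x$scan), x$n_perm))
  cat(sprintf("  peak LOD %.2f at %s (%s, %.1f cM)\n", x$scan$lod[pk],
              x$scan$marker_id[pk], x$scan$chrom[pk], x$scan$cM[pk]))
  cat(sprintf("  genome-wide thresholds: %s\n",
              paste(sprintf("%s = %.2f", names(x$thresholds),
                            x$thresholds), collapse = ", ")))
  if (nrow(x$intervals))
    cat(sprintf("  %d support interval(s): %s\n", nrow(x$intervals),
                paste(sprintf("%s %.1f-%.1f cM", x$intervals$chrom,
                              x$intervals$cM_lo, x$intervals$cM_hi),
                      collapse = "; ")))
  invisible(x)
}

#' @export
summary.lodscan <- function(object, ...) {
  print(object)
  sig <- object$scan$lod > object$thresholds[[1]]
  cat(sprintf("  markers above the %s threshold: %d on %s\n",
              names(object$thresholds)[1], sum(sig),
              paste(unique(object$scan$chrom[sig]), collapse = ", ")))
  invisible(object)
}

#' @export
plot.lodscan <- function(x, ...) {
  chroms <- unique(x$scan$chrom)
  off <- stats::setNames(
    cumsum(c(0, vapply(chroms, function(ch)
      max(x$scan$cM[x$scan$chrom == ch]) + 5, numeric(1))))[
        seq_along(chroms)], chroms)
  gx <- x$scan$cM + off[x$scan$chrom]
  plot(gx, x$scan$lod, type = "l", xlab = "map position (cM)",
       ylab = "LOD", ...)
  graphics::abline(h = x$thresholds[1], col = "red")
  graphics::abline(h = x$thresholds[2], col = "grey")
  invisible(x)
}

#' Haplotype-by-sex contingency table
#'
#' Cross-tabulates single-marker genotype classes, or the joint classes
#' of two markers, against sex, and reports the percent male per class.
#' Classes with no individuals are omitted with a note.
#'
#' @param classes1 per-individual class labels at the first marker.
#' @param sexes per-individual `"male"` / `"female"` labels.
#' @param classes2 optional class labels at a second marker (joint
#'   two-locus table).
#' @return `data.frame` of class `haplo_sex_table`: `class`, `n_male`,
#'   `n_female`, `percent_male`.
#' @export
haplotype_sex_table <- function(classes1, sexes, classes2 = NULL) {
  key <- if (is.null(classes2)) as.character(classes1) else
    paste(classes1, classes2, sep = ":")
  ok <- !is.na(key) & sexes %in% c("male", "female")
  key <- key[ok]
  male <- sexes[ok] == "male"
  lev <- sort(unique(key))
  full_lev <- if (is.null(classes2)) lev else {
    l1 <- sort(unique(as.character(classes1[ok])))
    l2 <- sort(unique(as.character(classes2[ok])))
    as.vector(outer(l1, l2, paste, sep = ":"))
  }
  empty <- setdiff(full_lev, lev)
  if (length(empty))
    message("omitting empty class(es): ", paste(empty, collapse = ", "))
  nm <- tapply(male, key, sum)
  nf <- tapply(!male, key, sum)
  out <- data.frame(class = names(nm), n_male = as.vector(nm),
                    n_female = as.vector(nf),
                    percent_male = 100 * as.vector(nm) /
                      (as.vector(nm) + as.vector(nf)),
                    stringsAsFactors = FALSE)
  class(out) <- c("haplo_sex_table", "data.frame")
  out
}

#' Two-sided Fisher's exact test for a 2 x 2 table
#'
#' Two-sided p-value by summing hypergeometric probabilities of all
#' tables no more probable than the observed one (the point-probability
#' method of [stats::fisher.test()]).
#'
#' @param table 2 x 2 matrix of non-negative counts with positive
#'   margins.
#' @return the two-sided p-value.
#' @export
fisher_exact_2x2 <- function(table) {
  table <- as.matrix(table)
  check_that(all(dim(table) == c(2, 2)), "table must be 2 x 2")
  check_that(all(table >= 0), "counts must be non-negative")
  check_that(all(rowSums(table) > 0) && all(colSums(table) > 0),
             "margins must be positive")
  stats::fisher.test(table)$p.value
}
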