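## Maximum-likelihood diploid genotype calling from per-site nucleotide
## read counts. The likelihood of each of the 10 unordered diploid
## genotypes is profiled over a bounded per-nucleotide sequencing error
## rate e in [eps_min, eps_max]; a genotype is assigned only when a
## likelihood ratio test between the two most likely genotypes is
## significant. Bounding e below ~read-count noise keeps uneven read counts
## at a true heterozygote from being absorbed into an inflated error rate
## and miscalled homozygous.
##
## Read model (identical to the simulator's):
##   homozygote ii:     P(i) = 1 - e,                 other bases e/3
##   heterozygote ij:   P(i) = P(j) = (1 - 2e/3)/2,   other bases e/3
## Log-likelihoods omit the multinomial coefficient, which is identical
## across genotypes at fixed counts and cancels from every ratio.

## the 10 unordered genotypes as index pairs into NUCS
GENO_PAIRS <- {
  g <- which(upper.tri(diag(4), diag = TRUE), arr.ind = TRUE)
  g[order(g[, "col"] != g[, "row"], g[, "row"], g[, "col"]), , drop = FALSE]
}
GENO_LABELS <- apply(GENO_PAIRS, 1, function(p)
  paste(NUCS[p[1]], NUCS[p[2]], sep = "/"))

#' Genotyper configuration
#'
#' @param eps_min,eps_max bounds of the uniform prior range on the
#'   per-nucleotide sequencing error rate; the likelihood is maximised
#'   only within this range.
#' @param alpha significance level of the likelihood ratio test between
#'   the two most likely genotypes (chi-square, 1 df).
#' @return a validated list of class `genotyper_config`.
#' @export
genotyper_config <- function(eps_min = 0.001, eps_max = 0.1, alpha = 0.01) {
  check_that(eps_min > 0 && eps_min < eps_max && eps_max < 0.75,
             "need 0 < eps_min < eps_max < 0.75")
  check_that(alpha > 0 && alpha < 1, "alpha must be in (0, 1)")
  structure(list(eps_min = eps_min, eps_max = eps_max, alpha = alpha,
                 lr_crit = stats::qchisq(1 - alpha, df = 1)),
            class = "genotyper_config")
}

#' Profile log-likelihood of one genotype
#'
#' Maximises the multinomial read-count log-likelihood of an unordered
#' diploid genotype over the bounded error rate. The interior maximiser is
#' closed-form — homozygote ii: e = (n - n_i)/n; heterozygote ij with
#' m = n_i + n_j: e = 3(n - m)/(2n) — clipped to `[eps_min, eps_max]`.
#'
#' @param genotype two nucleotides, e.g. `c("A","C")`, or a string
#'   `"A/C"`; order is ignored.
#' @param counts numeric length-4 vector of A, C, G, T read counts.
#' @param config a [genotyper_config()].
#' @return list with `lnL` (profile log-likelihood, multinomial
#'   coefficient omitted) and `eps` (the maximising error rate).
#' @export
profile_loglik <- function(genotype, counts, config = genotyper_config()) {
  if (length(genotype) == 1)
    genotype <- strsplit(genotype, "/", fixed = TRUE)[[1]]
  idx <- match(genotype, NUCS)
  check_that(length(idx) == 2 && !anyNA(idx),
             "genotype must be two of A, C, G, T")
  check_that(length(counts) == 4 && all(counts >= 0),
             "counts must be 4 non-negative numbers")
  n <- sum(counts)
  check_that(n >= 1, "total depth must be >= 1")
  clip <- function(e) pmin(pmax(e, config$eps_min), config$eps_max)
  if (idx[1] == idx[2]) {
    ni <- counts[idx[1]]
    eps <- clip((n - ni) / n)
    lnL <- ni * log(1 - eps) + (n - ni) * log(eps / 3)
  } else {
    m <- counts[idx[1]] + counts[idx[2]]
    eps <- clip(3 * (n - m) / (2 * n))
    lnL <- m * log((1 - 2 * eps / 3) / 2) + (n - m) * log(eps / 3)
  }
  list(lnL = lnL, eps = eps)
}

## all-10-genotype profile log-likelihoods for a matrix of count vectors
## (rows = sites); returns list(lnL = n x 10, eps = n x 10)
profile_loglik_all <- function(cnt, config) {
  n <- rowSums(cnt)
  lnL <- matrix(NA_real_, nrow(cnt), 10)
  eps <- matrix(NA_real_, nrow(cnt), 10)
  for (g in 1:10) {
    i <- GENO_PAIRS[g, 1]
    j <- GENO_PAIRS[g, 2]
    if (i == j) {
      ni <- cnt[, i]
      e <- pmin(pmax((n - ni) / n, config$eps_min), config$eps_max)
      lnL[, g] <- ni * log(1 - e) + (n - ni) * log(e / 3)
    } else {
      m <- cnt[, i] + cnt[, j]
      e <- pmin(pmax(3 * (n - m) / (2 * n), config$eps_min),
                config$eps_max)
      lnL[, g] <- m * log((1 - 2 * e / 3) / 2) + (n - m) * log(e / 3)
    }
    eps[, g] <- e
  }
  list(lnL = lnL, eps = eps)
}

#' Call a diploid genotype from one count vector
#'
#' Evaluates all 10 unordered genotypes by [profile_loglik()], ranks them,
#' and assigns the best genotype if the likelihood ratio statistic
#' `2 (lnL_best - lnL_second)` reaches the chi-square (1 df) critical
#' value at `1 - alpha`. Zero depth or an exact tie for first place gives
#' no call. Low-coverage sites therefore never reach significance: the
#' criterion is an implicit depth filter.
#'
#' @param counts numeric length-4 vector of A, C, G, T read counts.
#' @param config a [genotyper_config()].
#' @return list of class `genotype_call`: `genotype` (string like
#'   `"A/C"`, or `NA` for no call), `called`, `lnL_best`, `lnL_second`,
#'   `eps`, `lr_stat`, `depth`.
#' @export
call_genotype <- function(counts, config = genotyper_config()) {
  check_that(length(counts) == 4 && all(counts >= 0),
             "counts must be 4 non-negative numbers")
  n <- sum(counts)
  if (n == 0) {
    return(structure(list(genotype = NA_character_, called = FALSE,
                          lnL_best = NA_real_, lnL_second = NA_real_,
                          eps = NA_real_, lr_stat = NA_real_, depth = 0L),
                     class = "genotype_call"))
  }
  pl <- profile_loglik_all(matrix(counts, 1), config)
  o <- order(pl$lnL[1, ], decreasing = TRUE)
  l1 <- pl$lnL[1, o[1]]
  l2 <- pl$lnL[1, o[2]]
  lr <- 2 * (l1 - l2)
  tie <- l1 == l2
  called <- !tie && lr >= config$lr_crit
  structure(list(
    genotype = if (tie) NA_character_ else GENO_LABELS[o[1]],
    called = called, lnL_best = l1, lnL_second = l2,
    eps = pl$eps[1, o[1]], lr_stat = lr, depth = as.integer(n)),
    class = "genotype_call")
}

#' @export
print.genotype_call <- function(x, ...) {
  if (x$called) {
    cat(sprintf("call %s (LR = %.3f, eps = %.4f, depth = %d)\n",
                x$genotype, x$lr_stat, x$eps, x$depth))
  } else {
    cat(sprintf("NO_CALL (best %s, LR = %.3f, depth = %d)\n",
                ifelse(is.na(x$genotype), "-", x$genotype),
                ifelse(is.na(x$lr_stat), 0, x$lr_stat), x$depth))
  }
  invisible(x)
}

#' Call genotypes for a whole read-count table
#'
#' Vectorised genotype calling over every (marker, individual) record of a
#' read-count table, with a per-marker call-rate summary. If a sample
#' sheet is supplied the summary also counts called males and females per
#' marker (the quantity consumed by the scan's minimum-per-sex filter).
#'
#' @param table a read-counts `data.frame` (see [read_counts_table()]).
#' @param config a [genotyper_config()].
#' @param sheet optional sample-sheet `data.frame`.
#' @return an object of class `radsex_calls`: list with `calls`
#'   (data.frame: `marker_id`, `chrom`, `pos_bp`, `sample_id`, `depth`,
#'   `genotype`, `called`, `lr_stat`, `eps`) and `per_marker` (data.frame
#'   of call counts per marker).
#' @export
call_matrix <- function(table, config = genotyper_config(), sheet = NULL) {
  cnt <- as.matrix(table[c("n_A", "n_C", "n_G", "n_T")])
  n <- rowSums(cnt)
  geno <- rep(NA_character_, nrow(cnt))
  called <- rep(FALSE, nrow(cnt))
  lr <- rep(NA_real_, nrow(cnt))
  eps <- rep(NA_real_, nrow(cnt))
  pos <- which(n > 0)
  if (length(pos)) {
    pl <- profile_loglik_all(cnt[pos, , drop = FALSE], config)
    l <- pl$lnL
    best <- max.col(l, ties.method = "first")
    l1 <- l[cbind(seq_along(pos), best)]
    l2 <- apply(l, 1, function(r) -sort.int(-r, partial = 2)[2])
    tie <- l1 == l2
    lr[pos] <- 2 * (l1 - l2)
    called[pos] <- !tie & lr[pos] >= config$lr_crit
    geno[pos] <- ifelse(tie, NA_character_, GENO_LABELS[best])
    eps[pos] <- pl$eps[cbind(seq_along(pos), best)]
  }
  calls <- data.frame(
    marker_id = table$marker_id, chrom = table$chrom,
    pos_bp = table$pos_bp, sample_id = table$sample_id,
    depth = as.integer(n), genotype = geno, called = called,
    lr_stat = lr, eps = eps, stringsAsFactors = FALSE)

  per_marker <- aggregate(called ~ marker_id, data = calls, FUN = sum)
  names(per_marker)[2] <- "n_called"
  per_marker$n_total <- as.vector(table(calls$marker_id)[
    per_marker$marker_id])
  if (!is.null(sheet)) {
    sex <- sheet$sex[match(calls$sample_id, sheet$sample_id)]
    cm <- tapply(calls$called & sex == "male", calls$marker_id, sum)
    cf <- tapply(calls$called & sex == "female", calls$marker_id, sum)
    per_marker$n_male_called <- as.vector(cm[per_marker$marker_id])
    per_marker$n_female_called <- as.vector(cf[per_marker$marker_id])
  }
  structure(list(calls = calls, per_marker = per_marker, config = config),
            class = "radsex_calls")
}

#' @export
print.radsex_calls <- function(x, ...) {
  cat(sprintf("Genotype calls: %d records, %d markers; call rate %.1f%%\n",
              nrow(x$calls), nrow(x$per_marker),
              100 * mean(x$calls$called)))
  invisible(x)
}
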