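## Per-SNP G-test of genetic differentiation between males and females,
## with a minimum-individuals-per-sex filter and Benjamini-Hochberg FDR
## control within family.

#' G-test of independence for an r x c contingency table
#'
#' `G = 2 * sum O log(O/E)` over cells with `O > 0`, with expected counts
#' from independence of the margins; degrees of freedom `(r-1)(c-1)`;
#' p-value from the upper chi-square tail. No continuity or Williams
#' correction is applied.
#'
#' @param table matrix of non-negative counts, at least 2 x 2, with all
#'   row and column margins positive.
#' @return list with `G`, `df` and `p.value`.
#' @export
g_test <- function(table) {
  table <- as.matrix(table)
  check_that(nrow(table) >= 2 && ncol(table) >= 2,
             "table must be at least 2 x 2")
  check_that(all(table >= 0), "counts must be non-negative")
  rs <- rowSums(table)
  cs <- colSums(table)
  check_that(all(rs > 0) && all(cs > 0),
             "zero row/column margin; drop such rows/columns first")
  E <- outer(rs, cs) / sum(table)
  pos <- table > 0
  G <- 2 * sum(table[pos] * log(table[pos] / E[pos]))
  df <- (nrow(table) - 1L) * (ncol(table) - 1L)
  list(G = G, df = df, p.value = stats::pchisq(G, df, lower.tail = FALSE))
}

#' Benjamini-Hochberg q-values
#'
#' Step-up false-discovery-rate adjustment: sort p ascending,
#' `q_(i) = min_{j >= i} m p_(j) / j` clipped at 1, returned in the
#' original order. Delegates to [stats::p.adjust()].
#'
#' @param p_values numeric vector of p-values in \[0, 1\], non-empty.
#' @return numeric vector of q-values in the input order.
#' @export
bh_fdr <- function(p_values) {
  check_that(length(p_values) >= 1, "p_values must be non-empty")
  check_that(all(is.finite(p_values)) &&
               all(p_values >= 0 & p_values <= 1),
             "p-values must lie in [0, 1]")
  stats::p.adjust(p_values, method = "BH")
}

#' Filter SNPs genotyped in too few individuals of either sex
#'
#' Retains exactly the markers with at least `min_per_sex` called males
#' AND at least `min_per_sex` called females.
#'
#' @param calls calls `data.frame` (component `$calls` of
#'   [call_matrix()]), or a `radsex_calls` object.
#' @param sheet sample-sheet `data.frame`.
#' @param min_per_sex minimum called individuals per sex (default 20).
#' @return the filtered calls `data.frame`; the per-marker per-sex counts
#'   are attached as `attr(, "sex_counts")`.
#' @export
filter_min_per_sex <- function(calls, sheet, min_per_sex = 20) {
  if (inherits(calls, "radsex_calls")) calls <- calls$calls
  check_that(min_per_sex >= 1, "min_per_sex must be >= 1")
  sex <- sheet$sex[match(calls$sample_id, sheet$sample_id)]
  nm <- tapply(calls$called & sex == "male", calls$marker_id, sum)
  nf <- tapply(calls$called & sex == "female", calls$marker_id, sum)
  keep_mk <- names(nm)[nm >= min_per_sex & nf >= min_per_sex]
  out <- calls[calls$marker_id %in% keep_mk, , drop = FALSE]
  attr(out, "sex_counts") <- data.frame(
    marker_id = names(nm), n_male_called = as.vector(nm),
    n_female_called = as.vector(nf), stringsAsFactors = FALSE)
  out
}

#' Per-SNP G-test scan of differentiation between the sexes
#'
#' For every SNP surviving the minimum-per-sex filter, cross-tabulates
#' called genotypes (rows = sexes, columns = observed genotype classes,
#' all-zero columns dropped) and computes the G-test, then
#' Benjamini-Hochberg q-values within each family. SNPs with `q < fdr`
#' are flagged significant. An allelic 2 x 2 mode (allele counts rather
#' than genotype classes) is available for comparison.
#'
#' @param calls a `radsex_calls` object or its `$calls` data.frame.
#' @param sheet sample-sheet `data.frame`; individuals of unknown sex are
#'   excluded.
#' @param family optional family label to restrict the sheet to.
#' @param min_per_sex minimum called individuals per sex (default 20).
#' @param fdr FDR flag threshold on q (default 0.001, the "0.1 percent
#'   FDR" line).
#' @param mode `"genotypic"` (default) or `"allelic"`.
#' @return a `data.frame` of class `sexscan`, one row per tested SNP:
#'   `marker_id`, `chrom`, `pos_bp`, `allele1`, `allele2`, per-sex
#'   genotype counts, `n_male_called`, `n_female_called`, `G`, `df`, `p`,
#'   `q`, `neglog10p`, `significant`.
#' @export
run_sexscan <- function(calls, sheet, family = NULL, min_per_sex = 20,
                        fdr = 0.001, mode = c("genotypic", "allelic")) {
  mode <- match.arg(mode)
  if (inherits(calls, "radsex_calls")) calls <- calls$calls
  if (!is.null(family)) sheet <- sheet[sheet$family == family, , drop = FALSE]
  sheet <- sheet[sheet$sex %in% c("male", "female"), , drop = FALSE]
  calls <- calls[calls$sample_id %in% sheet$sample_id, , drop = FALSE]
  kept <- filter_min_per_sex(calls, sheet, min_per_sex)
  kept <- kept[kept$called, , drop = FALSE]
  if (nrow(kept) == 0) {
    counts <- attr(filter_min_per_sex(calls, sheet, min_per_sex),
                   "sex_counts")
    stop(sprintf(
      "no SNPs survive the >= %d-per-sex filter (%d markers seen, max male %s, max female %s)",
      min_per_sex, nrow(counts),
      if (nrow(counts)) max(counts$n_male_called) else 0,
      if (nrow(counts)) max(counts$n_female_called) else 0),
      call. = FALSE)
  }
  sex <- sheet$sex[match(kept$sample_id, sheet$sample_id)]
  rows <- lapply(split(seq_len(nrow(kept)), kept$marker_id), function(ii) {
    sub <- kept[ii, ]
    ssex <- sex[ii]
    gt <- sub$genotype
    als <- sort(table(unlist(strsplit(gt, "/", fixed = TRUE))),
                decreasing = TRUE)
    a1 <- names(als)[1]
    a2 <- if (length(als) >= 2) names(als)[2] else NA_character_
    if (mode == "allelic") {
      alls <- unlist(strsplit(gt, "/", fixed = TRUE))
      asex <- rep(ssex, each = 2)
      tab <- table(factor(asex, c("male", "female")), alls)
    } else {
      tab <- table(factor(ssex, c("male", "female")), gt)
    }
    tab <- tab[, colSums(tab) > 0, drop = FALSE]
    if (ncol(tab) < 2 || any(rowSums(tab) == 0)) return(NULL)
    gt_levels <- c(paste0(a1, "/", a1),
                   paste(sort(c(a1, a2)), collapse = "/"),
                   paste0(a2, "/", a2))
    gtab <- table(factor(ssex, c("male", "female")),
                  factor(gt, gt_levels))
    res <- g_test(tab)
    data.frame(
      marker_id = sub$marker_id[1], chrom = sub$chrom[1],
      pos_bp = sub$pos_bp[1], allele1 = a1, allele2 = a2,
      n_male_hom1 = gtab["male", 1], n_male_het = gtab["male", 2],
      n_male_hom2 = gtab["male", 3],
      n_female_hom1 = gtab["female", 1], n_female_het = gtab["female", 2],
      n_female_hom2 = gtab["female", 3],
      n_male_called = sum(ssex == "male"),
      n_female_called = sum(ssex == "female"),
      G = res$G, df = res$df, p = res$p.value,
      stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  check_that(!is.null(out) && nrow(out) > 0,
             "no polymorphic SNPs left to test after filtering")
  rownames(out) <- NULL
  out$q <- bh_fdr(out$p)
  out$neglog10p <- -log10(pmax(out$p, .Machine$double.xmin))
  out$significant <- out$q < fdr
  out <- out[order(out$chrom, out$pos_bp), ]
  rownames(out) <- NULL
  attr(out, "fdr") <- fdr
  attr(out, "mode") <- mode
  class(out) <- c("sexscan", "data.frame")
  out
}

#' @export
print.sexscan <- function(x, n = 6, ...) {
  cat(sprintf(
    "Sex-differentiation G-test scan: %d SNPs, %d significant at q < %g\n",
    nrow(x), sum(x$significant), attr(x, "fdr")))
  top <- x[order(x$p), , drop = FALSE]
  print.data.frame(utils::head(
    top[c("marker_id", "chrom", "pos_bp", "G", "df", "p", "q")], n),
    row.names = FALSE, digits = 4)
  invisible(x)
}

#' @export
summary.sexscan <- function(object, ...) {
  cat(sprintf("SNPs tested:      %d\n", nrow(object)))
  cat(sprintf("significant (q < %g): %d\n", attr(object, "fdr"),
              sum(object$significant)))
  if (any(object$significant)) {
    sig <- object[object$significant, ]
    for (ch in unique(sig$chrom)) {
      s <- sig[sig$chrom == ch, ]
      cat(sprintf("  %s: %d SNPs, %s..%s bp, min p = %.3g\n", ch, nrow(s),
                  format(min(s$pos_bp), big.mark = ","),
                  format(max(s$pos_bp), big.mark = ","), min(s$p)))
    }
  }
  invisible(object)
}

#' @export
plot.sexscan <- function(x, ...) {
  chroms <- unique(x$chrom)
  off <- stats::setNames(
    cumsum(c(0, vapply(chroms, function(ch)
      max(x$pos_bp[x$chrom == ch]), numeric(1))))[seq_along(chroms)],
    chroms)
  gx <- x$pos_bp + off[x$chrom]
  plot(gx, x$neglog10p, pch = 16, cex = 0.5,
       col = (match(x$chrom, chroms) %% 2) + 1,
       xlab = "genome position", ylab = expression(-log[10] ~ p), ...)
  thr <- x$p[x$q < attr(x, "fdr")]
  if (length(thr))
    graphics::abline(h = -log10(max(thr)), col = "red", lty = 2)
  invisible(x)
}
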