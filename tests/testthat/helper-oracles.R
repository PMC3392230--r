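## Independent oracles and small fixtures shared across the suite.

## Dense grid-search profile likelihood: maximises the multinomial
## log-likelihood of a genotype over an epsilon grid, independently of
## the closed-form path in the package.
grid_profile_max <- function(genotype, counts, eps_min = 0.001,
                             eps_max = 0.1, step = 1e-5) {
  if (length(genotype) == 1)
    genotype <- strsplit(genotype, "/", fixed = TRUE)[[1]]
  idx <- match(genotype, c("A", "C", "G", "T"))
  eps <- seq(eps_min, eps_max, by = step)
  n <- sum(counts)
  if (idx[1] == idx[2]) {
    ni <- counts[idx[1]]
    lnL <- ni * log(1 - eps) + (n - ni) * log(eps / 3)
  } else {
    m <- counts[idx[1]] + counts[idx[2]]
    lnL <- m * log((1 - 2 * eps / 3) / 2) + (n - m) * log(eps / 3)
  }
  max(lnL)
}

ALL_GENOS <- {
  nucs <- c("A", "C", "G", "T")
  g <- character(0)
  for (i in 1:4) for (j in i:4) g <- c(g, paste(nucs[i], nucs[j], sep = "/"))
  g
}

## Hand-written Benjamini-Hochberg step-up, independent of p.adjust.
bh_stepup <- function(p) {
  m <- length(p)
  o <- order(p)
  q <- p[o] * m / seq_len(m)
  q <- rev(cummin(rev(q)))
  q <- pmin(q, 1)
  out <- numeric(m)
  out[o] <- q
  out
}

## Brute-force binary-trait LOD via penetrance grid search. Classes with
## only one sex have their maximum at the boundary (log-likelihood 0).
lod_grid_oracle <- function(m, f, step = 1e-4) {
  p <- seq(step, 1 - step, by = step)
  ll_class <- function(mm, ff) {
    if (mm == 0 || ff == 0) return(0)
    max(mm * log(p) + ff * log(1 - p))
  }
  ll1 <- sum(mapply(ll_class, m, f))
  ll0 <- ll_class(sum(m), sum(f))
  (ll1 - ll0) / log(10)
}

## Small single-chromosome simulation config for fast tests.
tiny_config <- function(n_f2 = 100, n_markers = 6, cm_female = 30,
                        cm_male = 15, length_bp = 6e6, ...) {
  chroms <- data.frame(name = "chr1", length_bp = length_bp,
                       n_markers = as.integer(n_markers),
                       stringsAsFactors = FALSE)
  pos <- round(seq(1, length_bp, length.out = n_markers))
  sim_config(
    n_f2 = n_f2, chromosomes = chroms,
    cM_maps = list(chr1 = list(
      female = seq(0, cm_female, length.out = n_markers),
      male = seq(0, cm_male, length.out = n_markers))),
    sar_loci = list(list(chrom = "chr1", pos_bp = pos[n_markers - 1],
                         penetrance = c(G1G1 = 1, G1G2 = 0.16, G2G2 = 0))),
    suppress_chrom = NULL, ...)
}

## Fig-2A-style genotype-by-sex fixture: 70 C/C males, 12 C/G males,
## 63 C/G females.
sar4_classes <- c(rep("CC", 70), rep("CG", 12 + 63))
sar4_sexes <- c(rep("male", 70), rep("male", 12), rep("female", 63))

## write a data.frame as a TSV fixture under tempdir
write_fixture <- function(df, name) {
  path <- file.path(tempdir(), name)
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  path
}
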