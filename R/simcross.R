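## Forward simulator of a reciprocal F2 intercross between two divergent
## inbred-like founder strains (G1 = grandsire strain, G2 = granddam
## strain), with sex-specific recombination maps, penetrance-based sex
## determination at one or two sex-associated loci, and RAD-style
## multinomial read counts over negative-binomial depth.

#' Build and validate a simulation configuration
#'
#' The defaults describe the desk-scale study conditions used throughout
#' the package's tests: an F2 family of 145 mapped individuals, a 5 x 60 Mb
#' chromosome genome with 40 evenly spaced markers per chromosome, a female
#' map of 94 cM per chromosome, a male map half as long genome-wide with a
#' 5-fold compression of the terminal 10% of the sex-associated chromosome
#' ("chr4"), a single sex-associated locus near the chromosome end with
#' full penetrance in G1/G1 homozygotes and 16% male penetrance in
#' heterozygotes, mean sequencing depth 30 with dispersion 5, sequencing
#' error rate 0.01 and 5% missing (zero-depth) sites.
#'
#' @param n_f2 number of F2 individuals.
#' @param chromosomes `data.frame` with columns `name`, `length_bp`,
#'   `n_markers`.
#' @param cM_maps named list (per chromosome) of lists with numeric
#'   vectors `female` and `male`: cumulative cM at each marker
#'   (non-decreasing, length `n_markers`). `NULL` builds uniform maps from
#'   `female_cM_per_chrom`, `male_female_ratio` and the terminal
#'   suppression parameters.
#' @param founder_allele_freq_diff probability a marker is
#'   strain-diagnostic (fixed for different nucleotides in the founders).
#' @param sar_loci list of sex-associated loci; each element is a list
#'   with `chrom`, `pos_bp` (must coincide with a simulated marker) and
#'   `penetrance`, a named numeric vector mapping genotype classes
#'   (`G1G1`, `G1G2`, `G2G2`, or `:`-joined pairs of those for two-locus
#'   tables) to the probability of developing as male.
#' @param depth_mean,depth_dispersion negative-binomial read depth mean
#'   and dispersion (size).
#' @param error_rate true per-nucleotide sequencing error rate, in
#'   (0, 0.25).
#' @param p_missing probability a (marker, individual) site has zero
#'   depth, in \[0, 1).
#' @param female_cM_per_chrom female map length per chromosome (cM).
#' @param male_female_ratio genome-wide male/female map-length ratio.
#' @param suppress_chrom chromosome whose terminal region is
#'   recombination-suppressed in males (`NULL` for none).
#' @param suppress_frac terminal fraction of that chromosome suppressed.
#' @param suppress_fold fold-compression of the male map in that region.
#' @return a validated list of class `sim_config`.
#' @export
sim_config <- function(n_f2 = 145,
                       chromosomes = data.frame(
                         name = paste0("chr", 1:5),
                         length_bp = 60e6,
                         n_markers = 40L,
                         stringsAsFactors = FALSE),
                       cM_maps = NULL,
                       founder_allele_freq_diff = 0.9,
                       sar_loci = NULL,
                       depth_mean = 30,
                       depth_dispersion = 5,
                       error_rate = 0.01,
                       p_missing = 0.05,
                       female_cM_per_chrom = 94,
                       male_female_ratio = 0.5,
                       suppress_chrom = "chr4",
                       suppress_frac = 0.1,
                       suppress_fold = 5) {
  check_that(n_f2 >= 1, "n_f2 must be positive")
  check_that(all(chromosomes$n_markers >= 2),
             "each chromosome needs at least 2 markers")
  check_that(error_rate > 0 && error_rate < 0.25,
             "error_rate must be in (0, 0.25)")
  check_that(p_missing >= 0 && p_missing < 1, "p_missing must be in [0, 1)")
  check_that(depth_mean > 0 && depth_dispersion > 0,
             "depth parameters must be positive")
  check_that(founder_allele_freq_diff >= 0 && founder_allele_freq_diff <= 1,
             "founder_allele_freq_diff must be in [0, 1]")

  if (is.null(cM_maps)) {
    cM_maps <- default_cM_maps(chromosomes, female_cM_per_chrom,
                               male_female_ratio, suppress_chrom,
                               suppress_frac, suppress_fold)
  }
  for (ch in chromosomes$name) {
    m <- cM_maps[[ch]]
    check_that(!is.null(m), "cM_maps missing chromosome ", ch)
    nmk <- chromosomes$n_markers[chromosomes$name == ch]
    check_that(length(m$female) == nmk && length(m$male) == nmk,
               "cM map length mismatch on ", ch)
    check_that(!is.unsorted(m$female) && !is.unsorted(m$male),
               "cM maps must be non-decreasing on ", ch)
  }
  if (is.null(sar_loci)) {
    sar_chrom <- if (!is.null(suppress_chrom)) suppress_chrom else
      chromosomes$name[1]
    pos <- marker_positions(chromosomes[chromosomes$name == sar_chrom, ])
    sar_loci <- list(list(
      chrom = sar_chrom,
      pos_bp = pos[length(pos) - 1L],
      penetrance = c(G1G1 = 1.0, G1G2 = 0.16, G2G2 = 0.0)
    ))
  }
  for (s in sar_loci) {
    check_that(all(s$penetrance >= 0 & s$penetrance <= 1),
               "penetrance values must be in [0, 1]")
  }

  structure(list(
    n_f2 = as.integer(n_f2), chromosomes = chromosomes, cM_maps = cM_maps,
    founder_allele_freq_diff = founder_allele_freq_diff,
    sar_loci = sar_loci, depth_mean = depth_mean,
    depth_dispersion = depth_dispersion, error_rate = error_rate,
    p_missing = p_missing
  ), class = "sim_config")
}

## evenly spaced 1-based marker positions along one chromosome
marker_positions <- function(chrom_row) {
  n <- chrom_row$n_markers
  round(seq(1, chrom_row$length_bp, length.out = n))
}

default_cM_maps <- function(chromosomes, female_cM, ratio,
                            sup_chrom, sup_frac, sup_fold) {
  maps <- list()
  for (i in seq_len(nrow(chromosomes))) {
    n <- chromosomes$n_markers[i]
    u <- seq(0, 1, length.out = n)
    fem <- female_cM * u
    mal <- female_cM * ratio * u
    if (!is.null(sup_chrom) && chromosomes$name[i] == sup_chrom) {
      ## compress the male map sup_fold-fold over the terminal sup_frac of
      ## the chromosome, keeping it piecewise linear and non-decreasing
      brk <- 1 - sup_frac
      base <- female_cM * ratio
      mal <- ifelse(u <= brk, base * u,
                    base * brk + base * (u - brk) / sup_fold)
    }
    maps[[chromosomes$name[i]]] <- list(female = fem, male = mal)
  }
  maps
}

#' Simulate phase-known F2 genotypes and the true genetic map
#'
#' F0 grandparents are opposite homozygotes at every strain-diagnostic
#' marker, F1s are heterozygous, and each F2 gamete is produced by a
#' no-interference crossover process whose per-interval recombination
#' fraction is the Kosambi inverse of the parent-sex-specific cM interval.
#'
#' @param config a [sim_config()] object.
#' @param seed integer seed.
#' @return an object of class `radsex_geno`: a list with `map`
#'   (data.frame: `marker_id`, `chrom`, `pos_bp`, `cM_female`, `cM_male`),
#'   `mat_origin` and `pat_origin` (marker x individual integer matrices,
#'   1 = grandsire-strain allele, 2 = granddam-strain allele), and
#'   `founder_alleles` (data.frame: `marker_id`, `allele_g1`, `allele_g2`,
#'   `diagnostic`).
#' @export
simulate_pedigree_genotypes <- function(config, seed = 1L) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(seed)
  chroms <- config$chromosomes
  map_list <- list()
  mat_list <- list()
  pat_list <- list()
  n <- config$n_f2

  for (i in seq_len(nrow(chroms))) {
    ch <- chroms$name[i]
    pos <- marker_positions(chroms[i, ])
    fem <- config$cM_maps[[ch]]$female
    mal <- config$cM_maps[[ch]]$male
    nm <- length(pos)
    map_list[[ch]] <- data.frame(
      marker_id = sprintf("%s_M%03d", ch, seq_len(nm)),
      chrom = ch, pos_bp = pos, cM_female = fem, cM_male = mal,
      stringsAsFactors = FALSE)
    mat_list[[ch]] <- sim_gametes(fem, n)
    pat_list[[ch]] <- sim_gametes(mal, n)
  }
  map <- do.call(rbind, map_list)
  rownames(map) <- NULL
  mat_origin <- do.call(rbind, mat_list)
  pat_origin <- do.call(rbind, pat_list)
  dimnames(mat_origin) <- dimnames(pat_origin) <-
    list(map$marker_id, sprintf("F2_%04d", seq_len(n)))

  diag_mk <- stats::runif(nrow(map)) < config$founder_allele_freq_diff
  a1 <- character(nrow(map))
  a2 <- character(nrow(map))
  for (j in seq_len(nrow(map))) {
    pair <- sample(NUCS, 2)
    a1[j] <- pair[1]
    a2[j] <- if (diag_mk[j]) pair[2] else pair[1]
  }
  founder_alleles <- data.frame(
    marker_id = map$marker_id, allele_g1 = a1, allele_g2 = a2,
    diagnostic = diag_mk, stringsAsFactors = FALSE)

  structure(list(map = map, mat_origin = mat_origin,
                 pat_origin = pat_origin,
                 founder_alleles = founder_alleles),
            class = "radsex_geno")
}

## Gametes for one parent on one chromosome: marker x individual matrix of
## grandparental origins (1/2). Crossovers are interval-wise independent
## (no interference) with r = Kosambi inverse of the cM interval.
sim_gametes <- function(cm, n) {
  nm <- length(cm)
  d <- diff(cm)
  r <- kosambi_r(d)
  check_that(all(r < 0.5), "cM interval implies r >= 0.5")
  first <- stats::rbinom(n, 1, 0.5)
  if (nm == 1) return(matrix(1L + first, nrow = 1))
  sw <- matrix(stats::rbinom((nm - 1) * n, 1, rep(r, n)), nrow = nm - 1)
  orig <- apply(rbind(first, sw), 2, function(col) cumsum(col) %% 2L)
  matrix(1L + as.integer(orig), nrow = nm)
}

#' Collapsed genotype class at one marker
#'
#' Returns `G1G1`, `G1G2` or `G2G2` per individual — the number of
#' grandsire-strain alleles carried, ignoring parental phase.
#'
#' @param geno a `radsex_geno` object.
#' @param marker_id marker identifier.
#' @return character vector, one entry per F2 individual.
#' @export
genotype_classes <- function(geno, marker_id) {
  i <- match(marker_id, geno$map$marker_id)
  check_that(!is.na(i), "marker not found: ", marker_id)
  n1 <- (geno$mat_origin[i, ] == 1) + (geno$pat_origin[i, ] == 1)
  c("G2G2", "G1G2", "G1G1")[n1 + 1L]
}

#' Phase-known four-way class codes for all markers
#'
#' @param geno a `radsex_geno` object.
#' @return integer matrix (marker x individual) with values 1-4 coding the
#'   (maternal, paternal) grandparental-origin pair; the class labels are
#'   in `attr(, "labels")`.
#' @export
fourway_classes <- function(geno) {
  cl <- 2L * (geno$mat_origin - 1L) + geno$pat_origin
  attr(cl, "labels") <- c("G1|G1", "G1|G2", "G2|G1", "G2|G2")
  cl
}

#' Assign sex to simulated F2 individuals by penetrance
#'
#' Each F2 individual develops as male with the probability given by the
#' penetrance table at its genotype class — a single-locus lookup, or a
#' joint lookup on `:`-joined classes for a two-locus table.
#'
#' @param geno a `radsex_geno` object.
#' @param sar_loci list of sex-associated loci as in [sim_config()].
#' @param seed integer seed.
#' @param family family label written into the sheet.
#' @return a sample-sheet `data.frame` (F2 rows only).
#' @export
assign_sex <- function(geno, sar_loci, seed = 1L, family = "SIM") {
  set.seed(seed)
  classes <- lapply(sar_loci, function(s) {
    i <- which(geno$map$chrom == s$chrom & geno$map$pos_bp == s$pos_bp)
    check_that(length(i) == 1,
               "sar locus not at a simulated marker: ",
               s$chrom, ":", s$pos_bp)
    genotype_classes(geno, geno$map$marker_id[i])
  })
  key <- do.call(paste, c(classes, sep = ":"))
  pen <- if (length(sar_loci) == 1) sar_loci[[1]]$penetrance else {
    ## joint table must be supplied on the first locus for 2-locus designs
    p <- sar_loci[[1]]$penetrance
    check_that(any(grepl(":", names(p), fixed = TRUE)),
               "two sar loci require a joint penetrance table with ",
               "names like 'G1G1:G1G2'")
    p
  }
  miss <- setdiff(unique(key), names(pen))
  check_that(length(miss) == 0,
             "genotype class absent from penetrance table: ",
             paste(miss, collapse = ", "))
  p_male <- unname(pen[key])
  sex <- ifelse(stats::rbinom(length(key), 1, p_male) == 1, "male", "female")
  data.frame(sample_id = colnames(geno$mat_origin), family = family,
             generation = "F2", sex = sex, stringsAsFactors = FALSE)
}

#' Simulate RAD-style read counts from true genotypes
#'
#' Depth per (marker, individual) is negative binomial with the configured
#' mean and dispersion, set to zero with probability `p_missing`. Given
#' depth n and true genotype, nucleotide counts are multinomial with
#' per-read probabilities: homozygote i — P(i) = 1 - e, each other base
#' e/3; heterozygote ij — P(i) = P(j) = (1 - 2e/3)/2, other bases e/3,
#' where e is the true error rate.
#'
#' @param geno a `radsex_geno` object.
#' @param config a [sim_config()] object.
#' @param seed integer seed.
#' @return a read-counts `data.frame` (see [read_counts_table()]).
#' @export
simulate_read_counts <- function(geno, config, seed = 1L) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(seed)
  fa <- geno$founder_alleles
  check_that(all(!fa$diagnostic | fa$allele_g1 != fa$allele_g2),
             "diagnostic markers must have distinct founder nucleotides")
  nm <- nrow(geno$map)
  n <- ncol(geno$mat_origin)
  eps <- config$error_rate

  al_idx <- cbind(match(fa$allele_g1, NUCS), match(fa$allele_g2, NUCS))
  mat_al <- matrix(al_idx[cbind(rep(seq_len(nm), n),
                                as.vector(geno$mat_origin))], nm, n)
  pat_al <- matrix(al_idx[cbind(rep(seq_len(nm), n),
                                as.vector(geno$pat_origin))], nm, n)

  depth <- stats::rnbinom(nm * n, mu = config$depth_mean,
                          size = config$depth_dispersion)
  depth[stats::runif(nm * n) < config$p_missing] <- 0L

  a1 <- as.vector(mat_al)
  a2 <- as.vector(pat_al)
  counts <- matrix(0L, nm * n, 4)
  ## group sites by (allele pair) so each group is one vectorised
  ## multinomial draw via rmultinom
  grp <- paste(pmin(a1, a2), pmax(a1, a2))
  for (g in unique(grp)) {
    idx <- which(grp == g & depth > 0)
    if (length(idx) == 0) next
    pair <- as.integer(strsplit(g, " ", fixed = TRUE)[[1]])
    pr <- rep(eps / 3, 4)
    if (pair[1] == pair[2]) {
      pr[pair[1]] <- 1 - eps
    } else {
      pr[pair] <- (1 - 2 * eps / 3) / 2
    }
    ## one multinomial draw per site (depths differ across sites)
    for (d in unique(depth[idx])) {
      ii <- idx[depth[idx] == d]
      counts[ii, ] <- t(stats::rmultinom(length(ii), d, pr))
    }
  }
  data.frame(
    marker_id = rep(geno$map$marker_id, n),
    chrom = rep(geno$map$chrom, n),
    pos_bp = rep(geno$map$pos_bp, n),
    sample_id = rep(colnames(geno$mat_origin), each = nm),
    n_A = counts[, 1], n_C = counts[, 2],
    n_G = counts[, 3], n_T = counts[, 4],
    stringsAsFactors = FALSE)
}

#' Simulate a complete F2 cross
#'
#' Convenience wrapper running [simulate_pedigree_genotypes()],
#' [assign_sex()] and (optionally) [simulate_read_counts()] on seed
#' streams derived from one master seed.
#'
#' @param config a [sim_config()] object.
#' @param seed master integer seed.
#' @param reads if `TRUE`, also simulate read counts.
#' @param family family label.
#' @return an object of class `radsex_sim`: list with `geno`, `samples`,
#'   and (optionally) `counts`, plus the `config` and `seed` used.
#' @export
simulate_cross <- function(config = sim_config(), seed = 1L, reads = TRUE,
                           family = "SIM") {
  geno <- simulate_pedigree_genotypes(config, stage_seed(seed, "simulate"))
  samples <- assign_sex(geno, config$sar_loci, stage_seed(seed, "sex"),
                        family = family)
  counts <- if (reads) {
    simulate_read_counts(geno, config, stage_seed(seed, "reads"))
  }
  structure(list(geno = geno, samples = samples, counts = counts,
                 config = config, seed = seed),
            class = "radsex_sim")
}

#' @export
print.radsex_sim <- function(x, ...) {
  cat("Simulated F2 intercross\n")
  cat(sprintf("  %d F2 individuals (%d male, %d female)\n",
              nrow(x$samples), sum(x$samples$sex == "male"),
              sum(x$samples$sex == "female")))
  cat(sprintf("  %d markers on %d chromosome(s); %d strain-diagnostic\n",
              nrow(x$geno$map), length(unique(x$geno$map$chrom)),
              sum(x$geno$founder_alleles$diagnostic)))
  if (!is.null(x$counts))
    cat(sprintf("  read counts: %d site x individual records\n",
                nrow(x$counts)))
  invisible(x)
}
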