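test_that("binary LOD matches the closed form and its symmetries", {
  # equal sex ratios across classes: null equals alternative
  expect_equal(binary_lod(rep(c("a", "b"), each = 20),
                          rep(c("male", "female"), 20))$lod, 0)

  # sar4 peak table: 70/0 vs 12/63
  bl <- binary_lod(sar4_classes, sar4_sexes)
  expect_equal(bl$lod, 28.786, tolerance = 1e-3)
  expect_equal(unname(bl$penetrance["CC"]), 1.0)
  expect_equal(unname(bl$penetrance["CG"]), 12 / 75)

  # exchanging the sex labels leaves the LOD unchanged
  flipped <- ifelse(sar4_sexes == "male", "female", "male")
  expect_equal(binary_lod(sar4_classes, flipped)$lod, bl$lod)

  # single class: LOD zero with a warning, not an error
  expect_warning(z <- binary_lod(rep("a", 10), rep("male", 10)),
                 "one genotype class")
  expect_equal(z$lod, 0)
})

test_that("binary LOD equals a brute-force penetrance grid search", {
  set.seed(301)
  for (i in 1:100) {
    k <- sample(2:4, 1)
    m <- rpois(k, 12)
    f <- rpois(k, 12)
    keep <- m + f > 0
    m <- m[keep]; f <- f[keep]
    if (length(m) < 2) next
    cl <- rep(seq_along(m), m + f)
    sx <- unlist(mapply(function(mm, ff) c(rep("male", mm),
                                           rep("female", ff)),
                        m, f, SIMPLIFY = FALSE))
    expect_lt(abs(binary_lod(cl, sx)$lod - lod_grid_oracle(m, f)), 1e-3)
  }
})

test_that("the vectorised permutation engine agrees with binary_lod", {
  set.seed(302)
  classes <- matrix(sample(1:4, 30 * 80, replace = TRUE), 30, 80)
  classes[sample(length(classes), 100)] <- NA  # missingness handled
  sexes <- sample(c("male", "female"), 80, replace = TRUE)
  engine <- radsexscan:::lod_engine(
    classes, matrix(as.numeric(sexes == "male"), ncol = 1))
  direct <- vapply(seq_len(30), function(i)
    binary_lod(classes[i, ], sexes)$lod, numeric(1))
  expect_equal(as.vector(engine), direct, tolerance = 1e-10)
})

test_that("permutation thresholds are seeded, ordered and edge-safe", {
  set.seed(303)
  classes <- matrix(sample(1:4, 50 * 60, replace = TRUE), 50, 60)
  sexes <- rep(c("male", "female"), 30)
  a <- permutation_threshold(classes, sexes, n_perm = 200, seed = 99)
  b <- permutation_threshold(classes, sexes, n_perm = 200, seed = 99)
  expect_identical(a$thresholds, b$thresholds)
  expect_lte(a$thresholds[["10%"]], a$thresholds[["5%"]])

  # monomorphic markers: every permuted maximum is zero
  mono <- matrix(1L, 20, 60)
  m <- permutation_threshold(mono, sexes, n_perm = 150, seed = 1)
  expect_equal(unname(m$thresholds), c(0, 0))
  expect_error(permutation_threshold(classes, sexes, n_perm = 50,
                                     seed = 1), ">= 100")
})

test_that("1.5-LOD support intervals follow the flanking-marker rule", {
  mk_scan <- function(lod) data.frame(
    marker_id = sprintf("m%02d", seq_along(lod)), chrom = "chr1",
    pos_bp = seq_along(lod) * 1e6, cM = seq_along(lod), lod = lod)

  # triangular profile, peak 10 at marker 5: markers >= 8.5 are 4..6,
  # one conservative flank beyond on each side gives 3..7
  tri <- mk_scan(c(6, 7, 8, 9, 10, 9, 8, 7, 6, 5))
  iv <- lod_support_interval(tri, drop = 1.5)
  expect_equal(iv$cM_lo, 3)
  expect_equal(iv$cM_hi, 7)
  expect_equal(iv$peak_marker, "m05")

  # peak at the terminal marker: interval clamps to the chromosome end
  term <- mk_scan(c(1, 1, 1, 2, 28))
  ivt <- lod_support_interval(term, drop = 1.5)
  expect_equal(ivt$cM_lo, 4)  # flank of the peak
  expect_equal(ivt$cM_hi, 5)  # chromosome end
  expect_equal(ivt$bp_hi, 5e6)

  # drop = 0: only the peak qualifies, interval is its flanking pair
  iv0 <- lod_support_interval(tri, drop = 0)
  expect_equal(c(iv0$cM_lo, iv0$cM_hi), c(4, 6))

  # nothing above threshold: empty result
  expect_equal(nrow(lod_support_interval(tri, threshold = 99)), 0)
})

test_that("haplotype-by-sex tables reproduce the sar4 percentages", {
  ht <- haplotype_sex_table(sar4_classes, sar4_sexes)
  expect_equal(ht$percent_male[ht$class == "CC"], 100)
  expect_equal(ht$percent_male[ht$class == "CG"], 16)
  expect_equal(ht$n_male[ht$class == "CG"], 12)
  expect_equal(ht$n_female[ht$class == "CG"], 63)

  # two-marker joint mode notes absent combinations
  c1 <- c("AA", "AA", "BB")
  c2 <- c("CC", "DD", "DD")
  expect_message(
    ht2 <- haplotype_sex_table(c1, c("male", "female", "male"), c2),
    "omitting empty class")
  expect_setequal(ht2$class, c("AA:CC", "AA:DD", "BB:DD"))

  # two-locus simulation recovers the configured joint penetrance
  joint <- as.vector(outer(c(G1G1 = 1, G1G2 = 0.5, G2G2 = 0),
                           c(G1G1 = 0.9, G1G2 = 0.5, G2G2 = 0.1)))
  names(joint) <- as.vector(outer(c("G1G1", "G1G2", "G2G2"),
                                  c("G1G1", "G1G2", "G2G2"),
                                  function(a, b) paste(a, b, sep = ":")))
  cfg <- sim_config(
    n_f2 = 4000,
    chromosomes = data.frame(name = c("chr3", "chr4"),
                             length_bp = 3e7 + 1, n_markers = 4L),
    cM_maps = list(chr3 = list(female = c(0, 20, 40, 60),
                               male = c(0, 10, 20, 30)),
                   chr4 = list(female = c(0, 20, 40, 60),
                               male = c(0, 10, 20, 30))),
    sar_loci = list(
      list(chrom = "chr3", pos_bp = 20000001,
           penetrance = joint),
      list(chrom = "chr4", pos_bp = 20000001)),
    suppress_chrom = NULL)
  geno <- simulate_pedigree_genotypes(cfg, seed = 71)
  sheet <- assign_sex(geno, cfg$sar_loci, seed = 72)
  m3 <- geno$map$marker_id[geno$map$chrom == "chr3"][3]
  m4 <- geno$map$marker_id[geno$map$chrom == "chr4"][3]
  ht3 <- haplotype_sex_table(genotype_classes(geno, m3), sheet$sex,
                             genotype_classes(geno, m4))
  for (i in seq_len(nrow(ht3))) {
    n <- ht3$n_male[i] + ht3$n_female[i]
    p <- joint[[ht3$class[i]]]
    se <- sqrt(max(p * (1 - p), 0.25 / n) / n)
    expect_lt(abs(ht3$percent_male[i] / 100 - p), 4 * se + 1e-9)
  }
})

test_that("Fisher's exact test matches enumeration on small tables", {
  expect_equal(fisher_exact_2x2(rbind(c(3, 0), c(0, 3))), 0.1)
  expect_equal(fisher_exact_2x2(rbind(c(5, 5), c(5, 5))), 1)
  tab <- rbind(c(7, 2), c(3, 8))
  expect_equal(fisher_exact_2x2(tab), fisher_exact_2x2(t(tab)))
  expect_error(fisher_exact_2x2(rbind(c(-1, 2), c(3, 4))),
               "non-negative")
  expect_error(fisher_exact_2x2(rbind(c(0, 0), c(3, 4))), "margins")
})

test_that("run_lodscan finds the simulated locus and reports intervals", {
  sim <- simulate_cross(sim_config(n_f2 = 145), seed = 81, reads = FALSE)
  scan <- run_lodscan(sim$geno, sim$samples, n_perm = 300, seed = 82)
  pk <- scan$scan[which.max(scan$scan$lod), ]
  expect_equal(pk$chrom, sim$config$sar_loci[[1]]$chrom)
  expect_gt(pk$lod, scan$thresholds[["5%"]])
  expect_true(nrow(scan$intervals) >= 1)
  iv <- scan$intervals[scan$intervals$chrom == pk$chrom, ]
  expect_lte(iv$cM_lo, pk$cM)
  expect_gte(iv$cM_hi, pk$cM)
})
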