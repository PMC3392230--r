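test_that("G-test matches hand computation and basic symmetries", {
  # identical distributions: no differentiation
  null <- g_test(rbind(c(10, 10), c(10, 10)))
  expect_equal(null$G, 0)
  expect_equal(null$p.value, 1)

  # sar4 peak genotype-by-sex table
  tab <- rbind(male = c(70, 12), female = c(0, 63))
  res <- g_test(tab)
  expect_equal(res$G, 132.565, tolerance = 1e-3)
  expect_equal(res$df, 1)
  expect_lt(res$p.value, 2e-30)  # chi-square(1) tail of G = 132.565

  # row swap leaves G unchanged
  expect_equal(g_test(tab[2:1, ])$G, res$G)

  # proportional rows give exactly zero
  expect_equal(g_test(rbind(c(30, 60, 30), c(10, 20, 10)))$G, 0)

  expect_error(g_test(rbind(c(0, 0), c(1, 2))), "margin")
  expect_error(g_test(matrix(1, 1, 2)), "2 x 2")
})

test_that("bh_fdr implements the step-up rule", {
  expect_equal(bh_fdr(c(1, 1, 1)), c(1, 1, 1))
  expect_equal(bh_fdr(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_fdr(0.005), 0.005)
  expect_error(bh_fdr(c(0.1, 1.2)), "\\[0, 1\\]")
  expect_error(bh_fdr(numeric(0)), "non-empty")

  # matches an independent step-up implementation, in any input order
  set.seed(201)
  for (i in 1:25) {
    p <- runif(40)^2
    q <- bh_fdr(p)
    expect_equal(q, bh_stepup(p), tolerance = 1e-12)
    o <- sample(40)
    expect_equal(bh_fdr(p[o]), q[o], tolerance = 1e-12)
    # q >= p and q non-decreasing in p-order
    expect_true(all(q >= p))
    expect_true(!is.unsorted(q[order(p)]))
  }
})

test_that("the >=20-per-sex filter keeps exactly the qualifying SNPs", {
  mk_calls <- function(n_male, n_female, marker = "m1") {
    data.frame(
      marker_id = marker, chrom = "chr1", pos_bp = 1,
      sample_id = c(sprintf("M%02d", seq_len(n_male)),
                    sprintf("F%02d", seq_len(n_female))),
      depth = 30L, genotype = "A/A", called = TRUE,
      lr_stat = 10, eps = 0.01)
  }
  sheet <- data.frame(
    sample_id = c(sprintf("M%02d", 1:30), sprintf("F%02d", 1:30)),
    family = "A", generation = "F2",
    sex = rep(c("male", "female"), each = 30))
  expect_equal(nrow(filter_min_per_sex(mk_calls(20, 19), sheet)), 0)
  expect_equal(nrow(filter_min_per_sex(mk_calls(20, 20), sheet)), 40)
  expect_error(filter_min_per_sex(mk_calls(20, 20), sheet,
                                  min_per_sex = 0), ">= 1")

  # seeded simulation with forced missingness agrees with a recount
  sim <- simulate_cross(tiny_config(n_f2 = 50, n_markers = 8,
                                    p_missing = 0.4), seed = 31)
  cm <- call_matrix(sim$counts, sheet = sim$samples)
  kept <- filter_min_per_sex(cm, sim$samples, min_per_sex = 15)
  sex <- sim$samples$sex[match(cm$calls$sample_id,
                               sim$samples$sample_id)]
  nm <- tapply(cm$calls$called & sex == "male", cm$calls$marker_id, sum)
  nf <- tapply(cm$calls$called & sex == "female", cm$calls$marker_id, sum)
  expect_setequal(unique(kept$marker_id),
                  names(nm)[nm >= 15 & nf >= 15])
})

test_that("run_sexscan localises a simulated sex-associated locus", {
  hits <- 0
  for (seed in 41:45) {
    sim <- simulate_cross(sim_config(n_f2 = 145), seed = seed)
    cm <- call_matrix(sim$counts)
    scan <- run_sexscan(cm, sim$samples)
    top <- scan[which.min(scan$p), ]
    if (top$chrom == sim$config$sar_loci[[1]]$chrom) hits <- hits + 1
  }
  expect_gte(hits, 4)
})

test_that("run_sexscan handles degenerate inputs per contract", {
  # a single tested SNP with p = 1 keeps q = 1 and no flag
  calls <- data.frame(
    marker_id = "m1", chrom = "chr1", pos_bp = 5,
    sample_id = sprintf("S%03d", 1:80), depth = 30L,
    genotype = rep(c("A/A", "A/C"), 40), called = TRUE,
    lr_stat = 10, eps = 0.01)
  sheet <- data.frame(
    sample_id = sprintf("S%03d", 1:80), family = "A", generation = "F2",
    sex = rep(c("male", "female"), each = 40))
  scan <- run_sexscan(calls, sheet)
  expect_equal(nrow(scan), 1)
  expect_equal(scan$q, 1)
  expect_false(scan$significant)

  # all SNPs filtered out: informative error
  thin <- calls[1:20, ]
  expect_error(run_sexscan(thin, sheet), "no SNPs survive")
})

test_that("null G-test p-values are uniform across many SNPs", {
  set.seed(202)
  n_snp <- 10000
  males <- rmultinom(n_snp, 82, c(0.25, 0.5, 0.25))
  females <- rmultinom(n_snp, 63, c(0.25, 0.5, 0.25))
  pv <- vapply(seq_len(n_snp), function(i) {
    tab <- rbind(males[, i], females[, i])
    tab <- tab[, colSums(tab) > 0, drop = FALSE]
    if (ncol(tab) < 2) return(NA_real_)
    g_test(tab)$p.value
  }, numeric(1))
  pv <- pv[!is.na(pv)]
  ks <- suppressWarnings(stats::ks.test(pv, "punif"))
  expect_gt(ks$p.value, 0.001)
})

test_that("allelic mode reduces the table to 2 x 2 allele counts", {
  calls <- data.frame(
    marker_id = "m1", chrom = "chr1", pos_bp = 5,
    sample_id = sprintf("S%03d", 1:100), depth = 30L,
    genotype = c(rep("A/A", 50), rep("A/C", 30), rep("C/C", 20)),
    called = TRUE, lr_stat = 10, eps = 0.01)
  sheet <- data.frame(
    sample_id = sprintf("S%03d", 1:100), family = "A", generation = "F2",
    sex = rep(c("male", "female"), 50))
  scan <- run_sexscan(calls, sheet, mode = "allelic")
  expect_equal(scan$df, 1)
  # hand-built allele table: per sex, 2 alleles per individual
  sex <- sheet$sex
  als <- strsplit(calls$genotype, "/", fixed = TRUE)
  tab <- table(rep(sex, each = 2), unlist(als))
  expect_equal(scan$G, g_test(tab)$G, tolerance = 1e-12)
})
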