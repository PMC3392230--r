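test_that("profile likelihood matches the closed forms at the bounds", {
  # clean homozygote: error rate clips to the lower bound
  pl <- profile_loglik("A/A", c(30, 0, 0, 0))
  expect_equal(pl$eps, 0.001)
  expect_equal(pl$lnL, 30 * log(0.999))

  # interior maximiser for an imperfect homozygote
  pl2 <- profile_loglik("A/A", c(28, 0, 2, 0))
  expect_equal(pl2$eps, 2 / 30)

  # balanced heterozygote: error rate clips low
  pl3 <- profile_loglik("A/C", c(10, 10, 0, 0))
  expect_equal(pl3$eps, 0.001)
  expect_equal(pl3$lnL, 20 * log((1 - 2 * 0.001 / 3) / 2))

  expect_error(profile_loglik("A/A", c(0, 0, 0, 0)), "depth")
})

test_that("profile likelihood equals a dense epsilon-grid search", {
  set.seed(101)
  cfg <- genotyper_config()
  for (i in 1:200) {
    depth <- sample(1:60, 1)
    counts <- if (i %% 2 == 0) {
      as.vector(rmultinom(1, depth, prob = runif(4)))
    } else {
      # model-like reads: the maximiser sits inside the epsilon bounds
      e <- runif(1, 0.005, 0.09)
      pair <- match(strsplit(ALL_GENOS[sample.int(10, 1)], "/")[[1]],
                    c("A", "C", "G", "T"))
      pr <- rep(e / 3, 4)
      if (pair[1] == pair[2]) pr[pair[1]] <- 1 - e
      else pr[pair] <- (1 - 2 * e / 3) / 2
      as.vector(rmultinom(1, depth, pr))
    }
    g <- ALL_GENOS[sample.int(10, 1)]
    pl <- profile_loglik(g, counts, cfg)
    expect_lt(abs(pl$lnL - grid_profile_max(g, counts)), 1e-6)
  }
})

test_that("call assignment follows the chi-square LRT rule", {
  # shallow site: best A/C beats A/A by too little
  lo <- call_genotype(c(3, 1, 0, 0))
  expect_false(lo$called)
  expect_equal(lo$lr_stat, 1.884, tolerance = 1e-3)
  expect_equal(lo$genotype, "A/C")

  # deep site clears the 6.6349 critical value
  hi <- call_genotype(c(19, 1, 0, 0))
  expect_true(hi$called)
  expect_equal(hi$genotype, "A/A")
  expect_equal(hi$lr_stat, 17.615, tolerance = 1e-3)

  # zero depth and exact first-place ties give no call
  expect_false(call_genotype(c(0, 0, 0, 0))$called)
  expect_false(call_genotype(c(1, 1, 1, 1))$called)
})

test_that("LR statistic is invariant under nucleotide relabelling", {
  set.seed(102)
  for (i in 1:50) {
    counts <- as.vector(rmultinom(1, sample(5:50, 1), runif(4)))
    perm <- sample(4)
    a <- call_genotype(counts)
    b <- call_genotype(counts[perm])
    if (is.na(a$lr_stat)) {
      expect_true(is.na(b$lr_stat))
    } else {
      expect_equal(a$lr_stat, b$lr_stat, tolerance = 1e-12)
      expect_equal(a$called, b$called)
    }
  }
})

test_that("doubling the counts of a called site never flips the call", {
  set.seed(103)
  checked <- 0
  while (checked < 1000) {
    eps <- runif(1, 0.001, 0.05)
    depth <- sample(5:40, 1)
    true_g <- ALL_GENOS[sample.int(10, 1)]
    al <- strsplit(true_g, "/", fixed = TRUE)[[1]]
    pr <- rep(eps / 3, 4)
    idx <- match(al, c("A", "C", "G", "T"))
    if (idx[1] == idx[2]) pr[idx[1]] <- 1 - eps
    else pr[idx] <- (1 - 2 * eps / 3) / 2
    counts <- as.vector(rmultinom(1, depth, pr))
    a <- call_genotype(counts)
    if (!a$called) next
    b <- call_genotype(counts * 2)
    expect_true(b$called)
    expect_identical(b$genotype, a$genotype)
    checked <- checked + 1
  }
})

test_that("call_matrix is accurate on simulated reads and handles no-data", {
  cfg <- tiny_config(n_f2 = 40, n_markers = 10, error_rate = 0.01,
                     p_missing = 0)
  sim <- simulate_cross(cfg, seed = 21)
  cm <- call_matrix(sim$counts, sheet = sim$samples)
  calls <- cm$calls

  # truth: nucleotides implied by gametic origins and founder alleles
  fa <- sim$geno$founder_alleles
  mt <- sim$geno$mat_origin
  pt <- sim$geno$pat_origin
  truth <- vapply(seq_len(nrow(calls)), function(i) {
    j <- match(calls$marker_id[i], fa$marker_id)
    k <- match(calls$sample_id[i], colnames(mt))
    a <- c(fa$allele_g1[j], fa$allele_g2[j])
    paste(sort(c(a[mt[j, k]], a[pt[j, k]])), collapse = "/")
  }, character(1))
  called <- calls$called
  expect_gt(mean(called), 0.8)
  expect_lt(mean(calls$genotype[called] != truth[called]), 0.01)

  # per-marker per-sex call counts line up with a direct recount
  sex <- sim$samples$sex[match(calls$sample_id, sim$samples$sample_id)]
  recount <- tapply(called & sex == "male", calls$marker_id, sum)
  expect_equal(
    cm$per_marker$n_male_called,
    as.vector(recount[cm$per_marker$marker_id]))

  zero <- sim$counts
  zero[c("n_A", "n_C", "n_G", "n_T")] <- 0L
  expect_equal(sum(call_matrix(zero)$calls$called), 0)
})

test_that("call rate is non-decreasing in depth for a fixed genotype", {
  set.seed(104)
  eps <- 0.01
  pr <- c((1 - 2 * eps / 3) / 2, (1 - 2 * eps / 3) / 2,
          eps / 3, eps / 3)  # true A/C heterozygote
  depths <- c(2, 5, 10, 20, 40, 60)
  rate <- vapply(depths, function(d) {
    counts <- t(rmultinom(2000, d, pr))
    tab <- data.frame(marker_id = "m", chrom = "c", pos_bp = 1,
                      sample_id = seq_len(nrow(counts)),
                      n_A = counts[, 1], n_C = counts[, 2],
                      n_G = counts[, 3], n_T = counts[, 4])
    mean(call_matrix(tab)$calls$called)
  }, numeric(1))
  expect_true(all(diff(rate) >= -0.02))
  expect_equal(rate[1], 0)        # depth 2 can never reach LR 6.63
  expect_gt(rate[6], 0.99)
})

test_that("the bounded error prior protects heterozygotes with biased reads", {
  # enumerate all A:C splits at depth 50 and collect the counts wrongly
  # called homozygous under each prior; the bounded set must be strictly
  # contained in the unbounded one
  bounded <- genotyper_config(0.001, 0.1)
  unbounded <- genotyper_config(0.001, 0.7)
  wrong <- function(cfg) {
    k <- 0:50
    hom <- vapply(k, function(ka) {
      cl <- call_genotype(c(ka, 50 - ka, 0, 0), cfg)
      cl$called && cl$genotype %in% c("A/A", "C/C")
    }, logical(1))
    k[hom]
  }
  wb <- wrong(bounded)
  wu <- wrong(unbounded)
  expect_true(all(wb %in% wu))
  expect_gt(length(wu), length(wb))
  # consequently the miscall rate for a biased true heterozygote is lower
  p_wrong <- function(ks) sum(dbinom(ks, 50, 0.8))
  expect_lt(p_wrong(wb), p_wrong(wu))
})
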