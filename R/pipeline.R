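## End-to-end orchestration: simulate (or ingest) -> genotype -> sex scan
## -> LOD scan -> recombination windows -> enrichment -> text report.
## Every stage draws from its own seed stream derived from the master
## seed, so outputs are pure functions of (inputs, config, seed).

#' Family-level sex-ratio summary
#'
#' @param sheet sample-sheet `data.frame`.
#' @param family family label to summarise.
#' @return one-row `data.frame`: `family`, `n_male`, `n_female`,
#'   `sex_ratio` (male/female) and `sex_ratio_display` (one decimal,
#'   `"undefined"` when there are no females).
#' @export
summarize_family <- function(sheet, family) {
  s <- sheet[sheet$family == family, , drop = FALSE]
  check_that(nrow(s) > 0, "family not present: ", family)
  nm <- sum(s$sex == "male")
  nf <- sum(s$sex == "female")
  ratio <- if (nf > 0) nm / nf else NA_real_
  data.frame(
    family = family, n_male = nm, n_female = nf, sex_ratio = ratio,
    sex_ratio_display = if (nf > 0)
      sprintf("%.1f", round_half_away(ratio, 1)) else "undefined",
    stringsAsFactors = FALSE)
}

## simulate a demo element set: most classes uniform along the genome,
## one ("satellite_repeat") concentrated in the terminal region of the
## sex-associated chromosome, so the enrichment stage has signal
simulate_elements <- function(config, seed, sar_chrom,
                              n_per_class = c(uniform_repeat = 400,
                                              satellite_repeat = 300)) {
  set.seed(seed)
  chroms <- config$chromosomes
  tot <- sum(chroms$length_bp)
  rows <- list()
  for (k in names(n_per_class)) {
    n <- n_per_class[[k]]
    if (k == "satellite_repeat") {
      ## 70% of copies in the terminal 10% of the sar chromosome
      n_in <- round(0.7 * n)
      len <- chroms$length_bp[chroms$name == sar_chrom]
      st_in <- sort(sample.int(round(0.1 * len), n_in)) + round(0.9 * len)
      ch_in <- rep(sar_chrom, n_in)
      n_out <- n - n_in
      pos <- sample.int(tot, n_out)
      brk <- cumsum(as.numeric(chroms$length_bp))
      ci <- findInterval(pos - 1, c(0, brk[-length(brk)]))
      st_out <- pos - c(0, brk)[ci] - 1
      rows[[k]] <- data.frame(
        chrom = c(ch_in, chroms$name[ci]),
        start = c(st_in, st_out), element_class = k,
        stringsAsFactors = FALSE)
    } else {
      pos <- sample.int(tot, n)
      brk <- cumsum(as.numeric(chroms$length_bp))
      ci <- findInterval(pos - 1, c(0, brk[-length(brk)]))
      rows[[k]] <- data.frame(
        chrom = chroms$name[ci], start = pos - c(0, brk)[ci] - 1,
        element_class = k, stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  out$end <- out$start + 100L
  rownames(out) <- NULL
  out[c("chrom", "start", "end", "element_class")]
}

#' Run the full pipeline
#'
#' Simulates an F2 family (or ingests supplied read counts and sample
#' sheet), calls genotypes, runs the G-test sex scan and the binary LOD
#' scan, profiles sex-specific recombination rates, summarises element
#' enrichment in the terminal region of the sex-associated chromosome,
#' and writes every stage output plus a text report under `out_dir`.
#'
#' @param config a [sim_config()] object.
#' @param seed master integer seed.
#' @param out_dir output directory (created if needed).
#' @param counts_path,sheet_path optional paths to externally supplied
#'   read counts and sample sheet TSVs used in place of simulation (the
#'   LOD/recombination stages, which need phase-known truth genotypes,
#'   are skipped in that case).
#' @param n_perm permutations for the LOD thresholds (default 1000).
#' @param min_per_sex,fdr sex-scan filter and flag threshold.
#' @return (invisibly) a list with every stage result and the report
#'   path.
#' @export
run_all <- function(config = sim_config(), seed = 1L, out_dir,
                    counts_path = NULL, sheet_path = NULL,
                    n_perm = 1000, min_per_sex = 20, fdr = 0.001) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop(sprintf("pipeline stage '%s' failed: %s", name,
                   conditionMessage(e)), call. = FALSE))
  }
  external <- !is.null(counts_path)
  report <- c(sprintf("radsexscan pipeline report (seed %d)", seed))

  if (external) {
    check_that(!is.null(sheet_path),
               "external counts require a sample sheet")
    counts <- stage("ingest", read_counts_table(counts_path))
    sheet <- stage("ingest", read_sample_sheet(sheet_path))
    sim <- NULL
  } else {
    sim <- stage("simulate", simulate_cross(config, seed))
    counts <- sim$counts
    sheet <- sim$samples
    write_counts_table(counts, file.path(out_dir, "read_counts.tsv"))
    write_sample_sheet(sheet, file.path(out_dir, "sample_sheet.tsv"))
    write_genetic_map(sim$geno$map, file.path(out_dir, "true_map.tsv"))
    truth <- data.frame(
      marker_id = rep(rownames(sim$geno$mat_origin),
                      ncol(sim$geno$mat_origin)),
      sample_id = rep(colnames(sim$geno$mat_origin),
                      each = nrow(sim$geno$mat_origin)),
      mat_origin = as.vector(sim$geno$mat_origin),
      pat_origin = as.vector(sim$geno$pat_origin),
      stringsAsFactors = FALSE)
    write_tsv(truth, file.path(out_dir, "true_genotypes.tsv"))
  }

  fam <- unique(sheet$family)[1]
  fam_sum <- stage("summary", summarize_family(sheet, fam))
  write_tsv(fam_sum, file.path(out_dir, "family_summary.tsv"))
  report <- c(report, "",
              sprintf("Family %s: %d male, %d female (ratio %s:1)",
                      fam_sum$family, fam_sum$n_male, fam_sum$n_female,
                      fam_sum$sex_ratio_display))

  calls <- stage("genotype", call_matrix(counts, sheet = sheet))
  write_tsv(calls$calls, file.path(out_dir, "genotype_calls.tsv"))
  report <- c(report, sprintf("Genotyping: %d records, call rate %.1f%%",
                              nrow(calls$calls),
                              100 * mean(calls$calls$called)))

  scan <- stage("sexscan",
                run_sexscan(calls, sheet, min_per_sex = min_per_sex,
                            fdr = fdr))
  write_scan_results(scan, file.path(out_dir, "sexscan.tsv"))
  top <- scan[order(scan$p), ][1:min(5, nrow(scan)), ]
  report <- c(report, "",
              sprintf("Sex scan: %d SNPs tested, %d with q < %g",
                      nrow(scan), sum(scan$significant), fdr),
              sprintf("  top SNP %s (%s:%d)  G = %.1f  p = %.3g  q = %.3g",
                      top$marker_id[1], top$chrom[1], top$pos_bp[1],
                      top$G[1], top$p[1], top$q[1]))

  lod <- NULL
  windows <- NULL
  if (!external) {
    lod <- stage("qtlscan",
                 run_lodscan(sim$geno, sheet, n_perm = n_perm,
                             seed = stage_seed(seed, "qtl")))
    write_scan_results(lod$scan, file.path(out_dir, "lodscan.tsv"))
    write_tsv(data.frame(quantile = names(lod$thresholds),
                         lod = as.vector(lod$thresholds)),
              file.path(out_dir, "lod_thresholds.tsv"))
    if (nrow(lod$intervals))
      write_tsv(lod$intervals, file.path(out_dir, "lod_intervals.tsv"))
    pk <- which.max(lod$scan$lod)
    report <- c(report, "",
                sprintf("LOD scan: peak %.2f at %s (%s); thresholds %s",
                        lod$scan$lod[pk], lod$scan$marker_id[pk],
                        lod$scan$chrom[pk],
                        paste(sprintf("%s = %.2f", names(lod$thresholds),
                                      lod$thresholds), collapse = ", ")))
    if (nrow(lod$intervals))
      report <- c(report, sprintf(
        "  1.5-LOD interval: %s %.1f-%.1f cM (%d-%d bp)",
        lod$intervals$chrom[1], lod$intervals$cM_lo[1],
        lod$intervals$cM_hi[1], lod$intervals$bp_lo[1],
        lod$intervals$bp_hi[1]))

    emap_f <- stage("recomb", estimate_map(sim$geno, "female"))
    emap_m <- stage("recomb", estimate_map(sim$geno, "male"))
    emap <- emap_f
    names(emap)[names(emap) == "cM"] <- "cM_female"
    emap$cM_male <- emap_m$cM
    windows <- rbind(sliding_window_rate(emap, "female"),
                     sliding_window_rate(emap, "male"))
    write_tsv(windows, file.path(out_dir, "recomb_windows.tsv"))
    mean_f <- mean(windows$rate[windows$parent_sex == "female"])
    mean_m <- mean(windows$rate[windows$parent_sex == "male"])
    report <- c(report, "",
                sprintf(
                  "Recombination: mean rate %.2f (female) vs %.2f (male) cM/Mb",
                  mean_f, mean_m))
  }

  sar_chrom <- config$sar_loci[[1]]$chrom
  elements <- stage("enrich",
                    simulate_elements(config, stage_seed(seed, "elements"),
                                      sar_chrom))
  sar_len <- config$chromosomes$length_bp[
    config$chromosomes$name == sar_chrom]
  region_start <- round(0.9 * sar_len)
  frac <- (sar_len - region_start) / sum(config$chromosomes$length_bp)
  enr <- stage("enrich",
               region_enrichment(elements, sar_chrom, region_start,
                                 sar_len, frac))
  write_tsv(enr, file.path(out_dir, "enrichment.tsv"))
  report <- c(report, "", sprintf(
    "Enrichment in %s:%d-%d (%.2f%% of genome):", sar_chrom,
    region_start, sar_len, 100 * frac))
  report <- c(report, sprintf(
    "  %-18s n = %5d  expected %6s  observed %5d  (%s%%)  p = %.3g",
    enr$element_class, enr$n_genome, enr$expected_display, enr$observed,
    enr$percent_display, enr$p_binomial))

  report_path <- file.path(out_dir, "report.txt")
  writeLines(report, report_path)
  invisible(list(sim = sim, family_summary = fam_sum, calls = calls,
                 sexscan = scan, lodscan = lod, windows = windows,
                 enrichment = enr, report = report_path))
}
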