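## Readers and writers for the pipeline's tabular formats. All files are
## tab-separated UTF-8 with a mandatory header, no quoting; marker tables
## are 1-based bp, element intervals are 0-based half-open (BED).

COUNTS_COLS <- c("marker_id", "chrom", "pos_bp", "sample_id",
                 "n_A", "n_C", "n_G", "n_T")
SHEET_COLS <- c("sample_id", "family", "generation", "sex")
MAP_COLS <- c("marker_id", "chrom", "pos_bp", "cM_female", "cM_male")

read_tsv_strict <- function(path, required_cols) {
  check_that(file.exists(path), "file not found: ", path)
  x <- utils::read.delim(path, header = TRUE, sep = "\t", quote = "",
                         stringsAsFactors = FALSE, check.names = FALSE)
  missing <- setdiff(required_cols, names(x))
  check_that(length(missing) == 0,
             "missing column(s) in ", path, ": ",
             paste(missing, collapse = ", "))
  x[required_cols]
}

## data row i lives on file line i + 1 (header is line 1)
line_of <- function(i) i + 1L

#' Read a per-site, per-individual nucleotide read-count table
#'
#' Parses a tab-separated table with columns `marker_id`, `chrom`,
#' `pos_bp` (1-based), `sample_id`, and the four nucleotide read counts
#' `n_A`, `n_C`, `n_G`, `n_T`. Counts must be non-negative integers and
#' each (marker, sample) pair may occur once.
#'
#' @param path path to a TSV file.
#' @return a `data.frame` of validated read counts.
#' @export
read_counts_table <- function(path) {
  x <- read_tsv_strict(path, COUNTS_COLS)
  validate_counts_table(x, where = path)
  message(sprintf("read_counts_table: %d rows from %s", nrow(x), path))
  x
}

validate_counts_table <- function(x, where = "counts table") {
  cnt <- as.matrix(x[c("n_A", "n_C", "n_G", "n_T")])
  bad <- which(!is.finite(cnt) | cnt < 0 | cnt != floor(cnt),
               arr.ind = TRUE)
  check_that(nrow(bad) == 0 || length(bad) == 0,
             where, ": invalid nucleotide count at line ",
             line_of(bad[1, 1]))
  badpos <- which(!is.finite(x$pos_bp) | x$pos_bp < 1)
  check_that(length(badpos) == 0,
             where, ": pos_bp < 1 at line ", line_of(badpos[1]))
  key <- paste(x$marker_id, x$sample_id)
  dup <- which(duplicated(key))
  check_that(length(dup) == 0,
             where, ": duplicate (marker_id, sample_id) at line ",
             line_of(dup[1]))
  invisible(x)
}

#' Write a read-count table as TSV
#' @param x a counts `data.frame` (see [read_counts_table()]).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_counts_table <- function(x, path) {
  write_tsv(x[COUNTS_COLS], path)
}

#' Read a sample sheet
#'
#' Columns: `sample_id`, `family`, `generation` (F0/F1/F2), `sex`
#' (`male`, `female` or `unknown`, spelled out). Individuals whose gonadal
#' sex could not be determined are carried as `unknown` and excluded from
#' association stages downstream.
#'
#' @param path path to a TSV file.
#' @return a `data.frame` sample sheet.
#' @export
read_sample_sheet <- function(path) {
  x <- read_tsv_strict(path, SHEET_COLS)
  if (nrow(x) == 0) {
    warning("sample sheet is empty: ", path)
    return(x)
  }
  validate_sample_sheet(x, where = path)
  tal <- table(x$family, x$sex)
  message(sprintf("read_sample_sheet: %d samples; per family/sex: %s",
                  nrow(x),
                  paste(apply(as.data.frame(tal), 1, paste, collapse = ":"),
                        collapse = "; ")))
  x
}

validate_sample_sheet <- function(x, where = "sample sheet") {
  dup <- which(duplicated(x$sample_id))
  check_that(length(dup) == 0,
             where, ": duplicate sample_id at line ", line_of(dup[1]))
  badsex <- which(!x$sex %in% c("male", "female", "unknown"))
  check_that(length(badsex) == 0,
             where, ": unknown sex token '", x$sex[badsex[1]],
             "' at line ", line_of(badsex[1]),
             " (use male/female/unknown)")
  badgen <- which(!x$generation %in% c("F0", "F1", "F2"))
  check_that(length(badgen) == 0,
             where, ": unknown generation '", x$generation[badgen[1]],
             "' at line ", line_of(badgen[1]))
  invisible(x)
}

#' Write a sample sheet as TSV
#' @param x a sample-sheet `data.frame`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_sample_sheet <- function(x, path) {
  write_tsv(x[SHEET_COLS], path)
}

#' Read a genetic map
#'
#' Columns: `marker_id`, `chrom`, `pos_bp` (1-based), `cM_female`,
#' `cM_male` (cumulative sex-specific map positions). Within each
#' chromosome the cM columns must be non-decreasing in physical order.
#'
#' @param path path to a TSV file.
#' @return a `data.frame` genetic map.
#' @export
read_genetic_map <- function(path) {
  x <- read_tsv_strict(path, MAP_COLS)
  validate_genetic_map(x, where = path)
  message(sprintf("read_genetic_map: %d markers on %d chromosome(s)",
                  nrow(x), length(unique(x$chrom))))
  x
}

validate_genetic_map <- function(x, where = "genetic map") {
  check_that(all(x$pos_bp >= 1), where, ": pos_bp must be >= 1")
  check_that(all(x$cM_female >= 0) && all(x$cM_male >= 0),
             where, ": cM positions must be non-negative")
  for (ch in unique(x$chrom)) {
    sub <- x[x$chrom == ch, ]
    sub <- sub[order(sub$pos_bp), ]
    check_that(!is.unsorted(sub$cM_female) && !is.unsorted(sub$cM_male),
               where, ": cM not non-decreasing along chromosome ", ch)
  }
  invisible(x)
}

#' Write a genetic map as TSV
#' @param x a genetic-map `data.frame`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_genetic_map <- function(x, path) {
  write_tsv(x[MAP_COLS], path)
}

#' Read a genomic element set from BED
#'
#' Imports a BED file (0-based half-open intervals) and returns a plain
#' `data.frame` with columns `chrom`, `start` (0-based inclusive), `end`
#' (exclusive) and `element_class` (the BED name column).
#'
#' @param path path to a BED file with a name column.
#' @return a `data.frame` element set.
#' @export
read_elements_bed <- function(path) {
  check_that(file.exists(path), "file not found: ", path)
  gr <- as.data.frame(rtracklayer::import(path, format = "BED"))
  check_that(!is.null(gr$name) && !anyNA(gr$name),
             path, ": BED name column (element class) is required")
  out <- data.frame(
    chrom = as.character(gr$seqnames),
    start = gr$start - 1L,  # back to 0-based half-open
    end = gr$end,
    element_class = gr$name,
    stringsAsFactors = FALSE
  )
  check_that(all(out$start < out$end), path, ": interval with start >= end")
  out
}

#' Write a scan-result table as TSV
#'
#' Serialises any per-marker result table with a header, deterministic
#' (chrom, pos_bp) row order and floats at 6 significant digits.
#'
#' @param results non-empty `data.frame` with at least `chrom` and
#'   `pos_bp` columns.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_scan_results <- function(results, path) {
  check_that(is.data.frame(results) && nrow(results) > 0,
             "results must be a non-empty data.frame")
  check_that(all(c("chrom", "pos_bp") %in% names(results)),
             "results must have chrom and pos_bp columns")
  results <- results[order(results$chrom, results$pos_bp), , drop = FALSE]
  out <- results
  isnum <- vapply(out, is.double, logical(1))
  out[isnum] <- lapply(out[isnum], fmt_sig6)
  write_tsv(out, path)
}

#' Read back a scan-result table written by [write_scan_results()]
#' @param path path to the TSV file.
#' @return a `data.frame`.
#' @export
read_scan_results <- function(path) {
  check_that(file.exists(path), "file not found: ", path)
  utils::read.delim(path, sep = "\t", quote = "", stringsAsFactors = FALSE)
}

write_tsv <- function(x, path) {
  ok <- tryCatch({
    utils::write.table(x, path, sep = "\t", quote = FALSE,
                       row.names = FALSE, fileEncoding = "UTF-8")
    TRUE
  }, error = function(e) e)
  if (!isTRUE(ok)) stop("cannot write ", path, ": ",
                        conditionMessage(ok), call. = FALSE)
  invisible(path)
}

#' Export called genotypes as a minimal VCFv4.2 file
#'
#' Writes biallelic called genotypes with `GT` and `DP` fields. The
#' reference allele is taken as the major called allele at each site; sites
#' with more than two called alleles are skipped with a warning. This is an
#' export convenience only — no VCF parsing is provided.
#'
#' @param calls a calls `data.frame` from [call_matrix()] (component
#'   `$calls`).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_genotype_vcf <- function(calls, path) {
  check_that(is.data.frame(calls) && nrow(calls) > 0,
             "calls must be a non-empty data.frame")
  samples <- sort(unique(calls$sample_id))
  hdr <- c(
    "##fileformat=VCFv4.2",
    "##source=radsexscan",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Read depth\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", samples), collapse = "\t")
  )
  rows <- character(0)
  for (mk in unique(calls$marker_id)) {
    sub <- calls[calls$marker_id == mk, ]
    called <- sub[sub$called & !is.na(sub$genotype), ]
    if (nrow(called) == 0) next
    als <- sort(table(unlist(strsplit(called$genotype, "/", fixed = TRUE))),
                decreasing = TRUE)
    if (length(als) > 2) {
      warning("skipping multi-allelic site in VCF export: ", mk)
      next
    }
    ref <- names(als)[1]
    alt <- if (length(als) == 2) names(als)[2] else "."
    gt_of <- function(g, dp) {
      if (is.na(g)) return(sprintf("./.:%d", dp))
      a <- strsplit(g, "/", fixed = TRUE)[[1]]
      code <- ifelse(a == ref, "0", "1")
      sprintf("%s:%d", paste(sort(code), collapse = "/"), dp)
    }
    sub <- sub[match(samples, sub$sample_id), ]
    geno <- mapply(gt_of,
                   ifelse(sub$called, sub$genotype, NA_character_),
                   ifelse(is.na(sub$depth), 0L, sub$depth))
    rows <- c(rows, paste(c(sub$chrom[1], sub$pos_bp[1], mk, ref, alt, ".",
                            "PASS", ".", "GT:DP", geno), collapse = "\t"))
  }
  writeLines(c(hdr, rows), path)
  invisible(path)
}
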