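## Region-enrichment arithmetic for genomic element classes: observed
## counts in a target region, expected counts under uniform genome-wide
## placement, percent-in-region, and an upper-tail binomial test.

#' Count elements falling in a genomic region
#'
#' By the default start-point rule, an element is counted if its 0-based
#' start lies within the half-open region `[start, end)`. The
#' `"any"` rule instead counts any overlap.
#'
#' @param elements element-set `data.frame` (`chrom`, `start`, `end`,
#'   `element_class`; 0-based half-open — see [read_elements_bed()]).
#' @param chrom region chromosome.
#' @param start,end region bounds, 0-based half-open.
#' @param element_class optional class restriction.
#' @param rule `"start"` (default) or `"any"` overlap rule.
#' @return integer count.
#' @export
count_in_region <- function(elements, chrom, start, end,
                            element_class = NULL,
                            rule = c("start", "any")) {
  rule <- match.arg(rule)
  check_that(end > start, "region end must exceed start")
  sel <- elements$chrom == chrom
  if (!is.null(element_class))
    sel <- sel & elements$element_class == element_class
  e <- elements[sel, , drop = FALSE]
  hit <- if (rule == "start") {
    e$start >= start & e$start < end
  } else {
    e$start < end & e$end > start
  }
  sum(hit)
}

#' Enrichment summary for one element class in a target region
#'
#' Expected count under uniform placement is `n_genome * region_fraction`;
#' percent-in-region is `100 * observed / n_genome`; the enrichment
#' p-value is the upper-tail binomial probability
#' `P(X >= observed), X ~ Binomial(n_genome, region_fraction)`.
#' Display columns round half away from zero: percent to one decimal,
#' expected to one decimal below 10 and to an integer at 10 or above
#' (matching how such tables are conventionally printed).
#'
#' @param n_genome genome-wide copy number of the element class.
#' @param observed copies observed in the region.
#' @param region_fraction fraction of the genome covered by the region,
#'   in (0, 1\].
#' @param element_class optional label carried into the output.
#' @return one-row `data.frame` of class `region_enrichment`:
#'   `element_class`, `n_genome`, `region_fraction`, `expected`,
#'   `observed`, `percent_in_region`, `p_binomial`, `expected_display`,
#'   `percent_display`.
#' @export
enrichment_summary <- function(n_genome, observed, region_fraction,
                               element_class = NA_character_) {
  check_that(region_fraction > 0 && region_fraction <= 1,
             "region_fraction must be in (0, 1]")
  check_that(observed >= 0 && n_genome >= 0, "counts must be non-negative")
  check_that(observed <= n_genome, "observed cannot exceed n_genome")
  expected <- n_genome * region_fraction
  percent <- if (n_genome > 0) 100 * observed / n_genome else NA_real_
  p <- stats::pbinom(observed - 1, n_genome, region_fraction,
                     lower.tail = FALSE)
  out <- data.frame(
    element_class = element_class, n_genome = n_genome,
    region_fraction = region_fraction, expected = expected,
    observed = observed, percent_in_region = percent, p_binomial = p,
    expected_display = display_expected(expected),
    percent_display = sprintf("%.1f", round_half_away(percent, 1)),
    stringsAsFactors = FALSE)
  class(out) <- c("region_enrichment", "data.frame")
  out
}

## expected-count display: one decimal under 10, integer at >= 10
display_expected <- function(x) {
  ifelse(x < 10,
         sprintf("%.1f", round_half_away(x, 1)),
         sprintf("%d", as.integer(round_half_away(x, 0))))
}

#' Enrichment summaries for many element classes
#'
#' @param classes `data.frame` with columns `element_class`, `n_genome`,
#'   `observed`.
#' @param region_fraction fraction of the genome covered by the region.
#' @return a `region_enrichment` `data.frame`, one row per class.
#' @export
enrichment_table <- function(classes, region_fraction) {
  rows <- lapply(seq_len(nrow(classes)), function(i)
    enrichment_summary(classes$n_genome[i], classes$observed[i],
                       region_fraction,
                       element_class = classes$element_class[i]))
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Count-and-summarise enrichment from an element set
#'
#' Convenience wrapper: counts genome-wide and in-region copies of every
#' element class present and summarises each.
#'
#' @param elements element-set `data.frame`.
#' @param chrom,start,end target region (0-based half-open).
#' @param region_fraction fraction of the genome covered by the region.
#' @param rule counting rule, see [count_in_region()].
#' @return a `region_enrichment` `data.frame`.
#' @export
region_enrichment <- function(elements, chrom, start, end,
                              region_fraction, rule = "start") {
  cls <- sort(unique(elements$element_class))
  classes <- data.frame(
    element_class = cls,
    n_genome = vapply(cls, function(k)
      sum(elements$element_class == k), integer(1)),
    observed = vapply(cls, function(k)
      count_in_region(elements, chrom, start, end, k, rule = rule),
      integer(1)),
    stringsAsFactors = FALSE)
  enrichment_table(classes, region_fraction)
}
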