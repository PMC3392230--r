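## Sex-specific recombination fractions between adjacent markers, Kosambi
## map conversion, and 3-marker sliding-window cM/Mb rate profiles.

#' Kosambi map distance from a recombination fraction
#'
#' `d = 25 ln((1 + 2r) / (1 - 2r))` centiMorgans.
#'
#' @param r recombination fraction(s) in \[0, 0.5).
#' @return map distance(s) in cM.
#' @seealso [kosambi_r()] for the inverse.
#' @export
kosambi_cm <- function(r) {
  check_that(all(r >= 0) && all(r < 0.5), "r must be in [0, 0.5)")
  25 * log((1 + 2 * r) / (1 - 2 * r))
}

#' Kosambi recombination fraction from a map distance
#'
#' `r = 0.5 tanh(2 d / 100)` for `d` in centiMorgans.
#'
#' @param d map distance(s) in cM, non-negative.
#' @return recombination fraction(s) in \[0, 0.5).
#' @export
kosambi_r <- function(d) {
  check_that(all(d >= 0), "d must be non-negative")
  0.5 * tanh(2 * d / 100)
}

#' Estimate the recombination fraction between two markers
#'
#' For the chosen parent's gametes (maternal or paternal grandparental
#' origins in a phase-known cross), the estimate is the fraction of
#' individuals whose gametic origin switches between the two markers.
#' Individuals missing either marker are dropped pairwise. Estimates at
#' or above 0.5 are capped at 0.4999 (with a warning) so Kosambi
#' conversion stays finite.
#'
#' @param geno a `radsex_geno` object.
#' @param marker_a,marker_b marker identifiers.
#' @param parent_sex `"female"` (maternal gametes) or `"male"`.
#' @return list with `r` (capped estimate) and `n_informative`.
#' @export
estimate_rf <- function(geno, marker_a, marker_b,
                        parent_sex = c("female", "male")) {
  parent_sex <- match.arg(parent_sex)
  org <- if (parent_sex == "female") geno$mat_origin else geno$pat_origin
  ia <- match(marker_a, rownames(org))
  ib <- match(marker_b, rownames(org))
  check_that(!is.na(ia) && !is.na(ib), "marker not found")
  a <- org[ia, ]
  b <- org[ib, ]
  ok <- !is.na(a) & !is.na(b)
  n <- sum(ok)
  check_that(n > 0, "zero informative gametes for ", marker_a, " x ",
             marker_b)
  r <- sum(a[ok] != b[ok]) / n
  if (r >= 0.5) {
    warning(sprintf("r estimate %.4f >= 0.5 capped at 0.4999 (%s x %s)",
                    r, marker_a, marker_b))
    r <- 0.4999
  }
  list(r = r, n_informative = n)
}

#' Re-estimate a sex-specific genetic map from gametic origins
#'
#' Builds cumulative Kosambi cM positions per chromosome from
#' adjacent-marker recombination fractions of the chosen parent's
#' gametes.
#'
#' @param geno a `radsex_geno` object.
#' @param parent_sex `"female"` or `"male"`.
#' @return a `data.frame` with `marker_id`, `chrom`, `pos_bp`, `cM`.
#' @export
estimate_map <- function(geno, parent_sex = c("female", "male")) {
  parent_sex <- match.arg(parent_sex)
  map <- geno$map
  out <- lapply(unique(map$chrom), function(ch) {
    mk <- map$marker_id[map$chrom == ch]
    cm <- numeric(length(mk))
    for (i in seq_along(mk)[-1]) {
      rf <- estimate_rf(geno, mk[i - 1], mk[i], parent_sex)
      cm[i] <- cm[i - 1] + kosambi_cm(rf$r)
    }
    data.frame(marker_id = mk, chrom = ch,
               pos_bp = map$pos_bp[map$chrom == ch], cM = cm,
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Sliding-window recombination rates (cM per Mb)
#'
#' Over windows of `window_markers` markers advancing by `step`,
#' `rate = (cM(last) - cM(first)) / Mb(last bp - first bp)` for the
#' chosen parent sex, anchored at the window's middle marker. Windows
#' with non-positive physical span are skipped with a warning.
#'
#' @param map genetic-map `data.frame` (`marker_id`, `chrom`, `pos_bp`,
#'   `cM_female`, `cM_male`), sorted by physical position within
#'   chromosome.
#' @param parent_sex `"female"` or `"male"`.
#' @param window_markers markers per window (default 3).
#' @param step markers advanced per window (default 1).
#' @return `data.frame` of class `recomb_windows`: `chrom`, `window`,
#'   `marker_first`, `marker_mid`, `marker_last`, `pos_mid_bp`,
#'   `cM_span`, `Mb_span`, `rate`, `parent_sex`.
#' @export
sliding_window_rate <- function(map, parent_sex = c("female", "male"),
                                window_markers = 3, step = 1) {
  parent_sex <- match.arg(parent_sex)
  cm_col <- if (parent_sex == "female") "cM_female" else "cM_male"
  check_that(cm_col %in% names(map),
             "map lacks the ", cm_col, " column")
  out <- list()
  for (ch in unique(map$chrom)) {
    s <- map[map$chrom == ch, , drop = FALSE]
    check_that(!is.unsorted(s$pos_bp, strictly = TRUE),
               "map not sorted by pos_bp on chromosome ", ch)
    n <- nrow(s)
    if (n < window_markers) next
    starts <- seq(1, n - window_markers + 1, by = step)
    for (w in seq_along(starts)) {
      i <- starts[w]
      j <- i + window_markers - 1
      mid <- i + (window_markers - 1) %/% 2
      mb <- (s$pos_bp[j] - s$pos_bp[i]) / 1e6
      if (mb <= 0) {
        warning("skipping zero-span window at ", ch, ":", s$pos_bp[i])
        next
      }
      out[[length(out) + 1]] <- data.frame(
        chrom = ch, window = w,
        marker_first = s$marker_id[i], marker_mid = s$marker_id[mid],
        marker_last = s$marker_id[j], pos_mid_bp = s$pos_bp[mid],
        cM_span = s[[cm_col]][j] - s[[cm_col]][i], Mb_span = mb,
        rate = (s[[cm_col]][j] - s[[cm_col]][i]) / mb,
        parent_sex = parent_sex, stringsAsFactors = FALSE)
    }
  }
  check_that(length(out) > 0, "no chromosome has enough markers")
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  class(res) <- c("recomb_windows", "data.frame")
  res
}
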