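#' Two-sided Mann-Whitney U comparison
#'
#' Rank-sum comparison of two groups as used for all pairwise contrasts in
#' the analysis (non-normally distributed single-cell data). The exact
#' permutation distribution is used when both groups are at most
#' \code{exactThreshold} observations and there are no ties; otherwise the
#' normal approximation with tie and continuity correction.
#'
#' @param a,b numeric samples (both nonempty).
#' @param exactThreshold maximum group size for the exact path.
#' @return list with \code{n1}, \code{n2}, \code{U} (statistic for group a),
#'   \code{p} (two-sided), \code{median1}, \code{median2}, \code{exact}.
#' @examples
#' mannWhitney(c(1, 2, 3), c(4, 5, 6))$p  # 0.1, complete separation at n = 3
#' @export
mannWhitney <- function(a, b, exactThreshold = 8L) {
  if (!length(a) || !length(b)) stop("both groups must be nonempty")
  ties <- anyDuplicated(c(a, b)) > 0
  exact <- length(a) <= exactThreshold && length(b) <= exactThreshold && !ties
  wt <- suppressWarnings(
    stats::wilcox.test(a, b, exact = exact, correct = TRUE))
  list(n1 = length(a), n2 = length(b),
       U = unname(wt$statistic), p = wt$p.value,
       median1 = stats::median(a), median2 = stats::median(b),
       exact = exact)
}

#' Summary statistics with bootstrap SE of the median
#'
#' Median, mean, SD (n - 1 denominator) and a seeded bootstrap SE of the
#' median, the dispersion measure quoted for median cell properties.
#'
#' @param values numeric sample (nonempty).
#' @param nBoot bootstrap resamples.
#' @param seed integer seed.
#' @return list with \code{n}, \code{median}, \code{mean}, \code{sd},
#'   \code{seMedian}, and \code{degenerate} (TRUE for a single value, whose
#'   SD and SE are undefined).
#' @examples
#' summaryStats(c(1, 2, 3))$sd  # 1
#' @export
summaryStats <- function(values, nBoot = 2000L, seed = 1L) {
  values <- values[!is.na(values)]
  if (!length(values)) stop("values must be nonempty")
  if (length(values) == 1L)
    return(list(n = 1L, median = values, mean = values, sd = NA_real_,
                seMedian = NA_real_, degenerate = TRUE))
  set.seed(seed)
  boots <- vapply(seq_len(nBoot), function(i)
    stats::median(sample(values, replace = TRUE)), 0)
  list(n = length(values), median = stats::median(values),
       mean = mean(values), sd = stats::sd(values),
       seMedian = stats::sd(boots), degenerate = FALSE)
}

#' Redfield reference ratios
#' @return named numeric: canonical marine C:N (106/16), C:P (106) and
#'   N:P (16) molar ratios.
#' @export
redfieldRatios <- function() c(CN = 106 / 16, CP = 106, NP = 16)

#' Elemental-ratio comparison table
#'
#' Per elemental ratio (C:N, C:P, N:P): group medians, a Mann-Whitney
#' comparison between two groups (or against NULL for a single cohort), and
#' the fraction of cells below the canonical Redfield reference. Mirrors the
#' epibiont elemental-composition comparison (e.g. Aphanizomenon- vs
#' Nodularia-associated epibionts).
#'
#' @param compositions data.frame with per-cell molar ratio columns among
#'   \code{CN}, \code{CP}, \code{NP}; missing channels are skipped with a
#'   warning.
#' @param groups optional factor/character of group labels (2 groups for a
#'   comparison; NULL treats all cells as one cohort).
#' @return data.frame per ratio: n, medians (per group when grouped), p
#'   (NA for a single cohort), Redfield reference and fraction of cells
#'   below it.
#' @export
elementalRatioReport <- function(compositions, groups = NULL) {
  ref <- redfieldRatios()
  rows <- list()
  for (ratio in names(ref)) {
    if (!ratio %in% names(compositions)) {
      warning("ratio channel missing, skipped: ", ratio)
      next
    }
    x <- compositions[[ratio]]
    ok <- !is.na(x)
    x <- x[ok]
    if (is.null(groups)) {
      rows[[ratio]] <- data.frame(
        ratio = ratio, n = length(x), median = stats::median(x),
        medianA = NA_real_, medianB = NA_real_, p = NA_real_,
        redfield = unname(ref[ratio]),
        fractionBelowRedfield = mean(x < ref[ratio]))
    } else {
      g <- factor(groups[ok])
      if (nlevels(g) != 2L)
        stop("groups must have exactly two levels (or be NULL)")
      mw <- mannWhitney(x[g == levels(g)[1]], x[g == levels(g)[2]])
      rows[[ratio]] <- data.frame(
        ratio = ratio, n = length(x), median = stats::median(x),
        medianA = mw$median1, medianB = mw$median2, p = mw$p,
        redfield = unname(ref[ratio]),
        fractionBelowRedfield = mean(x < ref[ratio]))
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
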