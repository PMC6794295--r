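#' Epibiont share of total fixed C or N per cyanobacterial cell
#'
#' The percentage of the total element assimilation of a cyanobacterial cell
#' plus its attached epibionts that is recovered in the epibionts:
#' \code{share = E * n / (E * n + C) * 100}, with E the (median) per-epibiont
#' assimilation, n the number of epibionts per cyanobacterial cell and C the
#' (median) per-cell cyanobacterial assimilation (all fg cell^-1 day^-1).
#'
#' @param eAssim per-epibiont assimilation, >= 0.
#' @param n epibionts per cyanobacterial cell, >= 0.
#' @param cAssim per-cell cyanobacterial assimilation, >= 0.
#' @return share in percent (0-100).
#' @examples
#' epibiontShare(0.5, 2, 99)  # 1 percent
#' @export
epibiontShare <- function(eAssim, n, cAssim) {
  if (any(eAssim < 0) || any(n < 0) || any(cAssim < 0))
    stop("assimilations and n must be >= 0")
  tot <- eAssim * n + cAssim
  if (any(tot == 0))
    stop("total assimilation is zero; share undefined")
  eAssim * n / tot * 100
}

#' Epibionts per cyanobacterial cell from field-of-view counts
#'
#' Per-field ratio of epibiont to cyanobacterial cell counts, summarised as
#' median and mean +/- SD across fields. Fields with zero cyanobacterial
#' cells are excluded with a warning.
#'
#' @param epibionts integer vector, epibionts counted per field of view.
#' @param cells integer vector, cyanobacterial cells per field of view.
#' @return list with \code{perField}, \code{median}, \code{mean}, \code{sd},
#'   \code{nFields}.
#' @examples
#' epibiontsPerCell(c(4, 8, 6), c(2, 4, 2))$median
#' @export
epibiontsPerCell <- function(epibionts, cells) {
  if (!length(epibionts)) stop("need at least one field of view")
  if (length(epibionts) != length(cells))
    stop("epibionts and cells must have one entry per field")
  bad <- cells == 0
  if (any(bad)) {
    warning(sum(bad), " field(s) with zero cyanobacterial cells excluded")
    epibionts <- epibionts[!bad]; cells <- cells[!bad]
  }
  if (!length(epibionts)) stop("no usable fields of view")
  ratio <- epibionts / cells
  list(perField = ratio, median = stats::median(ratio), mean = mean(ratio),
       sd = if (length(ratio) > 1) stats::sd(ratio) else NA_real_,
       nFields = length(ratio))
}

#' Partition total fixed C and N between a cyanobacterial cell and its epibionts
#'
#' Computes the headline quantity of the analysis: from per-cell assimilation
#' cohorts, the epibiont share of the summed fixed C and N per cyanobacterial
#' cell. Shares use the median per-cell assimilations and the median
#' epibionts-per-cell count; means are reported alongside but never used for
#' the share. Uncertainty is a seeded nonparametric bootstrap over cells
#' ([propagateShareUncertainty()]).
#'
#' @param epiRates data.frame of epibiont cell rates (from [cellRates()]),
#'   with columns \code{assimC}, \code{assimN}.
#' @param cyanoRates data.frame of cyanobacterial cell rates, same columns.
#' @param n epibionts per cyanobacterial cell (median of
#'   [epibiontsPerCell()]).
#' @param nBoot bootstrap resamples for the share SE.
#' @param seed integer seed for the bootstrap.
#' @return data.frame with one row per element: cohort sizes, median and
#'   mean assimilations, the epibiont and cyanobacterial shares (percent,
#'   complementary to 100), and bootstrap SE of the epibiont share.
#' @export
colonyPartition <- function(epiRates, cyanoRates, n, nBoot = 2000L,
                            seed = 1L) {
  out <- lapply(c(C = "C", N = "N"), function(el) {
    eA <- epiRates[[paste0("assim", el)]]
    cA <- cyanoRates[[paste0("assim", el)]]
    eA <- eA[!is.na(eA)]; cA <- cA[!is.na(cA)]
    if (!length(eA) || !length(cA))
      stop("empty assimilation cohort for element ", el)
    share <- epibiontShare(stats::median(eA), n, stats::median(cA))
    se <- propagateShareUncertainty(eA, n, cA, nBoot = nBoot, seed = seed)
    data.frame(element = el, nEpibionts = length(eA),
               nCyano = length(cA), epibiontsPerCell = n,
               medianEpiAssim = stats::median(eA),
               meanEpiAssim = mean(eA),
               medianCyanoAssim = stats::median(cA),
               meanCyanoAssim = mean(cA),
               epibiontSharePct = share,
               cyanoSharePct = 100 - share,
               shareSE = se)
  })
  do.call(rbind, c(out, list(make.row.names = FALSE)))
}

#' Bootstrap SE of the epibiont share
#'
#' The share is a function of two cohort medians; its sampling uncertainty is
#' propagated by a seeded nonparametric bootstrap: resample the epibiont and
#' cyanobacterial assimilation cohorts with replacement, recompute the
#' medians and the share, and take the SD of the bootstrap shares.
#'
#' @param eAssim per-epibiont assimilation sample (one value per cell).
#' @param n epibionts per cyanobacterial cell.
#' @param cAssim per-cyanobacterium assimilation sample.
#' @param nBoot number of bootstrap resamples (>= 1000 recommended).
#' @param seed integer seed.
#' @return bootstrap SE of the share in percentage points; NA (with a
#'   warning) if either cohort has a single cell.
#' @export
propagateShareUncertainty <- function(eAssim, n, cAssim, nBoot = 2000L,
                                      seed = 1L) {
  if (!length(eAssim) || !length(cAssim))
    stop("assimilation samples must be nonempty")
  if (length(eAssim) < 2L || length(cAssim) < 2L) {
    warning("cohort of one cell: share SE undefined")
    return(NA_real_)
  }
  set.seed(seed)
  shares <- vapply(seq_len(nBoot), function(i) {
    e <- sample(eAssim, replace = TRUE)
    c_ <- sample(cAssim, replace = TRUE)
    epibiontShare(stats::median(e), n, stats::median(c_))
  }, 0)
  stats::sd(shares)
}

#' Compare two partitions (e.g. in-situ vs DIP-amended)
#'
#' @param partitionA,partitionB data.frames from [colonyPartition()] on the
#'   same element set; A is the baseline.
#' @param activityA,activityB optional named numeric median epibiont relative
#'   activities per element, to report their fold change as well.
#' @return data.frame per element: both shares, absolute change (percentage
#'   points), relative change (percent of baseline, NA-flagged when the
#'   baseline share is 0) and, if activities are given, their fold change.
#' @export
scenarioCompare <- function(partitionA, partitionB,
                            activityA = NULL, activityB = NULL) {
  if (!setequal(partitionA$element, partitionB$element))
    stop("partitions cover different element sets")
  b <- partitionB[match(partitionA$element, partitionB$element), ]
  baseline <- partitionA$epibiontSharePct
  rel <- ifelse(baseline > 0,
                (b$epibiontSharePct - baseline) / baseline * 100, NA_real_)
  out <- data.frame(
    element = partitionA$element,
    shareA = baseline,
    shareB = b$epibiontSharePct,
    deltaPct = b$epibiontSharePct - baseline,
    relChangePct = rel,
    baselineZero = baseline == 0)
  if (!is.null(activityA) && !is.null(activityB)) {
    aA <- activityA[out$element]; aB <- activityB[out$element]
    out$activityFoldChange <- ifelse(aA > 0, aB / aA, NA_real_)
  }
  out
}
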