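#' Per-cell isotope ratios from accumulated ion images and an ROI mask
#'
#' Sums counts per species over every labelled region and forms the
#' ratio-of-sums estimates r_C = 13C-/12C-, r_N = 12C15N-/12C14N- (the CN-
#' inference of 15N/14N) and r_S = 32S-/12C-, each with its Poisson
#' counting-statistics standard error
#' \code{SE = ratio * sqrt(1/minor + 1/major)}. Cell geometry (length and
#' width in um) comes from the second-moment best-fit ellipse of the ROI
#' pixel set.
#'
#' A region whose major-isotope (denominator) counts are zero is flagged
#' invalid for that ratio and excluded downstream; a region with zero minor
#' counts gets ratio 0 and a low-count flag.
#'
#' @param images named list of accumulated 2-D count matrices (from
#'   [accumulate()]), containing at least the species needed for the
#'   requested ratios.
#' @param mask integer label matrix (same size), 0 = background; labels >= 1
#'   are cells.
#' @param pixelSize um/pixel; defaults to the \code{pixelSize} attribute of
#'   \code{images}.
#' @param cellTypes optional named character vector mapping label ->
#'   cell type (\code{"vegetative"}, \code{"heterocyst"}, \code{"epibiont"}).
#' @return data.frame with one row per ROI: label, cellType, nPixels,
#'   per-species summed counts, ratios with SEs, validity / low-count flags,
#'   and the ellipse-fit \code{lengthUm} / \code{widthUm}.
#' @examples
#' img <- list(`13C` = matrix(5, 4, 4), `12C` = matrix(95, 4, 4))
#' m <- matrix(1L, 4, 4)
#' roiRatios(img, m, pixelSize = 0.1)$ratioC  # 5/95
#' @export
roiRatios <- function(images, mask, pixelSize = attr(images, "pixelSize"),
                      cellTypes = NULL) {
  if (is.null(pixelSize)) stop("pixelSize must be supplied")
  stopifnot(all(dim(mask) == dim(images[[1]])))
  if (any(mask != round(mask))) stop("mask must contain integer labels")
  labels <- sort(setdiff(unique(as.vector(mask)), 0))
  if (!length(labels))
    return(emptyRoiTable())
  grp <- as.vector(mask)
  keep <- grp > 0
  sumBy <- function(sp) {
    if (!sp %in% names(images)) return(rep(NA_real_, length(labels)))
    s <- rowsum(as.vector(images[[sp]])[keep], grp[keep])
    as.vector(s[match(labels, as.numeric(rownames(s))), 1])
  }
  c12 <- sumBy("12C"); c13 <- sumBy("13C")
  cn14 <- sumBy("12C14N"); cn15 <- sumBy("12C15N")
  p31 <- sumBy("31P"); s32 <- sumBy("32S")
  npx <- as.vector(table(factor(grp[keep], levels = labels)))

  ratioSE <- function(minor, major) {
    ratio <- ifelse(major > 0, minor / major, NA_real_)
    se <- ifelse(major > 0 & minor > 0,
                 ratio * sqrt(1 / minor + 1 / major), NA_real_)
    ratio[major > 0 & minor == 0] <- 0
    list(ratio = ratio, se = se,
         valid = !is.na(major) & major > 0,
         low = !is.na(major) & major > 0 & !is.na(minor) & minor == 0)
  }
  rC <- ratioSE(c13, c12)
  rN <- ratioSE(cn15, cn14)
  rS <- ratioSE(s32, c12)

  geom <- t(vapply(labels, function(l) {
    idx <- which(mask == l, arr.ind = TRUE)
    if (nrow(idx) == 1L) return(c(pixelSize, pixelSize))
    cv <- stats::cov(idx) * (nrow(idx) - 1) / nrow(idx)
    ev <- sort(eigen(cv, symmetric = TRUE, only.values = TRUE)$values,
               decreasing = TRUE)
    ev[ev < 0] <- 0
    pmax(4 * sqrt(ev) * pixelSize, pixelSize)
  }, numeric(2)))

  types <- if (is.null(cellTypes)) rep(NA_character_, length(labels))
           else unname(cellTypes[as.character(labels)])
  data.frame(
    label = labels, cellType = types, nPixels = npx,
    c12 = c12, c13 = c13, cn14 = cn14, cn15 = cn15, p31 = p31, s32 = s32,
    ratioC = rC$ratio, seC = rC$se, validC = rC$valid, lowCountC = rC$low,
    ratioN = rN$ratio, seN = rN$se, validN = rN$valid, lowCountN = rN$low,
    ratioS = rS$ratio, seS = rS$se, validS = rS$valid, lowCountS = rS$low,
    lengthUm = geom[, 1], widthUm = geom[, 2])
}

emptyRoiTable <- function() {
  data.frame(label = integer(), cellType = character(), nPixels = integer(),
             c12 = numeric(), c13 = numeric(), cn14 = numeric(),
             cn15 = numeric(), p31 = numeric(), s32 = numeric(),
             ratioC = numeric(), seC = numeric(), validC = logical(),
             lowCountC = logical(), ratioN = numeric(), seN = numeric(),
             validN = logical(), lowCountN = logical(), ratioS = numeric(),
             seS = numeric(), validS = logical(), lowCountS = logical(),
             lengthUm = numeric(), widthUm = numeric())
}

#' Detection-limit filter on per-cell isotope ratios
#'
#' A cell's C (resp. N) channel is retained iff its ratio is strictly above
#' the detection limit — the smallest ratio distinguishable from natural
#' abundance given counting statistics; 0.0117 for 13C/12C and 0.0043 for
#' 15N/14N by default. Invalid measurements are never retained.
#'
#' @param measurements data.frame from [roiRatios()].
#' @param dlC,dlN detection limits on the C and N ratio.
#' @return list with \code{measurements} (input plus logical
#'   \code{retainedC}, \code{retainedN}) and \code{summary}
#'   (per-channel retained/rejected tallies).
#' @examples
#' m <- data.frame(ratioC = c(0.0117, 0.02), validC = TRUE,
#'                 ratioN = c(0.005, 0.001), validN = TRUE)
#' applyDetectionLimits(m)$summary
#' @export
applyDetectionLimits <- function(measurements, dlC = 0.0117, dlN = 0.0043) {
  m <- measurements
  m$retainedC <- !is.na(m$ratioC) & m$validC & m$ratioC > dlC
  m$retainedN <- !is.na(m$ratioN) & m$validN & m$ratioN > dlN
  summary <- data.frame(
    channel = c("C", "N"),
    limit = c(dlC, dlN),
    retained = c(sum(m$retainedC), sum(m$retainedN)),
    rejected = c(sum(!m$retainedC), sum(!m$retainedN)))
  list(measurements = m, summary = summary)
}

#' Propose epibiont ROIs by thresholding an accumulated ion image
#'
#' Convenience segmentation of the CN- (or S-) channel: Otsu threshold,
#' connected components, size filter. Intended only to propose candidate
#' ROIs for review — supplied masks remain authoritative and are never
#' silently replaced. Touching cells may merge into one component; the
#' component count is up to the caller to sanity-check against expectation.
#'
#' @param images named list of accumulated count matrices.
#' @param species preferred channels in order; the first present is used.
#' @param minSize minimum component size in pixels.
#' @return integer label matrix (0 = background), empty (all zero) for a
#'   blank image.
#' @export
segmentEpibionts <- function(images, species = c("12C14N", "32S"),
                             minSize = 5L) {
  sp <- species[species %in% names(images)]
  if (!length(sp)) stop("none of the requested species present: ",
                        paste(species, collapse = ", "))
  img <- images[[sp[1]]]
  if (max(img) == 0) return(matrix(0L, nrow(img), ncol(img)))
  norm <- img / max(img)
  th <- EBImage::otsu(EBImage::Image(norm), range = c(0, 1))
  lab <- EBImage::bwlabel(EBImage::Image((norm > th) * 1))
  lab <- matrix(as.integer(EBImage::imageData(lab)), nrow(img), ncol(img))
  sizes <- table(lab[lab > 0])
  drop <- as.integer(names(sizes)[sizes < minSize])
  lab[lab %in% drop] <- 0L
  old <- sort(setdiff(unique(as.vector(lab)), 0L))
  relab <- matrix(0L, nrow(lab), ncol(lab))
  for (i in seq_along(old)) relab[lab == old[i]] <- i
  relab
}
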