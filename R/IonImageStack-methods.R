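#' Construct an IonImageStack
#'
#' @param counts named list of 3-D integer arrays (rows x cols x planes), one
#'   per secondary-ion species, all of identical dimensions.
#' @param pixelSize micrometres per pixel.
#' @return an [IonImageStack-class].
#' @examples
#' a <- array(rpois(4 * 4 * 2, 5), c(4, 4, 2))
#' stk <- IonImageStack(list(`12C` = a, `13C` = a), pixelSize = 0.06)
#' ionSpecies(stk)
#' nPlanes(stk)
#' @export
IonImageStack <- function(counts, pixelSize) {
  if (is.null(names(counts)) || any(!nzchar(names(counts))))
    stop("counts must be a named list (one entry per ion species)")
  counts <- lapply(counts, function(a) {
    storage.mode(a) <- "double"
    a
  })
  new("IonImageStack", counts = counts, species = names(counts),
      pixelSize = as.numeric(pixelSize))
}

#' @rdname IonImageStack-class
#' @export
setMethod("ionSpecies", "IonImageStack", function(x) x@species)

#' @rdname IonImageStack-class
#' @export
setMethod("pixelSize", "IonImageStack", function(x) x@pixelSize)

#' @rdname IonImageStack-class
#' @export
setMethod("nPlanes", "IonImageStack", function(x) dim(x@counts[[1]])[3])

#' @rdname IonImageStack-class
#' @export
setMethod("ionCounts", "IonImageStack", function(x, species) {
  if (!species %in% x@species)
    stop("unknown species: ", species)
  x@counts[[species]]
})

#' @rdname IonImageStack-class
#' @export
setMethod("dim", "IonImageStack", function(x) dim(x@counts[[1]])[1:2])

setMethod("show", "IonImageStack", function(object) {
  d <- dim(object@counts[[1]])
  cat("IonImageStack:", d[1], "x", d[2], "pixels,", d[3], "planes\n")
  cat("  species:", paste(object@species, collapse = ", "), "\n")
  cat("  pixel size:", signif(object@pixelSize, 4), "um\n")
  tot <- vapply(object@counts, sum, 0)
  cat("  total counts:",
      paste(sprintf("%s=%.3g", object@species, tot), collapse = ", "), "\n")
})

setMethod("show", "ColonyScene", function(object) {
  cat("ColonyScene:", nrow(object@cells), "cells (",
      paste(sprintf("%s=%d", names(table(object@cells$type)),
                    as.integer(table(object@cells$type))), collapse = ", "),
      ")\n")
  cat("  pixel size:", signif(object@pixelSize, 4), "um; background yields:",
      paste(sprintf("%s=%.3g", names(object@background), object@background),
            collapse = ", "), "\n")
})

setMethod("show", "LabelingConditions", function(object) {
  cat("LabelingConditions:\n")
  for (el in names(object@sourceFraction))
    cat(sprintf("  %s: source %.4f, natural abundance %.5f\n", el,
                object@sourceFraction[el], object@naturalAbundance[el]))
  cat("  duration:", object@duration, "days\n")
})

#' Cells table of a ColonyScene
#' @param scene a [ColonyScene-class].
#' @return the scene's per-cell ground-truth data.frame.
#' @export
sceneCells <- function(scene) {
  stopifnot(is(scene, "ColonyScene"))
  scene@cells
}
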