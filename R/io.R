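## 16-bit TIFF round-trips integers 0..65535 exactly (k/65535 quantises back
## to k); all raw per-plane nanoSIMS counts are far below that.
.tiffMax <- 65535

#' Write / read multi-plane ion stacks as TIFF
#'
#' One multi-page 16-bit TIFF per ion species (page = acquisition plane),
#' lossless for integer counts up to 65535.
#'
#' @param stack an [IonImageStack-class].
#' @param dir output directory (created if needed).
#' @param prefix file-name prefix; files are
#'   \code{<prefix>_<species>.tif}.
#' @return invisibly, the written file paths (named by species).
#' @export
writeIonStack <- function(stack, dir, prefix = "stack") {
  stopifnot(is(stack, "IonImageStack"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character()
  for (sp in ionSpecies(stack)) {
    arr <- ionCounts(stack, sp)
    if (max(arr) > .tiffMax)
      stop("counts exceed 16-bit range for species ", sp)
    pages <- lapply(seq_len(dim(arr)[3]), function(p) arr[, , p] / .tiffMax)
    path <- file.path(dir, paste0(prefix, "_", sp, ".tif"))
    tiff::writeTIFF(pages, path, bits.per.sample = 16)
    paths[sp] <- path
  }
  invisible(paths)
}

#' @rdname writeIonStack
#' @param paths named character vector of TIFF paths (names = species), as
#'   returned by [writeIonStack()].
#' @param pixelSize um/pixel of the read stack.
#' @export
readIonStack <- function(paths, pixelSize) {
  counts <- lapply(paths, function(p) {
    pages <- tiff::readTIFF(p, all = TRUE)
    if (!is.list(pages)) pages <- list(pages)
    arr <- array(0, c(dim(pages[[1]]), length(pages)))
    for (i in seq_along(pages)) arr[, , i] <- round(pages[[i]] * .tiffMax)
    arr
  })
  names(counts) <- names(paths)
  IonImageStack(counts, pixelSize = pixelSize)
}

#' Write / read a 16-bit label mask
#'
#' @param mask integer label matrix (0 = background, labels <= 65535).
#' @param path TIFF file path.
#' @return \code{readMask} returns the integer label matrix; non-integer
#'   pixel values are rejected.
#' @export
writeMask <- function(mask, path) {
  if (any(mask != round(mask)) || any(mask < 0) || max(mask) > .tiffMax)
    stop("mask must contain integer labels in [0, 65535]")
  tiff::writeTIFF(mask / .tiffMax, path, bits.per.sample = 16)
  invisible(path)
}

#' @rdname writeMask
#' @export
readMask <- function(path) {
  m <- tiff::readTIFF(path)
  if (is.list(m)) m <- m[[1]]
  vals <- m * .tiffMax
  if (max(abs(vals - round(vals))) > 1e-6)
    stop("mask contains non-integer pixel values: ", path)
  matrix(as.integer(round(vals)), nrow(m), ncol(m))
}

## CSV conventions: a '#'-prefixed provenance header, then a header row.
writeTableCsv <- function(df, path, configHash = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(configHash))
    writeLines(paste0("# configHash: ", configHash), con)
  utils::write.csv(df, con, row.names = FALSE)
  invisible(path)
}

#' Read a pipeline CSV table with schema checking
#'
#' Accepts the '#'-prefixed provenance header written by the pipeline.
#' Missing required columns are an error naming them; unknown extra columns
#' are accepted with a warning (forward compatibility).
#'
#' @param path CSV path.
#' @param required character vector of required column names.
#' @param known character vector of expected column names (superset of
#'   \code{required}); columns outside it trigger the warning.
#' @return data.frame.
#' @export
readTableCsv <- function(path, required = character(), known = required) {
  df <- utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
  missing <- setdiff(required, names(df))
  if (length(missing))
    stop("table ", basename(path), " is missing required columns: ",
         paste(missing, collapse = ", "))
  extra <- setdiff(names(df), known)
  if (length(known) && length(extra))
    warning("table ", basename(path), " has unknown columns (accepted): ",
            paste(extra, collapse = ", "))
  df
}

#' Columns of the per-ROI measurement CSV
#' @return character vector of the schema written by the pipeline.
#' @export
roiCsvColumns <- function() names(emptyRoiTable())

#' Read a pipeline configuration
#'
#' A YAML (or JSON) file, or an R list, with the blocks \code{mode}
#' (\code{"simulate"} or \code{"load"}), \code{scenario} or \code{input},
#' \code{labeling}, \code{detectionLimits}, \code{conversion},
#' \code{composition}, \code{epibiontsPerCell}, \code{bootstrap} and
#' \code{seed}. Unset blocks fall back to defaults; see [runPipeline()].
#'
#' @param config path to a YAML file, or a list.
#' @return the configuration list with defaults filled in.
#' @export
readPipelineConfig <- function(config) {
  if (is.character(config)) {
    if (!file.exists(config)) stop("config file not found: ", config)
    config <- yaml::read_yaml(config)
  }
  stopifnot(is.list(config))
  defaults <- list(
    mode = "simulate",
    scenario = list(organism = "nodularia", condition = "in_situ",
                    nEpibionts = NULL, imageSize = 256L, planes = 40L,
                    drift = "random_walk", seed = 1L),
    labeling = list(sourceC = 0.119, sourceN = 0.018,
                    naturalC = 0.0111, naturalN = 0.00366, durationDays = 1),
    detectionLimits = list(C = 0.0117, N = 0.0043),
    conversion = list(type = "constant", value = 250),
    composition = list(cnMolarEpibiont = 5.0, cnMolarCyano = 6.625),
    epibiontsPerCell = NULL,
    bootstrap = list(n = 2000L, seed = 1L),
    seed = 1L)
  out <- utils::modifyList(defaults, config)
  out
}

configHash <- function(config) {
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  writeLines(jsonlite::toJSON(config, auto_unbox = TRUE, digits = NA,
                              null = "null"), tmp)
  unname(tools::md5sum(tmp))
}
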