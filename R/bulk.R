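#' Construct a RadiotracerDesign
#'
#' Defaults emulate the bulk 33P-phosphate uptake incubations: 150 kBq
#' tracer in 60 mL, five replicates plus filtered and heat-killed controls,
#' subsamples every 6 h from time zero, 33P half-life 25.4 days.
#'
#' @param rate true DIP uptake rate (nmol P L^-1 h^-1).
#' @param dip ambient DIP concentration (nmol L^-1).
#' @param activityKBq added activity (kBq).
#' @param volumeMl incubation volume (mL).
#' @param times sampling times (h).
#' @param replicates live replicate bottles.
#' @param bindingFraction unspecific-binding fraction seen in controls.
#' @param countingDelayDays days between sampling and counting.
#' @param totalCounts expected scintillation counts for the full spike
#'   before decay (noise scale).
#' @param halfLife tracer half-life (days).
#' @return a [RadiotracerDesign-class].
#' @export
RadiotracerDesign <- function(rate = 2.25, dip = 34, activityKBq = 150,
                              volumeMl = 60, times = seq(0, 24, by = 6),
                              replicates = 5L, bindingFraction = 0.005,
                              countingDelayDays = 2, totalCounts = 5e5,
                              halfLife = 25.4) {
  new("RadiotracerDesign", rate = rate, dip = dip,
      activityKBq = activityKBq, volumeMl = volumeMl, times = times,
      replicates = as.integer(replicates),
      bindingFraction = bindingFraction,
      countingDelayDays = countingDelayDays, totalCounts = totalCounts,
      halfLife = halfLife)
}

#' Simulate a 33P radiotracer uptake experiment
#'
#' The fraction of tracer incorporated into biomass grows linearly at
#' \code{rate / dip} per hour until cumulative uptake exhausts the ambient
#' DIP pool (at \code{t = dip / rate} hours), then plateaus. Controls carry
#' only the unspecific-binding fraction. Recorded counts are decayed by the
#' counting-day delay and, when \code{noise = TRUE}, Poisson-distributed.
#'
#' @param design a [RadiotracerDesign-class].
#' @param seed optional integer seed.
#' @param noise apply Poisson counting noise (default TRUE); FALSE returns
#'   expected counts.
#' @return list with \code{samples} (data.frame: bottle, type, timeH,
#'   counts), \code{totals} (per-bottle total-activity counts),
#'   \code{dip}, \code{halfLife}, \code{countingDelayDays} and \code{truth}
#'   (true rate and pool-exhaustion time in hours).
#' @examples
#' sim <- simulateRadiotracer(RadiotracerDesign(), seed = 1)
#' head(sim$samples)
#' sim$truth$exhaustionH  # 34 / 2.25
#' @export
simulateRadiotracer <- function(design, seed = NULL, noise = TRUE) {
  stopifnot(is(design, "RadiotracerDesign"))
  validObject(design)
  if (!is.null(seed)) set.seed(seed)
  decay <- 2^(-design@countingDelayDays / design@halfLife)
  fTrue <- pmin(design@rate * design@times / design@dip, 1)
  bottles <- c(paste0("R", seq_len(design@replicates)),
               "control_filtered", "control_killed")
  types <- c(rep("sample", design@replicates), "control", "control")
  rows <- list()
  for (i in seq_along(bottles)) {
    f <- if (types[i] == "sample") fTrue else rep(0, length(design@times))
    expCounts <- (f + design@bindingFraction) * design@totalCounts * decay
    counts <- if (noise) stats::rpois(length(expCounts), expCounts) else expCounts
    rows[[i]] <- data.frame(bottle = bottles[i], type = types[i],
                            timeH = design@times, counts = counts)
  }
  totExp <- rep(design@totalCounts * decay, length(bottles))
  totals <- data.frame(bottle = bottles,
                       counts = if (noise) stats::rpois(length(totExp), totExp)
                                else totExp)
  list(samples = do.call(rbind, rows), totals = totals,
       dip = design@dip, halfLife = design@halfLife,
       countingDelayDays = design@countingDelayDays,
       truth = list(rate = design@rate,
                    exhaustionH = if (design@rate > 0)
                      design@dip / design@rate else Inf))
}

#' Radioactive decay correction
#'
#' Refers measured counts back to a common reference date:
#' \code{corrected = counts * 2^(elapsed / halfLife)}.
#'
#' @param counts measured counts.
#' @param elapsedDays days elapsed between the reference date and counting.
#' @param halfLife half-life in days (33P: 25.4).
#' @return decay-corrected counts.
#' @examples
#' decayCorrect(100, 25.4)  # 200
#' @export
decayCorrect <- function(counts, elapsedDays, halfLife = 25.4) {
  if (any(elapsedDays < 0)) stop("elapsedDays must be >= 0")
  if (halfLife <= 0) stop("halfLife must be > 0")
  counts * 2^(elapsedDays / halfLife)
}

#' Suggest the linear window of a tracer incorporation series
#'
#' Greedy prefix selection: starting from the first two time points, the next
#' point is accepted while the regression over the extended prefix keeps
#' R^2 at or above \code{r2Threshold} and the new point's residual stays
#' within 3 RMSE of the previous fit. Advisory only — an explicit user
#' window always overrides.
#'
#' @param times sampling times (h).
#' @param fractions incorporated fractions at those times.
#' @param r2Threshold minimum R^2 to keep extending.
#' @return list with \code{idx} (indices of the selected prefix),
#'   \code{window} (time range) and \code{minimal} (TRUE when only two
#'   points were available).
#' @export
linearWindow <- function(times, fractions, r2Threshold = 0.98) {
  n <- length(times)
  stopifnot(length(fractions) == n)
  if (n < 2L) stop("need at least two time points")
  if (n == 2L)
    return(list(idx = 1:2, window = range(times), minimal = TRUE))
  k <- 2L
  repeat {
    if (k >= n) break
    prevFit <- stats::lm(fractions[1:k] ~ times[1:k])
    rmse <- sqrt(mean(stats::residuals(prevFit)^2))
    cand <- 1:(k + 1)
    fit <- stats::lm(fractions[cand] ~ times[cand])
    r2 <- suppressWarnings(summary(fit)$r.squared)
    newResid <- abs(stats::residuals(fit)[k + 1])
    if (is.na(r2)) r2 <- 1
    ok <- r2 >= r2Threshold && (rmse == 0 || newResid <= 3 * rmse)
    if (!ok) break
    k <- k + 1L
  }
  list(idx = 1:k, window = c(times[1], times[k]), minimal = FALSE)
}

#' Bulk DIP uptake rate from a radiotracer series
#'
#' Per replicate, the fraction of added tracer incorporated at each time
#' point is \code{f(t) = (filter counts - mean control counts) / total
#' counts}, all decay-corrected to a common reference date (the correction
#' cancels when everything was counted on the same day, and the result is
#' invariant to the chosen reference). The uptake rate is the OLS slope of
#' f(t) over the linear window times the ambient DIP concentration.
#'
#' @param series a simulated or measured series in the format returned by
#'   [simulateRadiotracer()].
#' @param window numeric length-2 time range (h) to regress over; NULL picks
#'   the advisory [linearWindow()] on the replicate-mean series.
#' @param elapsedDays per-measurement days from the reference date to
#'   counting (scalar; defaults to the series' counting delay).
#' @return list with \code{rate} (mean over replicates, nmol L^-1 h^-1),
#'   \code{sd}, \code{perReplicate} (slopes, rates, R^2), \code{window},
#'   \code{fractions} (long data.frame of f(t)) and \code{contaminated}
#'   (TRUE with rate 0 when controls exceed samples throughout).
#' @export
dipUptakeRate <- function(series, window = NULL, elapsedDays = NULL) {
  if (is.null(elapsedDays)) elapsedDays <- series$countingDelayDays
  hl <- series$halfLife
  corr <- function(x) decayCorrect(x, elapsedDays, hl)
  s <- series$samples
  controls <- s[s$type == "control", ]
  samples <- s[s$type == "sample", ]
  ctrlMean <- tapply(corr(controls$counts), controls$timeH, mean)
  totals <- series$totals
  totalBy <- stats::setNames(corr(totals$counts), totals$bottle)

  samples$fraction <- (corr(samples$counts) -
    as.vector(ctrlMean[as.character(samples$timeH)])) /
    totalBy[samples$bottle]

  if (all(samples$fraction <= 0))
    return(list(rate = 0, sd = NA_real_, perReplicate = NULL,
                window = window, fractions = samples, contaminated = TRUE))

  meanF <- tapply(samples$fraction, samples$timeH, mean)
  tPts <- as.numeric(names(meanF))
  if (is.null(window)) {
    lw <- linearWindow(tPts, as.vector(meanF))
    window <- lw$window
  }
  inWin <- samples$timeH >= window[1] & samples$timeH <= window[2]
  if (!any(inWin)) stop("window excludes all time points")
  wdat <- samples[inWin, ]
  per <- do.call(rbind, lapply(split(wdat, wdat$bottle), function(d) {
    if (nrow(d) < 2L) stop("fewer than two time points inside the window")
    fit <- stats::lm(fraction ~ timeH, data = d)
    data.frame(bottle = d$bottle[1],
               slope = unname(stats::coef(fit)[2]),
               rate = unname(stats::coef(fit)[2]) * series$dip,
               r2 = suppressWarnings(summary(fit)$r.squared))
  }))
  rownames(per) <- NULL
  list(rate = mean(per$rate), sd = stats::sd(per$rate),
       perReplicate = per, window = window, fractions = samples,
       contaminated = FALSE)
}

#' Construct a BulkDesign
#'
#' Defaults emulate the bulk fixation incubations during the bloom: 24-h
#' triplicate incubations labelled to ~11.7 atom% 13C in the DIC pool and
#' ~4.3 atom% 15N in the N2 pool, with true rates near the measured bulk
#' CO2 and N2 fixation (15.5 umol C and 1.23 umol N L^-1 day^-1).
#'
#' @param rateC,rateN true fixation rates (umol L^-1 day^-1).
#' @param poc,pon particulate organic C and N pools (umol L^-1).
#' @param sourceFraction,naturalAbundance named atom fractions per element.
#' @param durationH incubation duration (h).
#' @param replicates labelled bottles.
#' @param noiseSD Gaussian SD on the measured particulate atom fraction.
#' @return a [BulkDesign-class].
#' @export
BulkDesign <- function(rateC = 15.5, rateN = 1.23, poc = 50, pon = 7,
                       sourceFraction = c(C = 0.117, N = 0.043),
                       naturalAbundance = c(C = 0.0111, N = 0.00366),
                       durationH = 24, replicates = 3L, noiseSD = 0) {
  new("BulkDesign", rateC = rateC, rateN = rateN, poc = poc, pon = pon,
      sourceFraction = sourceFraction, naturalAbundance = naturalAbundance,
      durationH = durationH, replicates = as.integer(replicates),
      noiseSD = noiseSD)
}

#' Simulate bulk fixation incubation end points
#'
#' The particulate atom fraction after time t is natural abundance plus
#' \code{(rate * t / pool)} times the source-pool excess, plus optional
#' Gaussian measurement noise — the exact inverse of [bulkFixationRate()] in
#' the noiseless case.
#'
#' @param design a [BulkDesign-class].
#' @param seed optional integer seed.
#' @return data.frame with one row per replicate per element: measured end
#'   atom fraction and the labelling context needed for the inversion.
#' @export
simulateBulkIncubation <- function(design, seed = NULL) {
  stopifnot(is(design, "BulkDesign"))
  validObject(design)
  if (!is.null(seed)) set.seed(seed)
  tDays <- design@durationH / 24
  rows <- list()
  for (el in c("C", "N")) {
    rate <- if (el == "C") design@rateC else design@rateN
    pool <- if (el == "C") design@poc else design@pon
    frac <- rate * tDays / pool
    if (frac > 1)
      stop("fixation exceeds the particulate pool for element ", el)
    na <- design@naturalAbundance[el]; src <- design@sourceFraction[el]
    aEnd <- na + frac * (src - na)
    noise <- if (design@noiseSD > 0)
      stats::rnorm(design@replicates, 0, design@noiseSD) else 0
    rows[[el]] <- data.frame(
      replicate = seq_len(design@replicates), element = el,
      aEnd = unname(aEnd + noise), aSource = unname(src), aNa = unname(na),
      pool = pool, durationH = design@durationH)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Bulk fixation rate by isotope mass balance
#'
#' The standard particulate excess mass balance:
#' \code{rate = (A_end - A_na) / (A_source - A_na) * pool / duration}, i.e.
#' the fraction of the particulate pool's atoms replaced by labelled
#' substrate, scaled by the pool and referred to a day.
#'
#' @param aEnd particulate atom fraction at the end of the incubation.
#' @param aSource source-pool atom fraction (> \code{aNa}).
#' @param aNa natural-abundance atom fraction (untreated control).
#' @param pool particulate pool (umol L^-1).
#' @param durationH incubation duration (h).
#' @return fixation rate in umol L^-1 day^-1.
#' @examples
#' bulkFixationRate(0.01366, 0.043, 0.00366, pool = 5, durationH = 24)
#' @export
bulkFixationRate <- function(aEnd, aSource, aNa, pool, durationH) {
  if (any(aSource <= aNa)) stop("source atom fraction must exceed natural abundance")
  if (any(pool <= 0)) stop("pool must be > 0")
  if (any(durationH <= 0)) stop("duration must be > 0")
  (aEnd - aNa) / (aSource - aNa) * pool / (durationH / 24)
}
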