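#' Detect ploidy-peak centers in a flow-cytometry intensity sample
#'
#' Builds a Freedman-Diaconis histogram of the log intensities (ploidy
#' peaks sit at 2x spacings with roughly constant CV, so in log space
#' they are equally spaced and equally wide), smooths the counts with a
#' 3-bin moving average, locates local maxima, keeps the `n_peaks`
#' highest, and refines each center by a few mean-shift passes (mean of
#' the events within +/-15% of the current center, safely inside the 2x
#' spacing of neighbouring ploidy populations).
#'
#' @param intensities Positive numeric vector of event intensities.
#' @param n_peaks Number of peaks to return.
#' @return Numeric vector of `n_peaks` peak centers, ascending.
#' @export
detect_peaks <- function(intensities, n_peaks) {
  if (length(intensities) == 0L) stop("no events")
  stopifnot(n_peaks >= 1L, all(intensities > 0))
  y <- log(intensities)
  bw <- 2 * stats::IQR(y) / length(y)^(1 / 3)   # exact FD width, log space
  if (bw <= 0) bw <- max(diff(range(y)) / max(1, ceiling(sqrt(length(y)))),
                         .Machine$double.eps)
  breaks <- seq(min(y), max(y) + bw, by = bw)
  h <- graphics::hist(y, breaks = breaks, plot = FALSE)
  sm <- moving_average(h$counts, halfwidth = 1L)
  n <- length(sm)
  is_max <- logical(n)
  for (i in seq_len(n)) {
    left <- if (i > 1L) sm[i - 1L] else -Inf
    right <- if (i < n) sm[i + 1L] else -Inf
    is_max[i] <- sm[i] > left && sm[i] >= right && sm[i] > 0
  }
  idx <- which(is_max)
  if (length(idx) < n_peaks)
    stop("only ", length(idx), " peaks found (centers: ",
         paste(signif(exp(h$mids[idx]), 4), collapse = ", "),
         "); requested ", n_peaks)
  top <- idx[order(sm[idx], decreasing = TRUE)][seq_len(n_peaks)]
  centers <- exp(sort(h$mids[top]))
  vapply(centers, function(cc) {
    for (k in 1:3) {
      local <- intensities[intensities >= 0.85 * cc &
                             intensities <= 1.15 * cc]
      if (length(local) == 0L) break
      cc <- mean(local)
    }
    cc
  }, numeric(1))
}

#' Coefficient of variation of a gated ploidy peak
#'
#' Gates events in a symmetric multiplicative window around the peak
#' center, `[center*(1-f), center*(1+f)]`, and returns
#' `100 * sd / mean` of the gated intensities — the peak-width
#' statistic used as a re-replication index. Invariant to global
#' intensity rescaling.
#'
#' @param intensities Event intensity vector.
#' @param center Peak center (e.g. from [detect_peaks()]).
#' @param gate_halfwidth_frac Gate half-width as a fraction of the
#'   center (default 0.25).
#' @return CV in percent.
#' @export
peak_cv <- function(intensities, center, gate_halfwidth_frac = 0.25) {
  stopifnot(center > 0, gate_halfwidth_frac > 0)
  gated <- intensities[intensities >= center * (1 - gate_halfwidth_frac) &
                         intensities <= center * (1 + gate_halfwidth_frac)]
  if (length(gated) < 50L)
    stop("only ", length(gated), " events in the gate; CV unstable below 50")
  100 * sd(gated) / mean(gated)
}

#' Normalize a peak CV to the wild-type CV
#'
#' @param cv_sample Sample CV (percent).
#' @param cv_wt Wild-type CV (percent, > 0).
#' @return `cv_sample / cv_wt`.
#' @export
normalize_cv <- function(cv_sample, cv_wt) {
  if (any(cv_wt <= 0)) stop("wild-type CV must be positive")
  cv_sample / cv_wt
}

#' Summarize replicate CV measurements
#'
#' @param cvs Numeric vector of per-replicate CVs (e.g. triplicates).
#' @return List with `mean`, `sd` and `n`.
#' @export
cv_replicate_summary <- function(cvs) {
  stopifnot(length(cvs) >= 1L)
  list(mean = mean(cvs), sd = if (length(cvs) > 1L) sd(cvs) else NA_real_,
       n = length(cvs))
}
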