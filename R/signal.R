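#' Count read 5' ends in fixed-width bins
#'
#' Tiles each chromosome into `bin_width`-bp bins from position 0 and
#' counts the placements whose 5' position falls in each half-open bin
#' `[i*w, (i+1)*w)`. The grand total over all bins equals the number of
#' placements (reads are never split or lost).
#'
#' @param reads A [ReadPlacements()] (deduplicate first for score
#'   tracks).
#' @param chrom_sizes Named numeric vector of chromosome lengths (bp).
#' @param bin_width Bin width in bp.
#' @return A [BinnedSignal()] of integer counts.
#' @export
bin_counts <- function(reads, chrom_sizes, bin_width) {
  if (bin_width <= 0) stop("bin_width must be positive")
  p <- reads$placements
  values <- lapply(names(chrom_sizes), function(chrom) {
    n_bins <- ceiling(chrom_sizes[[chrom]] / bin_width)
    pos <- p$pos5[p$chrom == chrom]
    if (length(pos) == 0L) return(integer(n_bins))
    tabulate(pmin(floor(pos / bin_width) + 1L, n_bins), nbins = n_bins)
  })
  names(values) <- names(chrom_sizes)
  BinnedSignal(values, bin_width, semantics = "count")
}

#' Moving average with truncated edge windows
#'
#' `out[i]` is the mean of `x[max(1, i-h) .. min(n, i+h)]`; windows are
#' truncated at the vector ends rather than padded, so no values are
#' invented beyond the chromosome.
#'
#' @param x Numeric vector.
#' @param halfwidth Non-negative integer window half-width `h`.
#' @return Numeric vector of the same length.
#' @export
moving_average <- function(x, halfwidth) {
  stopifnot(halfwidth >= 0)
  n <- length(x)
  if (n == 0L) return(x)
  if (halfwidth == 0) return(as.numeric(x))
  i <- seq_len(n)
  lo <- pmax(i - halfwidth, 1L)
  hi <- pmin(i + halfwidth, n)
  cs <- c(0, cumsum(x))
  (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
}

#' Iterated triangular smoothing
#'
#' Each iteration replaces interior values by the (0.25, 0.5, 0.25)
#' kernel `out[i] = 0.25*x[i-1] + 0.5*x[i] + 0.25*x[i+1]`; the two
#' endpoint values, where the kernel is undefined, are copied unchanged.
#'
#' @param x Numeric vector.
#' @param n_iter Number of smoothing passes (0 = identity).
#' @return Numeric vector of the same length.
#' @export
triangular_smooth <- function(x, n_iter = 1L) {
  stopifnot(n_iter >= 0)
  x <- as.numeric(x)
  n <- length(x)
  if (n < 3L || n_iter == 0L) return(x)
  for (iter in seq_len(n_iter)) {
    interior <- 0.25 * x[1:(n - 2L)] + 0.5 * x[2:(n - 1L)] + 0.25 * x[3:n]
    x <- c(x[1L], interior, x[n])
  }
  x
}

## smooth a vector that may contain NA by smoothing each non-missing run
.smooth_runs <- function(x, fun) {
  if (!anyNA(x)) return(fun(x))
  r <- rle(is.na(x))
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  for (k in seq_along(r$values)) {
    if (!r$values[k]) {
      idx <- starts[k]:ends[k]
      x[idx] <- fun(x[idx])
    }
  }
  x
}

#' Apply a smoother to every chromosome of a BinnedSignal
#'
#' Missing bins split the signal into runs that are smoothed
#' independently (no smoothing across gaps).
#'
#' @param signal A [BinnedSignal()].
#' @param method `"triangular"` or `"moving_average"`.
#' @param n_iter Iterations for triangular smoothing.
#' @param halfwidth Half-width for the moving average.
#' @return A smoothed `BinnedSignal`.
#' @export
smooth_signal <- function(signal, method = c("triangular", "moving_average"),
                          n_iter = 1L, halfwidth = 1L) {
  method <- match.arg(method)
  fun <- if (method == "triangular") function(v) triangular_smooth(v, n_iter)
         else function(v) moving_average(v, halfwidth)
  values <- lapply(signal$values, .smooth_runs, fun = fun)
  BinnedSignal(values, signal$bin_width, signal$semantics)
}

## average consecutive groups of k bins (rebin to a coarser width)
.rebin_mean <- function(v, k) {
  n_out <- ceiling(length(v) / k)
  grp <- rep(seq_len(n_out), each = k, length.out = length(v))
  as.numeric(tapply(v, grp, mean))
}

#' Boundary-anchored metaplot of a binned signal
#'
#' Averages a signal around region boundaries, oriented so that offset
#' x = 0 sits at the boundary, x < 0 points outside the region and
#' x > 0 points into it. Both boundaries of every region contribute;
#' right boundaries are mirrored. Offsets are reported as the bp of the
#' near edge of each bin relative to the boundary, spanning
#' `-flank_bp .. +flank_bp`.
#'
#' @param signal A [BinnedSignal()] whose bin width equals `bin_width`
#'   or divides it (the signal is then averaged down to `bin_width`).
#' @param regions A [RegionSet()]; regions shorter than one bin are
#'   skipped with a warning.
#' @param flank_bp Extent of the profile on each side of the boundary.
#' @param bin_width Metaplot bin width in bp.
#' @param size_strata Either `NULL` (one stratum covering all sizes),
#'   `"quartiles"` (default: strata at the quartiles of region size), or
#'   a list of `c(min_bp, max_bp)` pairs.
#' @param sides Which boundaries to aggregate (`"both"`, `"left"`,
#'   `"right"`); mainly for symmetry checks.
#' @param exclude_overlapping Skip boundaries whose flank window
#'   intersects a different region.
#' @return A list of `BoundaryProfile` data.frames (columns
#'   `offset_bp`, `mean`, `n`), one per stratum, each carrying
#'   `stratum` and `n_regions` attributes.
#' @export
boundary_metaplot <- function(signal, regions, flank_bp, bin_width,
                              size_strata = "quartiles",
                              sides = c("both", "left", "right"),
                              exclude_overlapping = FALSE) {
  sides <- match.arg(sides)
  w <- signal$bin_width
  if (bin_width %% w != 0)
    stop("signal bin width must equal or divide the metaplot bin width")
  k_rebin <- bin_width %/% w
  values <- if (k_rebin == 1L) signal$values
            else lapply(signal$values, .rebin_mean, k = k_rebin)

  sizes <- regions$end - regions$start
  short <- sizes < bin_width
  if (any(short)) {
    warning(sum(short), " regions shorter than one bin skipped")
    regions <- regions[!short, , drop = FALSE]
    sizes <- sizes[!short]
  }
  if (nrow(regions) == 0L) stop("no regions long enough for the metaplot")

  if (is.null(size_strata)) {
    strata <- list(c(0, Inf))
  } else if (identical(size_strata, "quartiles")) {
    q <- quantile(sizes, c(0.25, 0.5, 0.75))
    strata <- list(c(0, q[[1]]), c(q[[1]], q[[2]]),
                   c(q[[2]], q[[3]]), c(q[[3]], Inf))
  } else strata <- size_strata

  K <- flank_bp %/% bin_width
  offsets <- seq(-K, K - 1L)           # bin j covers [j*bw, (j+1)*bw) rel. to boundary
  gr_all <- .as_granges(regions)

  profile_for <- function(idx) {
    sums <- numeric(length(offsets))
    ns <- integer(length(offsets))
    for (r in idx) {
      chrom <- regions$chrom[r]
      v <- values[[chrom]]
      if (is.null(v)) next
      n_bins <- length(v)
      bounds <- list()
      if (sides %in% c("both", "left"))
        bounds <- c(bounds, list(list(pos = regions$start[r], dir = +1L)))
      if (sides %in% c("both", "right"))
        bounds <- c(bounds, list(list(pos = regions$end[r], dir = -1L)))
      for (b in bounds) {
        if (exclude_overlapping) {
          win <- GenomicRanges::GRanges(chrom,
                   IRanges::IRanges(max(1, b$pos - flank_bp + 1),
                                    b$pos + flank_bp))
          hits <- GenomicRanges::countOverlaps(win, gr_all)
          if (hits > 1L) next
        }
        ib <- round(b$pos / bin_width)       # boundary snapped to bin grid
        for (j in seq_along(offsets)) {
          ## dir=+1: inside lies rightward; dir=-1 (right boundary): mirrored
          bin <- if (b$dir == 1L) ib + offsets[j] else ib - 1L - offsets[j]
          if (bin < 0L || bin >= n_bins) next
          val <- v[bin + 1L]
          if (is.na(val)) next
          sums[j] <- sums[j] + val
          ns[j] <- ns[j] + 1L
        }
      }
    }
    data.frame(offset_bp = offsets * bin_width,
               mean = ifelse(ns > 0L, sums / pmax(ns, 1L), NA_real_),
               n = ns)
  }

  lapply(strata, function(st) {
    idx <- which(sizes >= st[1] & sizes < st[2])
    if (length(idx) == 0L) return(NULL)
    prof <- profile_for(idx)
    attr(prof, "stratum") <- st
    attr(prof, "n_regions") <- length(idx)
    class(prof) <- c("BoundaryProfile", "data.frame")
    prof
  })
}
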