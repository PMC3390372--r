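#' Pooled methylation level of a region
#'
#' The level is the ratio of summed counts
#' \eqn{\sum \#C / \sum(\#C + \#T)} over all in-region sites of the
#' requested context, pooling both strands (coverage-weighted, not a
#' mean of per-site ratios). A per-site mean is available behind
#' `per_site = TRUE`.
#'
#' @param calls A [MethylationCalls()].
#' @param region Optional region: `c(chrom, start, end)` (0-based
#'   half-open), a [RegionSet()] (union of its regions), or `NULL` for
#'   everything.
#' @param context `"CG"`, `"CHG"` or `"CHH"`.
#' @param per_site Average per-site ratios instead of pooling counts.
#' @return Level in `[0, 1]`, or `NA` when no covered site exists
#'   (missing, distinct from 0).
#' @export
methylation_level <- function(calls, region = NULL,
                              context = c("CG", "CHG", "CHH"),
                              per_site = FALSE) {
  context <- match.arg(context)
  sub <- calls[calls$context == context, , drop = FALSE]
  if (!is.null(region)) {
    if (inherits(region, "RegionSet") || is.data.frame(region)) {
      gr <- .as_granges(region)
      pts <- GenomicRanges::GRanges(sub$chrom,
                                    IRanges::IRanges(sub$pos + 1, width = 1))
      sub <- sub[GenomicRanges::countOverlaps(pts, gr) > 0L, , drop = FALSE]
    } else {
      chrom <- as.character(region[[1]])
      s <- as.numeric(region[[2]]); e <- as.numeric(region[[3]])
      sub <- sub[sub$chrom == chrom & sub$pos >= s & sub$pos < e, ,
                 drop = FALSE]
    }
  }
  cov <- sub$count_C + sub$count_T
  sub <- sub[cov > 0, , drop = FALSE]
  if (nrow(sub) == 0L) return(NA_real_)
  if (per_site)
    mean(sub$count_C / (sub$count_C + sub$count_T))
  else
    sum(sub$count_C) / sum(sub$count_C + sub$count_T)
}

#' Genome-wide methylation level per context
#'
#' @param calls A [MethylationCalls()].
#' @param region Optional region restriction as in
#'   [methylation_level()].
#' @return Named numeric vector with the pooled CG, CHG and CHH levels.
#' @export
methylation_levels_by_context <- function(calls, region = NULL) {
  vapply(c(CG = "CG", CHG = "CHG", CHH = "CHH"),
         function(ctx) methylation_level(calls, region, ctx), numeric(1))
}

#' Chromosome-scale methylation profile
#'
#' Pools calls of one context into fixed-width bins, computes the
#' coverage-weighted level per bin, and smooths triangularly. Bins with
#' zero coverage are missing (`NA`), never 0, and smoothing is applied
#' within runs of covered bins only.
#'
#' @param calls A [MethylationCalls()].
#' @param chrom_sizes Named chromosome lengths (bp).
#' @param bin_bp Bin width (default 100 kb for chromosomal views).
#' @param context Cytosine context.
#' @param smooth_iters Triangular smoothing passes (default 1).
#' @return A [BinnedSignal()] with semantics `"methylation"` and an
#'   extra `coverage` list of per-bin read totals.
#' @export
chromosome_profile <- function(calls, chrom_sizes, bin_bp = 100000L,
                               context = c("CG", "CHG", "CHH"),
                               smooth_iters = 1L) {
  context <- match.arg(context)
  if (bin_bp <= 0) stop("bin_bp must be positive")
  sub <- calls[calls$context == context, , drop = FALSE]
  values <- list(); coverage <- list()
  for (chrom in names(chrom_sizes)) {
    n_bins <- ceiling(chrom_sizes[[chrom]] / bin_bp)
    rows <- sub[sub$chrom == chrom, , drop = FALSE]
    if (nrow(rows) == 0L) {
      values[[chrom]] <- rep(NA_real_, n_bins)
      coverage[[chrom]] <- numeric(n_bins)
      next
    }
    bin <- pmin(floor(rows$pos / bin_bp) + 1L, n_bins)
    c_sum <- vapply(split(rows$count_C, factor(bin, levels = seq_len(n_bins))),
                    sum, numeric(1))
    t_sum <- vapply(split(rows$count_T, factor(bin, levels = seq_len(n_bins))),
                    sum, numeric(1))
    tot <- c_sum + t_sum
    lev <- ifelse(tot > 0, c_sum / tot, NA_real_)
    if (smooth_iters > 0L)
      lev <- .smooth_runs(lev, function(v) triangular_smooth(v, smooth_iters))
    values[[chrom]] <- unname(lev)
    coverage[[chrom]] <- unname(tot)
  }
  out <- BinnedSignal(values, bin_bp, semantics = "methylation")
  out$coverage <- coverage
  out$context <- context
  out
}

#' Feature-anchored methylation metaplot (TSS to TTS with flanks)
#'
#' Averages methylation over a set of stranded features: flanks are
#' binned at fixed `flank_bin_bp` resolution, feature bodies are scaled
#' to `n_body_bins` fractional bins, and minus-strand features are
#' reversed so the transcription start site is always on the left.
#' Counts are pooled across features per bin (coverage-weighted level),
#' then smoothed triangularly.
#'
#' @param calls A [MethylationCalls()].
#' @param features A [TEAnnotation()] or data.frame with columns
#'   `chrom`, `start`, `end`, `strand`. Features shorter than
#'   `n_body_bins` bp are length-scaled like any other (with a
#'   warning).
#' @param flank_bp Flank extent on each side (default 2000).
#' @param flank_bin_bp Flank bin width (default 100).
#' @param n_body_bins Number of scaled body bins (default 20).
#' @param context Cytosine context.
#' @param smooth_iters Triangular smoothing passes (default 3).
#' @return `data.frame` with columns `bin`, `zone`
#'   (`upstream`/`body`/`downstream`), `level`, `coverage`, `n_sites`.
#' @export
feature_metaplot <- function(calls, features, flank_bp = 2000L,
                             flank_bin_bp = 100L, n_body_bins = 20L,
                             context = c("CG", "CHG", "CHH"),
                             smooth_iters = 3L) {
  context <- match.arg(context)
  features <- as.data.frame(features)
  stopifnot(all(c("chrom", "start", "end", "strand") %in% names(features)))
  if (any(features$end - features$start < n_body_bins))
    warning("features shorter than n_body_bins bp are length-scaled")
  nf <- flank_bp %/% flank_bin_bp
  n_total <- 2L * nf + n_body_bins
  sub <- calls[calls$context == context & (calls$count_C + calls$count_T) > 0, ,
               drop = FALSE]
  c_sum <- numeric(n_total); t_sum <- numeric(n_total)
  n_sites <- integer(n_total)
  for (r in seq_len(nrow(features))) {
    chrom <- features$chrom[r]
    s <- features$start[r]; e <- features$end[r]
    minus <- identical(features$strand[r], "-")
    rows <- sub[sub$chrom == chrom & sub$pos >= s - flank_bp &
                  sub$pos < e + flank_bp, , drop = FALSE]
    if (nrow(rows) == 0L) next
    pos <- rows$pos
    ## signed distance along transcription direction from the TSS,
    ## with the body mapped to [0, 1)
    if (!minus) {
      d_tss <- pos - s          # bp upstream (<0) or into the body (>=0)
      d_tts <- pos - e          # >= 0 once past the TTS
      frac <- (pos - s) / (e - s)
    } else {
      d_tss <- (e - 1) - pos
      d_tts <- (s - 1) - pos    # distance past the TTS along transcription
      frac <- ((e - 1) - pos) / (e - s)
    }
    bin <- integer(nrow(rows))
    up <- d_tss < 0
    down <- d_tts >= 0
    body <- !up & !down
    bin[up] <- nf + 1L + floor(d_tss[up] / flank_bin_bp)     # 1..nf
    bin[body] <- nf + 1L + pmin(floor(frac[body] * n_body_bins),
                                n_body_bins - 1L)
    bin[down] <- nf + n_body_bins + 1L + floor(d_tts[down] / flank_bin_bp)
    keep <- bin >= 1L & bin <= n_total
    bin <- bin[keep]
    c_sum <- c_sum + vapply(split(rows$count_C[keep],
                                  factor(bin, levels = seq_len(n_total))),
                            sum, numeric(1))
    t_sum <- t_sum + vapply(split(rows$count_T[keep],
                                  factor(bin, levels = seq_len(n_total))),
                            sum, numeric(1))
    n_sites <- n_sites + tabulate(bin, nbins = n_total)
  }
  tot <- c_sum + t_sum
  level <- ifelse(tot > 0, c_sum / tot, NA_real_)
  if (smooth_iters > 0L)
    level <- .smooth_runs(level, function(v) triangular_smooth(v, smooth_iters))
  data.frame(bin = seq_len(n_total),
             zone = rep(c("upstream", "body", "downstream"),
                        times = c(nf, n_body_bins, nf)),
             level = unname(level), coverage = unname(tot),
             n_sites = n_sites)
}
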