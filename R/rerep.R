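#' Score pseudocount from library size
#'
#' The pseudocount added to every bin count is defined as the library
#' size in millions of uniquely mapping reads divided by 10, so deeper
#' libraries receive proportionally larger floors and the score of an
#' empty bin is depth-independent (c/0.1/M = 1).
#'
#' @param M Library size in millions of uniquely mapping reads.
#' @return The pseudocount `c = M/10`.
#' @examples
#' pseudocount(68) # 6.8
#' pseudocount(53) # 5.3
#' @export
pseudocount <- function(M) {
  if (!is.numeric(M) || any(M <= 0))
    stop("library size in millions must be positive")
  M / 10
}

#' Pseudocounted score track from 100-bp bin counts
#'
#' Computes `score[i] = (n[i] + c) / 0.1 kb / M`, i.e. reads per
#' kilobase per million mapped reads with a pseudocount floor, for each
#' bin. All scores are strictly positive, so downstream log2 ratios are
#' finite everywhere.
#'
#' @param counts A [BinnedSignal()] of integer counts (100-bp bins for
#'   the standard analysis).
#' @param M Library size in millions (post-deduplication).
#' @param c Pseudocount; defaults to [pseudocount()]`(M)`.
#' @return A `ScoreTrack` (a `BinnedSignal` with semantics `"score"`
#'   and `pseudocount`/`library_size_millions` fields).
#' @export
score_track <- function(counts, M, c = pseudocount(M)) {
  if (c <= 0) stop("pseudocount must be positive")
  kb <- counts$bin_width / 1000
  values <- lapply(counts$values, function(v) (v + c) / kb / M)
  out <- BinnedSignal(values, counts$bin_width, semantics = "score")
  out$pseudocount <- c
  out$library_size_millions <- M
  class(out) <- c("ScoreTrack", class(out))
  out
}

#' Per-bin log2 ratio of two score tracks
#'
#' @param mut,wt `ScoreTrack`s (or positive `BinnedSignal`s) on the same
#'   genome at the same bin width.
#' @return A [BinnedSignal()] with semantics `"log2_ratio"`.
#' @export
log2_ratio <- function(mut, wt) {
  if (mut$bin_width != wt$bin_width)
    stop("bin widths differ between the two tracks")
  if (!setequal(names(mut$values), names(wt$values)))
    stop("the two tracks cover different chromosomes")
  values <- lapply(names(mut$values), function(chrom) {
    a <- mut$values[[chrom]]; b <- wt$values[[chrom]]
    if (length(a) != length(b)) stop("bin count mismatch on ", chrom)
    log2(a / b)
  })
  names(values) <- names(mut$values)
  BinnedSignal(values, mut$bin_width, semantics = "log2_ratio")
}

#' Sliding-window Z-scores of a log2-ratio track
#'
#' Tiles each chromosome into overlapping windows (1 kb stepped 500 bp
#' by default), averages the constituent fine-bin log2 ratios per
#' window, and standardizes the window values to Z-scores against the
#' mean and standard deviation of all windows (genome-wide by default).
#' A final partial window shorter than `window_bp` is dropped so the Z
#' population is homogeneous. If the window values are constant
#' (sd = 0), all Z are defined as 0.
#'
#' @param ratio A [BinnedSignal()] log2-ratio track whose bin width
#'   divides `window_bp` and `step_bp`.
#' @param window_bp Window length in bp.
#' @param step_bp Step between window starts in bp.
#' @param per_chrom Standardize within each chromosome instead of
#'   genome-wide.
#' @return A `WindowZ` data.frame (columns `chrom`, `start`, `end`,
#'   `value`, `z`) with `window_bp`/`step_bp` attributes.
#' @export
window_z <- function(ratio, window_bp = 1000L, step_bp = 500L,
                     per_chrom = FALSE) {
  w <- ratio$bin_width
  if (window_bp %% w != 0 || step_bp %% w != 0)
    stop("window_bp and step_bp must be multiples of the bin width")
  k <- window_bp %/% w
  s <- step_bp %/% w
  rows <- lapply(names(ratio$values), function(chrom) {
    v <- ratio$values[[chrom]]
    if (length(v) < k) return(NULL)
    starts_bin <- seq(0L, length(v) - k, by = s)
    cs <- c(0, cumsum(v))
    vals <- (cs[starts_bin + k + 1L] - cs[starts_bin + 1L]) / k
    data.frame(chrom = chrom, start = starts_bin * w,
               end = starts_bin * w + window_bp, value = vals)
  })
  df <- do.call(rbind, rows)
  if (is.null(df) || nrow(df) < 2L)
    stop("fewer than 2 windows; cannot standardize")
  zscore <- function(v) {
    sigma <- sd(v)
    if (length(v) < 2L || sigma == 0) rep(0, length(v))
    else (v - mean(v)) / sigma
  }
  df$z <- if (per_chrom) ave(df$value, df$chrom, FUN = zscore)
          else zscore(df$value)
  attr(df, "window_bp") <- window_bp
  attr(df, "step_bp") <- step_bp
  class(df) <- c("WindowZ", "data.frame")
  df
}

#' Call re-replicated regions from window Z-scores
#'
#' Windows with Z above the cutoff are taken as intervals and merged
#' whenever the gap between them is at most `merge_gap_bp` (overlapping
#' and adjacent windows always merge). Each merged region carries the
#' maximum Z and mean window log2 ratio of its constituent windows.
#'
#' @param wz A `WindowZ` from [window_z()].
#' @param z_cut Z-score cutoff (windows with `z > z_cut` pass).
#' @param merge_gap_bp Maximum gap (bp) across which passing windows
#'   are merged.
#' @return A [RegionSet()] of disjoint sorted regions with extra
#'   columns `max_z` and `mean_log2`.
#' @export
call_regions <- function(wz, z_cut = 2, merge_gap_bp = 500L) {
  pass <- wz[wz$z > z_cut, , drop = FALSE]
  if (nrow(pass) == 0L)
    return(RegionSet(data.frame(chrom = character(), start = numeric(),
                                end = numeric()), label = "rerep_regions"))
  gr <- .as_granges(pass)
  merged <- GenomicRanges::reduce(gr, min.gapwidth = merge_gap_bp + 1L)
  hits <- GenomicRanges::findOverlaps(gr, merged)
  max_z <- tapply(pass$z[S4Vectors::queryHits(hits)],
                  S4Vectors::subjectHits(hits), max)
  mean_l2 <- tapply(pass$value[S4Vectors::queryHits(hits)],
                    S4Vectors::subjectHits(hits), mean)
  df <- .from_granges(merged)
  df$max_z <- as.numeric(max_z[as.character(seq_along(merged))])
  df$mean_log2 <- as.numeric(mean_l2[as.character(seq_along(merged))])
  RegionSet(df, label = "rerep_regions")
}

#' TEs overlapping called regions by at least 1 bp
#'
#' A transposable element is considered re-replicating when it shares at
#' least one base with any called region (half-open intervals that
#' merely touch do not overlap).
#'
#' @param regions A [RegionSet()] of called regions.
#' @param tes A [TEAnnotation()].
#' @return Character vector of re-replicating `te_id`s.
#' @export
annotate_rerep_tes <- function(regions, tes) {
  if (nrow(regions) == 0L || nrow(tes) == 0L) return(character())
  hits <- GenomicRanges::findOverlaps(.as_granges(tes), .as_granges(regions),
                                      minoverlap = 1L)
  sort(unique(tes$te_id[S4Vectors::queryHits(hits)]))
}

#' Chromosome-scale coverage view
#'
#' Bins reads into coarse bins (100 kb by default), converts to
#' normalized density (reads per base per million uniquely mapping
#' reads) and smooths triangularly. In `"log2_ratio"` mode the densities
#' are pseudocounted (per-bin count + M/10) before the ratio so the view
#' is finite in empty bins; in `"density"` mode the two raw density
#' tracks are returned for overlay plots.
#'
#' @param mut,wt Deduplicated [ReadPlacements()].
#' @param chrom_sizes Named chromosome lengths (bp).
#' @param bin_bp Bin width (default 100 kb).
#' @param smooth_iters Triangular smoothing passes (default 10).
#' @param mode `"log2_ratio"` or `"density"`.
#' @return A [BinnedSignal()] (log2 mode) or a list of two
#'   `BinnedSignal`s named `mut` and `wt` (density mode).
#' @export
chromosome_view <- function(mut, wt, chrom_sizes, bin_bp = 100000L,
                            smooth_iters = 10L,
                            mode = c("log2_ratio", "density")) {
  mode <- match.arg(mode)
  dens <- function(reads, pseudo) {
    counts <- bin_counts(reads, chrom_sizes, bin_bp)
    M <- reads$library_size_millions
    c0 <- if (pseudo) pseudocount(M) else 0
    values <- lapply(counts$values, function(v) (v + c0) / bin_bp / M)
    BinnedSignal(values, bin_bp, semantics = "density")
  }
  if (mode == "density") {
    out <- list(mut = dens(mut, FALSE), wt = dens(wt, FALSE))
    if (smooth_iters > 0L)
      out <- lapply(out, smooth_signal, method = "triangular",
                    n_iter = smooth_iters)
    return(out)
  }
  ratio <- log2_ratio(dens(mut, TRUE), dens(wt, TRUE))
  if (smooth_iters > 0L)
    ratio <- smooth_signal(ratio, method = "triangular",
                           n_iter = smooth_iters)
  ratio
}

#' Fraction of reads falling into heterochromatin
#'
#' @param reads A deduplicated [ReadPlacements()].
#' @param het A [RegionSet()] of heterochromatic regions.
#' @return Fraction in `[0, 1]` of placements whose 5' position lies
#'   inside the regions.
#' @export
het_fraction <- function(reads, het) {
  total <- nrow(reads$placements)
  if (total == 0L) stop("no reads: fraction undefined")
  if (nrow(het) == 0L) return(0)
  inside <- sum(GenomicRanges::countOverlaps(.placement_granges(reads),
                                             .as_granges(het)) > 0L)
  inside / total
}

#' Compare heterochromatin read fractions between two samples
#'
#' Tests association between sample identity and in/out-of-
#' heterochromatin read placement on the 2x2 count table, using the
#' chi-square test with continuity correction, or Fisher's exact test
#' when any cell is below 5.
#'
#' @param reads_a,reads_b Deduplicated [ReadPlacements()].
#' @param het A [RegionSet()].
#' @return List with `p.value`, `method`, `table`, and the two
#'   fractions.
#' @export
compare_het_fractions <- function(reads_a, reads_b, het) {
  counts <- function(reads) {
    total <- nrow(reads$placements)
    inside <- round(het_fraction(reads, het) * total)
    c(inside = inside, outside = total - inside)
  }
  tab <- rbind(a = counts(reads_a), b = counts(reads_b))
  if (any(rowSums(tab) == 0L) || any(colSums(tab) == 0L))
    stop("degenerate 2x2 table (zero margin)")
  if (any(tab < 5)) {
    method <- "fisher"
    p <- fisher.test(tab, conf.int = FALSE)$p.value
  } else {
    method <- "chisq_continuity"
    p <- suppressWarnings(chisq.test(tab, correct = TRUE)$p.value)
  }
  list(p.value = p, method = method, table = tab,
       fraction_a = tab[1, 1] / sum(tab[1, ]),
       fraction_b = tab[2, 1] / sum(tab[2, ]))
}

#' Per-TE genomic DNA read density
#'
#' Reads per kilobase of TE length per million mapping reads, counting
#' placements whose 5' position lies inside the element.
#'
#' @param reads A deduplicated [ReadPlacements()].
#' @param tes A [TEAnnotation()].
#' @param te_ids TEs to report (default: all annotated).
#' @return Named numeric vector of densities.
#' @export
te_dna_density <- function(reads, tes, te_ids = tes$te_id) {
  missing <- setdiff(te_ids, tes$te_id)
  if (length(missing))
    stop("unknown te_id: ", paste(missing, collapse = ", "))
  sub <- tes[match(te_ids, tes$te_id), , drop = FALSE]
  n <- GenomicRanges::countOverlaps(.as_granges(sub),
                                    .placement_granges(reads))
  dens <- n / ((sub$end - sub$start) / 1000) / reads$library_size_millions
  setNames(dens, te_ids)
}

#' Wilcoxon rank-sum comparison of two density vectors
#'
#' Two-sided Mann-Whitney/Wilcoxon rank-sum test. For small samples
#' (n + m <= 12) the null distribution of the rank-sum statistic is
#' enumerated exactly over all splits, which handles ties exactly (two
#' identical samples give p = 1); larger samples use
#' [stats::wilcox.test()].
#'
#' @param a,b Non-empty numeric vectors.
#' @return Two-sided p-value.
#' @export
ranksum_compare <- function(a, b) {
  if (length(a) == 0L || length(b) == 0L) stop("both samples must be non-empty")
  pooled <- c(a, b)
  if (length(unique(pooled)) == 1L) return(1)
  n <- length(a); m <- length(b)
  if (n + m <= 12L) {
    r <- rank(pooled)
    obs <- sum(r[seq_len(n)])
    splits <- utils::combn(n + m, n)
    stats <- colSums(matrix(r[splits], nrow = n))
    mu <- n * (n + m + 1) / 2
    p <- mean(abs(stats - mu) >= abs(obs - mu) - 1e-9)
    return(min(1, p))
  }
  suppressWarnings(wilcox.test(a, b, alternative = "two.sided"))$p.value
}

#' Merge a RegionSet (union of overlapping or nearby intervals)
#'
#' @param regions A [RegionSet()].
#' @param merge_gap_bp Maximum gap to bridge (0 merges only overlapping
#'   or bookended intervals).
#' @return A disjoint sorted `RegionSet`.
#' @export
merge_regions <- function(regions, merge_gap_bp = 0L) {
  if (nrow(regions) == 0L) return(regions)
  merged <- GenomicRanges::reduce(.as_granges(regions),
                                  min.gapwidth = merge_gap_bp + 1L)
  RegionSet(.from_granges(merged), label = attr(regions, "label"))
}

#' Jaccard overlap of two region sets
#'
#' Base-pair intersection over base-pair union; 1 when the sets cover
#' identical bases, 0 when disjoint.
#'
#' @param a,b [RegionSet()]s.
#' @return Jaccard index in `[0, 1]`.
#' @export
regions_jaccard <- function(a, b) {
  if (nrow(a) == 0L && nrow(b) == 0L) return(1)
  if (nrow(a) == 0L || nrow(b) == 0L) return(0)
  ga <- GenomicRanges::reduce(.as_granges(a))
  gb <- GenomicRanges::reduce(.as_granges(b))
  inter <- sum(GenomicRanges::width(GenomicRanges::intersect(ga, gb)))
  uni <- sum(GenomicRanges::width(GenomicRanges::union(ga, gb)))
  inter / uni
}

#' Full re-replication calling pipeline
#'
#' Convenience wrapper running the complete caller: dedup counts are
#' assumed done; bins reads at `bin_bp`, builds pseudocounted score
#' tracks, takes the log2 mutant/wild-type ratio, computes window
#' Z-scores, thresholds and merges regions, and annotates overlapping
#' TEs.
#'
#' @param mut,wt Deduplicated [ReadPlacements()].
#' @param chrom_sizes Named chromosome lengths (bp).
#' @param tes Optional [TEAnnotation()] to annotate.
#' @param bin_bp Fine bin width (default 100).
#' @param window_bp,step_bp Window tiling (default 1 kb / 500 bp).
#' @param z_cut,merge_gap_bp Calling parameters (default Z > 2, 500 bp).
#' @return List with `score_mut`, `score_wt`, `ratio`, `windows`,
#'   `regions`, and (if `tes` given) `rerep_te_ids`.
#' @export
call_rereplication <- function(mut, wt, chrom_sizes, tes = NULL,
                               bin_bp = 100L, window_bp = 1000L,
                               step_bp = 500L, z_cut = 2,
                               merge_gap_bp = 500L) {
  score_mut <- score_track(bin_counts(mut, chrom_sizes, bin_bp),
                           M = mut$library_size_millions)
  score_wt <- score_track(bin_counts(wt, chrom_sizes, bin_bp),
                          M = wt$library_size_millions)
  ratio <- log2_ratio(score_mut, score_wt)
  wz <- window_z(ratio, window_bp = window_bp, step_bp = step_bp)
  regions <- call_regions(wz, z_cut = z_cut, merge_gap_bp = merge_gap_bp)
  out <- list(score_mut = score_mut, score_wt = score_wt, ratio = ratio,
              windows = wz, regions = regions)
  if (!is.null(tes)) out$rerep_te_ids <- annotate_rerep_tes(regions, tes)
  out
}
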