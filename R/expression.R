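#' Reads per kilobase per million mapped reads
#'
#' @param count Read count(s) for the feature.
#' @param length_bp Feature length(s) in bp (> 0).
#' @param lib_size_reads Total mapped reads in the library (> 0).
#' @return `count / (length_bp/1000) / (lib_size_reads/1e6)`.
#' @export
rpkm <- function(count, length_bp, lib_size_reads) {
  if (any(length_bp <= 0)) stop("feature length must be positive")
  if (any(lib_size_reads <= 0)) stop("library size must be positive")
  count / (length_bp / 1000) / (lib_size_reads / 1e6)
}

#' Replace zero expression values by the sample floor
#'
#' Features with an expression level of zero are assigned the lowest
#' non-zero expression value of the same sample, so fold changes are
#' finite. Non-zero values are unchanged.
#'
#' @param x Numeric vector of expression values for one sample.
#' @return `x` with zeros replaced.
#' @export
replace_zeros <- function(x) {
  nz <- x[x > 0]
  if (length(nz) == 0L)
    stop("all expression values are zero: replacement floor undefined")
  x[x == 0] <- min(nz)
  x
}

#' Fisher's exact test for differential expression between two libraries
#'
#' Two-sided Fisher's exact test on the 2x2 table of feature count
#' versus remaining library count in each sample. Vectorized over
#' features; identical tables are computed once.
#'
#' @param count_mut,count_wt Feature counts in the two libraries.
#' @param lib_mut,lib_wt Total mapped reads of the two libraries.
#' @return Raw two-sided p-value(s).
#' @export
fisher_de <- function(count_mut, count_wt, lib_mut, lib_wt) {
  if (any(count_mut < 0) || any(count_wt < 0))
    stop("counts must be non-negative")
  if (any(count_mut > lib_mut) || any(count_wt > lib_wt))
    stop("counts exceed library size")
  n <- max(length(count_mut), length(count_wt))
  count_mut <- rep_len(count_mut, n); count_wt <- rep_len(count_wt, n)
  key <- paste(count_mut, count_wt, sep = ":")
  uniq <- !duplicated(key)
  p_uniq <- vapply(which(uniq), function(i) {
    tab <- matrix(c(count_mut[i], lib_mut - count_mut[i],
                    count_wt[i], lib_wt - count_wt[i]),
                  nrow = 2, byrow = TRUE)
    min(1, fisher.test(tab, conf.int = FALSE)$p.value)
  }, numeric(1))
  unname(p_uniq[match(key, key[uniq])])
}

#' Benjamini-Hochberg FDR adjustment
#'
#' Step-up adjusted p-values: with p sorted ascending,
#' `q(i) = min_{j >= i} p(j) * m / j`, capped at 1, returned in the
#' input order.
#'
#' @param p Raw p-values in `[0, 1]`.
#' @return Adjusted p-values.
#' @export
bh_adjust <- function(p) {
  if (any(is.na(p)) || any(p < 0) || any(p > 1 + 1e-12))
    stop("p-values must lie in [0, 1]")
  p.adjust(pmin(p, 1), method = "BH")
}

#' Call derepressed features across replicate pairs
#'
#' For every mutant-vs-wild-type replicate pair: RPKM is computed per
#' sample, zeros are replaced by the lowest non-zero value of that
#' sample, the fold change is the zero-replaced RPKM ratio, and
#' Fisher's exact p-values on the raw counts are BH-adjusted across
#' features. A feature is called derepressed only if fold change >
#' `fc_cut` and p < `p_cut` in *every* replicate pair.
#'
#' @param counts A [CountTable()].
#' @param pairs `data.frame` with columns `wt` and `mut` naming sample
#'   columns of `counts`; row i is replicate pair i.
#' @param fc_cut Fold-change cutoff (called when strictly exceeded).
#' @param p_cut P-value cutoff (called when strictly below).
#' @param use_adjusted Apply `p_cut` to BH-adjusted p-values (default)
#'   or to raw p-values.
#' @return A `DerepressionResult` data.frame with per-pair columns
#'   `rpkm_wt_<i>`, `rpkm_mut_<i>`, `fc_<i>`, `p_<i>`, `padj_<i>`, a
#'   logical `called` column, and attribute `called_ids`.
#' @export
call_derepressed <- function(counts, pairs, fc_cut = 4, p_cut = 0.01,
                             use_adjusted = TRUE) {
  pairs <- as.data.frame(pairs)
  if (!all(c("wt", "mut") %in% names(pairs)) || nrow(pairs) < 1L)
    stop("pairs must be a data.frame with >= 1 row and columns wt, mut")
  miss <- setdiff(unlist(pairs[c("wt", "mut")]), colnames(counts$counts))
  if (length(miss))
    stop("replicate pairing names samples absent from the table: ",
         paste(miss, collapse = ", "))
  features <- rownames(counts$counts)
  out <- data.frame(feature_id = features)
  pass <- matrix(TRUE, nrow = length(features), ncol = nrow(pairs))
  for (i in seq_len(nrow(pairs))) {
    wt <- as.character(pairs$wt[i]); mut <- as.character(pairs$mut[i])
    r_wt <- replace_zeros(rpkm(counts$counts[, wt], counts$lengths,
                               counts$lib_sizes[[wt]]))
    r_mut <- replace_zeros(rpkm(counts$counts[, mut], counts$lengths,
                                counts$lib_sizes[[mut]]))
    fc <- r_mut / r_wt
    p <- fisher_de(counts$counts[, mut], counts$counts[, wt],
                   counts$lib_sizes[[mut]], counts$lib_sizes[[wt]])
    padj <- bh_adjust(p)
    crit_p <- if (use_adjusted) padj else p
    pass[, i] <- fc > fc_cut & crit_p < p_cut
    out[[paste0("rpkm_wt_", i)]] <- unname(r_wt)
    out[[paste0("rpkm_mut_", i)]] <- unname(r_mut)
    out[[paste0("fc_", i)]] <- unname(fc)
    out[[paste0("p_", i)]] <- p
    out[[paste0("padj_", i)]] <- padj
  }
  out$called <- rowSums(pass) == nrow(pairs)
  attr(out, "called_ids") <- features[out$called]
  class(out) <- c("DerepressionResult", "data.frame")
  out
}

#' Overlap of two feature sets with hypergeometric enrichment
#'
#' @param set_a,set_b Character vectors of feature ids.
#' @param universe Character vector containing every id of both sets.
#' @return List with `n_intersect`, `n_a_only`, `n_b_only`,
#'   `p_enrich` (upper-tail hypergeometric probability of at least the
#'   observed intersection).
#' @export
overlap_sets <- function(set_a, set_b, universe) {
  set_a <- unique(set_a); set_b <- unique(set_b); universe <- unique(universe)
  out_a <- setdiff(set_a, universe); out_b <- setdiff(set_b, universe)
  if (length(out_a) || length(out_b))
    stop("sets contain ids outside the universe: ",
         paste(c(out_a, out_b), collapse = ", "))
  k <- length(intersect(set_a, set_b))
  list(n_intersect = k,
       n_a_only = length(setdiff(set_a, set_b)),
       n_b_only = length(setdiff(set_b, set_a)),
       p_enrich = phyper(k - 1, length(set_a),
                         length(universe) - length(set_a),
                         length(set_b), lower.tail = FALSE))
}

#' Superfamily composition of a feature set
#'
#' @param feature_set Character vector of `te_id`s.
#' @param tes A [TEAnnotation()].
#' @return `data.frame` (family, count, fraction) ordered by
#'   descending count; fractions sum to 1. Empty input gives an empty
#'   frame.
#' @export
family_composition <- function(feature_set, tes) {
  miss <- setdiff(feature_set, tes$te_id)
  if (length(miss)) stop("unknown te_id: ", paste(miss, collapse = ", "))
  if (length(feature_set) == 0L)
    return(data.frame(family = character(), count = integer(),
                      fraction = numeric()))
  fam <- tes$superfamily[match(feature_set, tes$te_id)]
  tab <- sort(table(fam), decreasing = TRUE)
  data.frame(family = names(tab), count = as.integer(tab),
             fraction = as.numeric(tab) / length(feature_set))
}

#' RPKM-normalized browser track in fine bins
#'
#' Bins read 5' ends into non-overlapping `bin_bp` bins (20 bp by
#' default) and normalizes each count to RPKM semantics:
#' `count / (bin_bp/1000) / M`.
#'
#' @param reads A deduplicated [ReadPlacements()].
#' @param chrom_sizes Named chromosome lengths (bp).
#' @param bin_bp Bin width (default 20).
#' @return A [BinnedSignal()] with semantics `"rpkm"`.
#' @export
browser_bins <- function(reads, chrom_sizes, bin_bp = 20L) {
  counts <- bin_counts(reads, chrom_sizes, bin_bp)
  M <- reads$library_size_millions
  values <- lapply(counts$values, function(v) v / (bin_bp / 1000) / M)
  BinnedSignal(values, bin_bp, semantics = "rpkm")
}
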