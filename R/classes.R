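#' Read placements for one sequencing library
#'
#' Holds deduplicatable uniquely-mapped read positions: one row per read
#' with chromosome, 0-based 5'-most coordinate and strand. The library
#' size in millions is always the current number of placements / 1e6, so
#' after [dedup_placements()] it is the post-deduplication size used by
#' the score pseudocount.
#'
#' @param sample_id Character scalar naming the library.
#' @param placements `data.frame` with columns `chrom` (character),
#'   `pos5` (non-negative integer, 0-based) and `strand` (`"+"`/`"-"`).
#' @return A `ReadPlacements` object (list with `sample_id`,
#'   `placements`, `library_size_millions`).
#' @export
ReadPlacements <- function(sample_id, placements) {
  stopifnot(is.character(sample_id), length(sample_id) == 1L)
  placements <- as.data.frame(placements)
  req <- c("chrom", "pos5", "strand")
  if (!all(req %in% names(placements)))
    stop("placements must have columns chrom, pos5, strand")
  placements <- placements[req]
  placements$chrom <- as.character(placements$chrom)
  placements$strand <- as.character(placements$strand)
  if (nrow(placements) > 0L) {
    if (any(placements$pos5 < 0)) stop("pos5 must be non-negative")
    if (!all(placements$strand %in% c("+", "-")))
      stop("strand must be '+' or '-'")
  }
  rownames(placements) <- NULL
  structure(
    list(sample_id = sample_id, placements = placements,
         library_size_millions = nrow(placements) / 1e6),
    class = "ReadPlacements")
}

#' @export
print.ReadPlacements <- function(x, ...) {
  cat(sprintf("ReadPlacements '%s': %d placements (%.3f million)\n",
              x$sample_id, nrow(x$placements), x$library_size_millions))
  invisible(x)
}

#' Set of genomic regions (0-based, half-open)
#'
#' @param regions `data.frame` with columns `chrom`, `start`, `end`
#'   (0-based half-open). Extra columns are retained.
#' @param label Character scalar describing the set.
#' @return A `RegionSet`: a data.frame sorted by (chrom, start) with
#'   class `RegionSet` and a `label` attribute.
#' @export
RegionSet <- function(regions, label = "regions") {
  regions <- as.data.frame(regions)
  if (nrow(regions) == 0L && !all(c("chrom", "start", "end") %in% names(regions)))
    regions <- data.frame(chrom = character(), start = numeric(), end = numeric())
  if (!all(c("chrom", "start", "end") %in% names(regions)))
    stop("regions must have columns chrom, start, end")
  regions$chrom <- as.character(regions$chrom)
  if (nrow(regions) > 0L) {
    if (any(regions$start < 0)) stop("start must be non-negative")
    if (any(regions$end <= regions$start))
      stop("invalid interval: end must exceed start (0-based half-open)")
    regions <- regions[order(regions$chrom, regions$start, regions$end), , drop = FALSE]
  }
  rownames(regions) <- NULL
  structure(regions, class = c("RegionSet", "data.frame"), label = label)
}

#' @export
print.RegionSet <- function(x, ...) {
  cat(sprintf("RegionSet '%s': %d regions, %s bp total\n",
              attr(x, "label"), nrow(x),
              format(sum(x$end - x$start), big.mark = ",")))
  if (nrow(x) > 0L) print.data.frame(head(as.data.frame(x), 6L))
  invisible(x)
}

#' Transposable-element annotation
#'
#' @param entries `data.frame` with columns `te_id`, `chrom`, `start`,
#'   `end` (0-based half-open), `superfamily` and optionally `strand`
#'   (defaults to `"+"`).
#' @return A `TEAnnotation` data.frame with unique `te_id`.
#' @export
TEAnnotation <- function(entries) {
  entries <- as.data.frame(entries)
  req <- c("te_id", "chrom", "start", "end", "superfamily")
  if (!all(req %in% names(entries)))
    stop("entries must have columns te_id, chrom, start, end, superfamily")
  if (is.null(entries$strand)) entries$strand <- rep("+", nrow(entries))
  entries <- entries[c(req, "strand")]
  for (col in c("te_id", "chrom", "superfamily", "strand"))
    entries[[col]] <- as.character(entries[[col]])
  if (anyDuplicated(entries$te_id))
    stop("duplicate te_id: ",
         paste(unique(entries$te_id[duplicated(entries$te_id)]), collapse = ", "))
  if (nrow(entries) > 0L && any(entries$end <= entries$start))
    stop("invalid TE interval: end must exceed start")
  rownames(entries) <- NULL
  structure(entries, class = c("TEAnnotation", "data.frame"))
}

#' @export
print.TEAnnotation <- function(x, ...) {
  cat(sprintf("TEAnnotation: %d elements, %d superfamilies\n",
              nrow(x), length(unique(x$superfamily))))
  if (nrow(x) > 0L) print.data.frame(head(as.data.frame(x), 6L))
  invisible(x)
}

#' Per-cytosine methylation calls
#'
#' One record per (chrom, pos, strand) with counts of unconverted (`count_C`,
#' methylated) and converted (`count_T`, unmethylated) read bases, in one
#' of the three plant cytosine contexts.
#'
#' @param records `data.frame` with columns `chrom`, `pos` (0-based),
#'   `strand`, `context` (`CG`/`CHG`/`CHH`), `count_C`, `count_T`.
#' @return A `MethylationCalls` data.frame.
#' @export
MethylationCalls <- function(records) {
  records <- as.data.frame(records)
  req <- c("chrom", "pos", "strand", "context", "count_C", "count_T")
  if (nrow(records) == 0L && length(names(records)) == 0L)
    records <- data.frame(chrom = character(), pos = integer(),
                          strand = character(), context = character(),
                          count_C = integer(), count_T = integer())
  if (!all(req %in% names(records)))
    stop("records must have columns ", paste(req, collapse = ", "))
  records <- records[req]
  records$chrom <- as.character(records$chrom)
  records$strand <- as.character(records$strand)
  records$context <- as.character(records$context)
  if (nrow(records) > 0L) {
    bad <- setdiff(unique(records$context), c("CG", "CHG", "CHH"))
    if (length(bad))
      stop("unknown methylation context: ", paste(bad, collapse = ", "))
    if (any(records$count_C < 0) || any(records$count_T < 0))
      stop("negative methylation counts")
  }
  rownames(records) <- NULL
  structure(records, class = c("MethylationCalls", "data.frame"))
}

#' @export
print.MethylationCalls <- function(x, ...) {
  cat(sprintf("MethylationCalls: %d sites (%s)\n", nrow(x),
              paste(names(table(x$context)), table(x$context),
                    sep = "=", collapse = ", ")))
  invisible(x)
}

#' Fixed-width binned signal over a genome
#'
#' Bins tile each chromosome from position 0; bin `i` (1-based index)
#' covers `[(i-1)*w, i*w)`. Vector lengths are `ceiling(size/w)`.
#'
#' @param values Named list: chromosome -> numeric vector of bin values.
#' @param bin_width Bin width in bp.
#' @param semantics What the values are (`"count"`, `"score"`,
#'   `"log2_ratio"`, `"methylation"`, `"density"`, `"rpkm"`).
#' @return A `BinnedSignal` object.
#' @export
BinnedSignal <- function(values, bin_width, semantics = "count") {
  stopifnot(is.list(values), !is.null(names(values)), bin_width > 0)
  structure(list(values = values, bin_width = bin_width,
                 semantics = semantics),
            class = "BinnedSignal")
}

#' @export
print.BinnedSignal <- function(x, ...) {
  cat(sprintf("BinnedSignal (%s): %d chromosome(s), bin %d bp\n",
              x$semantics, length(x$values), as.integer(x$bin_width)))
  invisible(x)
}

#' Feature-by-sample count table for expression analysis
#'
#' @param counts Integer matrix, features x samples, with dimnames.
#' @param lengths Named numeric vector of feature lengths (bp).
#' @param lib_sizes Named numeric vector of total mapped reads per sample.
#' @return A `CountTable` object.
#' @export
CountTable <- function(counts, lengths, lib_sizes) {
  counts <- as.matrix(counts)
  if (is.null(rownames(counts)) || is.null(colnames(counts)))
    stop("counts must have feature rownames and sample colnames")
  if (any(counts < 0)) stop("counts must be non-negative")
  lengths <- lengths[rownames(counts)]
  if (any(is.na(lengths)) || any(lengths <= 0))
    stop("every feature needs a positive length")
  if (!all(colnames(counts) %in% names(lib_sizes)))
    stop("every sample needs a library size")
  lib_sizes <- lib_sizes[colnames(counts)]
  if (any(lib_sizes <= 0)) stop("library sizes must be positive")
  structure(list(counts = counts, lengths = lengths, lib_sizes = lib_sizes),
            class = "CountTable")
}

#' @export
print.CountTable <- function(x, ...) {
  cat(sprintf("CountTable: %d features x %d samples\n",
              nrow(x$counts), ncol(x$counts)))
  invisible(x)
}

## --- internal coordinate helpers ------------------------------------

## 0-based half-open -> GRanges (1-based closed)
.as_granges <- function(df) {
  GenomicRanges::GRanges(df$chrom,
                         IRanges::IRanges(start = df$start + 1, end = df$end))
}

## GRanges -> 0-based half-open data.frame
.from_granges <- function(gr) {
  data.frame(chrom = as.character(GenomicRanges::seqnames(gr)),
             start = GenomicRanges::start(gr) - 1,
             end = GenomicRanges::end(gr))
}

## read 5' positions as width-1 GRanges
.placement_granges <- function(reads) {
  p <- reads$placements
  GenomicRanges::GRanges(p$chrom, IRanges::IRanges(p$pos5 + 1, width = 1))
}
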