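#' Read a BED file of genomic regions
#'
#' Parses a 3+ column BED file into a [RegionSet()]. BED coordinates are
#' already 0-based half-open and pass through unchanged. `track`,
#' `browser` and `#` comment lines are ignored.
#'
#' @param path Path to a BED3+ file.
#' @param label Label for the region set (defaults to the file name).
#' @return A `RegionSet`, sorted by (chrom, start).
#' @export
read_regions_bed <- function(path, label = basename(path)) {
  lines <- readLines(path)
  keep <- !grepl("^(track|browser|#)", lines) & nzchar(lines)
  idx <- which(keep)
  if (length(idx) == 0L)
    return(RegionSet(data.frame(chrom = character(), start = numeric(),
                                end = numeric()), label = label))
  fields <- strsplit(lines[idx], "\t", fixed = TRUE)
  out <- vector("list", length(idx))
  for (k in seq_along(idx)) {
    f <- fields[[k]]
    if (length(f) < 3L)
      stop(sprintf("malformed BED line %d in %s: fewer than 3 fields",
                   idx[k], path))
    s <- suppressWarnings(as.numeric(f[2])); e <- suppressWarnings(as.numeric(f[3]))
    if (is.na(s) || is.na(e))
      stop(sprintf("malformed BED line %d in %s: non-numeric coordinates",
                   idx[k], path))
    if (e <= s)
      stop(sprintf("invalid interval on line %d in %s: end (%s) <= start (%s)",
                   idx[k], path, f[3], f[2]))
    out[[k]] <- data.frame(chrom = f[1], start = s, end = e)
  }
  RegionSet(do.call(rbind, out), label = label)
}

#' Write a RegionSet as BED
#'
#' Extra numeric columns `name` and `score`, if present, are written as
#' BED columns 4-5.
#'
#' @param regions A `RegionSet`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_regions_bed <- function(regions, path) {
  df <- as.data.frame(regions)[c("chrom", "start", "end")]
  df$start <- format(df$start, scientific = FALSE, trim = TRUE)
  df$end <- format(df$end, scientific = FALSE, trim = TRUE)
  if (!is.null(regions$name)) df$name <- regions$name
  if (!is.null(regions$score)) df$score <- regions$score
  write.table(df, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a transposable-element annotation
#'
#' Supports GFF3 (1-based closed coordinates, converted to 0-based
#' half-open on read; element id from the `ID` or `Name` attribute,
#' superfamily from `family_attr`) and BED6+family (family label in a
#' designated extra column, 0-based coordinates passed through).
#'
#' @param path Path to the annotation file.
#' @param format `"gff3"` or `"bed"`.
#' @param family_attr GFF3 attribute holding the superfamily label.
#' @param family_col 1-based column index of the family label for BED
#'   input (default 7, i.e. BED6 + family).
#' @return A [TEAnnotation()]. Entries without a family label are kept
#'   with superfamily `"Unknown"` and a warning.
#' @export
read_te_annotation <- function(path, format = c("gff3", "bed"),
                               family_attr = "family", family_col = 7L) {
  format <- match.arg(format)
  if (format == "gff3") {
    gr <- rtracklayer::import(path, format = "gff3")
    mc <- S4Vectors::mcols(gr)
    te_id <- if (!is.null(mc$ID)) as.character(mc$ID) else as.character(mc$Name)
    if (is.null(te_id) || any(is.na(te_id)))
      stop("GFF3 entries must carry an ID or Name attribute")
    fam <- if (family_attr %in% names(mc)) as.character(mc[[family_attr]])
           else rep(NA_character_, length(gr))
    if (any(is.na(fam))) {
      warning(sum(is.na(fam)), " entries lack a '", family_attr,
              "' attribute; labeled Unknown")
      fam[is.na(fam)] <- "Unknown"
    }
    strand <- as.character(GenomicRanges::strand(gr))
    strand[strand == "*"] <- "+"
    entries <- data.frame(te_id = te_id,
                          chrom = as.character(GenomicRanges::seqnames(gr)),
                          start = GenomicRanges::start(gr) - 1,
                          end = GenomicRanges::end(gr),
                          superfamily = fam, strand = strand)
  } else {
    df <- read.table(path, sep = "\t", header = FALSE,
                     stringsAsFactors = FALSE)
    if (ncol(df) < family_col)
      stop("BED file has no column ", family_col, " for the family label")
    entries <- data.frame(te_id = as.character(df[[4]]),
                          chrom = as.character(df[[1]]),
                          start = df[[2]], end = df[[3]],
                          superfamily = as.character(df[[family_col]]),
                          strand = as.character(df[[6]]))
  }
  TEAnnotation(entries)
}

#' Write a TE annotation as GFF3
#'
#' @param tes A `TEAnnotation`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_te_gff3 <- function(tes, path) {
  lines <- sprintf(
    "%s\trerepseq\ttransposable_element\t%d\t%d\t.\t%s\t.\tID=%s;family=%s",
    tes$chrom, as.integer(tes$start + 1), as.integer(tes$end),
    tes$strand, tes$te_id, tes$superfamily)
  writeLines(c("##gff-version 3", lines), path)
  invisible(path)
}

#' Read aligned read placements
#'
#' Reduces each uniquely-aligned read to its 5'-most aligned base.
#' For BED input the 5' end is `start` on the `+` strand and `end - 1`
#' on the `-` strand. For SAM input, unmapped records (flag bit 0x4) are
#' skipped and the 5' end of a minus-strand read is the rightmost
#' reference base of its CIGAR alignment.
#'
#' @param path Path to a BED6 or SAM file.
#' @param format `"bed"` or `"sam"`.
#' @param sample_id Sample name (defaults to the file name).
#' @param chroms Optional character vector of known chromosome names;
#'   placements on other chromosomes are skipped with a warning and
#'   counted in the `n_skipped_chrom` attribute.
#' @return A [ReadPlacements()] (not deduplicated; see
#'   [dedup_placements()]). Attribute `n_unmapped` counts skipped SAM
#'   records.
#' @export
read_placements <- function(path, format = c("bed", "sam"),
                            sample_id = basename(path), chroms = NULL) {
  format <- match.arg(format)
  n_unmapped <- 0L
  if (format == "bed") {
    df <- read.table(path, sep = "\t", header = FALSE,
                     stringsAsFactors = FALSE)
    if (ncol(df) < 6L) stop("BED placements need 6 columns (strand in col 6)")
    strand <- as.character(df[[6]])
    if (!all(strand %in% c("+", "-")))
      stop("BED strand column must be '+' or '-'")
    pos5 <- ifelse(strand == "+", df[[2]], df[[3]] - 1)
    pl <- data.frame(chrom = as.character(df[[1]]), pos5 = pos5,
                     strand = strand)
  } else {
    lines <- readLines(path)
    lines <- lines[!grepl("^@", lines) & nzchar(lines)]
    if (length(lines) == 0L) {
      pl <- data.frame(chrom = character(), pos5 = numeric(),
                       strand = character())
    } else {
      fields <- strsplit(lines, "\t", fixed = TRUE)
      flag <- vapply(fields, function(f) as.integer(f[2]), integer(1))
      unmapped <- bitwAnd(flag, 4L) != 0L
      n_unmapped <- sum(unmapped)
      fields <- fields[!unmapped]
      if (length(fields) == 0L) {
        pl <- data.frame(chrom = character(), pos5 = numeric(),
                         strand = character())
      } else {
        flag <- flag[!unmapped]
        chrom <- vapply(fields, `[`, character(1), 3L)
        pos1 <- vapply(fields, function(f) as.numeric(f[4]), numeric(1))
        cigar <- vapply(fields, `[`, character(1), 6L)
        refw <- GenomicAlignments::cigarWidthAlongReferenceSpace(cigar)
        minus <- bitwAnd(flag, 16L) != 0L
        pos5 <- ifelse(minus, pos1 - 1 + refw - 1, pos1 - 1)
        pl <- data.frame(chrom = chrom, pos5 = pos5,
                         strand = ifelse(minus, "-", "+"))
      }
    }
  }
  n_skipped_chrom <- 0L
  if (!is.null(chroms) && nrow(pl) > 0L) {
    bad <- !(pl$chrom %in% chroms)
    n_skipped_chrom <- sum(bad)
    if (n_skipped_chrom > 0L) {
      warning(n_skipped_chrom, " placements on unknown chromosomes skipped: ",
              paste(unique(pl$chrom[bad]), collapse = ", "))
      pl <- pl[!bad, , drop = FALSE]
    }
  }
  out <- ReadPlacements(sample_id, pl)
  attr(out, "n_unmapped") <- n_unmapped
  attr(out, "n_skipped_chrom") <- n_skipped_chrom
  out
}

#' Write read placements as BED6
#'
#' Each placement is written as a 1-bp interval anchored at its 5' end,
#' so a read round-trips through [read_placements()] unchanged.
#'
#' @param reads A `ReadPlacements`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_placements_bed <- function(reads, path) {
  p <- reads$placements
  df <- data.frame(chrom = p$chrom,
                   start = format(p$pos5, scientific = FALSE, trim = TRUE),
                   end = format(p$pos5 + 1, scientific = FALSE, trim = TRUE),
                   name = paste0("r", seq_len(nrow(p))), score = 0L,
                   strand = p$strand)
  write.table(df, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Collapse reads mapping to identical positions
#'
#' Reads sharing (chrom, 5' position, strand) are collapsed into a
#' single read, the standard removal of presumed PCR duplicates for
#' single-end data. The library size in millions is recomputed from the
#' collapsed count.
#'
#' @param reads A `ReadPlacements`.
#' @param ignore_strand If `TRUE`, strand is excluded from the identity,
#'   so reads at the same position on opposite strands also collapse.
#' @return A deduplicated `ReadPlacements`.
#' @export
dedup_placements <- function(reads, ignore_strand = FALSE) {
  p <- reads$placements
  key <- if (ignore_strand) p[c("chrom", "pos5")] else p
  keep <- !duplicated(key)
  ReadPlacements(reads$sample_id, p[keep, , drop = FALSE])
}

#' Read a CX-report-style methylation table
#'
#' Expects a 6-column TSV: chrom, position (1-based), strand, context
#' (CG/CHG/CHH), count of methylated reads (#C), count of unmethylated
#' reads (#T). Positions are converted to 0-based.
#'
#' @param path Path to the TSV file.
#' @return A [MethylationCalls()].
#' @export
read_cx_report <- function(path) {
  first <- readLines(path, n = 1L)
  if (length(first) == 0L) return(MethylationCalls(data.frame()))
  df <- read.table(path, sep = "\t", header = FALSE,
                   stringsAsFactors = FALSE)
  if (ncol(df) < 6L) stop("CX report needs 6 columns")
  MethylationCalls(data.frame(
    chrom = as.character(df[[1]]), pos = df[[2]] - 1,
    strand = as.character(df[[3]]), context = as.character(df[[4]]),
    count_C = df[[5]], count_T = df[[6]]))
}

#' Write methylation calls as a CX-report-style table
#'
#' @param calls A `MethylationCalls`.
#' @param path Output path (positions written 1-based).
#' @return `path`, invisibly.
#' @export
write_cx_report <- function(calls, path) {
  df <- data.frame(calls$chrom, calls$pos + 1, calls$strand,
                   calls$context, calls$count_C, calls$count_T)
  write.table(df, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Write a BinnedSignal as bedGraph
#'
#' @param signal A `BinnedSignal`.
#' @param path Output path.
#' @param na_skip Drop bins with missing values (default) rather than
#'   writing them.
#' @return `path`, invisibly.
#' @export
write_bedgraph <- function(signal, path, na_skip = TRUE) {
  w <- signal$bin_width
  rows <- lapply(names(signal$values), function(chrom) {
    v <- signal$values[[chrom]]
    i <- seq_along(v)
    df <- data.frame(chrom = chrom, start = (i - 1) * w, end = i * w,
                     value = v)
    if (na_skip) df <- df[!is.na(df$value), , drop = FALSE]
    df
  })
  df <- do.call(rbind, rows)
  df$start <- format(df$start, scientific = FALSE, trim = TRUE)
  df$end <- format(df$end, scientific = FALSE, trim = TRUE)
  write.table(df, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}
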