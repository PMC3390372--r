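# Small in-code fixtures shared across test files.

make_placements <- function(chrom, pos5, strand, sample_id = "test") {
  ReadPlacements(sample_id,
                 data.frame(chrom = chrom, pos5 = pos5, strand = strand))
}

make_signal <- function(values_list, bin_width, semantics = "count") {
  BinnedSignal(values_list, bin_width, semantics)
}

# WindowZ built directly, for caller unit tests
make_wz <- function(chrom, start, end, value, z,
                    window_bp = 1000L, step_bp = 500L) {
  df <- data.frame(chrom = chrom, start = start, end = end,
                   value = value, z = z)
  attr(df, "window_bp") <- window_bp
  attr(df, "step_bp") <- step_bp
  class(df) <- c("WindowZ", "data.frame")
  df
}

write_tmp <- function(lines) {
  path <- tempfile(fileext = ".txt")
  writeLines(lines, path)
  path
}

# brute-force interval helpers (oracles)
bf_overlap_bp <- function(s1, e1, s2, e2) pmax(0, pmin(e1, e2) - pmax(s1, s2))

bf_merge <- function(df, gap) {
  out <- list()
  for (chrom in unique(df$chrom)) {
    sub <- df[df$chrom == chrom, ]
    sub <- sub[order(sub$start), ]
    cur_s <- sub$start[1]; cur_e <- sub$end[1]
    for (i in seq_len(nrow(sub))[-1]) {
      if (sub$start[i] - cur_e <= gap) {
        cur_e <- max(cur_e, sub$end[i])
      } else {
        out[[length(out) + 1]] <- data.frame(chrom = chrom, start = cur_s,
                                             end = cur_e)
        cur_s <- sub$start[i]; cur_e <- sub$end[i]
      }
    }
    out[[length(out) + 1]] <- data.frame(chrom = chrom, start = cur_s,
                                         end = cur_e)
  }
  df <- do.call(rbind, out)
  df[order(df$chrom, df$start), ]
}

# exact two-sided Fisher p by hypergeometric enumeration
bf_fisher_p <- function(a, b, c, d) {
  m <- a + c; n <- b + d; k <- a + b
  support <- max(0, k - n):min(k, m)
  probs <- dhyper(support, m, n, k)
  p_obs <- dhyper(a, m, n, k)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# reference BH step-up, written from the definition
bf_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  q <- p[o] * m / seq_len(m)
  q <- rev(cummin(rev(q)))
  q <- pmin(q, 1)
  out <- numeric(m)
  out[o] <- q
  out
}
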