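test_that("pseudocount is library size in millions over ten", {
  expect_equal(pseudocount(68), 6.8)
  expect_equal(pseudocount(53), 5.3)
  expect_equal(pseudocount(10), 1.0)
  expect_error(pseudocount(0), "positive")
  expect_error(pseudocount(-3), "positive")
})

test_that("score track evaluates (n + c)/0.1kb/M and is strictly positive", {
  counts <- make_signal(list(chr1 = c(10L, 0L, 3L)), 100)
  st <- score_track(counts, M = 68, c = 6.8)
  expect_equal(st$values$chr1[1], 16.8 / 0.1 / 68)
  expect_equal(score_track(make_signal(list(chr1 = 0L), 100),
                           M = 10, c = 1)$values$chr1, 1.0)
  zeros <- make_signal(list(chr1 = rep(0L, 5)), 100)
  st0 <- score_track(zeros, M = 20)
  expect_true(all(st0$values$chr1 > 0))
  expect_equal(st0$pseudocount, 2)
})

test_that("log2 ratio is elementwise and rejects incompatible tracks", {
  wt <- score_track(make_signal(list(chr1 = c(5L, 10L, 0L)), 100), M = 10)
  expect_equal(log2_ratio(wt, wt)$values$chr1, rep(0, 3))
  mut <- wt
  mut$values$chr1 <- 2 * wt$values$chr1
  expect_equal(log2_ratio(mut, wt)$values$chr1, rep(1, 3))
  # elementwise oracle on arbitrary positive tracks
  a <- make_signal(list(chr1 = c(2.4706, 1.5)), 100, "score")
  b <- make_signal(list(chr1 = c(0.9, 3.2)), 100, "score")
  expect_equal(log2_ratio(a, b)$values$chr1,
               log2(c(2.4706 / 0.9, 1.5 / 3.2)))
  wrong <- make_signal(list(chr1 = c(1, 2)), 200, "score")
  expect_error(log2_ratio(a, wrong), "bin width")
})

test_that("window Z-scores average fine bins and standardize genome-wide", {
  set.seed(31)
  vals <- list(chr1 = rnorm(60), chr2 = rnorm(35))
  ratio <- make_signal(vals, 100, "log2_ratio")
  wz <- window_z(ratio, window_bp = 1000, step_bp = 500)
  # independent oracle: explicit loops over full 10-bin windows
  oracle <- list()
  for (chrom in names(vals)) {
    v <- vals[[chrom]]
    for (s in seq(0, length(v) - 10, by = 5))
      oracle[[length(oracle) + 1]] <-
        data.frame(chrom = chrom, start = s * 100, value = mean(v[(s + 1):(s + 10)]))
  }
  oracle <- do.call(rbind, oracle)
  expect_equal(nrow(wz), nrow(oracle))
  expect_equal(wz$value, oracle$value, tolerance = 1e-12)
  expect_equal(wz$z, (oracle$value - mean(oracle$value)) / sd(oracle$value),
               tolerance = 1e-12)
  expect_equal(mean(wz$z), 0, tolerance = 1e-12)
  expect_equal(sd(wz$z), 1, tolerance = 1e-12)
  # elevated window has the max z
  vals$chr1[11:20] <- vals$chr1[11:20] + 50
  wz2 <- window_z(make_signal(vals, 100, "log2_ratio"), 1000, 500)
  expect_equal(wz2$start[which.max(wz2$z)], 1000)
})

test_that("constant ratio tracks give z = 0 everywhere and tiny inputs error", {
  flat <- make_signal(list(chr1 = rep(0.3, 40)), 100, "log2_ratio")
  expect_true(all(window_z(flat)$z == 0))
  expect_error(window_z(make_signal(list(chr1 = rep(1, 10)), 100)), "windows")
})

test_that("region calling merges passing windows across gaps of at most 500 bp", {
  wz <- make_wz(chrom = c("chr1", "chr1"), start = c(1000, 2400),
                end = c(2000, 3000), value = c(1, 1.2), z = c(3, 2.5))
  merged <- call_regions(wz)
  expect_equal(as.data.frame(merged)[c("chrom", "start", "end")],
               data.frame(chrom = "chr1", start = 1000, end = 3000))
  expect_equal(merged$max_z, 3)
  expect_equal(merged$mean_log2, 1.1)

  far <- make_wz(chrom = c("chr1", "chr1"), start = c(0, 2000),
                 end = c(1000, 3000), value = c(1, 1), z = c(3, 3))
  expect_equal(nrow(call_regions(far)), 2L)

  none <- make_wz("chr1", 0, 1000, 0.1, 0.5)
  expect_equal(nrow(call_regions(none)), 0L)
})

test_that("region calling is order-invariant and merging is idempotent", {
  set.seed(32)
  wz <- make_wz(chrom = sample(c("chr1", "chr2"), 40, TRUE),
                start = s <- sample(seq(0, 50000, 500), 40),
                end = s + 1000,
                value = runif(40), z = runif(40, 0, 4))
  a <- call_regions(wz)
  shuffled <- wz[sample(nrow(wz)), ]
  attr(shuffled, "window_bp") <- 1000; attr(shuffled, "step_bp") <- 500
  class(shuffled) <- c("WindowZ", "data.frame")
  b <- call_regions(shuffled)
  expect_equal(as.data.frame(a), as.data.frame(b))
  remerged <- merge_regions(a, 500)
  expect_equal(as.data.frame(remerged)[c("chrom", "start", "end")],
               as.data.frame(a)[c("chrom", "start", "end")])
})

test_that("interval merging matches a brute-force scan on random intervals", {
  set.seed(33)
  n <- 1000
  s <- sample(0:100000, n, TRUE)
  df <- data.frame(chrom = sample(c("chr1", "chr2", "chr3"), n, TRUE),
                   start = s, end = s + sample(50:2000, n, TRUE))
  merged <- merge_regions(RegionSet(df), merge_gap_bp = 500)
  oracle <- bf_merge(df, gap = 500)
  rownames(oracle) <- NULL
  expect_equal(as.data.frame(merged)[c("chrom", "start", "end")], oracle)
})

test_that("TE annotation uses the 1-bp overlap rule on half-open intervals", {
  tes <- TEAnnotation(data.frame(te_id = c("TE1", "TE2"), chrom = "chr1",
                                 start = c(100, 100), end = c(200, 200),
                                 superfamily = "LTR/Gypsy"))
  touch <- RegionSet(data.frame(chrom = "chr1", start = 200, end = 300))
  one_bp <- RegionSet(data.frame(chrom = "chr1", start = 199, end = 300))
  expect_equal(annotate_rerep_tes(one_bp, tes), c("TE1", "TE2"))
  expect_equal(annotate_rerep_tes(touch, tes), character())
  empty <- RegionSet(data.frame(chrom = character(), start = numeric(),
                                end = numeric()))
  expect_equal(annotate_rerep_tes(empty, tes), character())
})

test_that("TE overlap calls match a brute-force all-pairs scan", {
  set.seed(34)
  n_te <- 500; n_reg <- 60
  ts <- sample(0:200000, n_te, TRUE)
  tes <- TEAnnotation(data.frame(
    te_id = sprintf("TE%04d", 1:n_te),
    chrom = sample(c("chr1", "chr2"), n_te, TRUE),
    start = ts, end = ts + sample(100:5000, n_te, TRUE),
    superfamily = "LTR/Gypsy"))
  rs <- sample(0:200000, n_reg, TRUE)
  regions <- RegionSet(data.frame(
    chrom = sample(c("chr1", "chr2"), n_reg, TRUE),
    start = rs, end = rs + sample(500:20000, n_reg, TRUE)))
  got <- annotate_rerep_tes(regions, tes)
  oracle <- character()
  for (i in seq_len(n_te)) {
    for (j in seq_len(nrow(regions))) {
      if (tes$chrom[i] == regions$chrom[j] &&
          bf_overlap_bp(tes$start[i], tes$end[i],
                        regions$start[j], regions$end[j]) >= 1) {
        oracle <- c(oracle, tes$te_id[i]); break
      }
    }
  }
  expect_equal(got, sort(unique(oracle)))
})

test_that("heterochromatin read fraction counts 5' positions inside regions", {
  rp <- make_placements(rep("chr1", 200), seq(0, 1990, by = 10), "+")
  het <- RegionSet(data.frame(chrom = "chr1", start = 0, end = 500))
  expect_equal(het_fraction(rp, het), 0.25)
  whole <- RegionSet(data.frame(chrom = "chr1", start = 0, end = 2000))
  expect_equal(het_fraction(rp, whole), 1.0)
  empty <- make_placements(character(), numeric(), character())
  expect_error(het_fraction(empty, het), "no reads")
})

test_that("het-fraction comparison is symmetric and matches the chi-square formula", {
  mk <- function(n_in, n_out, id) {
    make_placements(rep("chr1", n_in + n_out),
                    c(seq_len(n_in) - 1, 1000 + seq_len(n_out) - 1),
                    "+", sample_id = id)
  }
  het <- RegionSet(data.frame(chrom = "chr1", start = 0, end = 1000))
  a <- mk(900, 100, "a"); b <- mk(500, 500, "b")
  res <- compare_het_fractions(a, b, het)
  # hand-evaluated chi-square with Yates continuity correction
  tab <- rbind(c(900, 100), c(500, 500))
  expected <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  stat <- sum((abs(tab - expected) - 0.5)^2 / expected)
  expect_equal(res$p.value, pchisq(stat, df = 1, lower.tail = FALSE),
               tolerance = 1e-12)
  expect_equal(res$method, "chisq_continuity")
  expect_equal(compare_het_fractions(b, a, het)$p.value, res$p.value)

  same <- compare_het_fractions(a, mk(900, 100, "c"), het)
  expect_equal(same$p.value, 1)

  small <- compare_het_fractions(mk(2, 60, "d"), mk(9, 50, "e"), het)
  expect_equal(small$method, "fisher")
})

test_that("per-TE DNA density is reads per kb per million, linear in counts", {
  tes <- TEAnnotation(data.frame(te_id = c("TE1", "TE2"), chrom = "chr1",
                                 start = c(0, 5000), end = c(1000, 7000),
                                 superfamily = "LTR/Gypsy"))
  rp <- ReadPlacements("x", data.frame(chrom = "chr1",
                                       pos5 = c(seq(0, 900, 100), 5000),
                                       strand = "+"))
  rp$library_size_millions <- 1   # pretend a 1M-read library
  dens <- te_dna_density(rp, tes)
  expect_equal(unname(dens["TE1"]), 10.0)
  expect_equal(unname(dens["TE2"]), 0.5)
  expect_error(te_dna_density(rp, tes, "TEX"), "unknown")
})

test_that("rank-sum comparison matches the exact null enumeration and is symmetric", {
  # exact reference: wilcox.test's exact path (no ties, small n)
  expect_equal(ranksum_compare(c(1, 2, 3), c(4, 5, 6)),
               wilcox.test(c(1, 2, 3), c(4, 5, 6), exact = TRUE)$p.value)
  expect_equal(ranksum_compare(c(1, 2, 3), c(4, 5, 6)), 0.1)
  set.seed(35)
  for (rep in 1:5) {
    a <- rnorm(4); b <- rnorm(5)
    expect_equal(ranksum_compare(a, b),
                 wilcox.test(a, b, exact = TRUE)$p.value)
    expect_equal(ranksum_compare(a, b), ranksum_compare(b, a))
  }
  expect_equal(ranksum_compare(c(1, 2, 3), c(1, 2, 3)), 1)
  expect_equal(ranksum_compare(rep(2, 4), rep(2, 6)), 1)
  expect_error(ranksum_compare(numeric(0), 1), "non-empty")
})

test_that("chromosome view is near zero for identical samples and elevated in planted patches", {
  cfg <- sim_config(seed = 5, n_chroms = 1, chrom_length = 2e6,
                    n_patches_per_chrom = 1, mean_cov = 10,
                    patch_size_range = c(300e3, 400e3))
  g <- simulate_genome(cfg)
  wt <- dedup_placements(simulate_dna_reads(g, "wt"))
  mut <- dedup_placements(simulate_dna_reads(g, "mutant"))
  view <- chromosome_view(mut, wt, g$chrom_sizes, bin_bp = 1e5,
                          smooth_iters = 10)
  patch <- g$het_patches
  in_bins <- (floor(patch$start / 1e5) + 1):ceiling(patch$end / 1e5)
  # ten smoothing passes flatten a 3-4 bin patch; the elevation must
  # still peak inside it
  expect_true(max(view$values$chr1[in_bins]) > 0.3)
  expect_true(which.max(view$values$chr1) %in% in_bins)

  same <- chromosome_view(wt, wt, g$chrom_sizes, bin_bp = 1e5)
  expect_true(all(abs(same$values$chr1) < 1e-12))

  raw <- chromosome_view(mut, wt, g$chrom_sizes, bin_bp = 1e5,
                         smooth_iters = 0, mode = "density")
  expect_equal(sum(raw$wt$values$chr1) * 1e5 * wt$library_size_millions,
               nrow(wt$placements), tolerance = 1e-6)
})
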