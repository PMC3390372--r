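test_that("genome simulation is deterministic and respects patch configuration", {
  cfg <- sim_config(seed = 1, n_chroms = 2, chrom_length = 5e5)
  g1 <- simulate_genome(cfg)
  g2 <- simulate_genome(cfg)
  expect_identical(g1$het_patches, g2$het_patches)
  expect_identical(g1$te_annotation, g2$te_annotation)
  expect_identical(g1$truth, g2$truth)

  none <- simulate_genome(sim_config(seed = 2, n_chroms = 1,
                                     chrom_length = 5e5,
                                     n_patches_per_chrom = 0))
  expect_equal(nrow(none$het_patches), 0L)

  # patches inside chromosome bounds, planted TEs inside the annotation
  expect_true(all(g1$het_patches$end <= 5e5))
  expect_true(all(g1$truth$planted_te_ids %in% g1$te_annotation$te_id))
  expect_true(all(g1$truth$planted_te_ids %in% g1$truth$expressed_te_ids))
})

test_that("TE density is higher inside heterochromatin patches", {
  g <- simulate_genome(sim_config(seed = 3))
  tes <- g$te_annotation
  te_bp_in <- 0; te_bp_total <- sum(tes$end - tes$start)
  for (i in seq_len(nrow(g$het_patches))) {
    p <- g$het_patches[i, ]
    sel <- tes$chrom == p$chrom
    te_bp_in <- te_bp_in + sum(pmax(0, pmin(tes$end[sel], p$end) -
                                      pmax(tes$start[sel], p$start)))
  }
  het_bp <- sum(g$het_patches$end - g$het_patches$start)
  genome_bp <- sum(g$chrom_sizes)
  frac_in <- te_bp_in / het_bp
  frac_out <- (te_bp_total - te_bp_in) / (genome_bp - het_bp)
  expect_gt(frac_in, frac_out)
})

test_that("DNA read simulation is seed-deterministic with Poisson bin counts", {
  g <- simulate_genome(sim_config(seed = 4, n_chroms = 1,
                                  chrom_length = 2e5,
                                  n_patches_per_chrom = 0))
  r1 <- simulate_dna_reads(g, "wt", seed = 10)
  r2 <- simulate_dna_reads(g, "wt", seed = 10)
  expect_identical(r1$placements, r2$placements)

  counts <- bin_counts(r1, g$chrom_sizes, 100)$values$chr1
  expect_equal(mean(counts), 50, tolerance = 0.05)
  expect_equal(var(counts), 50, tolerance = 0.15)
})

test_that("kappa = 1 gives mutant and wild-type bin counts identical in law", {
  g <- simulate_genome(sim_config(seed = 5, n_chroms = 1,
                                  chrom_length = 5e5))
  pass <- 0
  for (s in 1:10) {
    wt <- simulate_dna_reads(g, "wt", seed = 100 + s)
    mut <- simulate_dna_reads(g, "mutant", kappa = 1, seed = 200 + s)
    cw <- bin_counts(wt, g$chrom_sizes, 100)$values$chr1
    cm <- bin_counts(mut, g$chrom_sizes, 100)$values$chr1
    p <- suppressWarnings(ks.test(cw, cm)$p.value)
    if (p > 0.01) pass <- pass + 1
  }
  expect_gte(pass, 8)
})

test_that("kappa = 2 doubles in-patch coverage: mean log2 ratio near 1", {
  # patch small relative to the genome so library sizes stay comparable;
  # ratios taken on the raw simulated placements (the generator's
  # Poisson-mean property, before any duplicate saturation)
  g <- simulate_genome(sim_config(seed = 6, n_chroms = 1, chrom_length = 5e6,
                                  n_patches_per_chrom = 1,
                                  patch_size_range = c(1e5, 1e5)))
  wt <- simulate_dna_reads(g, "wt")
  mut <- simulate_dna_reads(g, "mutant")
  sm <- score_track(bin_counts(mut, g$chrom_sizes, 100),
                    mut$library_size_millions)
  sw <- score_track(bin_counts(wt, g$chrom_sizes, 100),
                    wt$library_size_millions)
  ratio <- log2_ratio(sm, sw)$values$chr1
  p <- g$het_patches
  bins <- (p$start / 100 + 1):(p$end / 100)   # 1,000 in-patch bins
  expect_equal(mean(ratio[bins]), 1.0, tolerance = 0.1)
  expect_equal(mean(ratio[-bins]), 0.0, tolerance = 0.1)
})

test_that("RNA-seq simulation plants the configured fold change and exercises zeros", {
  g <- simulate_genome(sim_config(seed = 7, n_chroms = 2, chrom_length = 2e6,
                                  te_length_range = c(300, 3000)))
  c1 <- simulate_rnaseq_counts(g, seed = 11)
  c2 <- simulate_rnaseq_counts(g, seed = 11)
  expect_identical(c1$counts, c2$counts)
  expect_gt(sum(c1$counts[, "wt_1"] == 0), 100)   # zero-replacement territory

  # near-Poisson regime: mean count ratio of non-planted expressed TEs ~ 1,
  # planted TEs ~ planted fold change
  c3 <- simulate_rnaseq_counts(g, dispersion = 0, seed = 12)
  expressed <- setdiff(g$truth$expressed_te_ids, g$truth$planted_te_ids)
  ratio_null <- sum(c3$counts[expressed, "mut_1"]) /
    sum(c3$counts[expressed, "wt_1"])
  expect_equal(ratio_null, 1, tolerance = 0.05)
  planted <- g$truth$planted_te_ids
  ratio_planted <- sum(c3$counts[planted, "mut_1"]) /
    sum(c3$counts[planted, "wt_1"])
  expect_equal(ratio_planted, g$truth$planted_fc, tolerance = 0.1 * 8)
})

test_that("methylome simulation hits configured means and respects compartments", {
  g <- simulate_genome(sim_config(seed = 8, n_chroms = 1, chrom_length = 1e6))
  meth <- simulate_methylome(g, seed = 13)
  expect_identical(simulate_methylome(g, seed = 13), meth)

  lev_het <- methylation_levels_by_context(meth, g$het_patches)
  expect_equal(unname(lev_het["CG"]), 0.8, tolerance = 0.03)
  expect_equal(unname(lev_het["CHG"]), 0.4, tolerance = 0.05)
  expect_true(lev_het["CG"] > lev_het["CHG"])
  expect_true(lev_het["CHG"] > lev_het["CHH"])

  zero <- simulate_methylome(g, means = list(
    het = c(CG = 0, CHG = 0, CHH = 0), eu = c(CG = 0, CHG = 0, CHH = 0)),
    seed = 14)
  expect_true(all(zero$count_C == 0))
})

test_that("FACS simulation is deterministic, labelled, and validates inputs", {
  x1 <- simulate_facs(seed = 9)
  x2 <- simulate_facs(seed = 9)
  expect_identical(x1, x2)
  expect_equal(length(attr(x1, "component")), length(x1))

  single <- simulate_facs(peaks = 800, cvs = 5, n_events = 10000, props = 1,
                          seed = 10)
  expect_equal(100 * sd(single) / mean(single), 5, tolerance = 0.5)

  expect_equal(length(simulate_facs(n_events = 0)), 0L)
  expect_error(simulate_facs(peaks = 100, cvs = 0, props = 1), "positive")
})

test_that("write_simulation emits files the readers round-trip", {
  g <- simulate_genome(sim_config(seed = 15, n_chroms = 1,
                                  chrom_length = 2e5,
                                  n_patches_per_chrom = 1,
                                  patch_size_range = c(20e3, 40e3),
                                  te_length_range = c(300, 2000)))
  wt <- dedup_placements(simulate_dna_reads(g, "wt", mean_cov = 2))
  meth <- simulate_methylome(g, site_density = 0.001)
  outdir <- tempfile()
  write_simulation(g, outdir, dna = list(wt), methylome = meth)
  het_back <- read_regions_bed(file.path(outdir, "het_patches.bed"))
  expect_equal(as.data.frame(het_back)[c("chrom", "start", "end")],
               as.data.frame(g$het_patches)[c("chrom", "start", "end")])
  tes_back <- read_te_annotation(file.path(outdir, "tes.gff3"))
  expect_equal(as.data.frame(tes_back), as.data.frame(g$te_annotation))
  reads_back <- read_placements(file.path(outdir, "sim_wt.bed"))
  expect_equal(reads_back$placements[c("chrom", "pos5", "strand")],
               wt$placements[c("chrom", "pos5", "strand")])
  meth_back <- read_cx_report(file.path(outdir, "methylome.cx.tsv"))
  expect_equal(as.data.frame(meth_back), as.data.frame(meth))
})
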