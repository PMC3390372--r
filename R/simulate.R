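#' Configuration for the synthetic-data generator
#'
#' Bundles and validates every parameter of the simulated study: a
#' multi-chromosome genome with pericentromeric heterochromatin
#' patches, TE-dense inside the patches; a mutant with a uniform
#' copy-number gain confined to the patches; RNA-seq counts with a
#' planted set of upregulated TEs; context-specific methylomes elevated
#' in heterochromatin; and mixture-of-ploidy-peak flow-cytometry
#' intensities. Defaults are the conditions the package's validation
#' suite runs under (see the methods vignette for the rationale of each
#' choice).
#'
#' @param seed Base RNG seed; stage generators derive their own streams
#'   from it by fixed offsets.
#' @param n_chroms,chrom_length Number and length (bp) of chromosomes.
#' @param n_patches_per_chrom Heterochromatin patches per chromosome,
#'   placed in the central (pericentromeric) 40% and snapped to 100 bp.
#' @param patch_size_range Patch size range in bp.
#' @param te_density_het,te_density_eu Fraction of bp covered by TEs
#'   inside/outside the patches.
#' @param te_length_range TE length range in bp.
#' @param family_props Named proportions of TE superfamilies (sum 1).
#' @param mean_cov Wild-type mean reads per 100-bp bin.
#' @param kappa Mutant copy factor in heterochromatin (>= 1).
#' @param n_replicates RNA-seq biological replicates per genotype.
#' @param lib_size RNA-seq library size (total mapped reads).
#' @param n_planted Number of TEs planted as upregulated in the mutant.
#' @param planted_fc Planted fold change of those TEs.
#' @param dispersion Negative-binomial dispersion of the counts
#'   (0 gives Poisson).
#' @param baseline_meanlog,baseline_sdlog Lognormal parameters of the
#'   baseline RPKM of expressed TEs.
#' @param silenced_rpkm Baseline RPKM of silenced TEs (low, so many
#'   zero counts arise).
#' @param frac_expressed Fraction of TEs transcriptionally active at
#'   baseline; planted TEs are drawn from this subset.
#' @param meth_means List with numeric vectors `het` and `eu`, each
#'   named CG/CHG/CHH, of per-context methylation means.
#' @param meth_depth Reads per cytosine site.
#' @param meth_site_density Cytosine sites per bp (all contexts
#'   combined, split evenly).
#' @param facs_peaks,facs_cvs,facs_props,facs_events Ploidy-peak means
#'   (2C/4C/8C/16C), per-peak CVs (percent), mixture proportions, and
#'   number of events.
#' @return A validated `SimConfig` list.
#' @export
sim_config <- function(seed = 1L,
                       n_chroms = 5L, chrom_length = 1e6,
                       n_patches_per_chrom = 2L,
                       patch_size_range = c(20e3, 100e3),
                       te_density_het = 0.6, te_density_eu = 0.1,
                       te_length_range = c(500, 8000),
                       family_props = c("LTR/Gypsy" = 0.45,
                                        "LTR/Copia" = 0.20,
                                        "LINE/L1" = 0.15,
                                        "DNA/MuDR" = 0.10,
                                        "RC/Helitron" = 0.10),
                       mean_cov = 50, kappa = 2,
                       n_replicates = 2L, lib_size = 5e6,
                       n_planted = 50L, planted_fc = 8,
                       dispersion = 0.01,
                       baseline_meanlog = log(10), baseline_sdlog = 0.8,
                       silenced_rpkm = 0.02, frac_expressed = 0.3,
                       meth_means = list(
                         het = c(CG = 0.8, CHG = 0.4, CHH = 0.1),
                         eu = c(CG = 0.1, CHG = 0.03, CHH = 0.01)),
                       meth_depth = 20L, meth_site_density = 0.03,
                       facs_peaks = c(100, 200, 400, 800),
                       facs_cvs = c(4, 4, 5, 5),
                       facs_props = c(0.4, 0.3, 0.2, 0.1),
                       facs_events = 10000L) {
  stopifnot(n_chroms >= 1L, chrom_length > 0, n_patches_per_chrom >= 0L,
            patch_size_range[1] > 0,
            patch_size_range[2] >= patch_size_range[1],
            te_density_het > 0, te_density_het < 1,
            te_density_eu > 0, te_density_eu < 1,
            mean_cov > 0, kappa >= 1,
            n_replicates >= 1L, lib_size > 0, n_planted >= 0L,
            planted_fc > 0, dispersion >= 0,
            silenced_rpkm > 0, frac_expressed > 0, frac_expressed <= 1,
            meth_depth >= 1L, meth_site_density > 0,
            length(facs_peaks) == length(facs_cvs),
            length(facs_peaks) == length(facs_props),
            all(facs_cvs > 0), all(facs_peaks > 0), facs_events >= 0L)
  if (abs(sum(family_props) - 1) > 1e-8)
    stop("family_props must sum to 1")
  if (abs(sum(facs_props) - 1) > 1e-8)
    stop("facs_props must sum to 1")
  for (comp in c("het", "eu"))
    if (any(meth_means[[comp]] < 0) || any(meth_means[[comp]] > 1))
      stop("methylation means must lie in [0, 1]")
  cfg <- as.list(environment())
  class(cfg) <- "SimConfig"
  cfg
}

## place n non-overlapping patches in [lo, hi), sizes snapped to `snap`
.place_patches <- function(n, lo, hi, size_range, snap = 100, min_gap = 10000) {
  if (n == 0L) return(data.frame(start = numeric(), end = numeric()))
  for (attempt in 1:200) {
    sizes <- round(runif(n, size_range[1], size_range[2]) / snap) * snap
    if (sum(sizes) + (n - 1) * min_gap > hi - lo) {
      if (attempt == 200) stop("patches cannot fit the chromosome")
      next
    }
    starts <- sort(round(runif(n, lo, hi - max(sizes)) / snap) * snap)
    ok <- all(diff(starts) >= sizes[-n] + min_gap) &&
      starts[n] + sizes[n] <= hi
    if (ok) return(data.frame(start = starts, end = starts + sizes))
  }
  stop("patches cannot fit the chromosome")
}

## tile TEs along [lo, hi) with target bp coverage `density`
.place_tes <- function(lo, hi, density, len_range) {
  mean_len <- mean(len_range)
  mean_gap <- mean_len * (1 - density) / density
  starts <- numeric(0); ends <- numeric(0)
  pos <- lo + rexp(1, 1 / mean_gap)
  while (pos < hi) {
    len <- round(runif(1, len_range[1], len_range[2]))
    if (pos + len > hi) break
    starts <- c(starts, round(pos)); ends <- c(ends, round(pos) + len)
    pos <- pos + len + rexp(1, 1 / mean_gap)
  }
  data.frame(start = starts, end = ends)
}

#' Simulate a genome model with planted ground truth
#'
#' Builds chromosomes, pericentromeric heterochromatin patches, a TE
#' annotation that is denser inside the patches, and a `truth` record
#' holding everything needed to score the downstream callers: the
#' copy factor, the planted-upregulated TE ids and fold change, the
#' expressed-TE subset, and the per-context methylation means.
#'
#' @param config A [sim_config()].
#' @return A `GenomeModel` list: `chrom_sizes`, `het_patches`
#'   ([RegionSet()]), `te_annotation` ([TEAnnotation()]), `truth`.
#' @export
simulate_genome <- function(config = sim_config()) {
  stopifnot(inherits(config, "SimConfig"))
  withr::with_seed(config$seed, {
    chroms <- paste0("chr", seq_len(config$n_chroms))
    chrom_sizes <- setNames(rep(config$chrom_length, config$n_chroms), chroms)
    patches <- list(); tes <- list()
    for (chrom in chroms) {
      L <- chrom_sizes[[chrom]]
      pp <- .place_patches(config$n_patches_per_chrom, 0.3 * L, 0.7 * L,
                           config$patch_size_range)
      if (nrow(pp) > 0L)
        patches[[chrom]] <- data.frame(chrom = chrom, pp)
      ## TE placement per compartment: euchromatic segments between
      ## patches at low density, patch interiors at high density
      bounds <- c(0, as.vector(t(as.matrix(pp))), L)
      seg_starts <- bounds[seq(1, length(bounds) - 1, by = 2)]
      seg_ends <- bounds[seq(2, length(bounds), by = 2)]
      for (k in seq_along(seg_starts)) {
        if (seg_ends[k] - seg_starts[k] < config$te_length_range[1]) next
        placed <- .place_tes(seg_starts[k], seg_ends[k], config$te_density_eu,
                             config$te_length_range)
        if (nrow(placed) > 0L)
          tes[[length(tes) + 1L]] <- data.frame(chrom = chrom, placed)
      }
      for (k in seq_len(nrow(pp))) {
        placed <- .place_tes(pp$start[k], pp$end[k], config$te_density_het,
                             config$te_length_range)
        if (nrow(placed) > 0L)
          tes[[length(tes) + 1L]] <- data.frame(chrom = chrom, placed)
      }
    }
    het <- if (length(patches))
      RegionSet(do.call(rbind, patches), label = "het_patches")
    else RegionSet(data.frame(chrom = character(), start = numeric(),
                              end = numeric()), label = "het_patches")
    te_df <- do.call(rbind, tes)
    te_df <- te_df[order(te_df$chrom, te_df$start), , drop = FALSE]
    n_te <- nrow(te_df)
    te_df$te_id <- sprintf("TE%05d", seq_len(n_te))
    te_df$superfamily <- sample(names(config$family_props), n_te,
                                replace = TRUE, prob = config$family_props)
    te_df$strand <- sample(c("+", "-"), n_te, replace = TRUE)
    annotation <- TEAnnotation(te_df)

    n_expr <- max(1L, round(config$frac_expressed * n_te))
    expressed <- sort(sample(annotation$te_id, n_expr))
    n_planted <- min(config$n_planted, n_expr)
    planted <- sort(sample(expressed, n_planted))

    structure(list(
      chrom_sizes = chrom_sizes,
      het_patches = het,
      te_annotation = annotation,
      truth = list(kappa = config$kappa,
                   planted_te_ids = planted,
                   planted_fc = config$planted_fc,
                   expressed_te_ids = expressed,
                   meth_means = config$meth_means),
      config = config), class = "GenomeModel")
  })
}

#' @export
print.GenomeModel <- function(x, ...) {
  cat(sprintf(paste0("GenomeModel: %d chromosomes (%s bp), %d het patches",
                     " (%.1f%% of genome), %d TEs\n"),
              length(x$chrom_sizes),
              format(sum(x$chrom_sizes), big.mark = ","),
              nrow(x$het_patches),
              100 * sum(x$het_patches$end - x$het_patches$start) /
                sum(x$chrom_sizes),
              nrow(x$te_annotation)))
  invisible(x)
}

#' Simulate genomic DNA read placements
#'
#' Per-100-bp-bin read counts are Poisson with mean `mean_cov` outside
#' heterochromatin and `kappa * mean_cov` inside (mutant sample only);
#' read positions are jittered uniformly within their bin and strands
#' drawn at random, so the output behaves like real placements under
#' deduplication.
#'
#' @param genome A [simulate_genome()] model.
#' @param sample `"wt"` or `"mutant"`.
#' @param mean_cov Mean reads per 100-bp bin (default from the genome's
#'   config).
#' @param kappa Copy factor in heterochromatin (default from config;
#'   forced to 1 for the wild type).
#' @param seed RNG seed (default derived from the genome's base seed).
#' @return A [ReadPlacements()] (not deduplicated).
#' @export
simulate_dna_reads <- function(genome, sample = c("wt", "mutant"),
                               mean_cov = genome$config$mean_cov,
                               kappa = genome$config$kappa, seed = NULL) {
  sample <- match.arg(sample)
  if (is.null(seed))
    seed <- genome$config$seed + if (sample == "wt") 101L else 102L
  stopifnot(kappa >= 1, mean_cov > 0)
  bin <- 100L
  withr::with_seed(seed, {
    out <- list()
    for (chrom in names(genome$chrom_sizes)) {
      n_bins <- floor(genome$chrom_sizes[[chrom]] / bin)
      lambda <- rep(mean_cov, n_bins)
      if (sample == "mutant" && kappa > 1) {
        pp <- genome$het_patches[genome$het_patches$chrom == chrom, ,
                                 drop = FALSE]
        for (k in seq_len(nrow(pp))) {
          b0 <- floor(pp$start[k] / bin) + 1L
          b1 <- min(ceiling(pp$end[k] / bin), n_bins)
          lambda[b0:b1] <- kappa * mean_cov
        }
      }
      counts <- rpois(n_bins, lambda)
      total <- sum(counts)
      if (total == 0L) next
      bin_start <- rep((seq_len(n_bins) - 1L) * bin, counts)
      out[[chrom]] <- data.frame(
        chrom = chrom,
        pos5 = bin_start + floor(runif(total, 0, bin)),
        strand = base::sample(c("+", "-"), total, replace = TRUE))
    }
    ReadPlacements(paste0("sim_", sample), do.call(rbind, out))
  })
}

#' Simulate RNA-seq count tables for wild type and mutant
#'
#' Baseline expression is lognormal RPKM for the expressed subset of
#' TEs and a low constant for silenced TEs (so many features have zero
#' counts). Planted TEs have their mutant mean multiplied by the
#' planted fold change; all counts are negative binomial with the
#' configured dispersion (Poisson when dispersion is 0).
#'
#' @param genome A [simulate_genome()] model.
#' @param n_replicates Replicates per genotype.
#' @param lib_sizes Library sizes, recycled over samples.
#' @param planted_fc Fold change of planted TEs in the mutant.
#' @param dispersion NB dispersion (`size = 1/dispersion`).
#' @param seed RNG seed.
#' @return A [CountTable()] with samples `wt_1..n, mut_1..n` and an
#'   attribute `baseline_rpkm`.
#' @export
simulate_rnaseq_counts <- function(genome,
                                   n_replicates = genome$config$n_replicates,
                                   lib_sizes = genome$config$lib_size,
                                   planted_fc = genome$config$planted_fc,
                                   dispersion = genome$config$dispersion,
                                   seed = genome$config$seed + 201L) {
  cfg <- genome$config
  tes <- genome$te_annotation
  n_te <- nrow(tes)
  len_kb <- (tes$end - tes$start) / 1000
  samples <- c(paste0("wt_", seq_len(n_replicates)),
               paste0("mut_", seq_len(n_replicates)))
  lib <- setNames(rep_len(lib_sizes, length(samples)), samples)
  withr::with_seed(seed, {
    base_rpkm <- rep(cfg$silenced_rpkm, n_te)
    expr_idx <- tes$te_id %in% genome$truth$expressed_te_ids
    base_rpkm[expr_idx] <- rlnorm(sum(expr_idx), cfg$baseline_meanlog,
                                  cfg$baseline_sdlog)
    fc <- ifelse(tes$te_id %in% genome$truth$planted_te_ids, planted_fc, 1)
    counts <- matrix(0L, nrow = n_te, ncol = length(samples),
                     dimnames = list(tes$te_id, samples))
    for (s in samples) {
      mu <- base_rpkm * len_kb * lib[[s]] / 1e6
      if (startsWith(s, "mut")) mu <- mu * fc
      counts[, s] <- if (dispersion > 0)
        rnbinom(n_te, mu = mu, size = 1 / dispersion)
      else rpois(n_te, mu)
    }
    out <- CountTable(counts,
                      lengths = setNames(len_kb * 1000, tes$te_id),
                      lib_sizes = lib)
    attr(out, "baseline_rpkm") <- setNames(base_rpkm, tes$te_id)
    out
  })
}

#' Simulate a bisulfite methylome
#'
#' Cytosine sites are scattered uniformly (unique positions per
#' chromosome and strand), assigned contexts at random, and given
#' binomial methylated-read counts at fixed depth with the configured
#' per-context mean inside or outside heterochromatin.
#'
#' @param genome A [simulate_genome()] model.
#' @param depth Reads per site.
#' @param means List with `het` and `eu` named context means (default
#'   from the genome truth).
#' @param site_density Sites per bp, all contexts combined.
#' @param seed RNG seed.
#' @return A [MethylationCalls()].
#' @export
simulate_methylome <- function(genome, depth = genome$config$meth_depth,
                               means = genome$truth$meth_means,
                               site_density = genome$config$meth_site_density,
                               seed = genome$config$seed + 301L) {
  stopifnot(depth >= 1)
  withr::with_seed(seed, {
    out <- list()
    for (chrom in names(genome$chrom_sizes)) {
      L <- genome$chrom_sizes[[chrom]]
      n_sites <- round(L * site_density)
      if (n_sites == 0L) next
      pos <- sort(sample.int(L, min(n_sites, L)) - 1L)
      context <- sample(c("CG", "CHG", "CHH"), length(pos), replace = TRUE)
      strand <- sample(c("+", "-"), length(pos), replace = TRUE)
      pp <- genome$het_patches[genome$het_patches$chrom == chrom, ,
                               drop = FALSE]
      in_het <- rep(FALSE, length(pos))
      if (nrow(pp) > 0L) {
        idx <- findInterval(pos, pp$start)
        in_het <- idx > 0L & pos < pp$end[pmax(idx, 1L)]
      }
      p <- ifelse(in_het, means$het[context], means$eu[context])
      count_C <- rbinom(length(pos), depth, p)
      out[[chrom]] <- data.frame(chrom = chrom, pos = pos, strand = strand,
                                 context = context, count_C = count_C,
                                 count_T = depth - count_C)
    }
    MethylationCalls(do.call(rbind, out))
  })
}

#' Simulate flow-cytometry ploidy-peak intensities
#'
#' Draws events from a Gaussian mixture with one component per ploidy
#' peak; each component's standard deviation is `cv * mean / 100`.
#'
#' @param peaks Component means (ascending, e.g. 2C/4C/8C/16C).
#' @param cvs Component CVs in percent (> 0).
#' @param n_events Number of events.
#' @param props Mixture proportions (sum 1).
#' @param seed RNG seed.
#' @return Numeric intensity vector with attribute `component` (the
#'   true component label per event) for scoring.
#' @export
simulate_facs <- function(peaks = c(100, 200, 400, 800),
                          cvs = c(4, 4, 5, 5), n_events = 10000L,
                          props = rep(1 / length(peaks), length(peaks)),
                          seed = 1L) {
  stopifnot(length(peaks) == length(cvs), length(peaks) == length(props))
  if (any(cvs <= 0)) stop("component CVs must be positive")
  if (abs(sum(props) - 1) > 1e-8) stop("mixture proportions must sum to 1")
  if (n_events == 0L) {
    out <- numeric(0); attr(out, "component") <- integer(0)
    return(out)
  }
  withr::with_seed(seed, {
    comp <- sample(seq_along(peaks), n_events, replace = TRUE, prob = props)
    x <- rnorm(n_events, mean = peaks[comp], sd = cvs[comp] * peaks[comp] / 100)
    attr(x, "component") <- comp
    x
  })
}

#' Write a simulated data set to disk in the package's file formats
#'
#' Emits the same formats the readers consume: BED placements, BED
#' heterochromatin patches, GFF3 TE annotation, CX-report methylation
#' TSV, a counts TSV, a one-column FACS TSV, and (when jsonlite is
#' available) a `truth.json` with the planted parameters.
#'
#' @param genome A [simulate_genome()] model.
#' @param outdir Output directory (created if missing).
#' @param dna,rnaseq,methylome,facs Optional simulated objects to
#'   write; pass `NULL` to skip a stage. `dna` is a list of
#'   `ReadPlacements`.
#' @return `outdir`, invisibly.
#' @export
write_simulation <- function(genome, outdir, dna = NULL, rnaseq = NULL,
                             methylome = NULL, facs = NULL) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  write_regions_bed(genome$het_patches, file.path(outdir, "het_patches.bed"))
  write_te_gff3(genome$te_annotation, file.path(outdir, "tes.gff3"))
  for (rp in dna)
    write_placements_bed(rp, file.path(outdir, paste0(rp$sample_id, ".bed")))
  if (!is.null(rnaseq)) {
    df <- data.frame(feature_id = rownames(rnaseq$counts),
                     length = rnaseq$lengths, rnaseq$counts,
                     check.names = FALSE)
    write.table(df, file.path(outdir, "counts.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
  }
  if (!is.null(methylome))
    write_cx_report(methylome, file.path(outdir, "methylome.cx.tsv"))
  if (!is.null(facs))
    write.table(data.frame(intensity = as.numeric(facs)),
                file.path(outdir, "facs_events.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE, col.names = FALSE)
  if (requireNamespace("jsonlite", quietly = TRUE))
    jsonlite::write_json(genome$truth, file.path(outdir, "truth.json"),
                         auto_unbox = TRUE)
  invisible(outdir)
}
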