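# End-to-end orchestration: load -> filter -> diversity -> scan ->
# regions -> haplotypes -> trees -> coalescent null -> dating ->
# substitutions, with a reproducibility manifest.

#' Windowed dXY between two sample groups
#'
#' Tiles a region into non-overlapping windows and computes dXY per
#' window with the window width as callable-site denominator and weight.
#' A trailing partial window is dropped.
#'
#' @param vm A `variant_matrix`.
#' @param group_a,group_b Sample id vectors.
#' @param region A [region()].
#' @param window Window size in bp (default 10 kbp).
#' @return Data frame with `start`, `end`, `dxy`, `weight`.
#' @export
windowed_dxy <- function(vm, group_a, group_b, region, window = 1e4) {
  starts <- seq(region$start, region$end - window + 1, by = window)
  if (length(starts) == 0) stop("region smaller than one window")
  out <- do.call(rbind, lapply(starts, function(ws) {
    r <- region(region$chrom, ws, ws + window - 1)
    data.frame(start = r$start, end = r$end,
               dxy = dxy(vm, group_a, group_b, region = r,
                         n_callable = window),
               weight = window)
  }))
  rownames(out) <- NULL
  out
}

#' Position of an observed FST in the simulated null
#'
#' Fraction of simulated loci with FST greater than or equal to the
#' observed region value; 0 means "never observed in the simulation".
#'
#' @param region_fst Observed FST value(s).
#' @param null A `split_null` from [simulate_distribution()], or a numeric
#'   vector of simulated FST values.
#' @return Numeric exceedance fraction per input value.
#' @export
report_null_position <- function(region_fst, null) {
  fst <- if (inherits(null, "split_null")) null$fst else null
  if (length(fst) == 0) stop("empty null distribution")
  vapply(region_fst, function(x) mean(fst >= x), numeric(1))
}

#' Pipeline configuration
#'
#' @param vcf,meta Paths to the VCF and sample metadata TSV (required).
#' @param gff,fasta,ancestral,depth,blacklist Optional paths enabling the
#'   annotation, substitution and depth-masking stages.
#' @param out_dir Output directory.
#' @param min_qual QUAL filter (default 50).
#' @param fst_threshold Outlier threshold (default 0.5).
#' @param merge_gap Region merge gap in bp (default 1 Mbp).
#' @param subblock_gap Fine-grained merge gap for sub-block reporting
#'   (default 50 kbp).
#' @param het_threshold,hom_threshold Haplotype-classification thresholds.
#' @param window Window size for dXY/topology windows (default 10 kbp).
#' @param boot_reps Bootstrap replicates for dXY intervals (default 2000).
#' @param clock A [clock_params()].
#' @param sim A [split_model()] for the null distribution.
#' @param sim_loci Loci simulated for the null (default 1e5).
#' @param genome_length Callable genome length; defaults to the span of
#'   observed positions per chromosome.
#' @param seed Integer seed recorded in the manifest and used for all
#'   stochastic stages.
#' @return An object of class `run_config`.
#' @export
run_config <- function(vcf, meta, gff = NULL, fasta = NULL,
                       ancestral = NULL, depth = NULL, blacklist = NULL,
                       out_dir = tempfile("hapblockr_run"),
                       min_qual = 50, fst_threshold = 0.5,
                       merge_gap = 1e6, subblock_gap = 5e4,
                       het_threshold = 0.88, hom_threshold = 0.60,
                       window = 1e4, boot_reps = 2000,
                       clock = clock_params(),
                       sim = split_model(), sim_loci = 1e5, seed = 1,
                       genome_length = NULL) {
  stopifnot(fst_threshold > 0, fst_threshold < 1,
            het_threshold > 0, het_threshold < 1,
            hom_threshold > 0, hom_threshold <= 1,
            window >= 1, boot_reps >= 1)
  structure(list(vcf = vcf, meta = meta, gff = gff, fasta = fasta,
                 ancestral = ancestral, depth = depth,
                 blacklist = blacklist, out_dir = out_dir,
                 min_qual = min_qual, fst_threshold = fst_threshold,
                 merge_gap = merge_gap, subblock_gap = subblock_gap,
                 het_threshold = het_threshold,
                 hom_threshold = hom_threshold, window = window,
                 boot_reps = boot_reps, clock = clock, sim = sim,
                 sim_loci = sim_loci, seed = seed,
                 genome_length = genome_length),
            class = "run_config")
}

#' Run the full haplotype-block analysis pipeline
#'
#' Executes, in order: data loading and site filtering; per-population
#' diversity (pi, Watterson's theta, N_E); the per-SNP habitat FST scan;
#' region delineation at the outlier threshold (merged and sub-block
#' granularity); genotype-composition haplotype classification with group
#' frequencies and dosage-level region FST; population and sample
#' neighbor-joining trees with windowed quartet topologies; the
#' coalescent split-model null with the observed region FSTs positioned
#' in it; per-region haplotype diversity, divergence and molecular-clock
#' dating with bootstrap intervals; and (when annotations are supplied)
#' outgroup polarization with branch-specific substitution summaries.
#' Tables are written to `cfg$out_dir` together with a manifest.
#'
#' @param cfg A [run_config()].
#' @return A list with all stage results (invisibly also written to
#'   disk).
#' @export
run_pipeline <- function(cfg) {
  set.seed(cfg$seed)
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  log_stage <- function(...) message("[hapblockr] ", sprintf(...))

  # -- load ------------------------------------------------------------
  log_stage("loading %s", cfg$vcf)
  ds <- load_dataset(cfg$vcf, cfg$meta, quiet = TRUE)
  vm <- ds$vm; samples <- ds$samples
  bl <- if (!is.null(cfg$blacklist)) read.delim(cfg$blacklist) else NULL
  n0 <- length(vm$pos)
  vm <- apply_site_filters(vm, min_qual = cfg$min_qual, blacklist = bl)
  log_stage("site filters: %d -> %d SNPs", n0, length(vm$pos))
  if (!is.null(cfg$depth)) {
    dt <- read_depth_table(cfg$depth)
    scope <- if ("cohort" %in% names(dt)) "cohort" else "depth"
    vm <- suppressWarnings(depth_mask(vm, dt, scope = scope))
    log_stage("depth mask: %d SNPs retained", length(vm$pos))
  }
  habitat_of <- setNames(samples$habitat, samples$sample)
  high <- samples$sample[samples$habitat == "highland"]
  low <- samples$sample[samples$habitat == "lowland"]

  glen <- cfg$genome_length
  if (is.null(glen))
    glen <- sum(tapply(vm$pos, vm$chrom, max))

  # -- per-population diversity ---------------------------------------
  log_stage("per-population diversity")
  div <- do.call(rbind, lapply(
    c(split(samples$sample, samples$population), list(ALL = samples$sample)),
    function(ss) {
      d <- nucleotide_diversity(vm, samples = ss, n_callable = glen)
      data.frame(n = length(ss), n_snps = d$n_snps,
                 pi_pct = 100 * d$pi, theta_w_pct = 100 * d$theta_w,
                 N_E = effective_population_size(d$theta_w, cfg$clock))
    }))
  div <- data.frame(population = rownames(div), div, row.names = NULL)
  write_tables(div, file.path(cfg$out_dir, "diversity.tsv"))

  # -- scan and regions -------------------------------------------------
  log_stage("per-SNP FST scan (%d highland vs %d lowland)",
            length(high), length(low))
  track <- persite_fst_scan(vm, high, low)
  write_tables(as.data.frame(track), file.path(cfg$out_dir, "fst_track.tsv"))
  scan_summary <- attr(track, "summary")
  regions <- delineate_regions(track, threshold = cfg$fst_threshold,
                               merge_gap = cfg$merge_gap)
  subregions <- delineate_regions(track, threshold = cfg$fst_threshold,
                                  merge_gap = cfg$subblock_gap)
  write_tables(regions, file.path(cfg$out_dir, "regions.tsv"))
  write_tables(subregions, file.path(cfg$out_dir, "regions_subblocks.tsv"))
  if (nrow(regions)) {
    write_region_bed(regions, file.path(cfg$out_dir, "regions.bed"))
    hist <- fst_histogram(track, regions = regions)
    write_tables(hist, file.path(cfg$out_dir, "fst_histogram.tsv"))
  }
  if (nrow(regions) == 0) {
    log_stage("no outlier regions; pipeline complete")
    manifest <- write_manifest(cfg, vm, samples)
    return(invisible(list(samples = samples, diversity = div,
                          track_summary = scan_summary,
                          regions = regions, manifest = manifest)))
  }

  # -- haplotype classification ----------------------------------------
  log_stage("haplotype classification over %d region(s)", nrow(regions))
  calls <- list(); freqs <- list(); region_fst <- list()
  for (k in seq_len(nrow(regions))) {
    rid <- regions$region_id[k]
    opos <- region_outlier_positions(track, regions[k, ],
                                     threshold = cfg$fst_threshold)
    cl <- genotype_composition(vm, regions$chrom[k], opos, region_id = rid)
    cl <- classify_haplotypes(cl, cfg$het_threshold, cfg$hom_threshold)
    calls[[rid]] <- cl
    freqs[[rid]] <- suppressWarnings(
      data.frame(region_id = rid,
                 haplotype_frequencies(cl, samples, "habitat")))
    rf <- suppressWarnings(region_fst_from_dosage(cl, samples, "habitat"))
    region_fst[[rid]] <- data.frame(region_id = rid, dosage_fst = rf$fst)
  }
  all_calls <- do.call(rbind, calls)
  write_tables(all_calls, file.path(cfg$out_dir, "haplotype_calls.tsv"))
  freqs <- do.call(rbind, freqs); rownames(freqs) <- NULL
  region_fst <- do.call(rbind, region_fst); rownames(region_fst) <- NULL
  write_tables(freqs, file.path(cfg$out_dir, "haplotype_frequencies.tsv"))
  write_tables(region_fst, file.path(cfg$out_dir, "region_dosage_fst.tsv"))

  # -- trees and topologies --------------------------------------------
  log_stage("trees and windowed topologies")
  pop_p <- sapply(split(samples$sample, samples$population), function(ss)
    site_allele_stats(vm_genotypes(vm, samples = ss))$p)
  pop_n <- sapply(split(samples$sample, samples$population), function(ss)
    site_allele_stats(vm_genotypes(vm, samples = ss))$n)
  pop_fst <- reynolds_fst(pop_p, pop_n)
  pop_tree <- neighbor_joining(pop_fst)
  ape::write.tree(pop_tree, file.path(cfg$out_dir, "population_tree.nwk"))
  sdm <- sample_distance_matrix(vm, n_callable = glen)
  sample_tree <- neighbor_joining(sdm)
  ape::write.tree(sample_tree, file.path(cfg$out_dir, "sample_tree.nwk"))
  topo <- NULL; enrich <- NULL
  if (length(unique(samples$population)) == 4) {
    topo <- window_topologies(vm, samples, window = cfg$window)
    write_tables(as.data.frame(topo),
                 file.path(cfg$out_dir, "window_topologies.tsv"))
    chroms <- setdiff(topo$chrom, "genome")
    enrich <- do.call(rbind, lapply(chroms, function(ch) {
      e <- try(topology_enrichment(topo, ch), silent = TRUE)
      if (inherits(e, "try-error"))
        return(data.frame(chrom = ch, odds_ratio = NA, p_value = NA))
      data.frame(chrom = ch, odds_ratio = e$odds_ratio,
                 p_value = e$p_value)
    }))
    write_tables(enrich, file.path(cfg$out_dir, "topology_enrichment.tsv"))
  }

  # -- coalescent null --------------------------------------------------
  log_stage("split-model null (%g loci)", cfg$sim_loci)
  null <- simulate_distribution(cfg$sim, n_loci = cfg$sim_loci)
  write_tables(null$bins, file.path(cfg$out_dir, "null_fst_bins.tsv"))
  null_pos <- data.frame(
    region_id = region_fst$region_id,
    dosage_fst = region_fst$dosage_fst,
    null_exceedance = report_null_position(region_fst$dosage_fst, null))
  write_tables(null_pos, file.path(cfg$out_dir, "null_position.tsv"))

  # -- per-region haplotype diversity and dating ------------------------
  log_stage("haplotype diversity and molecular-clock dating")
  dating <- list()
  for (k in seq_len(nrow(regions))) {
    rid <- regions$region_id[k]
    cl <- calls[[rid]]
    hs <- cl$sample[cl$class == "hom_alt"]
    ls <- cl$sample[cl$class == "hom_ref"]
    if (length(hs) < 2 || length(ls) < 2) next
    reg <- region(regions$chrom[k], regions$first_outlier_pos[k],
                  regions$last_outlier_pos[k])
    rlen <- reg$end - reg$start + 1
    dh <- nucleotide_diversity(vm, hs, region = reg)
    dl <- nucleotide_diversity(vm, ls, region = reg)
    dd <- dxy(vm, hs, ls, region = reg)
    ci <- c(low = NA_real_, high = NA_real_)
    if (rlen >= 2 * cfg$window) {
      wd <- windowed_dxy(vm, hs, ls, reg, window = cfg$window)
      ci <- window_bootstrap_ci(wd$dxy, wd$weight, reps = cfg$boot_reps)
    }
    dating[[rid]] <- data.frame(
      region_id = rid, n_hom_h = length(hs), n_hom_l = length(ls),
      pi_h_pct = 100 * dh$pi, pi_l_pct = 100 * dl$pi,
      theta_h_pct = 100 * dh$theta_w, theta_l_pct = 100 * dl$theta_w,
      NE_h = effective_population_size(dh$theta_w, cfg$clock),
      NE_l = effective_population_size(dl$theta_w, cfg$clock),
      delta_pi = if (dl$pi > 0) delta_pi(dh$pi, dl$pi) else NA_real_,
      dxy_pct = 100 * dd,
      split_mya = clock_date(dd, cfg$clock) / 1e6,
      split_mya_low = clock_date(ci["low"], cfg$clock) / 1e6,
      split_mya_high = clock_date(ci["high"], cfg$clock) / 1e6)
  }
  dating <- do.call(rbind, dating)
  if (!is.null(dating)) {
    rownames(dating) <- NULL
    write_tables(dating, file.path(cfg$out_dir, "haplotype_dating.tsv"))
  }

  # -- substitutions ----------------------------------------------------
  subst <- NULL
  if (!is.null(cfg$gff) && !is.null(cfg$fasta) && !is.null(cfg$ancestral)) {
    log_stage("substitution analysis")
    ann <- load_annotations(cfg$gff, cfg$ancestral)
    fa <- seqinr::read.fasta(cfg$fasta, as.string = TRUE, forceDNAtolower = FALSE)
    ref_seqs <- lapply(fa, function(s) toupper(as.character(s)))
    pol <- polarize_sites(vm, ann$ancestral)
    subst <- list()
    for (k in seq_len(nrow(regions))) {
      rid <- regions$region_id[k]
      cl <- calls[[rid]]
      hs <- cl$sample[cl$class == "hom_alt"]
      ls <- cl$sample[cl$class == "hom_ref"]
      if (length(hs) == 0 || length(ls) == 0) next
      reg <- region(regions$chrom[k], regions$first_outlier_pos[k],
                    regions$last_outlier_pos[k])
      vmr <- vm_subset(vm, vm_site_index(vm, reg))
      fx <- fixed_differences(vmr, hs, ls)
      if (nrow(fx) == 0) next
      fx <- assign_branches(fx, pol)
      eff <- coding_effect(fx$chrom, fx$pos, fx$ref, fx$alt, ann$genes,
                           ref_seqs)
      fx$effect <- eff$effect
      fx$region_id <- rid
      subst[[rid]] <- fx
    }
    if (length(subst)) {
      allfx <- do.call(rbind, subst)
      write_tables(allfx, file.path(cfg$out_dir, "substitutions.tsv"))
      summ <- do.call(rbind, lapply(names(subst), function(rid) {
        s <- branch_substitution_summary(
          subst[[rid]][subst[[rid]]$effect != "non-coding", , drop = FALSE])
        data.frame(region_id = rid, s$by_branch, fisher_p = s$fisher_p)
      }))
      write_tables(summ, file.path(cfg$out_dir, "substitution_summary.tsv"))
      subst <- list(records = allfx, summary = summ)
    } else subst <- NULL
  }

  manifest <- write_manifest(cfg, vm, samples)
  log_stage("done: outputs in %s", cfg$out_dir)
  invisible(list(
    samples = samples, vm = vm, diversity = div,
    track = track, track_summary = scan_summary,
    regions = regions, subregions = subregions, calls = calls,
    frequencies = freqs, region_dosage_fst = region_fst,
    population_tree = pop_tree, sample_tree = sample_tree,
    topologies = topo, enrichment = enrich,
    null = null, null_position = null_pos, dating = dating,
    substitutions = subst, manifest = manifest))
}

# manifest: versions, seed, configuration values and a config hash
# (output location excluded so identical analyses hash identically)
write_manifest <- function(cfg, vm, samples) {
  cfg_hashable <- unclass(cfg)
  cfg_hashable$out_dir <- NULL
  flat <- flatten_config(cfg_hashable)
  tmp <- file.path(cfg$out_dir, "config_flat.tsv")
  write_tables(flat, tmp)
  hash <- unname(tools::md5sum(tmp))
  manifest <- rbind(
    data.frame(key = "package_version",
               value = as.character(utils::packageVersion("hapblockr"))),
    data.frame(key = "r_version", value = paste(R.version$major,
                                                R.version$minor, sep = ".")),
    data.frame(key = "seed", value = as.character(cfg$seed)),
    data.frame(key = "n_snps", value = as.character(length(vm$pos))),
    data.frame(key = "n_samples", value = as.character(nrow(samples))),
    data.frame(key = "config_md5", value = hash))
  write_tables(manifest, file.path(cfg$out_dir, "manifest.tsv"))
  manifest
}

flatten_config <- function(cfg) {
  vals <- list()
  rec <- function(x, prefix) {
    for (nm in names(x)) {
      v <- x[[nm]]
      key <- if (prefix == "") nm else paste(prefix, nm, sep = ".")
      if (is.list(v) && !is.data.frame(v)) rec(v, key)
      else vals[[key]] <<- paste(format(unlist(v)), collapse = ",")
    }
  }
  rec(as.list(cfg), "")
  data.frame(key = names(vals), value = unlist(vals, use.names = FALSE),
             stringsAsFactors = FALSE)
}
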