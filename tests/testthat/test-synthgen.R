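# Synthetic-data generator: determinism, calibration, emission round
# trips, truth consistency.

test_that("generation is deterministic and emission is byte-identical", {
  cfg <- small_synth_config()
  a <- generate_dataset(cfg, seed = 5)
  b <- generate_dataset(cfg, seed = 5)
  expect_identical(a$vm$geno, b$vm$geno)
  expect_identical(a$vm$pos, b$vm$pos)
  expect_identical(a$ancestral, b$ancestral)
  d1 <- file.path(tempdir(), "synth_a"); d2 <- file.path(tempdir(), "synth_b")
  p1 <- emit_dataset(a, d1); p2 <- emit_dataset(b, d2)
  for (k in names(p1))
    expect_identical(unname(tools::md5sum(p1[k])),
                     unname(tools::md5sum(p2[k])), label = k)
  c_ <- generate_dataset(cfg, seed = 6)
  expect_false(identical(a$vm$geno, c_$vm$geno))
})

test_that("background-only data realize the target habitat FST", {
  cfg <- synth_config(chrom_lengths = c("1" = 2e6), blocks = list(),
                      unplaced = list(), background = list(
                        spacing = 20, t_hab = 0.046, t_loc = 0.09,
                        target_fst = 0.036),
                      genes = list(coding_fraction = 0, exon_len = 300,
                                   n_exons = 3, intron_len = 200))
  ds <- generate_dataset(cfg, seed = 10)
  expect_gt(length(ds$vm$pos), 9e4)
  hi <- ds$samples$sample[ds$samples$habitat == "highland"]
  lo <- ds$samples$sample[ds$samples$habitat == "lowland"]
  tr <- persite_fst_scan(ds$vm, hi, lo)
  expect_equal(attr(tr, "summary")$genome_fst, 0.036, tolerance = 0.01)
  # and a scan of it yields no extended regions
  reg <- delineate_regions(tr, merge_gap = 5000)
  expect_true(nrow(reg) == 0 || max(reg$length) <= 5000)
})

test_that("a zero-time background is unstructured", {
  cfg <- synth_config(chrom_lengths = c("1" = 3e5), blocks = list(),
                      unplaced = list(), background = list(
                        spacing = 30, t_hab = 0, t_loc = 0,
                        target_fst = 0),
                      genes = list(coding_fraction = 0, exon_len = 300,
                                   n_exons = 3, intron_len = 200))
  ds <- generate_dataset(cfg, seed = 2)
  hi <- ds$samples$sample[ds$samples$habitat == "highland"]
  lo <- ds$samples$sample[ds$samples$habitat == "lowland"]
  tr <- persite_fst_scan(ds$vm, hi, lo)
  expect_lt(abs(attr(tr, "summary")$genome_fst), 0.01)
})

test_that("outgroup divergence and coverage match their settings", {
  ds <- generate_dataset(small_synth_config(), seed = 8)
  ts <- ds$truth$sites
  cov <- nrow(ds$ancestral) / nrow(ts)
  expect_equal(cov, 0.78, tolerance = 0.02)
  m <- match(paste(ds$ancestral$chrom, ds$ancestral$pos),
             paste(ts$chrom, ts$pos))
  mismatch <- mean(ds$ancestral$allele != ts$anc_allele[m])
  expect_equal(mismatch, 0.069, tolerance = 0.01)
  # divergence 0 -> outgroup equals the ancestral truth everywhere covered
  cfg0 <- small_synth_config(outgroup = list(divergence = 0, coverage = 0.78))
  ds0 <- generate_dataset(cfg0, seed = 8)
  m0 <- match(paste(ds0$ancestral$chrom, ds0$ancestral$pos),
              paste(ds0$truth$sites$chrom, ds0$truth$sites$pos))
  expect_true(all(ds0$ancestral$allele == ds0$truth$sites$anc_allele[m0]))
})

test_that("gene models tile both strands at the coding fraction", {
  ds <- generate_dataset(small_synth_config(), seed = 4)
  genes <- ds$genes
  expect_gt(nrow(genes), 0)
  coding_bp <- sum(genes$end - genes$start + 1)
  frac <- coding_bp / sum(small_synth_config()$chrom_lengths)
  expect_equal(frac, 0.08, tolerance = 0.02)
  strands <- tapply(genes$strand, genes$transcript, `[`, 1)
  expect_gt(mean(strands == "-"), 0.3)
  expect_lt(mean(strands == "-"), 0.7)
  # the reference codons are readable: no segment violates its bounds
  expect_true(all(genes$end <= ds$truth$config$chrom_lengths[genes$chrom]))
  # coding fraction 0 -> no CDS
  cfg0 <- small_synth_config(genes = list(coding_fraction = 0,
                                          exon_len = 300, n_exons = 3,
                                          intron_len = 200))
  expect_equal(nrow(generate_dataset(cfg0, seed = 4)$genes), 0L)
})

test_that("emitted bundle round-trips through the package readers", {
  ds <- generate_dataset(small_synth_config(), seed = 9)
  dir <- file.path(tempdir(), "synth_rt")
  paths <- emit_dataset(ds, dir)
  back <- load_dataset(paths["vcf"], paths["meta"], quiet = TRUE)
  expect_identical(back$vm$geno, ds$vm$geno)
  expect_identical(back$vm$pos, ds$vm$pos)
  expect_identical(back$vm$ref, ds$vm$ref)
  expect_identical(back$samples$sample, ds$samples$sample)
  ann <- load_annotations(paths["gff"], paths["ancestral"])
  expect_equal(nrow(ann$genes), nrow(ds$genes))
  expect_equal(sort(unique(ann$genes$transcript)),
               sort(unique(ds$genes$transcript)))
  expect_equal(nrow(ann$ancestral), nrow(ds$ancestral))
  dep <- read_depth_table(paths["depth"])
  expect_equal(nrow(dep), length(ds$vm$pos))
  fa <- seqinr::read.fasta(paths["fasta"], as.string = TRUE)
  expect_equal(toupper(as.character(fa[["7"]])), ds$ref_seqs[["7"]])
})

test_that("an undiverged block is invisible to the scan", {
  cfg <- small_synth_config()
  cfg$blocks$r7$d_block <- 0
  cfg$blocks$r7$theta_h <- 0
  cfg$blocks$r7$theta_l <- 0
  cfg$blocks$r9 <- NULL
  cfg$unplaced <- list()
  ds <- generate_dataset(cfg, seed = 13)
  hi <- ds$samples$sample[ds$samples$habitat == "highland"]
  lo <- ds$samples$sample[ds$samples$habitat == "lowland"]
  tr <- persite_fst_scan(ds$vm, hi, lo)
  reg <- delineate_regions(tr, merge_gap = 5000)
  expect_true(nrow(reg) == 0 || max(reg$n_outliers) <= 2)
})

test_that("block truth is internally consistent with the genotypes", {
  ds <- generate_dataset(small_synth_config(), seed = 14)
  tb <- ds$truth$blocks$r7
  # founder sites carry exactly the per-sample dosage vector
  ts <- ds$truth$sites
  fidx <- which(ts$type == "founder" & ts$chrom == "7")
  vm_idx <- match(paste("7", ts$pos[fidx]),
                  paste(ds$vm$chrom, ds$vm$pos))
  g <- ds$vm$geno[vm_idx, , drop = FALSE]
  ok <- !is.na(g)
  expected <- matrix(rep(tb$dosage, each = length(fidx)),
                     nrow = length(fidx))
  expect_true(all(g[ok] == expected[ok]))
  # per-population truth frequencies are consistent with the copies
  expect_equal(unname(tb$freq_by_pop["MKF"]),
               sum(tb$dosage[ds$samples$population == "MKF"]) / 20)
})

test_that("highland depth is depressed over blocks for masking tests", {
  ds <- generate_dataset(small_synth_config(), seed = 15)
  dep <- ds$depth
  in_block <- !is.na(ds$truth$sites$block) &
    ds$truth$sites$chrom %in% c("7", "9")
  vm <- ds$vm
  m_high <- depth_mask(vm, setNames(dep[c("chrom", "pos", "highland",
                                          "called_frac")],
                                    c("chrom", "pos", "depth",
                                      "called_frac")))
  m_low <- depth_mask(vm, setNames(dep[c("chrom", "pos", "lowland",
                                         "called_frac")],
                                   c("chrom", "pos", "depth",
                                     "called_frac")))
  reg7 <- data.frame(region_id = "r7", chrom = "7",
                     first_outlier_pos = ds$truth$blocks$r7$start,
                     last_outlier_pos = ds$truth$blocks$r7$end)
  r_high <- mask_retention_by_region(vm, m_high, reg7)$retained_fraction
  r_low <- mask_retention_by_region(vm, m_low, reg7)$retained_fraction
  expect_lt(r_high, r_low - 0.1)
})
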