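# Block scan: per-SNP FST track, region delineation, haplotype
# classification and frequencies, unplaced assignment, depth masking.

# genotypes for two groups with a fixed-difference block in the middle
scan_fixture <- function() {
  set.seed(21)
  n <- 60
  g <- matrix(rbinom(n * 10, 2, 0.45), nrow = n)  # shared background
  g[21:30, 6:10] <- 2; g[21:30, 1:5] <- 0         # fixed block
  colnames(g) <- paste0("S", 1:10)
  toy_vm(g, pos = seq(10, by = 10, length.out = n))
}

test_that("per-SNP scan flags fixed blocks and vanishes under permutation", {
  vm <- scan_fixture()
  a <- paste0("S", 1:5); b <- paste0("S", 6:10)
  tr <- persite_fst_scan(vm, a, b)
  expect_equal(nrow(tr), 60L)
  expect_true(all(tr$fst[21:30] == 1))
  expect_true(attr(tr, "summary")$genome_fst > 0.2)
  set.seed(9)
  perm <- sample(colnames(vm$geno))
  tr0 <- persite_fst_scan(vm, perm[1:5], perm[6:10])
  expect_lt(abs(attr(tr0, "summary")$genome_fst), 0.15)
  expect_error(persite_fst_scan(vm, a, c(b, "S1")), "disjoint")
})

test_that("FST histogram bins are right-closed with region strata", {
  tr <- data.frame(chrom = "1", pos = 1:10, a = 1, b = 0, c = 0,
                   fst = rep(0.82, 10), defined = TRUE)
  h <- fst_histogram(tr)
  expect_equal(h$n[h$bin_lo == 0.80 & h$stratum == "genome"], 10L)
  expect_equal(sum(h$n), 10L)
  # boundary value falls in the bin it closes
  tr$fst <- rep(0.85, 10)
  h2 <- fst_histogram(tr)
  expect_equal(h2$n[h2$bin_lo == 0.80], 10L)
  # empty stratum stays all-zero
  regs <- data.frame(region_id = "rX", chrom = "2",
                     first_outlier_pos = 1, last_outlier_pos = 10)
  h3 <- fst_histogram(tr, regions = regs)
  expect_equal(sum(h3$n[h3$stratum == "rX"]), 0L)
})

test_that("region delineation follows first/last outlier, inclusive length", {
  tr <- data.frame(chrom = "1", pos = c(5, 10, 20, 40),
                   a = 1, b = 0, c = 0,
                   fst = c(0.1, 0.6, 0.7, 0.9), defined = TRUE)
  r <- delineate_regions(tr, threshold = 0.5, merge_gap = 100)
  expect_equal(nrow(r), 1L)
  expect_equal(r$first_outlier_pos, 10)
  expect_equal(r$last_outlier_pos, 40)
  expect_equal(r$length, 31)
  expect_equal(r$n_outliers, 3L)
  expect_equal(r$n_snps, 3L)
  # printed bounds of a real sub-block give the printed inclusive length
  tr2 <- data.frame(chrom = "7", pos = c(1511853, 1520000, 1533141),
                    a = 1, b = 0, c = 0, fst = 0.9, defined = TRUE)
  r2 <- delineate_regions(tr2)
  expect_equal(r2$length, 21289)
  # no outliers -> empty frame
  tr$fst <- 0.1
  expect_equal(nrow(delineate_regions(tr)), 0L)
  # merge gap splits distant outlier clusters
  tr3 <- data.frame(chrom = "1", pos = c(10, 20, 5000, 5010),
                    a = 1, b = 0, c = 0, fst = 0.9, defined = TRUE)
  expect_equal(nrow(delineate_regions(tr3, merge_gap = 100)), 2L)
  expect_equal(nrow(delineate_regions(tr3, merge_gap = 10000)), 1L)
})

test_that("genotype composition counts and group percentages", {
  g <- matrix(2L, nrow = 100, ncol = 1, dimnames = list(NULL, "S1"))
  vm <- toy_vm(g)
  cc <- genotype_composition(vm, "1", 1:100)
  expect_equal(unname(unlist(cc[1, c("n00", "n01", "n11")])), c(0, 0, 100))
  # printed-count arithmetic: hom-alt calls over n_outliers x n_samples
  calls <- data.frame(sample = paste0("H", 1:20),
                      n00 = 0, n01 = 0, n11 = 0)
  calls$n11 <- c(rep(13398, 19), 13385)  # sums to 267,947
  expect_equal(sum(calls$n11), 267947)
  s <- composition_summary(calls, list(highland = calls$sample),
                           n_outliers = 16001)
  expect_equal(round(s$pct11, 1), 83.7)
})

test_that("haplotype classification thresholds, ties and monotonicity", {
  calls <- data.frame(sample = c("a", "b", "c", "d"),
                      n00 = c(2, 0, 40, 0), n01 = c(90, 2, 20, 0),
                      n11 = c(8, 98, 40, 0))
  tot <- calls$n00 + calls$n01 + calls$n11
  calls$f00 <- ifelse(tot > 0, calls$n00 / tot, NA)
  calls$f01 <- ifelse(tot > 0, calls$n01 / tot, NA)
  calls$f11 <- ifelse(tot > 0, calls$n11 / tot, NA)
  cl <- classify_haplotypes(calls)
  expect_equal(cl$class, c("het", "hom_alt", "ambiguous", "ambiguous"))
  expect_equal(cl$dosage[2], 2L)
  expect_true(cl$tie[3])
  expect_true(is.na(cl$dosage[3]))
  # increasing n11 at fixed total never leaves hom_alt
  base <- c(n00 = 10, n01 = 20, n11 = 70)
  for (extra in seq(0, 10)) {
    cc <- data.frame(sample = "x", n00 = 10 - extra %/% 2,
                     n01 = 20 - (extra - extra %/% 2), n11 = 70 + extra)
    tot <- sum(cc[, -1])
    cc$f00 <- cc$n00 / tot; cc$f01 <- cc$n01 / tot; cc$f11 <- cc$n11 / tot
    expect_equal(classify_haplotypes(cc)$class, "hom_alt")
  }
})

test_that("haplotype frequencies are dosage sums over 2n", {
  st <- data.frame(sample = paste0("S", 1:20), locality = "Mau",
                   habitat = "highland", altitude = 1, population = "MF")
  calls <- data.frame(sample = st$sample, n00 = 0, n01 = 0, n11 = 100,
                      f00 = 0, f01 = 0, f11 = 1)
  cl <- classify_haplotypes(calls)
  expect_equal(haplotype_frequencies(cl, st)$frequency, 1)
  cl$dosage <- c(rep(2L, 18), 1L, 0L)
  expect_equal(haplotype_frequencies(cl, st)$frequency, 37 / 40)
})

test_that("dosage-level region FST equals the single-locus WC estimate", {
  st <- toy_sample_table(10)  # 40 samples over 4 pops
  st <- st[c(1:20, 21:39), ]  # 20 highland, 19 lowland
  dos <- integer(39)
  hi <- st$habitat == "highland"
  dos[hi] <- c(rep(2L, 18), 1L, 1L)
  dos[!hi] <- c(rep(0L, 17), 1L, 2L)
  calls <- data.frame(sample = st$sample, n00 = 0, n01 = 0, n11 = 0,
                      dosage = dos)
  got <- region_fst_from_dosage(calls, st)
  p_h <- sum(dos[hi]) / 40; p_l <- sum(dos[!hi]) / 38
  direct <- wc_fst_site(c(p_h, p_l),
                        c(mean(dos[hi] == 1), mean(dos[!hi] == 1)),
                        c(20, 19))
  expect_equal(got$fst, direct$fst)
  # frequencies like the observed haplotype frequencies give ~0.830
  dos[hi] <- c(rep(2L, 18), 1L, 1L)        # p = 0.95, het = 0.10
  dos[!hi] <- c(rep(0L, 16), 1L, 1L, 2L)   # p = 0.105, het = 0.105
  expect_equal(sum(dos[hi]) / 40, 0.95)
  calls$dosage <- dos
  got2 <- region_fst_from_dosage(calls, st)
  expect_equal(got2$fst, 0.830, tolerance = 5e-3)
})

test_that("identical dosage mixes across groups give near-zero FST", {
  st <- toy_sample_table(5)
  calls <- data.frame(sample = st$sample, n00 = 0, n01 = 0, n11 = 0,
                      dosage = rep(c(0L, 1L, 2L, 1L, 0L), 4))
  got <- region_fst_from_dosage(calls, st)
  expect_lt(abs(got$fst), 0.1)
})

test_that("unplaced scaffolds are assigned by dosage concordance", {
  set.seed(4)
  st <- toy_sample_table(5)  # 20 samples
  dos_r7 <- rep(c(2L, 0L), each = 10)
  ref_calls <- list(r7 = data.frame(sample = st$sample, dosage = dos_r7))
  # scaffold matching r7 exactly
  g <- matrix(rep(dos_r7, each = 10), nrow = 10)
  colnames(g) <- st$sample
  vm <- toy_vm(g, chrom = "Un1")
  trk <- persite_fst_scan(vm, st$sample[1:10], st$sample[11:20])
  res <- assign_unplaced(vm, trk, ref_calls)
  expect_equal(res$assigned, "r7")
  expect_equal(res$concordance, 1)
  # single outlier SNP stays unassigned under min_snps = 2
  vm1 <- toy_vm(g[1, , drop = FALSE], chrom = "Un869")
  trk1 <- persite_fst_scan(vm1, st$sample[1:10], st$sample[11:20])
  res1 <- assign_unplaced(vm1, trk1, ref_calls, min_snps = 2)
  expect_equal(res1$assigned, "unassigned")
  # uncorrelated random dosages stay unassigned
  g2 <- matrix(sample(c(0L, 2L), 200, replace = TRUE), nrow = 10)
  g2[, 1:10][g2[, 1:10] == 0] <- 2  # force some outliers vs group B
  colnames(g2) <- st$sample
  g2[1:10, 11:20] <- 0
  vmr <- toy_vm(g2, chrom = "UnR")
  trkr <- persite_fst_scan(vmr, st$sample[1:10], st$sample[11:20])
  ref_rand <- list(r7 = data.frame(sample = st$sample,
                                   dosage = sample(c(0L, 1L, 2L), 20,
                                                   replace = TRUE)))
  resr <- assign_unplaced(vmr, trkr, ref_rand, min_concordance = 0.9)
  expect_equal(resr$assigned, "unassigned")
})

test_that("depth masking removes out-of-band and undercalled sites", {
  vm <- toy_vm(matrix(0:1, 10, 2))
  depth <- data.frame(chrom = "1", pos = 1:10, depth = rep(10, 10),
                      called_frac = 1)
  m0 <- depth_mask(vm, depth)
  expect_equal(length(m0$pos), 10L)
  depth$depth[4] <- 100  # ~10x the average
  m1 <- depth_mask(vm, depth, high_frac = 3)
  expect_false(4 %in% m1$pos)
  depth$called_frac[7] <- 0.2
  m2 <- depth_mask(vm, depth, min_called = 0.5)
  expect_false(7 %in% m2$pos)
  expect_warning(depth_mask(vm, depth[-1, ]), "missing")
  expect_error(depth_mask(vm, depth[-1, ], strict = TRUE), "missing")
})

test_that("masking commutes with scanning on retained sites", {
  vm <- scan_fixture()
  a <- paste0("S", 1:5); b <- paste0("S", 6:10)
  depth <- data.frame(chrom = "1", pos = vm$pos, depth = 10)
  depth$depth[c(3, 25, 50)] <- 200
  masked <- depth_mask(vm, depth)
  tr_masked <- persite_fst_scan(masked, a, b)
  tr_full <- persite_fst_scan(vm, a, b)
  keep <- tr_full$pos %in% masked$pos
  expect_equal(tr_masked$fst, tr_full$fst[keep])
})
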