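# Independent brute-force oracles and small fixture builders.

# variant matrix from a dosage matrix (sites x samples)
toy_vm <- function(geno, chrom = "1", pos = NULL, qual = NULL,
                   ref = NULL, alt = NULL) {
  geno <- as.matrix(geno)
  n <- nrow(geno)
  if (is.null(pos)) pos <- seq_len(n)
  if (length(chrom) == 1) chrom <- rep(chrom, n)
  if (is.null(ref)) ref <- rep("A", n)
  if (is.null(alt)) alt <- rep("T", n)
  variant_matrix(chrom, pos, ref, alt, qual, geno)
}

# expand a dosage into its two (unordered) alleles
dosage_alleles <- function(x) {
  if (is.na(x)) return(integer(0))
  switch(x + 1L, c(0L, 0L), c(0L, 1L), c(1L, 1L))
}

# brute-force pi: explicit enumeration of all allele pairs per site
brute_pi <- function(geno, n_callable) {
  tot <- 0
  for (s in seq_len(nrow(geno))) {
    al <- unlist(lapply(geno[s, ], dosage_alleles))
    m <- length(al)
    if (m < 2) next
    acc <- 0
    for (i in seq_len(m - 1))
      for (j in (i + 1):m) acc <- acc + (al[i] != al[j])
    tot <- tot + acc / choose(m, 2)
  }
  tot / n_callable
}

# brute-force dXY: enumeration of all cross-group allele pairs per site
brute_dxy <- function(geno_a, geno_b, n_callable) {
  tot <- 0
  for (s in seq_len(nrow(geno_a))) {
    aa <- unlist(lapply(geno_a[s, ], dosage_alleles))
    bb <- unlist(lapply(geno_b[s, ], dosage_alleles))
    if (length(aa) == 0 || length(bb) == 0) next
    acc <- 0
    for (i in seq_along(aa))
      for (j in seq_along(bb)) acc <- acc + (aa[i] != bb[j])
    tot <- tot + acc / (length(aa) * length(bb))
  }
  tot / n_callable
}

# brute-force per-pair sample distance (average over the 4 allele pairs)
brute_sample_dist <- function(g1, g2, n_callable) {
  tot <- 0
  for (s in seq_along(g1)) {
    aa <- dosage_alleles(g1[s]); bb <- dosage_alleles(g2[s])
    if (length(aa) == 0 || length(bb) == 0) next
    acc <- 0
    for (i in 1:2) for (j in 1:2) acc <- acc + (aa[i] != bb[j])
    tot <- tot + acc / 4
  }
  tot / n_callable
}

# exact two-sided Fisher p by hypergeometric enumeration over all tables
# with the observed margins
fisher_enum <- function(tab) {
  a <- tab[1, 1]; b <- tab[1, 2]; cc <- tab[2, 1]; d <- tab[2, 2]
  r1 <- a + b; r2 <- cc + d; c1 <- a + cc
  lo <- max(0, c1 - r2); hi <- min(r1, c1)
  xs <- lo:hi
  probs <- dhyper(xs, r1, r2, c1)
  pobs <- dhyper(a, r1, r2, c1)
  sum(probs[probs <= pobs * (1 + 1e-7)])
}

# independent evaluation of the allele-count (Reynolds-type) pair
# coancestry used for population distances
reynolds_oracle <- function(p1, p2, m1, m2) {
  num <- 0; den <- 0
  for (s in seq_along(p1)) {
    mbar <- (m1 + m2) / 2
    mc <- 2 * mbar - (m1^2 + m2^2) / (2 * mbar)
    pbar <- (m1 * p1[s] + m2 * p2[s]) / (m1 + m2)
    s2 <- (m1 * (p1[s] - pbar)^2 + m2 * (p2[s] - pbar)^2) / mbar
    b <- (mbar / (mbar - 1)) * (pbar * (1 - pbar) - s2 / 2)
    a <- (mbar / mc) * (s2 - (pbar * (1 - pbar) - s2 / 2) / (mbar - 1))
    num <- num + a; den <- den + a + b
  }
  num / den
}

# standard sample table for 4 toy populations (3/3/3/3 samples)
toy_sample_table <- function(n_per = 3) {
  pops <- data.frame(
    population = c("MF", "MS", "MKF", "MKS"),
    locality = c("Mau", "Mau", "MtKenya", "MtKenya"),
    habitat = c("highland", "lowland", "highland", "lowland"),
    altitude = c(2900, 1900, 2300, 1100))
  do.call(rbind, lapply(seq_len(nrow(pops)), function(i)
    data.frame(sample = paste0(pops$population[i], seq_len(n_per)),
               locality = pops$locality[i], habitat = pops$habitat[i],
               altitude = pops$altitude[i],
               population = pops$population[i])))
}

# small synthetic config for fast end-to-end runs
small_synth_config <- function(...) {
  synth_config(
    chrom_lengths = c("1" = 2e5, "7" = 4e5, "9" = 4e5),
    blocks = list(
      r7 = list(chrom = "7", start = 100001, end = 300000,
                d_block = 0.0334,
                freq = c(MF = 0.86, MS = 0.16, MKF = 1.00, MKS = 0.00),
                theta_h = 0.0020, theta_l = 0.0069),
      r9 = list(chrom = "9", start = 100001, end = 350000,
                d_block = 0.0134,
                freq = c(MF = 0.91, MS = 0.25, MKF = 0.95, MKS = 0.17),
                theta_h = 0.0052, theta_l = 0.0072)),
    unplaced = list(Un1 = list(len = 20000, source = "r7"),
                    Un3 = list(len = 15000, source = "background")),
    ...)
}
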