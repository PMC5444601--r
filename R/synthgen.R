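# Synthetic dataset generator: a low-FST structured background across four
# populations in two habitats, embedded ancient non-recombining haplotype
# blocks at contrasting frequencies, an outgroup allele table, gene models
# with a consistent reference sequence, a depth table, and a
# machine-readable truth record. Fully deterministic given a seed.

#' Synthetic dataset configuration
#'
#' Defaults emulate the study conditions the analysis assumes, scaled to a
#' desk-size genome: four populations (two localities x two habitats,
#' 10/10/10/9 samples), a structured coalescent background calibrated to a
#' habitat-partition FST of about 0.036, and two embedded non-recombining
#' blocks ("r7-like": 500 kbp, founder divergence 3.34%/bp, highland
#' haplotype frequency 0.93 vs 0.08; "r9-like": 700 kbp, 1.34%/bp, 0.93
#' vs 0.21) with Table-3-like within-haplotype diversity. The outgroup
#' diverges by 6.9% and covers 78% of sites.
#'
#' @param chrom_lengths Named vector of chromosome lengths (bp).
#' @param populations Data frame: `population`, `locality`, `habitat`,
#'   `altitude`, `n`.
#' @param background List: `spacing` (mean bp per background SNP),
#'   `t_hab` and `t_loc` (scaled split times of the habitat pair within
#'   each locality and of the two localities; ms units), `target_fst`
#'   (recorded calibration target).
#' @param blocks Named list of block specs: `chrom`, `start`, `end`,
#'   `d_block` (total expected per-bp divergence between haplotype
#'   classes), `freq` (named per-population highland-haplotype frequency),
#'   `theta_h`, `theta_l` (within-class diversity per bp).
#' @param unplaced Named list of unplaced scaffolds: `len` plus `source`
#'   (`"background"` or a block name whose segregation pattern the
#'   scaffold carries).
#' @param outgroup List: `divergence`, `coverage`.
#' @param genes List: `coding_fraction`, `exon_len`, `n_exons`,
#'   `intron_len`.
#' @param branch_h_frac Fraction of fixed block differences placed on the
#'   highland branch.
#' @param nonsyn_weight Multiplier on the highland-branch probability at
#'   codon positions 1/2 (biases highland fixed changes toward
#'   non-synonymous sites).
#' @param geno_missing_rate Per-genotype missing probability.
#' @param qual_low_frac Fraction of sites given QUAL below 50 (default 0:
#'   the emitted bundle represents the post-QC callable SNP set, so
#'   per-bp statistics are not silently deflated; set a positive value to
#'   exercise the quality filter).
#' @param depth List: `base` (mean depth), `depressed_frac` and
#'   `depress_range` (fraction and depth multiplier range of
#'   highland-depressed block sites), `lowcall_rate` (fraction of sites
#'   with a low genotyped-sample fraction).
#' @return An object of class `synth_config`.
#' @export
synth_config <- function(
    chrom_lengths = c("1" = 6e5, "7" = 1e6, "9" = 1.2e6),
    populations = data.frame(
      population = c("MF", "MS", "MKF", "MKS"),
      locality = c("Mau", "Mau", "MtKenya", "MtKenya"),
      habitat = c("highland", "lowland", "highland", "lowland"),
      altitude = c(2900, 1900, 2300, 1100),
      n = c(10L, 10L, 10L, 9L),
      stringsAsFactors = FALSE),
    background = list(spacing = 100, t_hab = 0.046, t_loc = 0.09,
                      target_fst = 0.036),
    blocks = list(
      r7 = list(chrom = "7", start = 150001, end = 650000,
                d_block = 0.0334,
                freq = c(MF = 0.86, MS = 0.16, MKF = 1.00, MKS = 0.00),
                theta_h = 0.0020, theta_l = 0.0069),
      r9 = list(chrom = "9", start = 300001, end = 1000000,
                d_block = 0.0134,
                freq = c(MF = 0.91, MS = 0.25, MKF = 0.95, MKS = 0.17),
                theta_h = 0.0052, theta_l = 0.0072)),
    unplaced = list(
      Un1 = list(len = 30000, source = "r7"),
      Un2 = list(len = 25000, source = "r9"),
      Un3 = list(len = 20000, source = "background")),
    outgroup = list(divergence = 0.069, coverage = 0.78),
    genes = list(coding_fraction = 0.08, exon_len = 300, n_exons = 3,
                 intron_len = 200),
    branch_h_frac = 0.66,
    nonsyn_weight = 1.25,
    geno_missing_rate = 0.01,
    qual_low_frac = 0,
    depth = list(base = 10, depressed_frac = 0.35,
                 depress_range = c(0.05, 0.25), lowcall_rate = 0.01)) {
  for (b in blocks) {
    stopifnot(b$start >= 1, b$end <= chrom_lengths[[b$chrom]],
              all(b$freq >= 0 & b$freq <= 1))
  }
  structure(list(chrom_lengths = chrom_lengths, populations = populations,
                 background = background, blocks = blocks,
                 unplaced = unplaced, outgroup = outgroup, genes = genes,
                 branch_h_frac = branch_h_frac,
                 nonsyn_weight = nonsyn_weight,
                 geno_missing_rate = geno_missing_rate,
                 qual_low_frac = qual_low_frac, depth = depth),
            class = "synth_config")
}

BASES <- c("A", "C", "G", "T")

# sequences are handled as character vectors (one base per element)
# during generation and collapsed to strings once at the end
random_seq <- function(len) sample(BASES, len, replace = TRUE)

other_base <- function(base) {
  alt3 <- rbind(A = c("C", "G", "T"), C = c("A", "G", "T"),
                G = c("A", "C", "T"), T = c("A", "C", "G"))
  alt3[cbind(match(base, rownames(alt3)),
             sample.int(3, length(base), replace = TRUE))]
}

NONSTOP_CODONS <- local({
  all3 <- as.vector(outer(as.vector(outer(BASES, BASES, paste0)), BASES,
                          paste0))
  setdiff(all3, c("TAA", "TAG", "TGA"))
})

revcomp_str <- function(s) {
  x <- rev(strsplit(s, "")[[1]])
  paste(unname(c(A = "T", C = "G", G = "C", T = "A")[x]), collapse = "")
}

#' Generate a synthetic dataset
#'
#' Runs the full generator: sample table, reference sequences, gene
#' models, structured coalescent background, embedded haplotype blocks,
#' unplaced scaffolds, outgroup table, depth table and truth record.
#'
#' @param cfg A [synth_config()].
#' @param seed Integer seed (all randomness flows from it).
#' @return A list of class `synth_dataset` with elements `vm`, `samples`,
#'   `genes`, `ref_seqs`, `ancestral`, `depth`, `truth`.
#' @export
generate_dataset <- function(cfg = synth_config(), seed = 1) {
  set.seed(seed)
  pops <- cfg$populations
  samples <- do.call(rbind, lapply(seq_len(nrow(pops)), function(i) {
    data.frame(sample = paste0(pops$population[i], seq_len(pops$n[i])),
               locality = pops$locality[i], habitat = pops$habitat[i],
               altitude = pops$altitude[i],
               population = pops$population[i], stringsAsFactors = FALSE)
  }))
  nsamp <- nrow(samples)

  all_lens <- c(cfg$chrom_lengths,
                setNames(vapply(cfg$unplaced, `[[`, numeric(1), "len"),
                         names(cfg$unplaced)))
  ref_seqs <- lapply(all_lens, random_seq)

  gm <- generate_gene_models_internal(cfg, ref_seqs)
  genes <- gm$genes
  ref_seqs <- gm$ref_seqs

  # ---- background sites (structured 4-population coalescent) ----
  bg <- generate_background_internal(cfg, samples, all_lens)

  # ---- haplotype blocks ----
  blocks <- list()
  for (bn in names(cfg$blocks)) {
    blocks[[bn]] <- embed_block_internal(cfg, bn, cfg$blocks[[bn]],
                                         samples, genes)
  }
  # unplaced scaffolds carrying a block's segregation pattern
  for (un in names(cfg$unplaced)) {
    src <- cfg$unplaced[[un]]$source
    if (src != "background") {
      blocks[[paste0(un, "_", src)]] <- embed_block_internal(
        cfg, src,
        modifyList(cfg$blocks[[src]],
                   list(chrom = un, start = 1,
                        end = cfg$unplaced[[un]]$len,
                        theta_h = 0, theta_l = 0)),
        samples, genes, copies = blocks[[src]]$copies)
    }
  }

  # ---- assemble the variant matrix ----
  parts <- c(list(bg$sites), lapply(blocks, `[[`, "sites"))
  sites <- do.call(rbind, parts)
  chrom_order <- names(all_lens)
  sites$pos <- as.integer(sites$pos)
  ord <- order(match(sites$chrom, chrom_order), sites$pos)
  sites <- sites[ord, , drop = FALSE]
  dup <- duplicated(paste(sites$chrom, sites$pos))
  sites <- sites[!dup, , drop = FALSE]
  geno <- do.call(rbind, c(list(bg$geno), lapply(blocks, `[[`, "geno")))
  geno <- geno[ord, , drop = FALSE][!dup, , drop = FALSE]
  colnames(geno) <- samples$sample
  n <- nrow(sites)

  # true outlier span per block from the pre-missingness genotypes:
  # the realized span of sites whose full-call habitat FST exceeds 0.5
  hi_idx <- which(samples$habitat == "highland")
  lo_idx <- which(samples$habitat == "lowland")
  sa <- site_allele_stats(geno[, hi_idx, drop = FALSE])
  sb <- site_allele_stats(geno[, lo_idx, drop = FALSE])
  true_fst <- wc_fst_site(p = cbind(sa$p, sb$p),
                          h = cbind(sa$het_frac, sb$het_frac),
                          n = cbind(sa$n, sb$n))
  true_outlier <- !is.na(true_fst$fst) & true_fst$fst > 0.5
  for (bn in names(blocks)) {
    sel <- which(!is.na(sites$block) & sites$block == bn &
                   sites$chrom == blocks[[bn]]$chrom & true_outlier)
    pp <- sites$pos[sel]
    blocks[[bn]]$outlier_first <- if (length(pp)) min(pp) else NA
    blocks[[bn]]$outlier_last <- if (length(pp)) max(pp) else NA
    blocks[[bn]]$outlier_gap_max <- if (length(pp) > 1)
      max(diff(sort(pp))) else NA
    blocks[[bn]]$n_true_outliers <- length(pp)
  }

  # genotype missingness and site quality
  if (cfg$geno_missing_rate > 0) {
    nm <- rbinom(1, n * nsamp, cfg$geno_missing_rate)
    if (nm > 0) geno[sample.int(n * nsamp, nm)] <- NA_integer_
  }
  qual <- round(runif(n, 55, 3000), 1)
  lowq <- runif(n) < cfg$qual_low_frac
  qual[lowq] <- round(runif(sum(lowq), 10, 50), 1)

  # ref/alt nucleotides: ref is the reference-sequence base
  refb <- toupper(substring_vec(ref_seqs, sites$chrom, sites$pos))
  altb <- other_base(refb)
  ref_seqs <- lapply(ref_seqs, paste, collapse = "")

  vm <- variant_matrix(sites$chrom, sites$pos, refb, altb, qual, geno)

  # ---- outgroup / ancestral table ----
  # ancestral state: "ref" or "alt" per site (recorded in sites$anc)
  anc_base <- ifelse(sites$anc == "ref", refb, altb)
  covered <- runif(n) < cfg$outgroup$coverage
  mut <- runif(n) < cfg$outgroup$divergence
  og_base <- anc_base
  og_base[mut] <- other_base(anc_base[mut])
  ancestral <- data.frame(chrom = sites$chrom[covered],
                          pos = sites$pos[covered],
                          allele = og_base[covered],
                          stringsAsFactors = FALSE)

  # ---- depth table ----
  depth <- generate_depth_internal(cfg, sites)

  truth <- list(
    seed = seed, config = cfg,
    sites = data.frame(sites, ref = refb, alt = altb,
                       anc_allele = anc_base, outgroup_covered = covered,
                       stringsAsFactors = FALSE),
    blocks = lapply(blocks, function(b)
      b[c("block", "chrom", "start", "end", "founder_first",
          "founder_last", "founder_gap_max", "outlier_first",
          "outlier_last", "outlier_gap_max", "n_true_outliers",
          "d_founder", "dosage", "freq_by_pop")]),
    background = list(t_hab = cfg$background$t_hab,
                      t_loc = cfg$background$t_loc,
                      target_fst = cfg$background$target_fst))
  structure(list(vm = vm, samples = samples, genes = genes,
                 ref_seqs = ref_seqs, ancestral = ancestral, depth = depth,
                 truth = truth),
            class = "synth_dataset")
}

substring_vec <- function(ref_vecs, chrom, pos) {
  out <- character(length(pos))
  for (ch in unique(chrom)) {
    i <- chrom == ch
    out[i] <- ref_vecs[[ch]][pos[i]]
  }
  out
}

# ---- gene models -----------------------------------------------------

generate_gene_models_internal <- function(cfg, ref_seqs) {
  gcfg <- cfg$genes
  rows <- list()
  if (gcfg$coding_fraction > 0) {
    span <- gcfg$n_exons * gcfg$exon_len +
      (gcfg$n_exons - 1) * gcfg$intron_len
    coding <- gcfg$n_exons * gcfg$exon_len
    gap <- max(0, round(coding / gcfg$coding_fraction - span))
    for (ch in names(cfg$chrom_lengths)) {
      len <- cfg$chrom_lengths[[ch]]
      pos <- 1 + sample.int(2000, 1)
      k <- 0
      while (pos + span - 1 <= len) {
        k <- k + 1
        strand <- sample(c("+", "-"), 1)
        tid <- sprintf("t%s.%d", ch, k)
        gid <- sprintf("g%s.%d", ch, k)
        starts <- pos + (seq_len(gcfg$n_exons) - 1) *
          (gcfg$exon_len + gcfg$intron_len)
        ends <- starts + gcfg$exon_len - 1
        segs <- data.frame(transcript = tid, gene = gid, chrom = ch,
                           strand = strand, start = starts, end = ends,
                           phase = 0L, stringsAsFactors = FALSE)
        # order 5'->3' and assign phase by cumulative length
        if (strand == "-") segs <- segs[rev(seq_len(nrow(segs))), ]
        cl <- c(0, cumsum(segs$end - segs$start + 1))
        segs$phase <- as.integer((3 - cl[-length(cl)] %% 3) %% 3)
        segs$exon_rank <- seq_len(nrow(segs))
        rows[[length(rows) + 1]] <- segs
        # overwrite the reference with in-frame non-stop codons
        ncod <- sum(segs$end - segs$start + 1) %/% 3
        cds <- unlist(strsplit(sample(NONSTOP_CODONS, ncod,
                                      replace = TRUE), ""))
        ref_seqs[[ch]] <- write_cds_into_seq(ref_seqs[[ch]], segs, cds)
        pos <- pos + span + gap
      }
    }
  }
  genes <- if (length(rows)) do.call(rbind, rows) else
    data.frame(transcript = character(), gene = character(),
               chrom = character(), strand = character(),
               start = integer(), end = integer(), phase = integer(),
               exon_rank = integer())
  rownames(genes) <- NULL
  list(genes = genes, ref_seqs = ref_seqs)
}

# write a transcript-orientation CDS (character vector) into the genomic
# sequence (character vector)
write_cds_into_seq <- function(seq, segs, cds) {
  off <- 0
  for (k in seq_len(nrow(segs))) {
    l <- segs$end[k] - segs$start[k] + 1
    chunk <- cds[(off + 1):(off + l)]
    if (segs$strand[k] == "-")
      chunk <- rev(unname(COMPLEMENT[chunk]))
    seq[segs$start[k]:segs$end[k]] <- chunk
    off <- off + l
  }
  seq
}

# ---- structured background -------------------------------------------

# population order fixed as in cfg$populations; joins: habitat pairs
# within each locality first, then localities
background_joins <- function(cfg) {
  pops <- cfg$populations
  loc <- unique(pops$locality)
  t <- c(); from <- c(); to <- c()
  anchor <- integer(length(loc))
  for (i in seq_along(loc)) {
    idx <- which(pops$locality == loc[i])
    anchor[i] <- idx[1]
    for (j in idx[-1]) {
      t <- c(t, cfg$background$t_hab); from <- c(from, j)
      to <- c(to, idx[1])
    }
  }
  for (i in seq_along(loc)[-1]) {
    t <- c(t, cfg$background$t_loc); from <- c(from, anchor[i])
    to <- c(to, anchor[1])
  }
  list(t = t, from = from, to = to)
}

generate_background_internal <- function(cfg, samples, all_lens) {
  pops <- cfg$populations
  sizes <- 2L * pops$n
  joins <- background_joins(cfg)
  # candidate positions: everywhere except embedded block intervals
  pos_list <- list()
  for (ch in names(all_lens)) {
    src <- if (ch %in% names(cfg$unplaced)) cfg$unplaced[[ch]]$source
    else "chrom"
    if (!is.null(src) && src != "background" && src != "chrom") next
    len <- all_lens[[ch]]
    blocked <- rep(FALSE, len)
    for (b in cfg$blocks)
      if (b$chrom == ch) blocked[b$start:b$end] <- TRUE
    avail <- which(!blocked)
    k <- round(length(avail) / cfg$background$spacing)
    if (k < 1) next
    pos_list[[ch]] <- sort(sample(avail, k))
  }
  n_bg <- sum(lengths(pos_list))
  al <- sim_structured_alleles(sizes, joins, n_bg)
  # chromosome columns -> per-sample dosage (consecutive pairing)
  odd <- al[, seq(1, ncol(al), by = 2), drop = FALSE]
  even <- al[, seq(2, ncol(al), by = 2), drop = FALSE]
  geno <- odd + even
  sites <- data.frame(
    chrom = rep(names(pos_list), lengths(pos_list)),
    pos = unlist(pos_list, use.names = FALSE),
    type = "background", block = NA_character_, branch = NA_character_,
    anc = "ref", stringsAsFactors = FALSE)
  list(sites = sites, geno = geno)
}

# ---- blocks ----------------------------------------------------------

# expected per-site pi and derived-allele frequency for within-class
# polymorphism. Frequencies follow the neutral SFS (P(i) proportional to
# 1/i) restricted to the minor range i <= M/2: derived variants that have
# reached majority within a haplotype class are indistinguishable from
# founder differences and are accounted for by the founder-divergence
# term instead.
sfs_site_expectations <- function(M) {
  if (M < 4) return(list(Epi = 0, Ef = 0))
  i <- seq_len(M %/% 2)
  w <- (1 / i) / sum(1 / i)
  f <- i / M
  list(Epi = sum(w * 2 * f * (1 - f)) * M / (M - 1), Ef = sum(w * f))
}

embed_block_internal <- function(cfg, block_name, b, samples, genes,
                                 copies = NULL) {
  nsamp <- nrow(samples)
  len <- b$end - b$start + 1
  # per-sample haplotype copies: TRUE = highland founder haplotype
  if (is.null(copies)) {
    fr <- b$freq[samples$population]
    copies <- matrix(runif(2 * nsamp) < rep(fr, each = 2), nrow = 2)
  }
  dosage <- colSums(copies)
  M_h <- sum(copies); M_l <- 2 * nsamp - M_h
  ex_h <- sfs_site_expectations(M_h)
  ex_l <- sfs_site_expectations(M_l)
  n_h <- if (b$theta_h > 0 && ex_h$Epi > 0)
    round(len * b$theta_h / ex_h$Epi) else 0
  n_l <- if (b$theta_l > 0 && ex_l$Epi > 0)
    round(len * b$theta_l / ex_l$Epi) else 0
  inflation <- (n_h * ex_h$Ef + n_l * ex_l$Ef) / len
  d_f <- max(0, b$d_block - inflation)
  n_f <- rbinom(1, len, d_f)
  pool <- sample.int(len, n_f + n_h + n_l) + b$start - 1L
  pos_f <- sort(pool[seq_len(n_f)])
  pos_h <- sort(pool[n_f + seq_len(n_h)])
  pos_l <- sort(pool[n_f + n_h + seq_len(n_l)])

  # founder fixed differences: every sample's genotype equals its dosage
  geno_f <- matrix(rep(dosage, each = n_f), nrow = n_f, ncol = nsamp)
  # branch assignment, biased toward codon positions 1/2 for the
  # highland branch inside CDS
  cpos <- codon_position_of(b$chrom, pos_f, genes)
  ph <- rep(cfg$branch_h_frac, n_f)
  in12 <- !is.na(cpos) & cpos < 3
  in3 <- !is.na(cpos) & cpos == 3
  ph[in12] <- min(1, cfg$branch_h_frac * cfg$nonsyn_weight)
  ph[in3] <- max(0, 3 * cfg$branch_h_frac -
                   2 * min(1, cfg$branch_h_frac * cfg$nonsyn_weight))
  branch <- ifelse(runif(n_f) < ph, "highland", "lowland")
  # reference genome carries the lowland haplotype: alt = highland allele.
  # highland-branch mutation => ancestral = lowland allele = ref;
  # lowland-branch mutation => ancestral = highland allele = alt.
  anc_f <- ifelse(branch == "highland", "ref", "alt")

  # within-class polymorphism: derived alleles on copies of one class
  class_site <- function(pos, class_copies, M) {
    npos <- length(pos)
    g <- matrix(0L, nrow = npos, ncol = nsamp)
    if (npos == 0 || M < 4) return(g)
    i_seq <- seq_len(M %/% 2)
    w <- (1 / i_seq) / sum(1 / i_seq)
    idx_copies <- which(class_copies)  # positions in the 2 x nsamp grid
    for (s in seq_len(npos)) {
      i <- sample.int(M %/% 2, 1, prob = w)
      der <- sample(idx_copies, i)
      tab <- tabulate(((der - 1) %/% 2) + 1, nbins = nsamp)
      g[s, ] <- tab
    }
    g
  }
  geno_h <- class_site(pos_h, copies, M_h)
  geno_l <- class_site(pos_l, !copies, M_l)

  sites <- data.frame(
    chrom = rep(b$chrom, n_f + n_h + n_l),
    pos = c(pos_f, pos_h, pos_l),
    type = c(rep("founder", n_f), rep("class_poly_h", n_h),
             rep("class_poly_l", n_l)),
    block = rep(block_name, n_f + n_h + n_l),
    branch = c(branch, rep(NA_character_, n_h + n_l)),
    anc = c(anc_f, rep("ref", n_h + n_l)),
    stringsAsFactors = FALSE)
  # founder sites: ref allele = lowland; genotype counts highland copies.
  # class-poly sites: ref = ancestral; genotype counts derived copies.
  geno <- rbind(geno_f, geno_h, geno_l)
  ord <- order(sites$pos)
  sites <- sites[ord, , drop = FALSE]
  geno <- geno[ord, , drop = FALSE]
  list(block = block_name, chrom = b$chrom, start = b$start, end = b$end,
       founder_first = if (n_f) min(pos_f) else NA,
       founder_last = if (n_f) max(pos_f) else NA,
       founder_gap_max = if (n_f > 1) max(diff(sort(pos_f))) else NA,
       d_founder = d_f, copies = copies, dosage = dosage,
       freq_by_pop = tapply(dosage, samples$population, sum) /
         (2 * tapply(rep(1, nsamp), samples$population, sum)),
       sites = sites, geno = geno)
}

# codon position (1/2/3 in transcript orientation) of genomic sites, NA
# outside CDS; first overlapping transcript wins
codon_position_of <- function(chrom, pos, genes) {
  out <- rep(NA_integer_, length(pos))
  g <- genes[genes$chrom == chrom, , drop = FALSE]
  if (nrow(g) == 0 || length(pos) == 0) return(out)
  for (i in seq_along(pos)) {
    hit <- g[g$start <= pos[i] & g$end >= pos[i], , drop = FALSE]
    if (nrow(hit) == 0) next
    segs <- g[g$transcript == hit$transcript[1], , drop = FALSE]
    segs <- segs[order(ifelse(segs$strand == "+", 1, -1) * segs$start), ]
    cum <- c(0, cumsum(segs$end - segs$start + 1))
    k <- which(segs$start <= pos[i] & segs$end >= pos[i])[1]
    within <- if (segs$strand[1] == "+") pos[i] - segs$start[k] + 1
    else segs$end[k] - pos[i] + 1
    cds_pos <- cum[k] + within
    out[i] <- ((cds_pos - 1) %% 3) + 1
  }
  out
}

# ---- depth -----------------------------------------------------------

generate_depth_internal <- function(cfg, sites) {
  n <- nrow(sites)
  d <- cfg$depth
  noise <- function() exp(rnorm(n, 0, 0.08))
  highland <- d$base * noise()
  lowland <- d$base * noise()
  in_block <- !is.na(sites$block)
  depress <- in_block & runif(n) < d$depressed_frac
  highland[depress] <- highland[depress] *
    runif(sum(depress), d$depress_range[1], d$depress_range[2])
  called_frac <- rep(1, n) - runif(n, 0, 0.05)
  low <- runif(n) < d$lowcall_rate
  called_frac[low] <- runif(sum(low), 0, 0.4)
  data.frame(chrom = sites$chrom, pos = sites$pos,
             highland = round(highland, 2), lowland = round(lowland, 2),
             cohort = round((highland + lowland) / 2, 2),
             called_frac = round(called_frac, 3),
             stringsAsFactors = FALSE)
}

# ---- emission --------------------------------------------------------

#' Write a synthetic dataset bundle to disk
#'
#' Emits VCF, sample metadata TSV, GFF3 gene models, reference FASTA,
#' ancestral-allele TSV, depth TSV and truth TSVs. All files are plain
#' text and parse back through the package's readers.
#'
#' @param ds A `synth_dataset` from [generate_dataset()].
#' @param dir Output directory (created if needed).
#' @return Invisibly, a named vector of file paths.
#' @export
emit_dataset <- function(ds, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(vcf = file.path(dir, "variants.vcf"),
             meta = file.path(dir, "samples.tsv"),
             gff = file.path(dir, "genes.gff3"),
             fasta = file.path(dir, "reference.fa"),
             ancestral = file.path(dir, "ancestral.tsv"),
             depth = file.path(dir, "depth.tsv"),
             truth_sites = file.path(dir, "truth_sites.tsv"),
             truth_blocks = file.path(dir, "truth_blocks.tsv"),
             truth_haplotypes = file.path(dir, "truth_haplotypes.tsv"))
  write_vcf(ds$vm, paths["vcf"])
  write_tables(ds$samples, paths["meta"])
  write_gff3(ds$genes, paths["gff"])
  seqinr::write.fasta(lapply(ds$ref_seqs, function(s)
    seqinr::s2c(tolower(s))), names = names(ds$ref_seqs),
    file.out = paths["fasta"], nbchar = 70)
  write_tables(ds$ancestral, paths["ancestral"])
  write_tables(ds$depth, paths["depth"])
  write_tables(ds$truth$sites, paths["truth_sites"])
  tb <- do.call(rbind, lapply(ds$truth$blocks, function(b)
    data.frame(block = b$block, chrom = b$chrom, start = b$start,
               end = b$end, founder_first = b$founder_first,
               founder_last = b$founder_last,
               outlier_first = b$outlier_first,
               outlier_last = b$outlier_last,
               outlier_gap_max = b$outlier_gap_max,
               n_true_outliers = b$n_true_outliers,
               d_founder = b$d_founder, stringsAsFactors = FALSE)))
  write_tables(tb, paths["truth_blocks"])
  th <- do.call(rbind, lapply(ds$truth$blocks, function(b)
    data.frame(block = b$block, sample = ds$samples$sample,
               true_dosage = b$dosage, stringsAsFactors = FALSE)))
  write_tables(th, paths["truth_haplotypes"])
  invisible(paths)
}

#' Write gene models as GFF3
#'
#' @param genes Gene-model data frame (one row per CDS segment).
#' @param path Output path.
#' @return Invisibly, the path.
#' @export
write_gff3 <- function(genes, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("##gff-version 3", con)
  for (tid in unique(genes$transcript)) {
    segs <- genes[genes$transcript == tid, , drop = FALSE]
    gid <- segs$gene[1]
    lo <- min(segs$start); hi <- max(segs$end)
    writeLines(sprintf("%s\thapblockr\tgene\t%d\t%d\t.\t%s\t.\tID=%s",
                       segs$chrom[1], lo, hi, segs$strand[1], gid), con)
    writeLines(sprintf("%s\thapblockr\tmRNA\t%d\t%d\t.\t%s\t.\tID=%s;Parent=%s",
                       segs$chrom[1], lo, hi, segs$strand[1], tid, gid), con)
    for (k in seq_len(nrow(segs))) {
      writeLines(sprintf(
        "%s\thapblockr\tCDS\t%d\t%d\t.\t%s\t%d\tParent=%s;gene=%s",
        segs$chrom[k], segs$start[k], segs$end[k], segs$strand[k],
        segs$phase[k], tid, gid), con)
    }
  }
  invisible(path)
}
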