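# Outgroup polarization, fixed-difference detection between haplotype
# classes, synonymous/non-synonymous classification against gene models,
# branch-specific substitution counting and proportion tests.

#' Polarize sites against an outgroup allele table
#'
#' A site is `polarized` when the outgroup allele equals exactly one of
#' ref/alt (the shared allele is ancestral, the other derived),
#' `unpolarized` when the outgroup carries a third allele, and
#' `missing_outgroup` when the site has no outgroup record.
#'
#' @param vm A `variant_matrix`.
#' @param ancestral Ancestral table (`chrom`, `pos`, `allele`).
#' @return Data frame with `chrom`, `pos`, `ref`, `alt`, `outgroup`,
#'   `ancestral`, `derived`, `status`.
#' @export
polarize_sites <- function(vm, ancestral) {
  m <- match(paste(vm$chrom, vm$pos), paste(ancestral$chrom, ancestral$pos))
  og <- ancestral$allele[m]
  status <- ifelse(is.na(og) | og == "", "missing_outgroup",
                   ifelse(og == vm$ref | og == vm$alt, "polarized",
                          "unpolarized"))
  anc <- ifelse(status == "polarized", og, NA_character_)
  der <- ifelse(status == "polarized",
                ifelse(og == vm$ref, vm$alt, vm$ref), NA_character_)
  data.frame(chrom = vm$chrom, pos = vm$pos, ref = vm$ref, alt = vm$alt,
             outgroup = og, ancestral = anc, derived = der, status = status,
             stringsAsFactors = FALSE)
}

#' Fixed differences between two homozygous haplotype classes
#'
#' Sites at which every called genotype of one group is homozygous for one
#' allele and every called genotype of the other group homozygous for the
#' opposite allele. Heterozygous calls disqualify a site; up to
#' `max_missing` missing genotypes per group are tolerated.
#'
#' @param vm A `variant_matrix`.
#' @param group_h,group_l Sample ids of the two homozygous classes (e.g.
#'   from [classify_haplotypes()]).
#' @param max_missing Missing genotypes tolerated per group per site
#'   (default 0).
#' @return Data frame with `chrom`, `pos`, `ref`, `alt`, `h_allele`
#'   (`"ref"` or `"alt"`: the allele fixed in `group_h`).
#' @export
fixed_differences <- function(vm, group_h, group_l, max_missing = 0) {
  if (length(group_h) == 0 || length(group_l) == 0)
    stop("both groups must be non-empty")
  gh <- vm_genotypes(vm, samples = group_h)
  gl <- vm_genotypes(vm, samples = group_l)
  miss_h <- rowSums(is.na(gh)); miss_l <- rowSums(is.na(gl))
  all0 <- function(g) rowSums(g != 0L, na.rm = TRUE) == 0 &
    rowSums(!is.na(g)) > 0
  all2 <- function(g) rowSums(g != 2L, na.rm = TRUE) == 0 &
    rowSums(!is.na(g)) > 0
  ok_miss <- miss_h <= max_missing & miss_l <= max_missing
  h_alt <- all2(gh) & all0(gl) & ok_miss
  h_ref <- all0(gh) & all2(gl) & ok_miss
  idx <- which(h_alt | h_ref)
  data.frame(chrom = vm$chrom[idx], pos = vm$pos[idx], ref = vm$ref[idx],
             alt = vm$alt[idx],
             h_allele = ifelse(h_alt[idx], "alt", "ref"),
             stringsAsFactors = FALSE)
}

COMPLEMENT <- c(A = "T", C = "G", G = "C", T = "A")

revcomp1 <- function(base) unname(COMPLEMENT[base])

translate_codon <- function(codon) {
  seqinr::translate(seqinr::s2c(tolower(codon)))
}

#' Coding effect of substitutions
#'
#' Classifies each site against the gene models: `non-coding` outside all
#' CDS; otherwise the codon containing the site is reconstructed from the
#' reference sequence in transcript orientation (reverse-complemented on
#' the minus strand) and the substituted codon compared under the standard
#' genetic code (`synonymous`, `non-synonymous`, or `stop` when the
#' substitution creates a stop codon). Sites falling in an incomplete
#' terminal codon are `undetermined`. A site overlapping several
#' transcripts is non-synonymous if non-synonymous in any of them and is
#' flagged `multi`.
#'
#' @param chrom,pos,ref,alt Vectors describing the sites (ref must match
#'   the reference sequence).
#' @param genes Gene-model data frame from [load_annotations()].
#' @param ref_seqs Named character vector (or list) of reference sequences
#'   per chromosome.
#' @return Data frame with `chrom`, `pos`, `effect`, `transcript`,
#'   `gene`, `multi`.
#' @export
coding_effect <- function(chrom, pos, ref, alt, genes, ref_seqs) {
  n <- length(pos)
  effect <- character(n); transcript <- character(n)
  gene <- character(n); multi <- logical(n)
  for (i in seq_len(n)) {
    hits <- genes[genes$chrom == chrom[i] & genes$start <= pos[i] &
                    genes$end >= pos[i], , drop = FALSE]
    if (nrow(hits) == 0) {
      effect[i] <- "non-coding"; transcript[i] <- NA; gene[i] <- NA
      next
    }
    txs <- unique(hits$transcript)
    effs <- vapply(txs, function(tx) {
      site_effect_in_transcript(chrom[i], pos[i], ref[i], alt[i],
                                genes[genes$transcript == tx, , drop = FALSE],
                                ref_seqs)
    }, character(1))
    # severity order: stop > non-synonymous > synonymous > undetermined
    ord <- c(stop = 4, `non-synonymous` = 3, synonymous = 2,
             undetermined = 1)
    pick <- which.max(ord[effs])
    effect[i] <- effs[pick]
    transcript[i] <- txs[pick]
    gene[i] <- hits$gene[match(txs[pick], hits$transcript)]
    multi[i] <- length(txs) > 1
  }
  data.frame(chrom = chrom, pos = pos, effect = effect,
             transcript = transcript, gene = gene, multi = multi,
             stringsAsFactors = FALSE)
}

# effect of a substitution within one transcript's CDS
site_effect_in_transcript <- function(chrom, pos, ref, alt, segs, ref_seqs) {
  segs <- segs[order(ifelse(segs$strand == "+", 1, -1) * segs$start), ,
               drop = FALSE]
  strand <- segs$strand[1]
  lens <- segs$end - segs$start + 1
  cum <- c(0, cumsum(lens))
  seg_i <- which(segs$start <= pos & segs$end >= pos)[1]
  if (is.na(seg_i)) return("undetermined")
  within <- if (strand == "+") pos - segs$start[seg_i] + 1
  else segs$end[seg_i] - pos + 1
  cds_pos <- cum[seg_i] + within - segs$phase[1]
  if (cds_pos <= 0) return("undetermined")
  codon_idx <- (cds_pos - 1) %/% 3
  codon_cds <- codon_idx * 3 + 1:3 + segs$phase[1]
  # map CDS coordinates back to genomic positions
  gpos <- vapply(codon_cds, function(cp) {
    s <- findInterval(cp - 1e-9, cum)
    if (s < 1 || s > nrow(segs) || cp > cum[s + 1]) return(NA_integer_)
    off <- cp - cum[s]
    if (strand == "+") segs$start[s] + off - 1L
    else segs$end[s] - off + 1L
  }, numeric(1))
  if (any(is.na(gpos))) return("undetermined")
  seq <- ref_seqs[[chrom]]
  bases <- toupper(substring(seq, gpos, gpos))
  if (strand == "-") bases <- revcomp1(bases)
  ref_t <- if (strand == "+") toupper(ref) else revcomp1(toupper(ref))
  alt_t <- if (strand == "+") toupper(alt) else revcomp1(toupper(alt))
  at <- which(gpos == pos)
  if (length(at) != 1) return("undetermined")
  if (bases[at] != ref_t)
    warning("reference base mismatch at ", chrom, ":", pos)
  ref_codon <- paste(bases, collapse = "")
  alt_bases <- bases; alt_bases[at] <- alt_t
  alt_codon <- paste(alt_bases, collapse = "")
  aa_ref <- translate_codon(ref_codon)
  aa_alt <- translate_codon(alt_codon)
  if (aa_ref == aa_alt) "synonymous"
  else if (aa_alt == "*") "stop"
  else "non-synonymous"
}

#' Branch-specific substitution summary with proportion test
#'
#' Counts derived fixed changes per branch (highland / lowland /
#' unpolarized), their synonymous and non-synonymous members (stop-gain
#' changes count as non-synonymous), and the non-synonymous fraction, and
#' compares the highland and lowland coding fractions with a two-sided
#' Fisher's exact test.
#'
#' @param records Data frame with columns `branch` and `effect` (as
#'   produced by combining [polarize_sites()], [fixed_differences()] and
#'   [coding_effect()]).
#' @return A list with `by_branch` (data frame) and `fisher_p` (`NA` when
#'   either branch has no coding records).
#' @export
branch_substitution_summary <- function(records) {
  branches <- c("highland", "lowland", "unpolarized")
  by_branch <- do.call(rbind, lapply(branches, function(b) {
    d <- records[records$branch == b, , drop = FALSE]
    nonsyn <- sum(d$effect %in% c("non-synonymous", "stop"))
    syn <- sum(d$effect == "synonymous")
    data.frame(branch = b, n_total = nrow(d), n_nonsyn = nonsyn,
               n_syn = syn,
               nonsyn_fraction = if (nonsyn + syn > 0)
                 nonsyn / (nonsyn + syn) else NA_real_,
               stringsAsFactors = FALSE)
  }))
  hi <- by_branch[by_branch$branch == "highland", ]
  lo <- by_branch[by_branch$branch == "lowland", ]
  fisher_p <- NA_real_
  if (hi$n_nonsyn + hi$n_syn > 0 && lo$n_nonsyn + lo$n_syn > 0) {
    tab <- matrix(c(hi$n_nonsyn, hi$n_syn, lo$n_nonsyn, lo$n_syn),
                  nrow = 2, byrow = TRUE)
    fisher_p <- fisher_exact_2x2(tab)
  }
  list(by_branch = by_branch, fisher_p = fisher_p)
}

#' Assign fixed differences to haplotype branches
#'
#' Combines polarization with fixed-difference orientation: a site's
#' derived change is placed on the highland branch when the derived allele
#' is the highland-fixed allele, on the lowland branch when it is the
#' lowland-fixed allele, and `unpolarized` otherwise.
#'
#' @param fixed Data frame from [fixed_differences()].
#' @param polarized Data frame from [polarize_sites()].
#' @return `fixed` with `status`, `derived` and `branch` columns added.
#' @export
assign_branches <- function(fixed, polarized) {
  m <- match(paste(fixed$chrom, fixed$pos),
             paste(polarized$chrom, polarized$pos))
  st <- polarized$status[m]
  der <- polarized$derived[m]
  h_base <- ifelse(fixed$h_allele == "alt", fixed$alt, fixed$ref)
  l_base <- ifelse(fixed$h_allele == "alt", fixed$ref, fixed$alt)
  branch <- rep("unpolarized", nrow(fixed))
  pol <- !is.na(st) & st == "polarized"
  branch[pol & der == h_base] <- "highland"
  branch[pol & der == l_base] <- "lowland"
  fixed$status <- st
  fixed$derived <- der
  fixed$branch <- branch
  fixed
}

#' Two-sided Fisher's exact test for a 2x2 table
#'
#' Exact two-sided p-value by summation of hypergeometric probabilities
#' not exceeding the observed table's probability (the convention of
#' [stats::fisher.test()], which performs the computation).
#'
#' @param table 2x2 matrix of non-negative integer counts.
#' @return Two-sided p-value.
#' @export
fisher_exact_2x2 <- function(table) {
  table <- as.matrix(table)
  if (!all(dim(table) == c(2, 2))) stop("table must be 2x2")
  if (any(table < 0) || any(table != round(table)))
    stop("counts must be non-negative integers")
  stats::fisher.test(table)$p.value
}
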