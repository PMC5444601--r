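# Distance matrices, neighbor-joining trees, windowed four-taxon topology
# classification, and per-chromosome topology enrichment.

#' Pairwise sample distance matrix (dXY between diploids)
#'
#' Each entry is the average per-site difference between the two samples'
#' haplotype pairs (for dosages g1, g2 the per-site expectation is
#' `p1(1-p2) + p2(1-p1)` with `p = g/2`), summed over sites where both
#' samples are called and divided by `n_callable`.
#'
#' @param vm A `variant_matrix`.
#' @param samples Sample ids (default all).
#' @param region Optional `region()`.
#' @param n_callable Per-bp denominator; defaults to the region width when
#'   a region is given, else to the number of SNPs considered (per-SNP
#'   distance scale).
#' @return Symmetric labeled matrix with zero diagonal.
#' @export
sample_distance_matrix <- function(vm, samples = NULL, region = NULL,
                                   n_callable = NULL) {
  g <- vm_genotypes(vm, samples = samples, region = region)
  if (ncol(g) < 2) stop("need at least 2 samples")
  if (nrow(g) == 0) stop("no callable sites")
  if (is.null(n_callable)) {
    n_callable <- if (!is.null(region)) region$end - region$start + 1
    else nrow(g)
  }
  A <- g / 2
  C <- 1 * !is.na(A)
  A[is.na(A)] <- 0
  S1 <- t(A) %*% C          # sum over shared sites of p_i (vs j's mask)
  S2 <- t(A) %*% A          # sum of p_i * p_j
  D <- (S1 + t(S1) - 2 * S2) / n_callable
  diag(D) <- 0
  D
}

#' Neighbor-joining tree with non-negative branch lengths
#'
#' Standard Saitou-Nei agglomeration. Negative branch
#' lengths are clamped to zero and the deficit transferred to the sister
#' branch at the same node, preserving path lengths through the parent.
#'
#' @param d Symmetric distance matrix (labels as dimnames) or `dist`.
#' @return An `ape::phylo` tree (unrooted).
#' @export
neighbor_joining <- function(d) {
  m <- as.matrix(d)
  if (any(!is.finite(m))) stop("distance matrix has non-finite entries")
  if (nrow(m) < 3) stop("need at least 3 taxa")
  tr <- ape::nj(as.dist(m))
  neg <- which(tr$edge.length < 0)
  for (e in neg) {
    parent <- tr$edge[e, 1]
    sisters <- setdiff(which(tr$edge[, 1] == parent), e)
    if (length(sisters)) {
      s <- sisters[1]
      tr$edge.length[s] <- tr$edge.length[s] + tr$edge.length[e]
    }
    tr$edge.length[e] <- 0
  }
  tr$edge.length[tr$edge.length < 0] <- 0
  tr
}

#' Windowed four-taxon topology classification
#'
#' Splits each chromosome into non-overlapping windows, computes the
#' pairwise Reynolds FST matrix among the four populations per window
#' (negative entries floored at zero), and classifies the quartet by the
#' four-point condition: the pairing with the smallest sum of intra-pair
#' distances wins. The pairing whose pairs share a locality is labeled
#' `locality`, the one whose pairs share a habitat `habitat`, and the
#' remaining pairing `mixed`. Windows with fewer than `min_snps` SNPs, an
#' undefined pair, or a tie are `unresolved`.
#'
#' @param vm A `variant_matrix`.
#' @param sample_table Sample metadata with exactly 4 population labels.
#' @param window Window size in bp (default 10 kbp).
#' @param min_snps Minimum SNPs per window (default 10).
#' @return Data frame (class `topology_counts`) with per-chromosome and
#'   genome-total counts of `locality`, `mixed`, `habitat`, `unresolved`.
#' @export
window_topologies <- function(vm, sample_table, window = 1e4,
                              min_snps = 10) {
  pops <- sort(unique(sample_table$population))
  if (length(pops) != 4) stop("need exactly 4 populations")
  pop_of <- setNames(sample_table$population, sample_table$sample)
  pairings <- list(c(1, 2, 3, 4), c(1, 3, 2, 4), c(1, 4, 2, 3))
  # label each pairing by what its pairs share
  lab_of_pairing <- vapply(pairings, function(pr) {
    shares <- function(i, j, col) {
      a <- sample_table[[col]][match(pops[i], sample_table$population)]
      b <- sample_table[[col]][match(pops[j], sample_table$population)]
      identical(a, b)
    }
    if (shares(pr[1], pr[2], "locality") && shares(pr[3], pr[4], "locality"))
      "locality"
    else if (shares(pr[1], pr[2], "habitat") && shares(pr[3], pr[4], "habitat"))
      "habitat"
    else "mixed"
  }, character(1))
  rows <- list()
  for (ch in unique(vm$chrom)) {
    idx <- which(vm$chrom == ch)
    maxp <- max(vm$pos[idx])
    starts <- seq(1, maxp, by = window)
    cnt <- c(locality = 0L, mixed = 0L, habitat = 0L, unresolved = 0L)
    for (ws in starts) {
      widx <- idx[vm$pos[idx] >= ws & vm$pos[idx] < ws + window]
      if (length(widx) < min_snps) { cnt["unresolved"] <- cnt["unresolved"] + 1L; next }
      g <- vm$geno[widx, , drop = FALSE]
      P <- sapply(pops, function(p) {
        st <- site_allele_stats(g[, names(pop_of)[pop_of == p], drop = FALSE])
        st$p
      })
      N <- sapply(pops, function(p) {
        st <- site_allele_stats(g[, names(pop_of)[pop_of == p], drop = FALSE])
        st$n
      })
      fm <- reynolds_fst(rbind(P), pmax(rbind(N), 0))
      if (any(is.na(fm[upper.tri(fm)]))) {
        cnt["unresolved"] <- cnt["unresolved"] + 1L; next
      }
      fm <- pmax(fm, 0)
      sums <- vapply(pairings, function(pr)
        fm[pr[1], pr[2]] + fm[pr[3], pr[4]], numeric(1))
      winners <- which(sums == min(sums))
      if (length(winners) != 1) cnt["unresolved"] <- cnt["unresolved"] + 1L
      else cnt[lab_of_pairing[winners]] <- cnt[lab_of_pairing[winners]] + 1L
    }
    rows[[ch]] <- data.frame(chrom = ch, t(cnt), stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, rows)
  total <- data.frame(chrom = "genome",
                      locality = sum(res$locality), mixed = sum(res$mixed),
                      habitat = sum(res$habitat),
                      unresolved = sum(res$unresolved),
                      stringsAsFactors = FALSE)
  out <- rbind(res, total)
  rownames(out) <- NULL
  class(out) <- c("topology_counts", "data.frame")
  out
}

#' Per-chromosome topology enrichment (Fisher's exact test)
#'
#' Two-sided Fisher's exact test of the 2x2 table of focal-topology
#' windows on the focal chromosome versus the rest of the genome
#' (unresolved windows excluded).
#'
#' @param counts Output of [window_topologies()].
#' @param chrom Focal chromosome.
#' @param topology Topology column to test (default `"habitat"`).
#' @return A list with `odds_ratio` (sample OR), `p_value`, and the 2x2
#'   `table`.
#' @export
topology_enrichment <- function(counts, chrom, topology = "habitat") {
  resolved <- function(row) sum(row[c("locality", "mixed", "habitat")])
  foc <- counts[counts$chrom == chrom, , drop = FALSE]
  if (nrow(foc) != 1) stop("chromosome not found: ", chrom)
  rest <- counts[!(counts$chrom %in% c(chrom, "genome")), , drop = FALSE]
  f1 <- foc[[topology]]
  f0 <- resolved(foc) - f1
  r1 <- sum(rest[[topology]])
  r0 <- sum(resolved(rest)) - r1
  if (f1 + f0 == 0 || r1 + r0 == 0) stop("zero resolved windows")
  tab <- matrix(c(f1, f0, r1, r0), nrow = 2, byrow = TRUE,
                dimnames = list(c(chrom, "rest"),
                                c(topology, "other")))
  p <- fisher_exact_2x2(tab)
  or <- (f1 / f0) / (r1 / r0)
  list(odds_ratio = or, p_value = p, table = tab)
}
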