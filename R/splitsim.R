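# Coalescent null model: clean two-population split, one segregating site
# per independent locus, ms time scaling (units of 4*N0 generations).
# The same multi-population engine also powers the synthetic-data
# generator's structured background.

#' Two-population split model
#'
#' Parameters of the neutral clean-split null: per-population chromosome
#' counts, the scaled population-join time (ms convention: units of 4*N0
#' generations), number of unlinked loci (one segregating site each), and
#' a seed. `theta` mirrors the mutation-rate argument of ms-style
#' commands; with a single placed segregating site per locus it does not
#' affect allele placement and is recorded for provenance only.
#'
#' @param n_chroms Integer vector of sampled chromosomes per population
#'   (default `c(40, 38)`, i.e. 20 and 19 diploids).
#' @param t_join Scaled join time (default 0.01833, the value implied by a
#'   genome-wide FST of 0.036 via [split_scaled_time()]).
#' @param n_loci Number of independent loci (default 1e6).
#' @param theta Scaled locus mutation rate, recorded but unused for the
#'   single conditioned mutation (default 8.2).
#' @param seed Optional integer seed.
#' @return An object of class `split_model`.
#' @export
split_model <- function(n_chroms = c(40, 38), t_join = 0.01833,
                        n_loci = 1e6, theta = 8.2, seed = NULL) {
  stopifnot(length(n_chroms) >= 1, all(n_chroms >= 2), t_join >= 0,
            n_loci >= 1)
  structure(list(n_chroms = as.integer(n_chroms), t_join = t_join,
                 n_loci = as.integer(n_loci), theta = theta, seed = seed),
            class = "split_model")
}

#' @exportS3Method base::print
print.split_model <- function(x, ...) {
  cat(sprintf("split_model: %s chromosomes, join at T = %g, %d loci\n",
              paste(x$n_chroms, collapse = "+"), x$t_join, x$n_loci))
  invisible(x)
}

# joins for a clean split: all populations merge into pop 1 at t_join
split_joins <- function(model) {
  k <- length(model$n_chroms)
  if (k == 1) return(list(t = numeric(0), from = integer(0),
                          to = integer(0)))
  list(t = rep(model$t_join, k - 1), from = 2:k, to = rep(1L, k - 1))
}

#' Simulate single-mutation loci under the split model
#'
#' Backward-in-time Kingman coalescent per locus: within each population,
#' k lineages coalesce with exponential waiting at rate k(k-1) in units of
#' 4*N0 generations; at the join time all surviving lineages merge; one
#' mutation is placed on a branch drawn with probability proportional to
#' branch length, and its descendants carry the derived allele.
#' Chromosomes are paired consecutively into diploids.
#'
#' @param model A [split_model()].
#' @param n_loci Number of loci (default: from the model).
#' @param alleles If `TRUE`, also return the per-chromosome allele matrix
#'   (0 = ancestral, 1 = derived).
#' @return A data frame with per-locus derived counts (`d1`, `d2`, ...),
#'   heterozygous diploid counts (`het1`, ...) and `tree_length`; when
#'   `alleles = TRUE`, a list with elements `loci` and `alleles`.
#' @export
simulate_split_loci <- function(model, n_loci = model$n_loci,
                                alleles = FALSE) {
  if (!is.null(model$seed)) set.seed(model$seed)
  j <- split_joins(model)
  npop <- length(model$n_chroms)
  if (alleles) {
    al <- .sim_split_alleles(model$n_chroms, j$t, j$from - 1L, j$to - 1L,
                             as.integer(n_loci))
    loci <- loci_from_alleles(al, model$n_chroms)
    return(list(loci = loci, alleles = al))
  }
  m <- .sim_split_counts(model$n_chroms, j$t, j$from - 1L, j$to - 1L,
                         as.integer(n_loci))
  out <- as.data.frame(m)
  names(out) <- c(paste0("d", seq_len(npop)), paste0("het", seq_len(npop)),
                  "tree_length")
  out
}

# summarize an allele matrix (loci x chromosomes) into per-pop derived and
# het counts using consecutive pairing
loci_from_alleles <- function(al, n_chroms) {
  npop <- length(n_chroms)
  off <- c(0, cumsum(n_chroms))
  out <- data.frame(row.names = seq_len(nrow(al)))
  for (p in seq_len(npop)) {
    block <- al[, (off[p] + 1):off[p + 1], drop = FALSE]
    out[[paste0("d", p)]] <- rowSums(block)
    odd <- block[, seq(1, ncol(block), by = 2), drop = FALSE]
    even <- block[, seq(2, ncol(block), by = 2), drop = FALSE]
    out[[paste0("het", p)]] <- rowSums(odd != even)
  }
  out
}

#' Pair haploid chromosomes into diploids
#'
#' Consecutive chromosomes are paired; returns per-population alt-allele
#' frequency, observed heterozygote fraction and diploid count, the
#' sufficient statistics for the Weir-Cockerham estimator. Lineages are
#' exchangeable under the coalescent, so consecutive pairing is equivalent
#' to random pairing.
#'
#' @param chrom_alleles List (one element per population) of 0/1 allele
#'   vectors, each of even length.
#' @return Data frame with `p`, `het_frac`, `n_diploid` per population.
#' @export
pair_into_diploids <- function(chrom_alleles) {
  if (!is.list(chrom_alleles)) chrom_alleles <- list(chrom_alleles)
  do.call(rbind, lapply(seq_along(chrom_alleles), function(i) {
    a <- chrom_alleles[[i]]
    if (length(a) %% 2 != 0) stop("odd chromosome count cannot be paired")
    odd <- a[seq(1, length(a), by = 2)]
    even <- a[seq(2, length(a), by = 2)]
    data.frame(population = i, p = mean(a), het_frac = mean(odd != even),
               n_diploid = length(a) / 2)
  }))
}

#' Per-locus FST for simulated loci
#'
#' Applies the same Weir-Cockerham site estimator used for empirical data
#' to the diploid summaries of simulated loci.
#'
#' @param loci Data frame from [simulate_split_loci()].
#' @param n_chroms Chromosome counts per population.
#' @return Data frame from [wc_fst_site()] (one row per locus).
#' @export
split_loci_fst <- function(loci, n_chroms) {
  npop <- length(n_chroms)
  ndip <- n_chroms / 2
  p <- sapply(seq_len(npop), function(i) loci[[paste0("d", i)]] / n_chroms[i])
  h <- sapply(seq_len(npop), function(i) loci[[paste0("het", i)]] / ndip[i])
  wc_fst_site(p = p, h = h, n = ndip)
}

#' Simulate the null FST distribution under the split model
#'
#' Runs the coalescent engine, computes per-locus Weir-Cockerham FST with
#' the shared estimator code path, and summarizes the distribution in
#' 0.01-wide bins.
#'
#' @param model A [split_model()].
#' @param n_loci Number of loci (default: from the model).
#' @param bin_width Histogram bin width (default 0.01).
#' @param cutoffs FST cutoffs at which upper-tail fractions are reported.
#' @return A list of class `split_null` with `fst` (per-locus estimates),
#'   `bins` (data frame), and `summary` (mean of per-locus ratios,
#'   ratio-of-sums, maximum, tail fractions, counts).
#' @export
simulate_distribution <- function(model, n_loci = model$n_loci,
                                  bin_width = 0.01,
                                  cutoffs = c(0.5, 0.655, 0.682, 0.832)) {
  loci <- simulate_split_loci(model, n_loci = n_loci)
  comp <- split_loci_fst(loci, model$n_chroms)
  fst <- comp$fst[comp$defined]
  breaks <- seq(-1, 1, by = bin_width)
  cnt <- table(cut(fst, breaks = breaks, include.lowest = TRUE))
  bins <- data.frame(bin_lo = breaks[-length(breaks)], bin_hi = breaks[-1],
                     n = as.integer(cnt))
  bins <- bins[bins$n > 0 | (bins$bin_lo >= 0 & bins$bin_lo < 1), ,
               drop = FALSE]
  rownames(bins) <- NULL
  tails <- vapply(cutoffs, function(x) mean(fst >= x), numeric(1))
  names(tails) <- paste0("ge_", cutoffs)
  structure(list(
    fst = fst, bins = bins,
    summary = list(mean_of_ratios = mean(fst),
                   ratio_of_sums = sum(comp$a[comp$defined]) /
                     sum((comp$a + comp$b + comp$c)[comp$defined]),
                   max = max(fst), n_defined = length(fst),
                   n_loci = n_loci, tail_fractions = tails)),
    class = "split_null")
}

#' @exportS3Method base::print
print.split_null <- function(x, ...) {
  s <- x$summary
  cat(sprintf(
    "split-model null: %d loci (%d defined)\n  mean per-locus FST = %.4f, ratio-of-sums = %.4f, max = %.4f\n",
    s$n_loci, s$n_defined, s$mean_of_ratios, s$ratio_of_sums, s$max))
  invisible(x)
}

# internal: multi-population engine for the synthetic generator.
# sizes: chromosomes per population; joins: list(t, from, to) with 1-based
# population indices, times non-decreasing.
sim_structured_alleles <- function(sizes, joins, n_loci) {
  .sim_split_alleles(as.integer(sizes), joins$t, as.integer(joins$from) - 1L,
                     as.integer(joins$to) - 1L, as.integer(n_loci))
}
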