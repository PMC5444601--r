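# Core population-genetic estimators: pi, Watterson's theta, dXY,
# Weir-Cockerham and Reynolds FST, effective size, scaled split time,
# molecular-clock dating and window bootstrap intervals.
#
# All estimators are phase-free: diploid genotypes enter only through
# per-site allele counts and observed heterozygote fractions, so phased
# and unphased input are treated identically.

#' Molecular clock parameters
#'
#' Bundle of the constants used for effective-size and split-age
#' calculations. The defaults are a honey bee neutral mutation rate of
#' 5.27e-9 mutations/bp/generation, a one-year generation time, and the
#' haplodiploid inheritance scalar 3 (a diploid species would use 4).
#'
#' @param mu Mutation rate per bp per generation (> 0).
#' @param generation_years Years per generation (> 0).
#' @param inheritance_scalar Ploidy-dependent scalar relating theta to
#'   `N_E * mu` (3 for haplodiploids, 4 for diploids).
#' @return An object of class `clock_params`.
#' @export
clock_params <- function(mu = 5.27e-9, generation_years = 1,
                         inheritance_scalar = 3) {
  stopifnot(mu > 0, generation_years > 0, inheritance_scalar > 0)
  structure(list(mu = mu, generation_years = generation_years,
                 inheritance_scalar = inheritance_scalar),
            class = "clock_params")
}

harmonic_number <- function(m) {
  # a_n = sum_{i=1}^{m-1} 1/i for haplotype sample size m
  vapply(m, function(k) if (k < 2) NA_real_ else sum(1 / seq_len(k - 1)),
         numeric(1))
}

# per-site called-diploid count, alt-allele frequency and observed het
# fraction for a genotype matrix (sites x samples, dosage 0/1/2/NA)
site_allele_stats <- function(geno) {
  geno <- rbind(geno)
  called <- !is.na(geno)
  n <- as.numeric(rowSums(called))
  ac <- rowSums(geno, na.rm = TRUE)
  het <- rowSums(geno == 1L, na.rm = TRUE)
  p <- ifelse(n > 0, ac / (2 * n), NA_real_)
  h <- ifelse(n > 0, het / n, NA_real_)
  list(n = n, p = p, het_frac = h)
}

#' Nucleotide diversity and Watterson's theta
#'
#' Computes pi (mean pairwise difference per bp between haplotypes, Nei-Li
#' form with the unbiased m/(m-1) pairing correction for m called
#' haplotypes) and Watterson's theta per bp from the genotypes of a sample
#' set. Missing genotypes are excluded per site; each segregating site
#' contributes `1/a(m_s)` to the theta numerator, where `a(m)` is the
#' harmonic number of the site's called haplotype count, which reduces to
#' the textbook `S / a(2n)` without missingness.
#'
#' @param vm A `variant_matrix`.
#' @param samples Character vector of sample ids (default: all samples).
#' @param region Optional `region()` restricting the computation.
#' @param n_callable Number of callable (monomorphic + polymorphic) sites
#'   used as the per-bp denominator. Defaults to the region width when a
#'   region is given; must be supplied otherwise.
#' @return A list of class `diversity_result` with elements `pi`,
#'   `theta_w`, `n_sites` (callable sites) and `n_snps` (segregating
#'   sites).
#' @export
nucleotide_diversity <- function(vm, samples = NULL, region = NULL,
                                 n_callable = NULL) {
  g <- vm_genotypes(vm, samples = samples, region = region)
  n_callable <- resolve_n_callable(n_callable, region, nrow(g))
  if (nrow(g) == 0) {
    out <- list(pi = 0, theta_w = 0, n_sites = n_callable, n_snps = 0L)
    class(out) <- "diversity_result"
    return(out)
  }
  st <- site_allele_stats(g)
  m <- 2 * st$n                      # called haplotypes per site
  usable <- m >= 2
  if (!any(usable))
    stop("fewer than 2 callable haplotypes at every site")
  p <- st$p[usable]
  m <- m[usable]
  seg <- p > 0 & p < 1
  pi_sum <- sum(2 * p * (1 - p) * m / (m - 1))
  theta_sum <- sum(1 / harmonic_number(m[seg]))
  out <- list(pi = pi_sum / n_callable,
              theta_w = theta_sum / n_callable,
              n_sites = n_callable,
              n_snps = sum(seg))
  class(out) <- "diversity_result"
  out
}

#' @exportS3Method base::print
print.diversity_result <- function(x, ...) {
  cat(sprintf("pi = %.6g /bp, theta_w = %.6g /bp (S = %d over %g callable sites)\n",
              x$pi, x$theta_w, x$n_snps, x$n_sites))
  invisible(x)
}

#' Between-group divergence dXY
#'
#' Mean per-site difference over all cross-group haplotype pairs, divided
#' by the callable site count: `sum_s [p_a(1-p_b) + p_b(1-p_a)] /
#' n_callable` with per-site allele frequencies from called genotypes.
#'
#' @inheritParams nucleotide_diversity
#' @param group_a,group_b Disjoint character vectors of sample ids.
#' @return Divergence per bp (numeric scalar).
#' @export
dxy <- function(vm, group_a, group_b, region = NULL, n_callable = NULL) {
  if (length(group_a) == 0 || length(group_b) == 0)
    stop("both groups must be non-empty")
  if (length(intersect(group_a, group_b)) > 0)
    stop("groups must be disjoint")
  ga <- vm_genotypes(vm, samples = group_a, region = region)
  gb <- vm_genotypes(vm, samples = group_b, region = region)
  n_callable <- resolve_n_callable(n_callable, region, nrow(ga))
  if (nrow(ga) == 0) return(0)
  sa <- site_allele_stats(ga)
  sb <- site_allele_stats(gb)
  ok <- sa$n > 0 & sb$n > 0
  sum(sa$p[ok] * (1 - sb$p[ok]) + sb$p[ok] * (1 - sa$p[ok])) / n_callable
}

resolve_n_callable <- function(n_callable, region, n_snps) {
  if (is.null(n_callable)) {
    if (is.null(region))
      stop("n_callable must be supplied when no region is given")
    n_callable <- region$end - region$start + 1
  }
  if (n_callable < n_snps)
    stop("n_callable is smaller than the number of SNPs in the region")
  n_callable
}

#' Weir-Cockerham variance components for one or more sites
#'
#' Evaluates the Weir & Cockerham (1984) components a (among populations),
#' b (among individuals within populations) and c (within individuals)
#' from per-population alt-allele frequencies, observed heterozygote
#' fractions and diploid sample counts. The per-site estimate is
#' `a/(a+b+c)`; sites monomorphic across all populations (a+b+c = 0) or
#' with fewer than 2 called diploids in any population are flagged
#' undefined and excluded from multi-site ratio-of-sums estimates.
#'
#' @param p Matrix (sites x r populations) of alt-allele frequencies, or a
#'   vector for a single site.
#' @param h Observed heterozygote fractions, same shape as `p`.
#' @param n Called diploid counts per population: vector of length r, or a
#'   sites x r matrix when missingness varies by site.
#' @return Data frame with columns `a`, `b`, `c`, `fst`, `defined`.
#' @export
wc_fst_site <- function(p, h, n) {
  p <- rbind(p); h <- rbind(h)
  r <- ncol(p)
  if (r < 2) stop("need at least 2 populations")
  if (is.matrix(n)) {
    if (!all(dim(n) == dim(p))) stop("n matrix must match p")
  } else {
    n <- matrix(n, nrow = nrow(p), ncol = r, byrow = TRUE)
  }
  if (!all(dim(h) == dim(p))) stop("h must match p")
  nbar <- rowSums(n) / r
  nc <- (r * nbar - rowSums(n^2) / (r * nbar)) / (r - 1)
  pbar <- rowSums(n * p) / (r * nbar)
  s2 <- rowSums(n * (p - pbar)^2) / ((r - 1) * nbar)
  hbar <- rowSums(n * h) / (r * nbar)
  a <- (nbar / nc) *
    (s2 - (pbar * (1 - pbar) - (r - 1) / r * s2 - hbar / 4) / (nbar - 1))
  b <- (nbar / (nbar - 1)) *
    (pbar * (1 - pbar) - (r - 1) / r * s2 - (2 * nbar - 1) / (4 * nbar) * hbar)
  cc <- hbar / 2
  denom <- a + b + cc
  defined <- is.finite(denom) & denom != 0 &
    apply(n >= 2, 1, all) & is.finite(a)
  fst <- ifelse(defined, a / denom, NA_real_)
  data.frame(a = a, b = b, c = cc, fst = fst, defined = defined)
}

#' Combine site-level Weir-Cockerham components (ratio of sums)
#'
#' @param site_results Data frame from [wc_fst_site()] (or rbind of such).
#' @return A list with `theta_hat`, summed components and `n_sites` (the
#'   number of defined sites used).
#' @export
wc_fst_multi <- function(site_results) {
  d <- site_results[site_results$defined, , drop = FALSE]
  if (nrow(d) == 0) stop("no defined sites")
  A <- sum(d$a); B <- sum(d$b); C <- sum(d$c)
  list(theta_hat = A / (A + B + C), a = A, b = B, c = C, n_sites = nrow(d))
}

#' Pairwise Reynolds-type coancestry FST matrix
#'
#' Per-pair coancestry in the Reynolds-Weir-Cockerham (1983) family,
#' evaluated on allele counts (the haploid reduction of the 1984
#' variance-component estimator: samples of 2n alleles, no
#' within-individual component) and combined across loci as a ratio of
#' per-locus numerator/denominator sums.
#'
#' @param p Matrix (sites x r populations) of alt-allele frequencies.
#' @param n Diploid sample counts per population (vector of length r, or a
#'   sites x r matrix).
#' @return Symmetric r x r matrix with zero diagonal; `NA` where a pair
#'   shares no polymorphic defined site.
#' @export
reynolds_fst <- function(p, n) {
  p <- rbind(p)
  r <- ncol(p)
  if (r < 2) stop("need at least 2 populations")
  if (is.matrix(n)) m <- 2 * n else
    m <- matrix(2 * n, nrow = nrow(p), ncol = r, byrow = TRUE)
  labs <- colnames(p)
  out <- matrix(0, r, r, dimnames = list(labs, labs))
  for (i in seq_len(r - 1)) {
    for (j in (i + 1):r) {
      ab <- reynolds_pair_components(p[, i], p[, j], m[, i], m[, j])
      num <- sum(ab$a, na.rm = TRUE)
      den <- sum(ab$a + ab$b, na.rm = TRUE)
      out[i, j] <- out[j, i] <- if (den == 0) NA_real_ else num / den
    }
  }
  out
}

# allele-count (haploid) WC components for one population pair;
# m1, m2 are haplotype (allele) sample sizes
reynolds_pair_components <- function(p1, p2, m1, m2) {
  mbar <- (m1 + m2) / 2
  mc <- 2 * mbar - (m1^2 + m2^2) / (2 * mbar)
  pbar <- (m1 * p1 + m2 * p2) / (m1 + m2)
  s2 <- (m1 * (p1 - pbar)^2 + m2 * (p2 - pbar)^2) / mbar
  b <- (mbar / (mbar - 1)) * (pbar * (1 - pbar) - s2 / 2)
  a <- (mbar / mc) * (s2 - (pbar * (1 - pbar) - s2 / 2) / (mbar - 1))
  list(a = a, b = b)
}

#' Effective population size from Watterson's theta
#'
#' `N_E = theta_w / (inheritance_scalar * mu)`; the default scalar 3
#' reflects haplodiploid inheritance.
#'
#' @param theta_w Watterson's theta per bp (>= 0).
#' @param clock A [clock_params()] object.
#' @return Effective population size (numeric).
#' @export
effective_population_size <- function(theta_w, clock = clock_params()) {
  stopifnot(theta_w >= 0)
  theta_w / (clock$inheritance_scalar * clock$mu)
}

#' Relative diversity difference between haplotype classes
#'
#' `delta_pi = (pi_h - pi_l) / pi_l`; strongly negative values indicate
#' reduced variation on the first (e.g. highland) haplotype.
#'
#' @param pi_h,pi_l Per-bp diversities; `pi_l` must be positive.
#' @return Relative difference (numeric scalar).
#' @export
delta_pi <- function(pi_h, pi_l) {
  if (any(pi_l <= 0)) stop("pi_l must be positive")
  (pi_h - pi_l) / pi_l
}

#' Scaled split time from FST
#'
#' Under a clean two-population split without gene flow,
#' `T = -ln(1 - FST) / 2` in coalescent-scaled time units.
#'
#' @param fst FST in `[0, 1)`.
#' @return Scaled time `T`.
#' @export
split_scaled_time <- function(fst) {
  if (any(fst < 0 | fst >= 1)) stop("fst must be in [0, 1)")
  -log(1 - fst) / 2
}

#' Molecular-clock split age from dXY
#'
#' `age = dxy / (2 * mu)` generations, converted to years with the clock's
#' generation time.
#'
#' @param dxy Per-bp divergence (>= 0).
#' @param clock A [clock_params()] object.
#' @return Split age in years.
#' @export
clock_date <- function(dxy, clock = clock_params()) {
  stopifnot(all(dxy >= 0, na.rm = TRUE))
  dxy / (2 * clock$mu) * clock$generation_years
}

#' Percentile bootstrap interval for a weighted window mean
#'
#' Windows are resampled with replacement; the weighted mean is recomputed
#' per replicate and a percentile interval returned. Weights default to
#' equal; for per-bp statistics the callable site count per window is the
#' natural weight.
#'
#' @param values Per-window statistic.
#' @param weights Per-window weights (default equal).
#' @param reps Bootstrap replicates (default 2000).
#' @param level Confidence level (default 0.95).
#' @param seed Optional integer seed for the resampling RNG.
#' @return Named numeric vector `c(low, high)`.
#' @export
window_bootstrap_ci <- function(values, weights = NULL, reps = 2000,
                                level = 0.95, seed = NULL) {
  k <- length(values)
  if (k < 1) stop("need at least one window")
  if (is.null(weights)) weights <- rep(1, k)
  stopifnot(length(weights) == k)
  if (!is.null(seed)) set.seed(seed)
  stat <- numeric(reps)
  for (r in seq_len(reps)) {
    idx <- sample.int(k, k, replace = TRUE)
    stat[r] <- sum(values[idx] * weights[idx]) / sum(weights[idx])
  }
  alpha <- (1 - level) / 2
  ci <- unname(quantile(stat, c(alpha, 1 - alpha), names = FALSE))
  c(low = ci[1], high = ci[2])
}

#' Excess divergence ratio between two groups
#'
#' Mean cross-group pairwise sample distance divided by the mean
#' within-group pairwise distance (pooled over both groups). A value near
#' 1 indicates panmixia; `Inf` (flagged with a warning) indicates fully
#' diverged groups with no within-group variation.
#'
#' @inheritParams dxy
#' @return Numeric ratio.
#' @export
excess_divergence_ratio <- function(vm, group_a, group_b, region = NULL,
                                    n_callable = NULL) {
  if (length(group_a) == 0 || length(group_b) == 0)
    stop("both groups must be non-empty")
  if (length(group_a) < 2 && length(group_b) < 2)
    stop("at least one group must contain >= 2 samples")
  D <- sample_distance_matrix(vm, samples = c(group_a, group_b),
                              region = region, n_callable = n_callable)
  ia <- match(group_a, rownames(D)); ib <- match(group_b, rownames(D))
  cross <- mean(D[ia, ib, drop = FALSE])
  within <- c(D[ia, ia][upper.tri(diag(length(ia)))],
              D[ib, ib][upper.tri(diag(length(ib)))])
  w <- mean(within)
  if (w == 0) {
    warning("no within-group variation; ratio is infinite")
    return(Inf)
  }
  cross / w
}
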