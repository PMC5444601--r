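# Genome scan for divergent haplotype blocks: per-SNP FST track, outlier
# region delineation, genotype-composition haplotype classification,
# haplotype frequencies, dosage-level region FST, unplaced-scaffold
# assignment, FST histograms and depth/coverage masking.

#' Per-SNP Weir-Cockerham FST scan between two sample groups
#'
#' Computes site-level Weir-Cockerham components for every SNP between two
#' groups (e.g. the highland/lowland habitat partition). The returned
#' track carries a summary attribute with the genome-wide ratio-of-sums
#' FST and the fraction of defined SNPs below 0.1 and 0.5.
#'
#' @param vm A `variant_matrix`.
#' @param group_a,group_b Disjoint character vectors of sample ids.
#' @return Data frame (class `fst_track`) with columns `chrom`, `pos`,
#'   `a`, `b`, `c`, `fst`, `defined`; attribute `summary`.
#' @export
persite_fst_scan <- function(vm, group_a, group_b) {
  if (length(intersect(group_a, group_b)) > 0)
    stop("groups must be disjoint")
  sa <- site_allele_stats(vm_genotypes(vm, samples = group_a))
  sb <- site_allele_stats(vm_genotypes(vm, samples = group_b))
  comp <- wc_fst_site(p = cbind(sa$p, sb$p), h = cbind(sa$het_frac, sb$het_frac),
                      n = cbind(sa$n, sb$n))
  track <- data.frame(chrom = vm$chrom, pos = vm$pos, comp,
                      stringsAsFactors = FALSE)
  class(track) <- c("fst_track", "data.frame")
  d <- track[track$defined, , drop = FALSE]
  attr(track, "summary") <- list(
    genome_fst = sum(d$a) / sum(d$a + d$b + d$c),
    n_defined = nrow(d),
    frac_below_0.1 = mean(d$fst < 0.1),
    frac_below_0.5 = mean(d$fst < 0.5))
  track
}

#' Binned FST histogram per region stratum
#'
#' Counts SNPs in FST bins of the given width for each region and for the
#' remaining genome. Bins are left-open right-closed except the first,
#' which includes zero; negative site estimates are counted in the first
#' bin.
#'
#' @param track An `fst_track`.
#' @param bin_width Bin width; must divide 1 (default 0.05).
#' @param regions Optional region-call data frame from
#'   [delineate_regions()].
#' @return Data frame with `stratum`, `bin_lo`, `bin_hi`, `n`.
#' @export
fst_histogram <- function(track, bin_width = 0.05, regions = NULL) {
  nb <- 1 / bin_width
  if (abs(nb - round(nb)) > 1e-9) stop("bin_width must divide 1")
  breaks <- seq(0, 1, by = bin_width)
  stratum <- rep("genome", nrow(track))
  if (!is.null(regions) && nrow(regions) > 0) {
    for (k in seq_len(nrow(regions))) {
      inside <- track$chrom == regions$chrom[k] &
        track$pos >= regions$first_outlier_pos[k] &
        track$pos <= regions$last_outlier_pos[k]
      stratum[inside] <- regions$region_id[k]
    }
  }
  strata <- unique(c("genome", if (!is.null(regions)) regions$region_id))
  out <- do.call(rbind, lapply(strata, function(s) {
    f <- track$fst[stratum == s & track$defined]
    f <- pmax(f, 0)
    cnt <- table(cut(f, breaks = breaks, include.lowest = TRUE))
    data.frame(stratum = s, bin_lo = breaks[-length(breaks)],
               bin_hi = breaks[-1], n = as.integer(cnt),
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' Delineate divergent regions from an FST track
#'
#' Outlier SNPs (`fst > threshold`) are clustered per chromosome; runs of
#' outliers whose neighbours lie within `merge_gap` bp form one region.
#' Region bounds are the first and last outlier positions (1-based
#' inclusive; `length = last - first + 1`), and the region-level FST is
#' the ratio-of-sums estimate over all SNPs inside the bounds.
#'
#' @param track An `fst_track`.
#' @param threshold Outlier threshold (default 0.5).
#' @param merge_gap Maximum gap (bp) between adjacent outliers within one
#'   region (default 1 Mbp).
#' @return Data frame with `region_id`, `chrom`, `first_outlier_pos`,
#'   `last_outlier_pos`, `length`, `n_snps`, `n_outliers`, `region_fst`,
#'   `mean_site_fst`.
#' @export
delineate_regions <- function(track, threshold = 0.5, merge_gap = 1e6) {
  out <- list()
  for (ch in unique(track$chrom)) {
    tr <- track[track$chrom == ch, , drop = FALSE]
    op <- tr$pos[tr$defined & tr$fst > threshold]
    if (length(op) == 0) next
    brk <- c(0, which(diff(op) > merge_gap), length(op))
    for (k in seq_len(length(brk) - 1)) {
      pp <- op[(brk[k] + 1):brk[k + 1]]
      inside <- tr$pos >= pp[1] & tr$pos <= pp[length(pp)]
      din <- tr[inside & tr$defined, , drop = FALSE]
      out[[length(out) + 1]] <- data.frame(
        chrom = ch, first_outlier_pos = pp[1],
        last_outlier_pos = pp[length(pp)],
        length = pp[length(pp)] - pp[1] + 1,
        n_snps = sum(inside),
        n_outliers = length(pp),
        region_fst = sum(din$a) / sum(din$a + din$b + din$c),
        mean_site_fst = mean(din$fst),
        stringsAsFactors = FALSE)
    }
  }
  if (length(out) == 0)
    return(data.frame(region_id = character(), chrom = character(),
                      first_outlier_pos = integer(),
                      last_outlier_pos = integer(), length = integer(),
                      n_snps = integer(), n_outliers = integer(),
                      region_fst = numeric(), mean_site_fst = numeric(),
                      stringsAsFactors = FALSE))
  res <- do.call(rbind, out)
  res <- res[order(res$chrom, res$first_outlier_pos), , drop = FALSE]
  counts <- stats::ave(seq_len(nrow(res)), res$chrom, FUN = seq_along)
  nper <- table(res$chrom)
  res$region_id <- ifelse(nper[res$chrom] > 1,
                          paste0("r", res$chrom, ".", counts),
                          paste0("r", res$chrom))
  rownames(res) <- NULL
  res[, c("region_id", "chrom", "first_outlier_pos", "last_outlier_pos",
          "length", "n_snps", "n_outliers", "region_fst", "mean_site_fst")]
}

#' Outlier SNP positions of a region
#'
#' @param track An `fst_track`.
#' @param region_row One row of the [delineate_regions()] output.
#' @param threshold Outlier threshold used in the scan.
#' @return Integer vector of positions.
#' @export
region_outlier_positions <- function(track, region_row, threshold = 0.5) {
  tr <- track[track$chrom == region_row$chrom & track$defined &
                track$fst > threshold &
                track$pos >= region_row$first_outlier_pos &
                track$pos <= region_row$last_outlier_pos, , drop = FALSE]
  tr$pos
}

#' Genotype composition of samples at a region's outlier SNPs
#'
#' Counts, per sample, the number of hom-ref (0/0), het (0/1), hom-alt
#' (1/1) and missing genotypes across the given outlier positions.
#'
#' @param vm A `variant_matrix`.
#' @param chrom Chromosome of the region.
#' @param positions Outlier SNP positions (see
#'   [region_outlier_positions()]).
#' @param samples Sample ids (default all).
#' @param region_id Label recorded in the output.
#' @return Data frame (class `haplotype_calls`) with counts and fractions
#'   per sample.
#' @export
genotype_composition <- function(vm, chrom, positions, samples = NULL,
                                 region_id = NA_character_) {
  idx <- which(vm$chrom == chrom & vm$pos %in% positions)
  g <- vm$geno[idx, , drop = FALSE]
  if (!is.null(samples)) g <- g[, samples, drop = FALSE]
  n00 <- colSums(g == 0L, na.rm = TRUE)
  n01 <- colSums(g == 1L, na.rm = TRUE)
  n11 <- colSums(g == 2L, na.rm = TRUE)
  nmiss <- colSums(is.na(g))
  tot <- n00 + n01 + n11
  out <- data.frame(sample = colnames(g), region_id = region_id,
                    n00 = n00, n01 = n01, n11 = n11, n_missing = nmiss,
                    f00 = ifelse(tot > 0, n00 / tot, NA_real_),
                    f01 = ifelse(tot > 0, n01 / tot, NA_real_),
                    f11 = ifelse(tot > 0, n11 / tot, NA_real_),
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  attr(out, "n_outliers") <- length(idx)
  class(out) <- c("haplotype_calls", "data.frame")
  out
}

#' Group-level genotype-composition percentages
#'
#' Aggregate percentage of each genotype class per group, with denominator
#' `n_outliers x n_samples` (missing genotypes included in the
#' denominator), as used to summarize hom-alt enrichment in one group
#' versus the other.
#'
#' @param calls A `haplotype_calls` data frame (counts present).
#' @param groups Named list mapping group label to sample ids, or a factor
#'   / character vector aligned with `calls$sample`.
#' @param n_outliers Number of outlier SNPs (default: the attribute stored
#'   on `calls`).
#' @return Data frame with per-group counts and percentages of 0/0, 0/1,
#'   1/1.
#' @export
composition_summary <- function(calls, groups, n_outliers = NULL) {
  if (is.null(n_outliers)) n_outliers <- attr(calls, "n_outliers")
  if (is.null(n_outliers)) stop("n_outliers not available")
  if (!is.list(groups)) {
    groups <- split(calls$sample, groups)
  }
  do.call(rbind, lapply(names(groups), function(gname) {
    d <- calls[calls$sample %in% groups[[gname]], , drop = FALSE]
    denom <- n_outliers * nrow(d)
    data.frame(group = gname, n_samples = nrow(d), n_outliers = n_outliers,
               n00 = sum(d$n00), n01 = sum(d$n01), n11 = sum(d$n11),
               pct00 = 100 * sum(d$n00) / denom,
               pct01 = 100 * sum(d$n01) / denom,
               pct11 = 100 * sum(d$n11) / denom,
               stringsAsFactors = FALSE)
  }))
}

#' Classify per-sample haplotypes from genotype composition
#'
#' A sample is `het` when its heterozygote fraction exceeds
#' `het_threshold` (default 0.88, i.e. "heterozygous for more than 88% of
#' genotypes"), `hom_alt`/`hom_ref` when the corresponding fraction is at
#' least `hom_threshold`, and `ambiguous` otherwise. Dosage (copies of the
#' non-reference haplotype) is 0/1/2 for hom_ref/het/hom_alt; ambiguous
#' samples receive a majority-rule dosage, with exact ties flagged and
#' left `NA`. Samples with zero counted genotypes are ambiguous.
#'
#' @param calls A `haplotype_calls` data frame with counts.
#' @param het_threshold Het fraction above which a sample is called `het`.
#' @param hom_threshold Hom fraction at or above which a sample is called
#'   homozygous. The default 0.60 is a clear-majority rule: in blocks with
#'   appreciable within-haplotype variation a substantial minority of
#'   outlier SNPs segregate within one haplotype class, so true
#'   homozygotes match well below 100% of outlier genotypes (compositions
#'   around 75% hom-alt are typical for such regions).
#' @return The input with `class`, `dosage` and `tie` columns added.
#' @export
classify_haplotypes <- function(calls, het_threshold = 0.88,
                                hom_threshold = 0.60) {
  tot <- calls$n00 + calls$n01 + calls$n11
  cls <- rep("ambiguous", nrow(calls))
  cls[tot > 0 & calls$f01 > het_threshold] <- "het"
  cls[tot > 0 & calls$f11 >= hom_threshold] <- "hom_alt"
  cls[tot > 0 & calls$f00 >= hom_threshold] <- "hom_ref"
  dosage <- rep(NA_integer_, nrow(calls))
  dosage[cls == "hom_ref"] <- 0L
  dosage[cls == "het"] <- 1L
  dosage[cls == "hom_alt"] <- 2L
  tie <- rep(FALSE, nrow(calls))
  amb <- which(cls == "ambiguous" & tot > 0)
  if (length(amb)) {
    cnt <- as.matrix(calls[amb, c("n00", "n01", "n11"), drop = FALSE])
    for (k in seq_along(amb)) {
      mx <- max(cnt[k, ])
      winners <- which(cnt[k, ] == mx)
      if (length(winners) == 1) dosage[amb[k]] <- winners - 1L
      else tie[amb[k]] <- TRUE
    }
  }
  calls$class <- cls
  calls$dosage <- dosage
  calls$tie <- tie
  calls
}

#' Haplotype frequencies per group
#'
#' Frequency of the non-reference (alt-enriched) haplotype per group:
#' `sum(dosage) / (2 * n)` over classified samples. Samples with `NA`
#' dosage (unresolved ambiguous calls) are excluded with a warning.
#'
#' @param calls Classified `haplotype_calls` (with `dosage`).
#' @param sample_table Sample metadata (columns `sample` and the grouping
#'   column).
#' @param group_by Metadata column to group by (default `"habitat"`).
#' @return Data frame with `group`, `n`, `frequency`.
#' @export
haplotype_frequencies <- function(calls, sample_table, group_by = "habitat") {
  if (any(is.na(calls$dosage))) {
    warning(sum(is.na(calls$dosage)),
            " sample(s) without dosage excluded from frequencies")
    calls <- calls[!is.na(calls$dosage), , drop = FALSE]
  }
  grp <- sample_table[[group_by]][match(calls$sample, sample_table$sample)]
  out <- do.call(rbind, lapply(split(seq_len(nrow(calls)), grp), function(i) {
    data.frame(group = grp[i[1]], n = length(i),
               frequency = sum(calls$dosage[i]) / (2 * length(i)),
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' Region-level FST from haplotype dosages
#'
#' Treats the whole region as one biallelic locus whose per-sample
#' genotype is the classified haplotype dosage, and applies the
#' single-locus Weir-Cockerham estimator (heterozygote fraction = fraction
#' of dosage-1 samples).
#'
#' @param calls Classified `haplotype_calls`.
#' @param sample_table Sample metadata.
#' @param group_by Metadata column defining the two groups (default
#'   `"habitat"`).
#' @return A one-row data frame from [wc_fst_site()] with an `fst` column.
#' @export
region_fst_from_dosage <- function(calls, sample_table, group_by = "habitat") {
  calls <- calls[!is.na(calls$dosage), , drop = FALSE]
  grp <- sample_table[[group_by]][match(calls$sample, sample_table$sample)]
  gl <- sort(unique(grp))
  if (length(gl) != 2) stop("need exactly two groups")
  st <- lapply(gl, function(g) {
    d <- calls$dosage[grp == g]
    c(p = sum(d) / (2 * length(d)), h = mean(d == 1L), n = length(d))
  })
  res <- wc_fst_site(p = c(st[[1]]["p"], st[[2]]["p"]),
                     h = c(st[[1]]["h"], st[[2]]["h"]),
                     n = c(st[[1]]["n"], st[[2]]["n"]))
  if (!res$defined) warning("region is monomorphic across groups; FST undefined")
  res
}

#' Assign unplaced scaffolds to candidate regions
#'
#' Classifies every sample from each unplaced scaffold's outlier SNPs and
#' compares the resulting dosage vector against each candidate region's
#' dosage vector. A scaffold is assigned to the region with maximal
#' concordance when that concordance reaches `min_concordance` and the
#' scaffold carries at least `min_snps` outlier SNPs; otherwise it is
#' unassigned.
#'
#' @param vm A `variant_matrix` covering the unplaced scaffolds.
#' @param unplaced_track An `fst_track` over the unplaced scaffolds.
#' @param reference_calls Named list of classified `haplotype_calls`, one
#'   per candidate region.
#' @param threshold Outlier threshold (default 0.5).
#' @param min_snps Minimum outlier SNP count (default 2).
#' @param min_concordance Minimum per-sample dosage concordance (default
#'   0.8).
#' @param het_threshold,hom_threshold Passed to [classify_haplotypes()].
#' @return Data frame with `scaffold`, `n_outliers`, `best_region`,
#'   `concordance`, `assigned`.
#' @export
assign_unplaced <- function(vm, unplaced_track, reference_calls,
                            threshold = 0.5, min_snps = 2,
                            min_concordance = 0.8,
                            het_threshold = 0.88, hom_threshold = 0.60) {
  scaffolds <- unique(unplaced_track$chrom)
  out <- list()
  for (sc in scaffolds) {
    tr <- unplaced_track[unplaced_track$chrom == sc & unplaced_track$defined &
                           unplaced_track$fst > threshold, , drop = FALSE]
    if (nrow(tr) == 0) next
    calls <- genotype_composition(vm, sc, tr$pos, region_id = sc)
    calls <- classify_haplotypes(calls, het_threshold, hom_threshold)
    best <- NA_character_; bestc <- NA_real_
    for (rn in names(reference_calls)) {
      ref <- reference_calls[[rn]]
      d1 <- calls$dosage[match(ref$sample, calls$sample)]
      d2 <- ref$dosage
      ok <- !is.na(d1) & !is.na(d2)
      conc <- if (any(ok)) mean(d1[ok] == d2[ok]) else NA_real_
      if (!is.na(conc) && (is.na(bestc) || conc > bestc)) {
        bestc <- conc; best <- rn
      }
    }
    assigned <- !is.na(bestc) && bestc >= min_concordance &&
      nrow(tr) >= min_snps
    out[[length(out) + 1]] <- data.frame(
      scaffold = sc, n_outliers = nrow(tr),
      best_region = best, concordance = bestc,
      assigned = if (assigned) best else "unassigned",
      stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Depth and coverage masking
#'
#' Removes sites whose depth (in the chosen scope column of the depth
#' table) falls outside `[low_frac, high_frac]` times the cohort-average
#' depth, or whose genotyped-sample fraction is below `min_called`.
#'
#' @param vm A `variant_matrix`.
#' @param depth Depth table (see [read_depth_table()]).
#' @param scope Name of the depth column to filter on (default
#'   `"depth"`).
#' @param low_frac,high_frac Retained depth band relative to the cohort
#'   average (defaults 0.3 and 3.0).
#' @param min_called Minimum genotyped-sample fraction (default 0.5; only
#'   applied when the table has a `called_frac` column).
#' @param strict Error (instead of warn and retain) on sites absent from
#'   the depth table.
#' @return The filtered `variant_matrix`; attribute `mask_report` holds
#'   retained fractions and counts.
#' @export
depth_mask <- function(vm, depth, scope = "depth", low_frac = 0.3,
                       high_frac = 3.0, min_called = 0.5, strict = FALSE) {
  if (!scope %in% names(depth)) stop("no depth column named ", scope)
  key <- paste(vm$chrom, vm$pos)
  m <- match(key, paste(depth$chrom, depth$pos))
  absent <- is.na(m)
  if (any(absent)) {
    if (strict) stop(sum(absent), " site(s) missing from the depth table")
    warning(sum(absent), " site(s) missing from the depth table; retained")
  }
  d <- depth[[scope]][m]
  avg <- mean(depth[[scope]], na.rm = TRUE)
  keep <- absent | (d >= low_frac * avg & d <= high_frac * avg)
  if ("called_frac" %in% names(depth)) {
    cf <- depth$called_frac[m]
    keep <- keep & (absent | cf >= min_called)
  }
  out <- vm_subset(vm, which(keep))
  attr(out, "mask_report") <- list(
    n_in = length(key), n_retained = sum(keep),
    retained_fraction = mean(keep), cohort_average = avg)
  out
}

#' Per-region retained fraction after masking
#'
#' @param vm_before,vm_after Variant matrices before and after a mask.
#' @param regions Region-call data frame.
#' @return Data frame with `region_id` and `retained_fraction`.
#' @export
mask_retention_by_region <- function(vm_before, vm_after, regions) {
  do.call(rbind, lapply(seq_len(nrow(regions)), function(k) {
    r <- region(regions$chrom[k], regions$first_outlier_pos[k],
                regions$last_outlier_pos[k])
    nb <- length(vm_site_index(vm_before, r))
    na_ <- length(vm_site_index(vm_after, r))
    data.frame(region_id = regions$region_id[k],
               retained_fraction = if (nb > 0) na_ / nb else NA_real_,
               stringsAsFactors = FALSE)
  }))
}
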