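# Data model and readers/writers: VariantMatrix, SampleTable, gene models,
# ancestral table, depth table; VCF/TSV/GFF3/BED surfaces.
#
# Internal coordinates are 1-based inclusive (VCF convention); BED export
# is the only 0-based half-open surface.

#' Construct a variant matrix
#'
#' Container for biallelic SNP genotypes: per-site chromosome, 1-based
#' position, single-nucleotide ref/alt alleles, site quality and a sites x
#' samples matrix of alt-allele dosages (0/1/2, `NA` = missing).
#'
#' @param chrom Character vector of chromosome/scaffold names per site.
#' @param pos Integer vector of 1-based positions, strictly increasing
#'   within each chromosome.
#' @param ref,alt Single-nucleotide alleles per site.
#' @param qual Numeric site quality (optional; `NA` allowed).
#' @param geno Integer matrix (sites x samples) of dosages with sample ids
#'   as column names.
#' @return An object of class `variant_matrix`.
#' @export
variant_matrix <- function(chrom, pos, ref, alt, qual = NULL, geno) {
  geno <- as.matrix(geno)
  n <- length(pos)
  stopifnot(length(chrom) == n, length(ref) == n, length(alt) == n,
            nrow(geno) == n)
  if (is.null(qual)) qual <- rep(NA_real_, n)
  stopifnot(length(qual) == n)
  if (is.null(colnames(geno)))
    colnames(geno) <- paste0("S", seq_len(ncol(geno)))
  vals <- geno[!is.na(geno)]
  if (length(vals) && !all(vals %in% 0:2))
    stop("genotype dosages must be 0, 1, 2 or NA")
  bad_allele <- !(ref %in% c("A", "C", "G", "T")) |
    !(alt %in% c("A", "C", "G", "T")) | ref == alt
  if (any(bad_allele)) stop("alleles must be distinct single nucleotides")
  for (ch in unique(chrom)) {
    pp <- pos[chrom == ch]
    if (any(diff(pp) <= 0))
      stop("positions must be strictly increasing within chromosome ", ch)
  }
  structure(list(chrom = as.character(chrom), pos = as.integer(pos),
                 ref = as.character(ref), alt = as.character(alt),
                 qual = as.numeric(qual),
                 geno = matrix(as.integer(geno), nrow = n,
                               dimnames = dimnames(geno))),
            class = "variant_matrix")
}

#' @exportS3Method base::print
print.variant_matrix <- function(x, ...) {
  cat(sprintf("variant_matrix: %d SNPs x %d samples on %d chromosome(s)\n",
              length(x$pos), ncol(x$geno), length(unique(x$chrom))))
  invisible(x)
}

#' @exportS3Method
dim.variant_matrix <- function(x) dim(x$geno)

#' Genomic region (1-based, inclusive)
#'
#' @param chrom Chromosome name.
#' @param start,end 1-based inclusive bounds, `start <= end`.
#' @return A list of class `region`.
#' @export
region <- function(chrom, start, end) {
  stopifnot(start >= 1, end >= start)
  structure(list(chrom = as.character(chrom), start = as.integer(start),
                 end = as.integer(end)), class = "region")
}

#' Site indices of a variant matrix inside a region
#'
#' @param vm A `variant_matrix`.
#' @param region A [region()], or `NULL` for all sites.
#' @return Integer vector of site indices.
#' @export
vm_site_index <- function(vm, region = NULL) {
  if (is.null(region)) return(seq_along(vm$pos))
  which(vm$chrom == region$chrom & vm$pos >= region$start &
          vm$pos <= region$end)
}

# genotype submatrix for samples/region, keeping site order
vm_genotypes <- function(vm, samples = NULL, region = NULL) {
  idx <- vm_site_index(vm, region)
  g <- vm$geno[idx, , drop = FALSE]
  if (!is.null(samples)) {
    missing <- setdiff(samples, colnames(g))
    if (length(missing))
      stop("unknown sample id(s): ", paste(missing, collapse = ", "))
    g <- g[, samples, drop = FALSE]
  }
  g
}

#' Subset a variant matrix by site index
#'
#' @param vm A `variant_matrix`.
#' @param idx Integer site indices (kept in order).
#' @return A `variant_matrix` with the selected sites.
#' @export
vm_subset <- function(vm, idx) {
  variant_matrix(vm$chrom[idx], vm$pos[idx], vm$ref[idx], vm$alt[idx],
                 vm$qual[idx], vm$geno[idx, , drop = FALSE])
}

#' Load a VCF + sample metadata into the internal data model
#'
#' Reads a VCF 4.x file, retains biallelic SNP records only (multiallelic
#' sites and indels are dropped with a logged count), extracts GT-based
#' alt-allele dosages, and attaches the sample metadata table. Sample
#' order in the matrix follows the VCF header; every VCF sample must be
#' present in the metadata.
#'
#' @param vcf_path Path to a VCF file.
#' @param metadata_path Path to a TSV with columns `sample`, `locality`,
#'   `habitat`, `altitude`, `population`.
#' @param quiet Suppress the dropped-record message.
#' @return A list with `vm` (a [variant_matrix()]) and `samples` (the
#'   metadata data frame, ordered as the VCF header).
#' @export
load_dataset <- function(vcf_path, metadata_path, quiet = FALSE) {
  v <- vcfR::read.vcfR(vcf_path, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  if (nrow(v@gt) == 0 || !any(grepl("GT", v@gt[, "FORMAT"])))
    stop("VCF has no GT field")
  ref <- fix[, "REF"]; alt <- fix[, "ALT"]
  keep <- !is.na(alt) & ref %in% c("A", "C", "G", "T") &
    alt %in% c("A", "C", "G", "T")
  if (!quiet && any(!keep))
    message(sum(!keep), " record(s) dropped (multiallelic or not a SNP)")
  gt <- vcfR::extract.gt(v, element = "GT")
  meta <- read_sample_table(metadata_path)
  absent <- setdiff(colnames(gt), meta$sample)
  if (length(absent))
    stop("VCF sample(s) missing from metadata: ",
         paste(absent, collapse = ", "))
  meta <- meta[match(colnames(gt), meta$sample), , drop = FALSE]
  rownames(meta) <- NULL
  gt <- gt[keep, , drop = FALSE]
  dos <- gt_to_dosage(gt)
  dimnames(dos) <- list(NULL, colnames(gt))
  qual <- suppressWarnings(as.numeric(fix[keep, "QUAL"]))
  vm <- variant_matrix(chrom = fix[keep, "CHROM"],
                       pos = as.integer(fix[keep, "POS"]),
                       ref = ref[keep], alt = alt[keep],
                       qual = qual, geno = dos)
  attr(vm, "n_dropped") <- sum(!keep)
  list(vm = vm, samples = meta)
}

# GT strings -> dosage via a lookup over the distinct GT values present
gt_to_dosage <- function(gt) {
  u <- unique(as.vector(gt))
  lut <- vapply(u, function(s) {
    if (is.na(s) || s %in% c(".", "./.", ".|.")) return(NA_integer_)
    al <- strsplit(s, "[/|]")[[1]]
    if (any(al == ".")) return(NA_integer_)
    sum(al == "1")
  }, integer(1))
  m <- matrix(lut[match(as.vector(gt), u)], nrow = nrow(gt),
              dimnames = dimnames(gt))
  m
}

#' Read a sample metadata table
#'
#' @param path TSV with columns `sample`, `locality`, `habitat`,
#'   `altitude`, `population`; habitat must be `highland` or `lowland`.
#' @return Data frame (one row per sample, unique ids).
#' @export
read_sample_table <- function(path) {
  meta <- read.delim(path, stringsAsFactors = FALSE)
  need <- c("sample", "locality", "habitat", "altitude", "population")
  miss <- setdiff(need, names(meta))
  if (length(miss))
    stop("metadata missing column(s): ", paste(miss, collapse = ", "))
  if (anyDuplicated(meta$sample)) stop("duplicate sample ids in metadata")
  bad <- setdiff(unique(meta$habitat), c("highland", "lowland"))
  if (length(bad))
    stop("habitat must be 'highland' or 'lowland'; found: ",
         paste(bad, collapse = ", "))
  meta
}

#' Quality and blacklist site filters
#'
#' Removes sites with `qual <= min_qual` (the conventional "QUAL > 50"
#' cutoff is the default) and sites listed in a blacklist of known
#' unreliable positions (e.g. positions heterozygous in haploid drones).
#'
#' @param vm A `variant_matrix`.
#' @param min_qual Sites with quality less than or equal to this are
#'   removed (`NA` quality is retained).
#' @param blacklist Optional data frame with columns `chrom`, `pos`.
#' @return Filtered `variant_matrix`; attribute `removed` holds the per-
#'   filter removal counts.
#' @export
apply_site_filters <- function(vm, min_qual = 50, blacklist = NULL) {
  keep_q <- is.na(vm$qual) | vm$qual > min_qual
  keep_b <- rep(TRUE, length(vm$pos))
  if (!is.null(blacklist) && nrow(blacklist) > 0) {
    key <- paste(vm$chrom, vm$pos)
    keep_b <- !(key %in% paste(blacklist$chrom, blacklist$pos))
  }
  out <- vm_subset(vm, which(keep_q & keep_b))
  attr(out, "removed") <- c(qual = sum(!keep_q),
                            blacklist = sum(keep_q & !keep_b))
  out
}

#' Load gene models (GFF3) and an ancestral-allele table
#'
#' CDS features are grouped per transcript via their `Parent` attribute
#' and ordered 5' to 3' in transcript orientation (ascending coordinates
#' on the plus strand, descending on the minus strand). Transcripts whose
#' CDS strand is unknown are skipped with a warning. The ancestral table
#' is the product of a whole-genome outgroup alignment (chrom, pos,
#' outgroup allele), consumed as-is.
#'
#' @param gff_path Path to a GFF3 file with CDS features.
#' @param ancestral_path Path to a TSV with columns `chrom`, `pos`,
#'   `allele` (optional; `NULL` to skip).
#' @return A list with `genes` (data frame: transcript, gene, chrom,
#'   strand, start, end, phase, exon_rank) and `ancestral` (data frame or
#'   `NULL`).
#' @export
load_annotations <- function(gff_path, ancestral_path = NULL) {
  g <- ape::read.gff(gff_path, GFF3 = TRUE)
  cds <- g[g$type == "CDS", , drop = FALSE]
  if (nrow(cds) == 0) {
    genes <- data.frame(transcript = character(), gene = character(),
                        chrom = character(), strand = character(),
                        start = integer(), end = integer(),
                        phase = integer(), exon_rank = integer())
  } else {
    parent <- attr_field(cds$attributes, "Parent")
    gene <- attr_field(cds$attributes, "gene")
    strand <- as.character(cds$strand)
    unknown <- is.na(strand) | !(strand %in% c("+", "-"))
    if (any(unknown)) {
      warning("skipping transcript(s) with unknown strand: ",
              paste(unique(parent[unknown]), collapse = ", "))
      skip <- parent %in% unique(parent[unknown])
      cds <- cds[!skip, , drop = FALSE]
      parent <- parent[!skip]; gene <- gene[!skip]; strand <- strand[!skip]
    }
    genes <- data.frame(transcript = parent, gene = gene,
                        chrom = as.character(cds$seqid),
                        strand = strand,
                        start = cds$start, end = cds$end,
                        phase = suppressWarnings(as.integer(as.character(cds$phase))),
                        stringsAsFactors = FALSE)
    genes$phase[is.na(genes$phase)] <- 0L
    ord <- order(genes$transcript, ifelse(genes$strand == "+", 1, -1) * genes$start)
    genes <- genes[ord, , drop = FALSE]
    genes$exon_rank <- stats::ave(seq_len(nrow(genes)), genes$transcript,
                                  FUN = seq_along)
    rownames(genes) <- NULL
  }
  anc <- NULL
  if (!is.null(ancestral_path)) {
    anc <- read.delim(ancestral_path, stringsAsFactors = FALSE)
    need <- c("chrom", "pos", "allele")
    if (!all(need %in% names(anc)))
      stop("ancestral table must have columns chrom, pos, allele")
    anc$chrom <- as.character(anc$chrom)
    if (anyDuplicated(paste(anc$chrom, anc$pos)))
      stop("ancestral table has duplicate sites")
  }
  list(genes = genes, ancestral = anc)
}

attr_field <- function(attributes, field) {
  pat <- paste0("(^|;)\\s*", field, "=([^;]+)")
  hit <- regmatches(attributes, regexpr(pat, attributes))
  out <- rep(NA_character_, length(attributes))
  has <- grepl(pat, attributes)
  out[has] <- sub(pat, "\\2", regmatches(attributes, regexpr(pat, attributes)))
  out
}

#' Fraction of variant sites covered by the ancestral table
#'
#' @param ancestral Ancestral table (chrom, pos, allele).
#' @param vm A `variant_matrix`.
#' @return Fraction in `[0, 1]`.
#' @export
ancestral_coverage <- function(ancestral, vm) {
  mean(paste(vm$chrom, vm$pos) %in%
         paste(ancestral$chrom, ancestral$pos))
}

#' Read a per-site depth table
#'
#' @param path TSV with columns `chrom`, `pos`, one numeric depth column
#'   per group (or a single `depth` column), and optionally `called_frac`.
#' @return Data frame.
#' @export
read_depth_table <- function(path) {
  d <- read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("chrom", "pos") %in% names(d)))
    stop("depth table must have chrom and pos columns")
  num <- setdiff(names(d), c("chrom", "pos"))
  if (any(vapply(d[num], function(x) any(x < 0, na.rm = TRUE), logical(1))))
    stop("depths must be non-negative")
  d$chrom <- as.character(d$chrom)
  d
}

#' Write a results table as TSV
#'
#' @param results Data frame with named columns.
#' @param path Output path.
#' @return Invisibly, the path.
#' @export
write_tables <- function(results, path) {
  write.table(results, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Convert region calls to BED (0-based half-open)
#'
#' The internal convention is 1-based inclusive; BED starts are therefore
#' `start - 1` and BED ends equal the inclusive end.
#'
#' @param regions Data frame with `chrom`, `first_outlier_pos`,
#'   `last_outlier_pos` (as from [delineate_regions()]) or `chrom`,
#'   `start`, `end`.
#' @return Data frame with columns `chrom`, `start`, `end`, `name`.
#' @export
regions_to_bed <- function(regions) {
  s <- if ("first_outlier_pos" %in% names(regions))
    regions$first_outlier_pos else regions$start
  e <- if ("last_outlier_pos" %in% names(regions))
    regions$last_outlier_pos else regions$end
  nm <- if ("region_id" %in% names(regions)) regions$region_id
  else paste0("region", seq_len(nrow(regions)))
  data.frame(chrom = regions$chrom, start = s - 1L, end = e, name = nm,
             stringsAsFactors = FALSE)
}

#' Write BED lines for region calls
#'
#' @param regions See [regions_to_bed()].
#' @param path Output path.
#' @return Invisibly, the path.
#' @export
write_region_bed <- function(regions, path) {
  bed <- regions_to_bed(regions)
  write.table(bed, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  invisible(path)
}

#' Write a variant matrix as a minimal VCF 4.2 file
#'
#' Emits GT-only diploid records (unphased). Used by the synthetic-data
#' generator; round-trips through [load_dataset()].
#'
#' @param vm A `variant_matrix`.
#' @param path Output path.
#' @return Invisibly, the path.
#' @export
write_vcf <- function(vm, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("##fileformat=VCFv4.2",
               "##source=hapblockr",
               '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">'),
             con)
  writeLines(paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                     "INFO", "FORMAT", colnames(vm$geno)), collapse = "\t"),
             con)
  gtmap <- c("0/0", "0/1", "1/1")
  gt <- matrix("./.", nrow = nrow(vm$geno), ncol = ncol(vm$geno))
  ok <- !is.na(vm$geno)
  gt[ok] <- gtmap[vm$geno[ok] + 1L]
  qual <- ifelse(is.na(vm$qual), ".", format(vm$qual, trim = TRUE,
                                             scientific = FALSE))
  body <- paste(vm$chrom, vm$pos, ".", vm$ref, vm$alt, qual, "PASS", ".",
                "GT", apply(gt, 1, paste, collapse = "\t"), sep = "\t")
  writeLines(body, con)
  invisible(path)
}
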