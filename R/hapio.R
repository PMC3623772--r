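#' Construct a phased haplotype matrix
#'
#' The central data container: a matrix of 0/1 alleles with rows for
#' haplotypes (two per diploid sample, in sample order) and columns for
#' biallelic sites at strictly increasing physical positions on one contig.
#' Allele 0 is REF and allele 1 is ALT as in the source VCF; ancestral-state
#' polarization is never implicit.
#'
#' @param alleles integer/numeric matrix of 0 and 1; rows are haplotypes,
#'   columns are sites. No missing values are allowed.
#' @param positions 1-based physical coordinates, strictly increasing, one
#'   per column.
#' @param contig chromosome name.
#' @param sample_ids one id per diploid sample; `nrow(alleles)` must equal
#'   `2 * length(sample_ids)`.
#' @param population_of optional named character vector mapping sample id to
#'   population label.
#' @param ref,alt optional REF/ALT allele strings per site (defaults "A"/"G"),
#'   kept so that VCF output round-trips.
#' @return an object of class `HaplotypeMatrix` with fields `alleles`,
#'   `positions`, `contig`, `sample_ids`, `haplotype_ids`, `population_of`,
#'   `monomorphic` (logical per site), `ref`, `alt`.
#' @export
haplotype_matrix <- function(alleles, positions, contig, sample_ids,
                             population_of = NULL, ref = NULL, alt = NULL) {
  alleles <- as.matrix(alleles)
  storage.mode(alleles) <- "integer"
  if (anyNA(alleles)) stop("alleles must not contain missing values")
  if (length(alleles) && !all(alleles %in% c(0L, 1L)))
    stop("alleles must be coded 0 (REF) / 1 (ALT)")
  if (ncol(alleles) != length(positions))
    stop("one position per site column required")
  positions <- as.integer(positions)
  if (length(positions) > 1 && any(diff(positions) <= 0))
    stop("positions must be strictly increasing")
  if (nrow(alleles) != 2L * length(sample_ids))
    stop("need exactly 2 haplotype rows per diploid sample")
  hap_ids <- if (length(sample_ids))
    paste0(rep(sample_ids, each = 2L), "_", rep(1:2, length(sample_ids)))
  else character(0)
  rownames(alleles) <- hap_ids
  if (!is.null(population_of)) {
    population_of <- population_of[sample_ids]
    names(population_of) <- sample_ids
  }
  cs <- if (nrow(alleles)) colSums(alleles) else integer(0)
  mono <- cs == 0L | cs == nrow(alleles)
  if (is.null(ref)) ref <- rep("A", length(positions))
  if (is.null(alt)) alt <- rep("G", length(positions))
  structure(list(
    alleles = alleles, positions = positions, contig = as.character(contig),
    sample_ids = as.character(sample_ids), haplotype_ids = hap_ids,
    population_of = population_of, monomorphic = mono,
    ref = ref, alt = alt
  ), class = "HaplotypeMatrix")
}

#' @export
print.HaplotypeMatrix <- function(x, ...) {
  cat(sprintf("HaplotypeMatrix: %d haplotypes (%d samples) x %d sites on %s",
              nrow(x$alleles), length(x$sample_ids), ncol(x$alleles), x$contig))
  if (length(x$positions))
    cat(sprintf(" [%s-%s]", format(min(x$positions), big.mark = ","),
                format(max(x$positions), big.mark = ",")))
  cat("\n")
  if (!is.null(x$population_of))
    cat("populations:", paste(names(table(x$population_of)), collapse = " "), "\n")
  invisible(x)
}

#' Number of haplotypes / sites
#' @param m a `HaplotypeMatrix`
#' @export
n_haplotypes <- function(m) nrow(m$alleles)

#' @rdname n_haplotypes
#' @export
n_sites <- function(m) ncol(m$alleles)

#' Population label per haplotype row
#'
#' Expands the per-sample population map to one label per haplotype row.
#' @param m a `HaplotypeMatrix` with `population_of` set
#' @return character vector, length `n_haplotypes(m)`
#' @export
haplotype_populations <- function(m) {
  if (is.null(m$population_of)) stop("no population assignments; see set_populations()")
  rep(unname(m$population_of[m$sample_ids]), each = 2L)
}

#' Attach population labels from a panel
#' @param m a `HaplotypeMatrix`
#' @param panel a data frame as returned by [read_population_panel()]
#' @export
set_populations <- function(m, panel) {
  pop <- stats::setNames(panel$pop, panel$sample)
  missing <- setdiff(m$sample_ids, panel$sample)
  if (length(missing))
    stop("samples absent from panel: ", paste(missing, collapse = ", "))
  m$population_of <- stats::setNames(unname(pop[m$sample_ids]), m$sample_ids)
  m
}

#' Restrict a haplotype matrix to one population's samples
#' @param m a `HaplotypeMatrix` with population assignments
#' @param pop population label
#' @return a `HaplotypeMatrix` over the samples assigned to `pop`
#' @export
subset_population <- function(m, pop) {
  keep <- m$sample_ids[m$population_of[m$sample_ids] == pop]
  if (!length(keep)) stop("no samples in population '", pop, "'")
  rows <- which(rep(m$sample_ids, each = 2L) %in% keep)
  haplotype_matrix(m$alleles[rows, , drop = FALSE], m$positions, m$contig,
                   keep, population_of = m$population_of[keep],
                   ref = m$ref, alt = m$alt)
}

#' 1-based inclusive genomic interval
#' @param contig chromosome name
#' @param start,end 1-based inclusive bounds, `start <= end`
#' @export
genomic_interval <- function(contig, start, end) {
  start <- as.integer(start); end <- as.integer(end)
  if (is.na(start) || is.na(end) || start > end) stop("need start <= end")
  structure(list(contig = as.character(contig), start = start, end = end),
            class = "GenomicInterval")
}

#' @export
print.GenomicInterval <- function(x, ...) {
  cat(sprintf("%s:%s-%s (%s bp)\n", x$contig, format(x$start, big.mark = ","),
              format(x$end, big.mark = ","),
              format(interval_length(x), big.mark = ",")))
  invisible(x)
}

#' Length of a 1-based inclusive interval
#' @param iv a `GenomicInterval`
#' @export
interval_length <- function(iv) iv$end - iv$start + 1L

#' Read phased genotypes from a VCF file
#'
#' Loads biallelic SNPs with fully phased diploid genotypes into a
#' [haplotype_matrix()]. Multiallelic sites, indels, sites with any missing
#' or unphased genotype, and duplicated positions are excluded (never
#' imputed) and tallied in the attached load report.
#'
#' @param path path to a VCF 4.x file (plain text or bgzip)
#' @param region optional [genomic_interval()]; only sites inside it are kept.
#'   If the region's contig is absent from the file an empty matrix is
#'   returned with `region_contig_absent = TRUE` in the load report, with a
#'   warning.
#' @return a `HaplotypeMatrix`; `load_report(m)` retrieves a list with counts
#'   `n_records`, `n_kept`, `n_multiallelic`, `n_indel`,
#'   `n_missing_or_unphased`, `n_duplicate_position`, `n_outside_region`.
#' @export
read_phased_vcf <- function(path, region = NULL) {
  vcf <- tryCatch(vcfR::read.vcfR(path, verbose = FALSE),
                  error = function(e) stop("malformed VCF '", path, "': ",
                                           conditionMessage(e)))
  fix <- vcfR::getFIX(vcf)
  if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1, dimnames = list(NULL, names(fix)))
  gt <- vcf@gt
  samples <- colnames(gt)[-1]
  n_rec <- nrow(fix)
  chrom <- fix[, "CHROM"]; pos <- as.integer(fix[, "POS"])
  ref <- fix[, "REF"]; alt <- fix[, "ALT"]
  report <- list(n_records = n_rec, n_kept = 0L, n_multiallelic = 0L,
                 n_indel = 0L, n_missing_or_unphased = 0L,
                 n_duplicate_position = 0L, n_outside_region = 0L,
                 region_contig_absent = FALSE)

  contigs <- unique(chrom)
  if (is.null(region) && length(contigs) > 1)
    stop("VCF spans multiple contigs (", paste(contigs, collapse = ", "),
         "); supply a region")
  target_contig <- if (is.null(region)) contigs[1] else region$contig
  if (!is.null(region) && !(target_contig %in% contigs)) {
    warning("region contig '", target_contig, "' absent from VCF")
    report$region_contig_absent <- TRUE
    report$n_outside_region <- n_rec
    m <- haplotype_matrix(matrix(0L, 2L * length(samples), 0L), integer(0),
                          target_contig, samples)
    attr(m, "load_report") <- report
    return(m)
  }

  keep <- chrom == target_contig
  if (!is.null(region)) keep <- keep & pos >= region$start & pos <= region$end
  report$n_outside_region <- sum(!keep)

  is_multi <- grepl(",", alt, fixed = TRUE)
  is_indel <- !is_multi & (nchar(ref) != 1L | nchar(alt) != 1L |
                             !(ref %in% c("A", "C", "G", "T")) |
                             !(alt %in% c("A", "C", "G", "T")))
  report$n_multiallelic <- sum(keep & is_multi)
  report$n_indel <- sum(keep & is_indel)
  keep <- keep & !is_multi & !is_indel

  # strip any per-genotype annotations; require fully phased diploid calls
  gt_only <- sub(":.*$", "", gt[, -1, drop = FALSE])
  phased_ok <- matrix(grepl("^[01]\\|[01]$", gt_only), nrow = n_rec)
  site_ok <- rowSums(phased_ok) == length(samples)
  report$n_missing_or_unphased <- sum(keep & !site_ok)
  keep <- keep & site_ok

  dup <- duplicated(pos) & keep
  report$n_duplicate_position <- sum(dup & keep)
  keep <- keep & !dup

  idx <- which(keep)
  idx <- idx[order(pos[idx])]
  report$n_kept <- length(idx)

  n_hap <- 2L * length(samples)
  alle <- matrix(0L, n_hap, length(idx))
  if (length(idx)) {
    g <- gt_only[idx, , drop = FALSE]
    a1 <- substr(g, 1L, 1L); a2 <- substr(g, 3L, 3L)
    # interleave phases so rows follow sample order
    for (j in seq_along(idx)) {
      alle[seq(1L, n_hap, 2L), j] <- as.integer(a1[j, ])
      alle[seq(2L, n_hap, 2L), j] <- as.integer(a2[j, ])
    }
  }
  m <- haplotype_matrix(alle, pos[idx], target_contig, samples,
                        ref = ref[idx], alt = alt[idx])
  attr(m, "load_report") <- report
  m
}

#' Load report of a VCF read
#' @param m a `HaplotypeMatrix` returned by [read_phased_vcf()]
#' @export
load_report <- function(m) attr(m, "load_report")

#' Write a haplotype matrix as a phased VCF
#'
#' Emits a minimal plain-text VCF 4.2 with phased `GT` fields that
#' [read_phased_vcf()] reads back bit-exactly.
#' @param m a `HaplotypeMatrix`
#' @param path output file path
#' @export
write_phased_vcf <- function(m, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("##fileformat=VCFv4.2",
               paste0("##contig=<ID=", m$contig, ">"),
               '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">'),
             con)
  writeLines(paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                     "INFO", "FORMAT", m$sample_ids), collapse = "\t"), con)
  if (n_sites(m)) {
    n_s <- length(m$sample_ids)
    a1 <- m$alleles[seq(1L, 2L * n_s, 2L), , drop = FALSE]
    a2 <- m$alleles[seq(2L, 2L * n_s, 2L), , drop = FALSE]
    for (j in seq_len(n_sites(m))) {
      gts <- paste0(a1[, j], "|", a2[, j])
      writeLines(paste(c(m$contig, m$positions[j], paste0("snp", j),
                         m$ref[j], m$alt[j], ".", "PASS", ".", "GT", gts),
                       collapse = "\t"), con)
    }
  }
  invisible(path)
}

#' Read a sample-to-population panel
#'
#' @param path TSV with header `sample`, `pop`, `super_pop`
#' @return data frame with unique sample ids
#' @export
read_population_panel <- function(path) {
  panel <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("sample", "pop", "super_pop")
  if (!all(need %in% names(panel)))
    stop("panel must have columns: ", paste(need, collapse = ", "))
  dup <- panel$sample[duplicated(panel$sample)]
  if (length(dup))
    stop("duplicated sample id(s) in panel: ", paste(unique(dup), collapse = ", "))
  if (any(!nzchar(panel$pop))) stop("empty population labels in panel")
  panel
}

#' Write a population panel
#' @param panel data frame with `sample`, `pop`, `super_pop`
#' @param path output TSV path
#' @export
write_population_panel <- function(panel, path) {
  utils::write.table(panel[, c("sample", "pop", "super_pop")], path,
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Restrict a haplotype matrix to an interval
#'
#' Keeps the site columns with `iv$start <= position <= iv$end`, preserving
#' order. An empty result is allowed.
#' @param m a `HaplotypeMatrix`
#' @param iv a [genomic_interval()] on `m$contig`
#' @export
extract_region <- function(m, iv) {
  if (!identical(iv$contig, m$contig)) {
    warning("interval contig '", iv$contig, "' differs from matrix contig '",
            m$contig, "'; empty result")
    keep <- rep(FALSE, n_sites(m))
  } else {
    keep <- m$positions >= iv$start & m$positions <= iv$end
  }
  out <- m
  out$alleles <- m$alleles[, keep, drop = FALSE]
  out$positions <- m$positions[keep]
  out$monomorphic <- m$monomorphic[keep]
  out$ref <- m$ref[keep]
  out$alt <- m$alt[keep]
  attr(out, "load_report") <- NULL
  out
}

#' Read genomic intervals from a BED file
#'
#' BED is 0-based half-open on disk; intervals are converted to the package's
#' 1-based inclusive convention at this boundary.
#' @param path BED file path
#' @return data frame with columns `contig`, `start`, `end` (1-based inclusive)
#' @export
read_bed_intervals <- function(path) {
  gr <- rtracklayer::import(path, format = "bed")
  data.frame(contig = as.character(GenomicRanges::seqnames(gr)),
             start = GenomicRanges::start(gr),
             end = GenomicRanges::end(gr),
             stringsAsFactors = FALSE)
}

#' Write genomic intervals to a BED file
#' @param intervals data frame with `contig`, `start`, `end` (1-based inclusive)
#' @param path output BED path
#' @export
write_bed_intervals <- function(intervals, path) {
  gr <- GenomicRanges::GRanges(intervals$contig,
                               IRanges::IRanges(intervals$start, intervals$end))
  rtracklayer::export(gr, path, format = "bed")
  invisible(path)
}
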