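## Comparison of modern haplotypes to an archaic consensus sequence,
## read-depth deletion genotyping, and deletion breakpoint mapping from
## reference/sample sequence pairs.

#' Distances of modern haplotypes to an archaic consensus
#'
#' The archaic chromosome is treated as a single consensus haplotype over
#' the shared sites (reference-genome alignment style, no genotype
#' likelihoods); sites where the archaic allele is undefined (`NA`) are
#' dropped pairwise. Optionally contrasts two named haplotype groups with a
#' Mann-Whitney test (e.g. NE1 vs nonNE1, or CEU vs YRI).
#'
#' @param m a `HaplotypeMatrix`
#' @param archaic 0/1 vector over `m`'s sites, `NA` where undefined
#' @param groups optional list of two named logical/integer vectors (or a
#'   character vector of group labels, one per haplotype, with exactly two
#'   levels) selecting haplotypes to compare
#' @return list: `distances` (per haplotype), `n_sites_used`, and when
#'   `groups` is given `group_means` and `test` (Mann-Whitney)
#' @export
distance_to_archaic <- function(m, archaic, groups = NULL) {
  if (length(archaic) != n_sites(m))
    stop("archaic haplotype must cover the matrix sites")
  use <- !is.na(archaic)
  if (!any(use)) stop("no shared (defined) sites with the archaic haplotype")
  x <- m$alleles[, use, drop = FALSE]
  a <- archaic[use]
  d <- as.vector(abs(sweep(x, 2, a)) %*% rep(1, length(a)))
  names(d) <- m$haplotype_ids
  out <- list(distances = d, n_sites_used = sum(use))
  if (!is.null(groups)) {
    if (is.character(groups) || is.factor(groups)) {
      lv <- unique(as.character(groups))
      if (length(lv) != 2) stop("groups must have exactly two levels")
      groups <- stats::setNames(list(which(groups == lv[1]),
                                     which(groups == lv[2])), lv)
    }
    g1 <- d[groups[[1]]]; g2 <- d[groups[[2]]]
    out$group_means <- stats::setNames(c(mean(g1), mean(g2)), names(groups))
    out$test <- mann_whitney_u(g1, g2)
  }
  out
}

#' Call deletion zygosity from a read-depth profile
#'
#' Compares the mean depth inside a candidate interval to the mean depth in
#' its flanks. Dose thresholds (fractions of the flanking mean):
#' below `hom_max` -> homozygous deletion; inside `het_range` ->
#' heterozygous; above `no_del_min` -> no deletion; anything else is
#' `indeterminate`.
#'
#' @param profile data frame with `pos` (1-based, strictly increasing) and
#'   `depth` (non-negative integers)
#' @param candidate a [genomic_interval()] within the profile span
#' @param hom_max,het_range,no_del_min dose thresholds (defaults 0.1,
#'   c(0.35, 0.65), 0.8)
#' @return list: `call` in `hom_del`/`het_del`/`no_del`/`indeterminate`,
#'   `mean_inside`, `mean_flank`, `dose`
#' @export
call_deletion_from_depth <- function(profile, candidate, hom_max = 0.1,
                                     het_range = c(0.35, 0.65),
                                     no_del_min = 0.8) {
  if (any(profile$depth < 0)) stop("depths must be non-negative")
  if (is.unsorted(profile$pos, strictly = TRUE))
    stop("profile positions must be strictly increasing")
  if (candidate$start < min(profile$pos) || candidate$end > max(profile$pos))
    stop("candidate interval outside profile span")
  inside <- profile$pos >= candidate$start & profile$pos <= candidate$end
  if (!any(inside) || all(inside)) stop("candidate must split the profile")
  flank_mean <- mean(profile$depth[!inside])
  if (flank_mean <= 0) stop("zero flanking coverage")
  inside_mean <- mean(profile$depth[inside])
  dose <- inside_mean / flank_mean
  call <- if (dose < hom_max) "hom_del"
          else if (dose >= het_range[1] && dose <= het_range[2]) "het_del"
          else if (dose > no_del_min) "no_del"
          else "indeterminate"
  list(call = call, mean_inside = inside_mean, mean_flank = flank_mean,
       dose = dose)
}

#' Read / write a depth profile TSV
#' @param path TSV with columns `pos`, `depth`
#' @export
read_depth_profile <- function(path) {
  utils::read.delim(path, stringsAsFactors = FALSE)
}

#' @rdname read_depth_profile
#' @param profile data frame with `pos`, `depth`
#' @export
write_depth_profile <- function(profile, path) {
  utils::write.table(profile[, c("pos", "depth")], path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Map deletion breakpoints from a reference/sample sequence pair
#'
#' The sample must equal the reference with one contiguous block removed.
#' The deleted interval is located via the longest common prefix and suffix
#' and reported at its leftmost equivalent placement; `ambiguity_width`
#' counts the equivalent placements allowed by micro-homology at the
#' breakpoints (1 = unambiguous).
#'
#' @param reference,sample DNA sequences over A/C/G/T (character strings or
#'   `Biostrings::DNAString`s)
#' @param origin 1-based genomic coordinate of the first reference base
#'   (default 1), so that the returned interval is in genomic coordinates
#' @param contig contig name used for the returned interval
#' @return list of class `BreakpointCall`: `interval` (a
#'   [genomic_interval()], 1-based inclusive, leftmost placement), `length`
#'   in bp, `ambiguity_width`
#' @export
map_deletion_breakpoints <- function(reference, sample, origin = 1L,
                                     contig = "ref") {
  ref <- toupper(as.character(reference))
  smp <- toupper(as.character(sample))
  if (grepl("[^ACGT]", ref) || grepl("[^ACGT]", smp))
    stop("sequences must be over A/C/G/T")
  r <- nchar(ref); s <- nchar(smp)
  if (s >= r) {
    if (identical(ref, smp)) stop("sequences are identical: no deletion")
    stop("sample is not shorter than reference: not a single deletion")
  }
  d <- r - s
  rv <- strsplit(ref, "")[[1]]
  sv <- strsplit(smp, "")[[1]]
  ## longest common prefix / suffix lengths
  p <- 0L
  while (p < s && rv[p + 1L] == sv[p + 1L]) p <- p + 1L
  q <- 0L
  while (q < s && rv[r - q] == sv[s - q]) q <- q + 1L
  if (p + q < s)
    stop("sample is not derivable from the reference by one contiguous deletion")
  ## valid placements: deletion starting at i for i in [max(1, s-q+1), p+1]
  i_min <- max(1L, s - q + 1L)
  i_max <- p + 1L
  width <- i_max - i_min + 1L
  iv <- genomic_interval(contig, origin + i_min - 1L, origin + i_min + d - 2L)
  structure(list(interval = iv, length = d, ambiguity_width = width),
            class = "BreakpointCall")
}

#' @export
print.BreakpointCall <- function(x, ...) {
  cat(sprintf("deletion of %s bp at %s:%s-%s (leftmost of %d placement%s)\n",
              format(x$length, big.mark = ","), x$interval$contig,
              format(x$interval$start, big.mark = ","),
              format(x$interval$end, big.mark = ","),
              x$ambiguity_width, if (x$ambiguity_width == 1) "" else "s"))
  invisible(x)
}

#' Apply a deletion to a reference sequence
#'
#' Utility (the inverse of [map_deletion_breakpoints()]): removes the
#' 1-based inclusive interval `[start, end]` (in `origin` coordinates) from
#' the reference.
#' @param reference sequence string
#' @param iv a [genomic_interval()]
#' @param origin coordinate of the first reference base
#' @export
apply_deletion <- function(reference, iv, origin = 1L) {
  ref <- as.character(reference)
  i <- iv$start - origin + 1L
  j <- iv$end - origin + 1L
  if (i < 1L || j > nchar(ref)) stop("interval outside the reference")
  paste0(substr(ref, 1L, i - 1L), substr(ref, j + 1L, nchar(ref)))
}
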