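## Tag-SNP haplogroup classification and related haplotype-level analyses:
## PCA of the allele matrix, within-group diversity per population, and
## genotype-set concordance between call sets.

#' Construct a tag-SNP panel
#'
#' A panel of diagnostic SNPs with one consensus allele vector per
#' haplogroup. The two consensus vectors must differ at every tag position
#' (otherwise the SNP is not diagnostic).
#'
#' @param positions physical positions of the tag SNPs
#' @param consensus_a,consensus_b 0/1 allele vectors for the two haplogroups
#' @param labels haplogroup names, default `c("NE1", "nonNE1")`
#' @param snp_ids optional SNP identifiers
#' @return list of class `TagSnpPanel`
#' @export
tag_snp_panel <- function(positions, consensus_a, consensus_b,
                          labels = c("NE1", "nonNE1"), snp_ids = NULL) {
  k <- length(positions)
  if (length(consensus_a) != k || length(consensus_b) != k)
    stop("consensus vectors must match the number of tag positions")
  if (any(consensus_a == consensus_b))
    stop("consensus vectors must differ at every tag position")
  if (length(labels) != 2) stop("exactly two haplogroup labels required")
  if (is.null(snp_ids)) snp_ids <- paste0("tag", seq_len(k))
  structure(list(snp_ids = snp_ids, positions = as.integer(positions),
                 consensus_a = as.integer(consensus_a),
                 consensus_b = as.integer(consensus_b), labels = labels),
            class = "TagSnpPanel")
}

#' Read a tag-SNP panel from TSV
#' @param path TSV with columns `snp_id`, `position`, `allele_NE1`,
#'   `allele_nonNE1`
#' @export
read_tag_snp_panel <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  tag_snp_panel(tab$position, tab$allele_NE1, tab$allele_nonNE1,
                snp_ids = tab$snp_id)
}

#' Classify haplotypes into haplogroups by tag SNPs
#'
#' Each haplotype is assigned to the consensus it mismatches least, provided
#' that count is at most `max_mismatch` and strictly smaller than for the
#' other consensus; ties and poor matches are left `unclassified` (never
#' assigned arbitrarily).
#'
#' @param m a `HaplotypeMatrix` containing all panel positions
#' @param panel a [tag_snp_panel()]
#' @param max_mismatch maximum tolerated mismatches; defaults to 1 for
#'   panels of 12+ SNPs and 0 for smaller panels (near-exact matching)
#' @return data frame: `haplotype_id`, `label`, `mismatches` (vs the chosen
#'   consensus; the minimum of the two when unclassified), plus the two
#'   per-consensus mismatch counts
#' @export
classify_by_tag_snps <- function(m, panel, max_mismatch = NULL) {
  idx <- match(panel$positions, m$positions)
  if (anyNA(idx)) {
    miss <- panel$snp_ids[is.na(idx)]
    stop("tag SNP position(s) absent from matrix: ", paste(miss, collapse = ", "))
  }
  if (is.null(max_mismatch))
    max_mismatch <- if (length(panel$positions) >= 12) 1L else 0L
  x <- m$alleles[, idx, drop = FALSE]
  mm_a <- as.vector(abs(sweep(x, 2, panel$consensus_a)) %*%
                      rep(1, ncol(x)))
  mm_b <- as.vector(abs(sweep(x, 2, panel$consensus_b)) %*%
                      rep(1, ncol(x)))
  label <- rep("unclassified", nrow(x))
  label[mm_a < mm_b & mm_a <= max_mismatch] <- panel$labels[1]
  label[mm_b < mm_a & mm_b <= max_mismatch] <- panel$labels[2]
  data.frame(haplotype_id = m$haplotype_ids, label = label,
             mismatches = pmin(mm_a, mm_b),
             mismatches_a = mm_a, mismatches_b = mm_b,
             stringsAsFactors = FALSE)
}

#' Per-haplotype group memberships -> within-group nucleotide diversity
#'
#' Computes [nucleotide_diversity()] separately for every population-by-
#' haplogroup group with at least two members; smaller groups are skipped
#' and listed in the `skipped` attribute.
#'
#' @param m a `HaplotypeMatrix` with population assignments
#' @param calls classification data frame from [classify_by_tag_snps()]
#' @param region_length optional region length in bases for `pi_per_site`
#' @return data frame: `population`, `label`, `n_haplotypes`, `S`,
#'   `pi_total`, `pi_per_site`
#' @export
within_group_diversity <- function(m, calls, region_length = NULL) {
  pops <- haplotype_populations(m)
  grp <- interaction(pops, calls$label, drop = TRUE, sep = ":")
  out <- list(); skipped <- character(0)
  for (g in levels(grp)) {
    rows <- which(grp == g)
    parts <- strsplit(g, ":", fixed = TRUE)[[1]]
    if (length(rows) < 2) {
      skipped <- c(skipped, g)
      next
    }
    ## group members need not pair into diploids; diversity only needs rows
    div <- nucleotide_diversity_rows(m, rows, region_length)
    out[[g]] <- data.frame(population = parts[1], label = parts[2],
                           n_haplotypes = length(rows), S = div$S,
                           pi_total = div$pi_total,
                           pi_per_site = div$pi_per_site,
                           stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  attr(res, "skipped") <- skipped
  res
}

## Diversity over an arbitrary subset of haplotype rows (no diploid pairing
## requirement).
nucleotide_diversity_rows <- function(m, rows, region_length = NULL) {
  n <- length(rows)
  if (n < 2) stop("need at least 2 haplotypes")
  if (is.null(region_length)) {
    region_length <- if (n_sites(m) > 0)
      max(m$positions) - min(m$positions) + 1L else NA_integer_
  }
  cnt <- colSums(m$alleles[rows, , drop = FALSE])
  pi_total <- sum(cnt * (n - cnt)) / choose(n, 2)
  S <- sum(cnt > 0 & cnt < n)
  list(pi_total = pi_total, pi_per_site = pi_total / region_length,
       S = as.integer(S), n_haplotypes = n)
}

#' Principal component analysis of haplotypes
#'
#' Column-centered, unscaled 0/1 allele matrix decomposed by singular
#' values; deep haplogroup structure appears as discrete clusters on PC1.
#'
#' @param m a `HaplotypeMatrix` with >= 3 haplotypes and >= 2 sites
#' @param k number of components (truncated to the matrix rank, with a note)
#' @return list: `coords` (haplotypes x k), `explained_variance` (fraction
#'   per returned component), `note` (non-NULL when k was truncated)
#' @export
haplotype_pca <- function(m, k = 2) {
  if (n_haplotypes(m) < 3 || n_sites(m) < 2)
    stop("need at least 3 haplotypes and 2 sites")
  x <- scale(m$alleles, center = TRUE, scale = FALSE)
  sv <- svd(x)
  pos <- sum(sv$d > max(sv$d) * 1e-9)
  note <- NULL
  if (k > pos) {
    note <- sprintf("k = %d exceeds rank %d; truncated", k, pos)
    k <- pos
  }
  coords <- sv$u[, seq_len(k), drop = FALSE] %*% diag(sv$d[seq_len(k)], k, k)
  rownames(coords) <- m$haplotype_ids
  colnames(coords) <- paste0("PC", seq_len(k))
  list(coords = coords,
       explained_variance = (sv$d^2 / sum(sv$d^2))[seq_len(k)],
       note = note)
}

#' Concordance between two genotype call sets
#'
#' Fraction of shared samples assigned the identical genotype class
#' (0/1/2 copies), the check used to validate deletion genotypes compiled
#' from independent sources.
#'
#' @param callsA,callsB named vectors (sample -> genotype class)
#' @return list: `concordance`, `n_shared`, `n_discordant`
#' @export
genotype_concordance <- function(callsA, callsB) {
  shared <- intersect(names(callsA), names(callsB))
  if (!length(shared)) stop("no shared samples between call sets")
  eq <- callsA[shared] == callsB[shared]
  list(concordance = mean(eq), n_shared = length(shared),
       n_discordant = sum(!eq))
}

#' Haplogroup frequency table per population
#'
#' @param m a `HaplotypeMatrix` with population assignments
#' @param calls data frame from [classify_by_tag_snps()]
#' @return data frame of counts and frequencies per population x label
#' @export
haplogroup_frequencies <- function(m, calls) {
  pops <- haplotype_populations(m)
  tab <- as.data.frame(table(population = pops, label = calls$label),
                       stringsAsFactors = FALSE)
  names(tab)[3] <- "count"
  tot <- tapply(tab$count, tab$population, sum)
  tab$frequency <- tab$count / as.vector(tot[tab$population])
  tab
}
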