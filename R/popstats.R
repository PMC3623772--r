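## Core per-region population-genetic statistics. All estimators work on the
## 0/1 allele matrix of a HaplotypeMatrix; derived-allele counts per site are
## sufficient for pi, S, theta_W and Tajima's D, so those are computed from
## the site frequency spectrum rather than explicit pair enumeration (the
## test suite checks equality against brute-force pair loops).

harmonic_number <- function(n) if (n < 1) 0 else sum(1 / seq_len(n))

derived_counts <- function(m) {
  if (!inherits(m, "HaplotypeMatrix")) stop("expected a HaplotypeMatrix")
  colSums(m$alleles)
}

#' Nucleotide diversity (pi) and Watterson's theta for a region
#'
#' `pi_total` is the mean pairwise (Hamming) difference over all unordered
#' haplotype pairs; `pi_per_site` divides by the region length in bases
#' (not the SNP count), matching per-window diversity profiles.
#'
#' @param m a `HaplotypeMatrix` with at least 2 haplotypes
#' @param region_length region length in bases used for `pi_per_site`;
#'   defaults to the span of the observed positions.
#' @return list of class `DiversityResult`: `pi_total`, `pi_per_site`, `S`,
#'   `theta_w`, `n_haplotypes`, `a_n`, `region_length`.
#' @export
nucleotide_diversity <- function(m, region_length = NULL) {
  n <- n_haplotypes(m)
  if (n < 2) stop("need at least 2 haplotypes")
  if (is.null(region_length)) {
    region_length <- if (n_sites(m) > 0)
      max(m$positions) - min(m$positions) + 1L else NA_integer_
  }
  cnt <- derived_counts(m)
  pi_total <- sum(cnt * (n - cnt)) / choose(n, 2)
  S <- sum(cnt > 0 & cnt < n)
  a_n <- harmonic_number(n - 1)
  structure(list(pi_total = pi_total,
                 pi_per_site = pi_total / region_length,
                 S = as.integer(S), theta_w = S / a_n,
                 n_haplotypes = n, a_n = a_n,
                 region_length = region_length),
            class = "DiversityResult")
}

#' Watterson's estimator of theta
#'
#' @param S number of segregating sites
#' @param n number of sampled haplotypes (>= 2)
#' @return `S / a_n` with `a_n = sum_{j=1}^{n-1} 1/j`
#' @export
watterson_theta <- function(S, n) {
  if (n < 2) stop("need at least 2 haplotypes")
  S / harmonic_number(n - 1)
}

## Tajima (1989) normalization constants for sample size n.
tajima_constants <- function(n) {
  a1 <- harmonic_number(n - 1)
  a2 <- sum(1 / seq_len(n - 1)^2)
  b1 <- (n + 1) / (3 * (n - 1))
  b2 <- 2 * (n^2 + n + 3) / (9 * n * (n - 1))
  c1 <- b1 - 1 / a1
  c2 <- b2 - (n + 2) / (a1 * n) + a2 / a1^2
  e1 <- c1 / a1
  e2 <- c2 / (a1^2 + a2)
  list(a1 = a1, a2 = a2, b1 = b1, b2 = b2, c1 = c1, c2 = c2, e1 = e1, e2 = e2)
}

tajimas_d_from_summary <- function(pi_total, S, n, const = tajima_constants(n)) {
  if (S == 0) return(NA_real_)
  v <- const$e1 * S + const$e2 * S * (S - 1)
  if (v <= 0) return(NA_real_)
  (pi_total - S / const$a1) / sqrt(v)
}

#' Tajima's D
#'
#' Normalized difference between the pairwise-difference and segregating-site
#' estimators of theta; positive values indicate an excess of
#' intermediate-frequency variants, a signature of balancing selection.
#'
#' @param m a `HaplotypeMatrix`
#' @return list of class `TajimaResult`: `D`, `defined`, `S`, `pi_total`,
#'   `theta_w`, `n`. With `S = 0` (or a zero variance term) `defined` is
#'   `FALSE` and `D` is `NA`.
#' @export
tajimas_d <- function(m) {
  n <- n_haplotypes(m)
  if (n < 2) stop("need at least 2 haplotypes")
  div <- nucleotide_diversity(m)
  D <- tajimas_d_from_summary(div$pi_total, div$S, n)
  structure(list(D = D, defined = is.finite(D), S = div$S,
                 pi_total = div$pi_total, theta_w = div$theta_w, n = n),
            class = "TajimaResult")
}

## Coalescent genealogy summarised as branches: for each branch the number
## of subtended tips and its length (time in units of 2N generations).
## O(n): epoch k (k lineages) lasts Exp(k(k-1)/2).
sim_coalescent_branch_sizes <- function(n) {
  sizes <- rep(1L, n)
  birth <- rep(0, n)
  out_size <- integer(2L * (n - 1L))
  out_len <- numeric(2L * (n - 1L))
  t <- 0
  alive <- seq_len(n)
  nb <- 0L
  for (k in n:2) {
    t <- t + stats::rexp(1L, rate = k * (k - 1) / 2)
    pick <- sample(length(alive), 2L)
    i <- alive[pick[1L]]; j <- alive[pick[2L]]
    out_size[nb + 1L] <- sizes[i]; out_len[nb + 1L] <- t - birth[i]
    out_size[nb + 2L] <- sizes[j]; out_len[nb + 2L] <- t - birth[j]
    nb <- nb + 2L
    sizes[i] <- sizes[i] + sizes[j]
    birth[i] <- t
    alive <- alive[-pick[2L]]
  }
  list(sizes = out_size, lengths = out_len, tmrca = t)
}

#' Coalescent-simulation p-value for Tajima's D
#'
#' Simulates neutral genealogies for `n` tips and places exactly `S`
#' mutations on branches with probability proportional to branch length
#' (the conditional-on-S convention of DNAsp), recomputes D per replicate,
#' and returns the add-one two-sided empirical p-value
#' `(1 + #\{|D_sim| >= |D_obs|\}) / (1 + reps)`.
#'
#' @param D_obs observed Tajima's D
#' @param n number of haplotypes
#' @param S observed number of segregating sites (>= 1)
#' @param reps number of coalescent replicates (>= 100)
#' @param seed optional RNG seed for reproducibility
#' @return two-sided p-value in (0, 1]
#' @export
tajima_p_by_simulation <- function(D_obs, n, S, reps = 10000, seed = NULL) {
  if (reps < 100) stop("need at least 100 replicates")
  if (S < 1) stop("S must be >= 1")
  if (!is.null(seed)) set.seed(seed)
  const <- tajima_constants(n)
  npairs <- choose(n, 2)
  hits <- 0L
  for (r in seq_len(reps)) {
    g <- sim_coalescent_branch_sizes(n)
    branch <- sample.int(length(g$lengths), S, replace = TRUE, prob = g$lengths)
    i <- g$sizes[branch]
    poly <- i > 0L & i < n      # all are, by construction
    S_eff <- sum(poly)
    pi_tot <- sum(i[poly] * (n - i[poly])) / npairs
    D_sim <- tajimas_d_from_summary(pi_tot, S_eff, n, const)
    if (is.finite(D_sim) && abs(D_sim) >= abs(D_obs)) hits <- hits + 1L
  }
  (1 + hits) / (1 + reps)
}

#' Hudson's FST between two populations
#'
#' Per site, `1 - Hw/Hb` where `Hw` is the mean within-population pairwise
#' difference (average of the two populations) and `Hb` the mean
#' between-population pairwise difference (Hudson et al. 1992). The region
#' estimate aggregates as a ratio of averages, `1 - mean(Hw)/mean(Hb)`,
#' over sites where `Hb > 0`.
#'
#' @param m a `HaplotypeMatrix` with population assignments
#' @param pops ordered pair of population labels, each with >= 2 haplotypes
#' @return list of class `FstResult`: `per_site_fst` (NA where `Hb = 0`),
#'   `region_fst`, `populations`, `n_sites_used`.
#' @export
hudson_fst <- function(m, pops) {
  if (length(pops) != 2) stop("pops must be an ordered pair of labels")
  hp <- haplotype_populations(m)
  i1 <- hp == pops[1]; i2 <- hp == pops[2]
  n1 <- sum(i1); n2 <- sum(i2)
  if (n1 < 2 || n2 < 2) stop("both populations need >= 2 haplotypes")
  x1 <- colSums(m$alleles[i1, , drop = FALSE])
  x2 <- colSums(m$alleles[i2, , drop = FALSE])
  hw1 <- x1 * (n1 - x1) / choose(n1, 2)
  hw2 <- x2 * (n2 - x2) / choose(n2, 2)
  hw <- (hw1 + hw2) / 2
  hb <- (x1 * (n2 - x2) + x2 * (n1 - x1)) / (n1 * n2)
  fst <- ifelse(hb > 0, 1 - hw / hb, NA_real_)
  use <- hb > 0
  region <- if (any(use)) 1 - mean(hw[use]) / mean(hb[use]) else NA_real_
  structure(list(per_site_fst = fst, region_fst = region,
                 populations = pops, n_sites_used = sum(use)),
            class = "FstResult")
}

#' Mean pairwise linkage disequilibrium (r-squared)
#'
#' For every pair of SNPs passing the minor-allele-frequency filter,
#' `r^2 = D^2 / (pA(1-pA) pB(1-pB))` with `D = pAB - pA pB` taken directly
#' from phased haplotypes (no EM).
#'
#' @param m a `HaplotypeMatrix`
#' @param maf_min minor allele frequency filter (default 0.05)
#' @return list: `mean_r2`, `n_pairs`, `defined` (`FALSE` when fewer than 2
#'   sites qualify)
#' @export
mean_pairwise_r2 <- function(m, maf_min = 0.05) {
  n <- n_haplotypes(m)
  p <- derived_counts(m) / n
  maf <- pmin(p, 1 - p)
  keep <- maf >= maf_min & p > 0 & p < 1
  if (sum(keep) < 2)
    return(list(mean_r2 = NA_real_, n_pairs = 0L, defined = FALSE))
  x <- m$alleles[, keep, drop = FALSE]
  r2 <- stats::cor(x)^2
  ut <- upper.tri(r2)
  list(mean_r2 = mean(r2[ut]), n_pairs = sum(ut), defined = TRUE)
}

#' Pairwise Hamming distances between haplotypes
#'
#' With one matrix, all unordered within-set pairs; with two matrices over
#' the same sites, all cross pairs; with a single haplotype vector against a
#' matrix, one distance per haplotype of `b`.
#'
#' @param a `HaplotypeMatrix` or a single 0/1 haplotype vector
#' @param b optional second `HaplotypeMatrix`
#' @return numeric vector of distances (for matrix-vs-matrix the `a`-major
#'   flattening of the cross matrix)
#' @export
pairwise_differences <- function(a, b = NULL) {
  if (inherits(a, "HaplotypeMatrix") && is.null(b)) {
    x <- a$alleles
    d <- as.matrix(stats::dist(x, method = "manhattan"))
    return(d[upper.tri(d)])
  }
  if (is.numeric(a) && inherits(b, "HaplotypeMatrix")) {
    if (length(a) != n_sites(b)) stop("site sets differ")
    return(as.vector(abs(sweep(b$alleles, 2, a)) %*% rep(1, length(a))))
  }
  if (inherits(a, "HaplotypeMatrix") && inherits(b, "HaplotypeMatrix")) {
    if (!identical(a$positions, b$positions)) stop("site sets differ")
    xa <- a$alleles; xb <- b$alleles
    ## |xa_i - xb_j| summed over sites: cross Hamming via matrix product
    d <- xa %*% t(1 - xb) + (1 - xa) %*% t(xb)
    return(as.vector(t(d)))
  }
  stop("unsupported argument types")
}

#' Mann-Whitney U test
#'
#' Exact two-sided p by complete enumeration of labelings when
#' `length(x) + length(y) <= 12` (valid under ties); otherwise the normal
#' approximation with tie and continuity corrections.
#'
#' @param x,y non-empty numeric samples
#' @return list: `U` (for `x`), `p_two_sided`, `method`
#' @export
mann_whitney_u <- function(x, y) {
  if (!length(x) || !length(y)) stop("both samples must be non-empty")
  nx <- length(x); ny <- length(y); N <- nx + ny
  u_stat <- function(xs, ys) {
    r <- rank(c(xs, ys))
    sum(r[seq_along(xs)]) - length(xs) * (length(xs) + 1) / 2
  }
  U <- u_stat(x, y)
  mu <- nx * ny / 2
  pooled <- c(x, y)
  if (length(unique(pooled)) == 1L)
    return(list(U = U, p_two_sided = 1, method = "degenerate"))
  if (N <= 12) {
    combs <- utils::combn(N, nx)
    dev_obs <- abs(U - mu)
    hits <- 0L
    for (k in seq_len(ncol(combs))) {
      xi <- combs[, k]
      Up <- u_stat(pooled[xi], pooled[-xi])
      if (abs(Up - mu) >= dev_obs - 1e-9) hits <- hits + 1L
    }
    return(list(U = U, p_two_sided = hits / ncol(combs), method = "exact"))
  }
  ties <- table(pooled)
  sigma2 <- nx * ny / 12 * ((N + 1) - sum(ties^3 - ties) / (N * (N - 1)))
  if (sigma2 <= 0) return(list(U = U, p_two_sided = 1, method = "normal"))
  z <- (U - mu - sign(U - mu) * 0.5) / sqrt(sigma2)
  list(U = U, p_two_sided = min(1, 2 * stats::pnorm(-abs(z))),
       method = "normal")
}

#' Spearman rank association of allele count with expression
#'
#' The eQTL primitive: associates per-sample allele counts (coded 0/1/2)
#' with normalized expression by Spearman rank correlation, with average
#' ranks for ties, the asymptotic t-approximation for the p-value, and a
#' Bonferroni-adjusted p for `m_tests` tests.
#'
#' @param genotype integer vector of allele counts 0/1/2, one per sample
#' @param expression numeric vector, same length
#' @param m_tests number of tests for the Bonferroni correction (default 1)
#' @return list: `rho`, `p`, `p_bonferroni`, `defined` (`FALSE` with a
#'   constant genotype, which is flagged rather than an error)
#' @export
spearman_assoc <- function(genotype, expression, m_tests = 1) {
  if (length(genotype) != length(expression)) stop("length mismatch")
  if (length(genotype) < 5) stop("need at least 5 samples")
  if (length(unique(genotype)) == 1L)
    return(list(rho = NA_real_, p = NA_real_, p_bonferroni = NA_real_,
                defined = FALSE))
  ct <- suppressWarnings(stats::cor.test(genotype, expression,
                                         method = "spearman", exact = FALSE))
  p <- ct$p.value
  list(rho = unname(ct$estimate), p = p,
       p_bonferroni = min(1, m_tests * p), defined = TRUE)
}
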