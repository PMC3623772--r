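panel6 <- tag_snp_panel(positions = c(10, 20, 30, 40, 50, 60),
                        consensus_a = c(1, 1, 1, 1, 1, 1),
                        consensus_b = c(0, 0, 0, 0, 0, 0))

mat_from_rows <- function(rows, pos, pops = NULL) {
  x <- do.call(rbind, rows)
  ids <- paste0("s", seq_len(nrow(x) / 2))
  haplotype_matrix(x, pos, "chrT", ids, population_of =
                     if (is.null(pops)) NULL else stats::setNames(pops, ids))
}

test_that("tag-SNP classification follows the mismatch rule", {
  m <- mat_from_rows(list(
    c(1, 1, 1, 1, 1, 1),   # exact NE1
    c(0, 0, 0, 0, 0, 0),   # exact nonNE1
    c(0, 1, 1, 1, 1, 1),   # 1 from NE1, 5 from nonNE1
    c(1, 1, 1, 0, 0, 0)),  # tie: 3 and 3
    panel6$positions)
  calls <- classify_by_tag_snps(m, panel6, max_mismatch = 1)
  expect_equal(calls$label, c("NE1", "nonNE1", "NE1", "unclassified"))
  expect_equal(calls$mismatches[1:3], c(0, 0, 1))

  # small panels default to exact matching: the two singleton 6-mers that
  # match neither consensus are left out rather than forced into a group
  calls0 <- classify_by_tag_snps(m, panel6)
  expect_equal(calls0$label, c("NE1", "nonNE1", "unclassified", "unclassified"))

  expect_error(classify_by_tag_snps(
    mat_from_rows(list(c(0, 1), c(1, 0)), c(10, 99)),
    tag_snp_panel(c(10, 20), c(1, 1), c(0, 0))), "absent")
})

test_that("consensus vectors must be diagnostic at every tag", {
  expect_error(tag_snp_panel(c(1, 2), c(1, 1), c(0, 1)), "differ at every")
})

test_that("classification is order-independent", {
  r <- simulate_substructure_locus(substructure_config(
    n_per_pop = 20, pops = c(AFR = 0.2, EUR = 0.4), locus_bp = 8000, seed = 5))
  calls <- classify_by_tag_snps(r$matrix, r$panel)
  set.seed(1)
  perm <- sample(n_haplotypes(r$matrix))
  # permuting haplotypes permutes the calls identically; rebuild via pairs
  # of permuted rows under fresh ids
  m2 <- r$matrix
  m2$alleles <- r$matrix$alleles[perm, , drop = FALSE]
  m2$haplotype_ids <- r$matrix$haplotype_ids[perm]
  calls2 <- classify_by_tag_snps(m2, r$panel)
  expect_equal(calls2$label, calls$label[perm])
})

test_that("tag-SNP calls equal deletion carriage (perfect LD) and truth", {
  r <- simulate_substructure_locus(substructure_config(seed = 8))
  calls <- classify_by_tag_snps(r$matrix, r$panel)
  expect_equal(calls$label, unname(r$truth$clade))
  is_carrier <- r$matrix$haplotype_ids %in% r$truth$deletion_carriers
  expect_equal(calls$label == "NE1", is_carrier)

  # per-population frequency table conserves haplotype counts
  freq <- haplogroup_frequencies(r$matrix, calls)
  tot <- tapply(freq$count, freq$population, sum)
  expect_true(all(tot == r$config$n_per_pop))
  ne1 <- freq[freq$label == "NE1", ]
  expect_equal(stats::setNames(ne1$frequency, ne1$population)[
    names(r$config$pops)], r$config$pops)
})

test_that("within-group diversity contrasts deep and shallow clades", {
  r <- simulate_substructure_locus(substructure_config(
    pops = c(AFR = 0.16, EUR = 0.36, EAS = 0.30), seed = 12))
  calls <- classify_by_tag_snps(r$matrix, r$panel)
  wg <- within_group_diversity(r$matrix, calls, region_length = 36000)
  pi_afr <- wg$pi_total[wg$population == "AFR" & wg$label == "NE1"]
  pi_eur <- wg$pi_total[wg$population == "EUR" & wg$label == "NE1"]
  expect_gt(pi_afr, pi_eur)

  # Mann-Whitney on within-group pairwise distances separates the clades
  rows_afr <- which(r$truth$clade == "NE1" &
                      haplotype_populations(r$matrix) == "AFR")
  rows_eur <- which(r$truth$clade == "NE1" &
                      haplotype_populations(r$matrix) == "EUR")
  sub <- function(rows) {
    x <- r$matrix$alleles[rows, , drop = FALSE]
    as.vector(as.matrix(stats::dist(x, "manhattan")))[
      rep(seq_along(rows), each = length(rows)) < rep(seq_along(rows),
                                                      length(rows))]
  }
  mw <- mann_whitney_u(sub(rows_afr), sub(rows_eur))
  expect_lt(mw$p_two_sided, 0.01)

  # group of identical haplotypes and group-of-all identities
  ident <- haplotype_matrix(matrix(0L, 4, 2), c(5, 9), "c", c("a", "b"),
                            population_of = c(a = "P", b = "P"))
  calls_id <- data.frame(haplotype_id = ident$haplotype_ids,
                         label = rep("NE1", 4))
  wg_id <- within_group_diversity(ident, calls_id)
  expect_equal(wg_id$pi_total, 0)

  all_one <- within_group_diversity(
    r$matrix, data.frame(haplotype_id = r$matrix$haplotype_ids,
                         label = "NE1"))
  ne1_rows <- all_one[all_one$label == "NE1", ]
  pops <- haplotype_populations(r$matrix)
  for (p in unique(pops)) {
    rows <- which(pops == p)
    expect_equal(ne1_rows$S[ne1_rows$population == p],
                 sum(apply(r$matrix$alleles[rows, ], 2,
                           function(cl) length(unique(cl)) == 2)))
  }
})

test_that("the deep African NE1 clade is usually more diverse", {
  ok <- 0
  for (s in 1:60) {
    r <- simulate_substructure_locus(substructure_config(
      pops = c(AFR = 0.16, EUR = 0.36, EAS = 0.30), locus_bp = 20000,
      seed = 7000 + s))
    calls <- classify_by_tag_snps(r$matrix, r$panel)
    wg <- within_group_diversity(r$matrix, calls, region_length = 20000)
    ok <- ok + (wg$pi_total[wg$population == "AFR" & wg$label == "NE1"] >
                  wg$pi_total[wg$population == "EUR" & wg$label == "NE1"])
  }
  expect_gte(ok / 60, 0.8)
})

test_that("haplotype PCA separates the haplogroups on PC1", {
  # two clusters of identical haplotypes: PC1 separates with zero
  # within-cluster spread
  m <- mat_from_rows(c(rep(list(rep(0L, 6)), 4), rep(list(rep(1L, 6)), 4)),
                     seq(10, 60, 10))
  p <- haplotype_pca(m, 2)
  expect_equal(p$note, "k = 2 exceeds rank 1; truncated")
  pc1 <- p$coords[, 1]
  expect_equal(stats::sd(pc1[1:4]), 0)
  expect_gt(abs(mean(pc1[1:4]) - mean(pc1[5:8])), 1)

  # order permutation leaves coordinates unchanged up to sign
  r <- simulate_substructure_locus(substructure_config(
    n_per_pop = 30, pops = c(AFR = 0.2, EUR = 0.4), locus_bp = 9000,
    seed = 3))
  p1 <- haplotype_pca(r$matrix, 2)
  perm <- sample(n_haplotypes(r$matrix))
  m2 <- r$matrix
  m2$alleles <- r$matrix$alleles[perm, , drop = FALSE]
  p2 <- haplotype_pca(m2, 2)
  agree <- abs(sum(p1$coords[perm, 1] * p2$coords[, 1])) /
    (sqrt(sum(p1$coords[, 1]^2)) * sqrt(sum(p2$coords[, 1]^2)))
  expect_equal(agree, 1, tolerance = 1e-8)

  # synthetic haplogroups are linearly separable on PC1 (>= 99% accuracy
  # by nearest cluster mean)
  r <- simulate_substructure_locus(substructure_config(seed = 17))
  pc1 <- haplotype_pca(r$matrix, 1)$coords[, 1]
  lab <- r$truth$clade
  mu <- tapply(pc1, lab, mean)
  pred <- names(mu)[apply(abs(outer(pc1, mu, `-`)), 1, which.min)]
  expect_gte(mean(pred == lab), 0.99)
  expect_gt(haplotype_pca(r$matrix, 1)$explained_variance[1], 0.2)
})

test_that("genotype concordance counts shared identical classes", {
  a <- stats::setNames(c(0, 1, 2, 1, 0, 2, 1, 1, 0, 2), paste0("s", 1:10))
  expect_equal(genotype_concordance(a, a)$concordance, 1)
  b <- a; b["s4"] <- 0
  expect_equal(genotype_concordance(a, b)$concordance, 0.9)
  expect_error(genotype_concordance(a, stats::setNames(1, "zz")), "shared")

  # random perturbation at rate q gives concordance about 1 - q
  set.seed(6)
  big <- stats::setNames(sample(0:2, 1000, replace = TRUE), paste0("x", 1:1000))
  q <- 0.07
  flip <- runif(1000) < q
  pert <- big
  pert[flip] <- (pert[flip] + 1) %% 3
  got <- genotype_concordance(big, pert)$concordance
  expect_equal(got, 1 - mean(flip))
  expect_equal(got, 1 - q, tolerance = 0.35)
})
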