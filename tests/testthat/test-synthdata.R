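test_that("neutral simulation respects theta = 0 and basic geometry", {
  m <- simulate_neutral_sample(10, 0, seed = 1)
  expect_equal(n_sites(m), 0)
  expect_equal(n_haplotypes(m), 10)
  expect_error(simulate_neutral_sample(9, 1), "even")

  m2 <- simulate_neutral_sample(8, 5, seed = 2, window_bp = 1000, start = 501)
  expect_true(all(m2$positions >= 501 & m2$positions <= 1500))
  expect_false(is.unsorted(m2$positions, strictly = TRUE))
})

test_that("neutral moments track coalescent expectations at small scale", {
  # E[pi] = theta for n = 2; reduced replicate count, wide tolerance
  set.seed(3)
  pis <- replicate(2500, nucleotide_diversity(
    simulate_neutral_sample(2, 1))$pi_total)
  expect_equal(mean(pis), 1, tolerance = 0.12)

  # E[S] = theta * a_n
  set.seed(4)
  Ss <- replicate(800, nucleotide_diversity(
    simulate_neutral_sample(20, 5))$S)
  expect_equal(mean(Ss), 5 * sum(1 / (1:19)), tolerance = 0.05)
})

test_that("generation is deterministic given the seed", {
  cfg <- substructure_config(n_per_pop = 20, pops = c(A = 0.2, B = 0.5),
                             locus_bp = 5000, seed = 42)
  r1 <- simulate_substructure_locus(cfg)
  r2 <- simulate_substructure_locus(cfg)
  expect_identical(r1$matrix$alleles, r2$matrix$alleles)
  expect_identical(r1$matrix$positions, r2$matrix$positions)
  expect_identical(r1$truth$clade, r2$truth$clade)
  expect_identical(r1$archaic, r2$archaic)

  g1 <- simulate_genome_background(4, 20, 5, seed = 9)
  g2 <- simulate_genome_background(4, 20, 5, seed = 9)
  expect_identical(g1$matrix$alleles, g2$matrix$alleles)
})

test_that("substructure truth is consistent with the emitted data", {
  cfg <- substructure_config(seed = 31)
  r <- simulate_substructure_locus(cfg)
  m <- r$matrix

  # exact target frequencies per population
  pops <- haplotype_populations(m)
  for (p in names(cfg$pops)) {
    expect_equal(mean(r$truth$clade[pops == p] == "NE1"),
                 unname(cfg$pops[p]))
  }

  # tag SNPs are fixed differences between the clades (perfect LD)
  tag_cols <- match(r$truth$tag_positions, m$positions)
  ne1 <- r$truth$clade == "NE1"
  for (j in tag_cols) {
    expect_true(all(m$alleles[ne1, j] == 1))
    expect_true(all(m$alleles[!ne1, j] == 0))
  }

  # deletion carriers are exactly the NE1 haplotypes, and per-sample
  # genotype classes count NE1 copies
  expect_equal(r$truth$deletion_carriers, m$haplotype_ids[ne1])
  expect_equal(as.vector(r$truth$deletion_genotype),
               as.vector(tapply(ne1, rep(seq_along(m$sample_ids), each = 2),
                                sum)))

  # archaic haplotype carries all tag SNPs (NE1 stem) and no private ones
  expect_true(all(r$archaic[tag_cols] == 1))
  arch_sites <- which(r$archaic == 1)
  for (j in arch_sites) expect_true(all(m$alleles[ne1, j] == 1))

  # truth labels survive a VCF round trip + tag classification
  path <- tempfile(fileext = ".vcf")
  write_phased_vcf(m, path)
  m2 <- read_phased_vcf(path)
  calls <- classify_by_tag_snps(m2, r$panel)
  expect_equal(calls$label, unname(r$truth$clade))
})

test_that("frequency zero and infeasible frequencies are handled", {
  r <- simulate_substructure_locus(substructure_config(
    n_per_pop = 20, pops = c(A = 0, B = 0.5), locus_bp = 4000, seed = 2))
  pops <- haplotype_populations(r$matrix)
  expect_true(all(r$truth$clade[pops == "A"] == "nonNE1"))
  expect_error(substructure_config(n_per_pop = 10, pops = c(A = 0.25)),
               "whole number")
  expect_error(substructure_config(n_per_pop = 11), "even")
})

test_that("genome backgrounds tile windows and plant the locus on demand", {
  expect_error(simulate_genome_background(0, 10, 5), "at least one")

  g <- simulate_genome_background(5, 20, 5, seed = 11, window_bp = 2000)
  expect_equal(nrow(g$windows), 5)
  expect_true(all(g$matrix$positions <= 10000))
  expect_false(any(g$windows$is_planted))

  gp <- simulate_genome_background(6, 20, 5, seed = 12, window_bp = 3000,
                                   plant = substructure_config(
                                     n_per_pop = 20,
                                     pops = c(AFR = 0.1, EUR = 0.4)),
                                   plant_window = 4)
  expect_true(gp$windows$is_planted[4])
  expect_equal(n_haplotypes(gp$matrix), 40)   # 20 haplotypes x 2 populations
  tagpos <- gp$truth$tag_positions
  expect_true(all(tagpos > 9000 & tagpos <= 12000))
  # deletion interval refitted inside the planted window
  expect_gte(gp$truth$deletion_interval$start, 9001)
  expect_lte(gp$truth$deletion_interval$end, 12000)
})

test_that("expression coupling behaves at its edges and under the null", {
  g <- rep(0:2, 20)
  expect_equal(simulate_expression(g, beta = 1, sigma = 0, seed = 1), g)
  e <- simulate_expression(g, beta = 1, sigma = 0, seed = 1)
  expect_equal(spearman_assoc(g, e)$rho, 1, tolerance = 1e-9)

  # beta = 0: p-values are uniform, about 5% below 0.05
  hits <- vapply(1:400, function(s) {
    e <- simulate_expression(g, beta = 0, sigma = 1, seed = s)
    spearman_assoc(g, e)$p < 0.05
  }, logical(1))
  expect_equal(mean(hits), 0.05, tolerance = 0.6)
  expect_lt(abs(mean(hits) - 0.05), 0.035)
})

test_that("depth profiles have the right doses and flank coverage", {
  iv <- genomic_interval("c", 5001, 6000)
  hom <- simulate_depth_profile(iv, 30, "hom_del", seed = 3)
  inside <- hom$pos >= 5001 & hom$pos <= 6000
  expect_true(all(hom$depth[inside] == 0))
  expect_gt(mean(hom$depth[!inside]), 0)

  big <- simulate_depth_profile(genomic_interval("c", 6001, 6100), 30,
                                "no_del", seed = 4, flank_bp = 5000)
  expect_equal(mean(big$depth), 30, tolerance = 0.02)
  expect_error(simulate_depth_profile(iv, 0, "no_del"), "positive")

  # pipeline closure: archaic profile recovers the planted zygosity
  prof <- simulate_depth_profile(iv, 30, "hom_del", seed = 5)
  expect_equal(call_deletion_from_depth(prof, iv)$call, "hom_del")
})

test_that("HKA simulation matches its Poisson means", {
  a_n <- sum(1 / (1:9))
  d <- simulate_hka_dataset(4000, theta = 0.01, T = 2, n = 10, L = 1000,
                            seed = 6)
  expect_equal(mean(d$S), 0.01 * 1000 * a_n, tolerance = 0.03)
  expect_equal(mean(d$D), 0.01 * 1000 * 3, tolerance = 0.03)
  d5 <- simulate_hka_dataset(2000, theta = 0.01, T = 2, n = 10, L = 1000,
                             k = 5, seed = 7)
  expect_equal(mean(d5$S), 5 * 0.01 * 1000 * a_n, tolerance = 0.03)
})
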