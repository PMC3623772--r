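hm <- function(x, pos = NULL) {
  x <- as.matrix(x)
  if (is.null(pos)) pos <- seq_len(ncol(x))
  haplotype_matrix(x, pos, "chrT", paste0("s", seq_len(nrow(x) / 2)))
}

test_that("nucleotide diversity equals the mean pairwise difference", {
  # haplotypes {00, 01, 11}: pairs differ by 1, 2, 1 -> mean 4/3
  trio <- rbind(c(0, 0), c(0, 1), c(1, 1))
  expect_equal(oracle_pi_total(trio), 4 / 3)
  m <- haplotype_matrix(rbind(trio, c(0, 0)), 1:2, "chrT", c("a", "b"))
  d <- pairwise_differences(m)
  # column-major upper triangle: the first three entries are the pairs
  # (1,2), (1,3), (2,3) among the trio
  expect_equal(mean(d[1:3]), 4 / 3)
  expect_equal(nucleotide_diversity(m)$pi_total, oracle_pi_total(m$alleles))
  m3 <- hm(rbind(c(0, 0), c(0, 1), c(1, 1), c(0, 1)))
  expect_equal(nucleotide_diversity(m3)$pi_total, oracle_pi_total(m3$alleles))
  ident <- hm(matrix(1L, 4, 3))
  expect_equal(nucleotide_diversity(ident)$pi_total, 0)
})

test_that("Watterson's theta follows S over the harmonic number", {
  expect_equal(watterson_theta(5, 10), 5 / sum(1 / (1:9)))
  expect_equal(watterson_theta(5, 10), 1.7674, tolerance = 1e-4)
  expect_equal(watterson_theta(0, 10), 0)
  expect_equal(watterson_theta(7, 2), 7)   # a_1 = 1
  expect_error(watterson_theta(5, 1), "at least 2")
})

test_that("Tajima's D matches the worked singleton example and the oracle", {
  m <- hm(rbind(c(1, 0, 0), c(0, 1, 0), c(0, 0, 1), c(0, 0, 0)))
  td <- tajimas_d(m)
  expect_equal(td$pi_total, 1.5)
  expect_equal(td$theta_w, 3 / (1 + 1 / 2 + 1 / 3))
  expect_equal(td$D, -0.7544, tolerance = 1e-4)
  expect_equal(td$D, oracle_tajima_d(m$alleles))

  expect_false(tajimas_d(hm(matrix(0L, 4, 0)))$defined)
  expect_true(is.na(tajimas_d(hm(matrix(0L, 4, 0)))$D))

  for (i in 1:10) {
    mm <- rand_hapmat(10, 20, seed = 100 + i)
    expect_equal(tajimas_d(mm)$D, oracle_tajima_d(mm$alleles))
  }
})

test_that("Tajima's D is invariant to 0/1 relabeling at any site", {
  for (i in 1:5) {
    mm <- rand_hapmat(10, 15, seed = 200 + i)
    flip <- sample(ncol(mm$alleles), 5)
    m2 <- mm
    m2$alleles[, flip] <- 1L - m2$alleles[, flip]
    m2 <- haplotype_matrix(m2$alleles, mm$positions, mm$contig, mm$sample_ids)
    expect_equal(tajimas_d(m2)$D, tajimas_d(mm)$D)
  }
})

test_that("coalescent-simulation p-values behave across the null", {
  expect_gte(tajima_p_by_simulation(0, 20, 10, reps = 1000, seed = 1), 0.9)
  expect_equal(tajima_p_by_simulation(10, 20, 10, reps = 500, seed = 1),
               1 / 501)
  p <- tajima_p_by_simulation(2.5, 20, 30, reps = 2000, seed = 2)
  expect_lt(p, 0.05)
  expect_error(tajima_p_by_simulation(1, 10, 5, reps = 50), "100")
})

test_that("Hudson FST covers fixed, undifferentiated and mixed sites", {
  pops <- function(m) {
    m$population_of <- stats::setNames(rep(c("P1", "P2"),
                                           each = length(m$sample_ids) / 2),
                                       m$sample_ids)
    m
  }
  fixed <- pops(hm(matrix(c(1, 1, 1, 1, 0, 0, 0, 0), ncol = 1)))
  expect_equal(hudson_fst(fixed, c("P1", "P2"))$region_fst, 1)

  # identical sample frequencies: the unbiased pairwise-difference
  # estimator gives the finite-sample value -1/(n-1), approaching 0 as n
  # grows (0 in expectation under equal population frequencies)
  same <- pops(hm(matrix(c(1, 0, 1, 0, 1, 0, 1, 0), ncol = 1)))
  expect_equal(hudson_fst(same, c("P1", "P2"))$region_fst, -1 / 3)
  same20 <- pops(hm(matrix(rep(c(1, 0), 10), ncol = 1)))
  expect_equal(hudson_fst(same20, c("P1", "P2"))$region_fst, -1 / 9)

  mixed <- pops(hm(matrix(c(1, 1, 1, 0, 0, 0, 0, 0), ncol = 1)))
  r <- hudson_fst(mixed, c("P1", "P2"))
  expect_equal(r$region_fst, 2 / 3)
  expect_equal(r$per_site_fst, 2 / 3)

  for (i in 1:10) {
    mm <- rand_hapmat_pops(12, 15, seed = 300 + i)
    got <- hudson_fst(mm, c("P1", "P2"))$region_fst
    grp <- rep(c("P1", "P2"), each = 6)
    expect_equal(got, oracle_fst_region(mm$alleles, grp, "P1", "P2"))
    expect_lte(got, 1)
  }
})

test_that("pairwise r-squared matches hand computations and the oracle", {
  perfect <- hm(rbind(c(0, 0), c(0, 0), c(1, 1), c(1, 1)))
  expect_equal(mean_pairwise_r2(perfect, maf_min = 0)$mean_r2, 1)

  ex <- hm(rbind(c(0, 0), c(0, 0), c(1, 1), c(0, 1)))
  expect_equal(mean_pairwise_r2(ex, maf_min = 0)$mean_r2, 1 / 3)

  equi <- hm(rbind(c(0, 0), c(0, 1), c(1, 0), c(1, 1)))
  expect_equal(mean_pairwise_r2(equi, maf_min = 0)$mean_r2, 0)

  single <- hm(matrix(c(0, 1, 0, 1), ncol = 1))
  expect_false(mean_pairwise_r2(single)$defined)

  for (i in 1:10) {
    mm <- rand_hapmat(10, 12, seed = 400 + i)
    expect_equal(mean_pairwise_r2(mm)$mean_r2,
                 oracle_mean_r2(mm$alleles))
  }
})

test_that("pairwise differences handle vector, within-set and cross-set", {
  b <- hm(rbind(c(0, 1, 0), c(0, 1, 1), c(1, 1, 1), c(0, 0, 0)))
  expect_equal(pairwise_differences(c(0, 0, 0), b), c(1, 2, 3, 0))

  ident <- hm(matrix(0L, 4, 3))
  expect_true(all(pairwise_differences(ident) == 0))

  for (i in 1:5) {
    ma <- rand_hapmat(6, 10, seed = 500 + i)
    mb <- rand_hapmat(4, 10, seed = 600 + i)
    mb$positions <- ma$positions
    expect_equal(pairwise_differences(ma, mb),
                 oracle_pairwise(ma$alleles, mb$alleles))
    expect_equal(sort(pairwise_differences(ma)),
                 sort(oracle_pairwise(ma$alleles, ma$alleles)[
                   rep(1:6, each = 6) < rep(1:6, 6)]))
  }
  mbad <- rand_hapmat(4, 10, seed = 7)
  mbad$positions <- mbad$positions + 1L
  expect_error(pairwise_differences(rand_hapmat(4, 10, seed = 7), mbad),
               "site sets differ")
})

test_that("Mann-Whitney exact enumeration and approximation are sound", {
  r <- mann_whitney_u(c(1, 2), c(3, 4))
  expect_equal(r$U, 0)
  expect_equal(r$p_two_sided, 1 / 3)
  expect_equal(r$method, "exact")

  same <- mann_whitney_u(c(1, 2, 3), c(1, 2, 3))
  expect_equal(same$p_two_sided, 1)

  expect_equal(mann_whitney_u(rep(2, 4), rep(2, 5))$p_two_sided, 1)

  # power sanity on large shifted samples
  set.seed(1)
  big <- mann_whitney_u(rnorm(60), rnorm(60) + 2)
  expect_lt(big$p_two_sided, 0.001)

  # cross-check against the standard implementation where both are exact
  set.seed(2)
  for (i in 1:5) {
    x <- round(rnorm(5), 4); y <- round(rnorm(6) + 0.5, 4)
    ours <- mann_whitney_u(x, y)
    ref <- stats::wilcox.test(x, y, exact = TRUE, correct = FALSE)
    expect_equal(ours$p_two_sided, ref$p.value)
  }
  # and approximately in the normal regime
  set.seed(3)
  x <- rnorm(30); y <- rnorm(35) + 0.6
  ours <- mann_whitney_u(x, y)
  ref <- stats::wilcox.test(x, y, exact = FALSE, correct = TRUE)
  expect_equal(ours$p_two_sided, ref$p.value, tolerance = 1e-6)
})

test_that("Spearman association flags constants and finds planted effects", {
  expect_equal(spearman_assoc(c(0, 0, 1, 1, 2, 2), c(1, 1, 2, 2, 3, 3))$rho,
               1, tolerance = 1e-9)
  expect_equal(spearman_assoc(c(0, 0, 1, 1, 2, 2), c(3, 3, 2, 2, 1, 1))$rho,
               -1, tolerance = 1e-9)
  expect_false(spearman_assoc(rep(1, 6), rnorm(6))$defined)
  expect_error(spearman_assoc(c(0, 1, 2), c(1, 2, 3)), "at least 5")

  g <- rep(0:2, length.out = 100)
  e <- simulate_expression(g, beta = 1, sigma = 0.5, seed = 11)
  r <- spearman_assoc(g, e, m_tests = 21800)
  expect_lt(r$p_bonferroni, 0.05)
})
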