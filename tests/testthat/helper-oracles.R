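# Brute-force oracles, coded independently of the package internals:
# explicit pair enumeration throughout, no site-frequency shortcuts.

oracle_pi_total <- function(x) {
  n <- nrow(x)
  tot <- 0; pairs <- 0
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    tot <- tot + sum(x[i, ] != x[j, ])
    pairs <- pairs + 1
  }
  tot / pairs
}

oracle_pairwise <- function(xa, xb) {
  out <- c()
  for (i in seq_len(nrow(xa))) for (j in seq_len(nrow(xb)))
    out <- c(out, sum(xa[i, ] != xb[j, ]))
  out
}

oracle_fst_region <- function(x, grp, g1, g2) {
  x1 <- x[grp == g1, , drop = FALSE]
  x2 <- x[grp == g2, , drop = FALSE]
  hw_sum <- 0; hb_sum <- 0
  for (s in seq_len(ncol(x))) {
    hw1 <- mean(utils::combn(x1[, s], 2, function(p) p[1] != p[2]))
    hw2 <- mean(utils::combn(x2[, s], 2, function(p) p[1] != p[2]))
    hb <- mean(outer(x1[, s], x2[, s], `!=`))
    if (hb > 0) {
      hw_sum <- hw_sum + (hw1 + hw2) / 2
      hb_sum <- hb_sum + hb
    }
  }
  if (hb_sum == 0) return(NA_real_)
  1 - hw_sum / hb_sum
}

oracle_mean_r2 <- function(x, maf_min = 0.05) {
  n <- nrow(x)
  p <- colMeans(x)
  keep <- pmin(p, 1 - p) >= maf_min & p > 0 & p < 1
  x <- x[, keep, drop = FALSE]
  if (ncol(x) < 2) return(NA_real_)
  vals <- c()
  for (a in seq_len(ncol(x) - 1)) for (b in (a + 1):ncol(x)) {
    pa <- mean(x[, a]); pb <- mean(x[, b])
    pab <- mean(x[, a] == 1 & x[, b] == 1)
    Dld <- pab - pa * pb
    vals <- c(vals, Dld^2 / (pa * (1 - pa) * pb * (1 - pb)))
  }
  mean(vals)
}

# Independent Tajima (1989) implementation: pair-enumerated pi, direct
# constants, written without reference to the package's internals.
oracle_tajima_d <- function(x) {
  n <- nrow(x)
  S <- sum(apply(x, 2, function(col) length(unique(col)) == 2))
  if (S == 0) return(NA_real_)
  k_hat <- oracle_pi_total(x)
  a1 <- sum(1 / (1:(n - 1)))
  a2 <- sum(1 / (1:(n - 1))^2)
  b1 <- (n + 1) / (3 * (n - 1))
  b2 <- 2 * (n * n + n + 3) / (9 * n * (n - 1))
  c1 <- b1 - 1 / a1
  c2 <- b2 - (n + 2) / (a1 * n) + a2 / (a1 * a1)
  V <- (c1 / a1) * S + (c2 / (a1 * a1 + a2)) * S * (S - 1)
  (k_hat - S / a1) / sqrt(V)
}

# Random fixture matrix
rand_hapmat <- function(n = 10, L = 20, seed = 1, p = NULL) {
  set.seed(seed)
  if (is.null(p)) p <- runif(L, 0.1, 0.9)
  x <- sapply(p, function(q) rbinom(n, 1, q))
  haplotype_matrix(x, sort(sample.int(10 * L, L)), "chrT",
                   paste0("s", seq_len(n / 2)))
}

# Matrix with populations attached (half P1, half P2)
rand_hapmat_pops <- function(n = 12, L = 15, seed = 1) {
  m <- rand_hapmat(n, L, seed)
  pops <- stats::setNames(rep(c("P1", "P2"), each = n / 4), m$sample_ids)
  m$population_of <- pops
  m
}
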