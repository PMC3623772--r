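## Maximum-likelihood HKA test. Polymorphism and divergence counts at locus
## i are modelled as independent Poisson draws:
##
##   S_i ~ Poisson(k_i * theta_i * L_i * a_n)
##   D_i ~ Poisson(theta_i * L_i * (T + k_i))
##
## with a_n the harmonic number for n sampled chromosomes, T the divergence
## time in coalescent units, theta_i a per-locus scaled mutation parameter
## and k_i a per-locus selection parameter (fixed to 1 at neutral loci).
## k > 1 deepens the within-locus coalescence, inflating both polymorphism
## and the ancestral-polymorphism component of divergence — the signature
## of balancing selection. The neutral and selection models are nested, so
## a likelihood-ratio test with df = number of selected loci applies.

#' Assemble an HKA dataset
#'
#' @param locus_id identifiers, one per locus
#' @param L locus lengths in bp (> 0)
#' @param S segregating-site counts in the focal-species sample
#' @param D divergence counts to the outgroup (consensus-vs-outgroup
#'   differences per locus)
#' @param n number of sampled chromosomes (shared across loci, >= 2)
#' @param is_selected logical; loci given a free selection parameter
#' @return data frame of class `HKADataset` with attribute `n`
#' @export
hka_dataset <- function(locus_id, L, S, D, n, is_selected = NULL) {
  if (is.null(is_selected)) is_selected <- rep(FALSE, length(locus_id))
  stopifnot(length(L) == length(locus_id), length(S) == length(locus_id),
            length(D) == length(locus_id))
  if (any(L <= 0)) stop("locus lengths must be positive")
  if (any(S < 0) || any(D < 0)) stop("counts must be non-negative")
  if (n < 2) stop("need n >= 2 sampled chromosomes")
  out <- data.frame(locus_id = as.character(locus_id), L = L,
                    S = as.integer(S), D = as.integer(D),
                    is_selected = is_selected, stringsAsFactors = FALSE)
  attr(out, "n") <- as.integer(n)
  class(out) <- c("HKADataset", class(out))
  out
}

#' Read an HKA dataset from TSV
#' @param path TSV with columns `locus_id`, `L`, `S`, `D`, `is_selected`
#' @param n number of sampled chromosomes
#' @export
read_hka_dataset <- function(path, n) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  hka_dataset(tab$locus_id, tab$L, tab$S, tab$D, n,
              as.logical(tab$is_selected))
}

#' HKA log-likelihood
#'
#' Poisson log-likelihood of the polymorphism/divergence counts with
#' constant terms (factorials) dropped:
#' `sum_i S_i log(lamS_i) - lamS_i + D_i log(lamD_i) - lamD_i`.
#'
#' @param data an [hka_dataset()]
#' @param theta per-locus theta values (> 0)
#' @param T divergence time, coalescent units (> 0)
#' @param k per-locus selection parameters (default all 1)
#' @return log-likelihood; `-Inf` when a zero mean meets a positive count
#' @export
hka_loglik <- function(data, theta, T, k = NULL) {
  n <- attr(data, "n")
  a_n <- harmonic_number(n - 1)
  if (is.null(k)) k <- rep(1, nrow(data))
  lamS <- k * theta * data$L * a_n
  lamD <- theta * data$L * (T + k)
  term <- function(x, lam) {
    out <- numeric(length(x))
    pos <- lam > 0
    out[pos] <- x[pos] * log(lam[pos]) - lam[pos]
    bad <- !pos & x > 0
    out[bad] <- -Inf
    out
  }
  sum(term(data$S, lamS)) + sum(term(data$D, lamD))
}

## Profile MLE of theta_i given (T, k): d logL / d theta_i = 0 gives
## theta_i = (S_i + D_i) / (L_i (k_i a_n + T + k_i)).
hka_profile_theta <- function(data, T, k, a_n) {
  (data$S + data$D) / (data$L * (k * a_n + T + k))
}

#' Fit the HKA model by maximum likelihood
#'
#' theta_i is profiled out in closed form; the remaining low-dimensional
#' surface over (log T, log k_selected) is maximized by seeded multi-start
#' Nelder-Mead. Deterministic for a given seed.
#'
#' @param data an [hka_dataset()]
#' @param free_k indices (or logical) of loci with a free selection
#'   parameter (constrained to `[0.01, 100]`); default taken from
#'   `data$is_selected`. Empty = neutral fit.
#' @param n_starts number of random restarts
#' @param seed RNG seed for the restart draws
#' @return list of class `HKAFit`: `theta`, `T`, `k`, `logL`, `converged`,
#'   `n_free_k`
#' @export
fit_hka <- function(data, free_k = NULL, n_starts = 20, seed = 1) {
  if (nrow(data) < 2) stop("need at least 2 loci")
  if (is.null(free_k)) free_k <- which(data$is_selected)
  if (is.logical(free_k)) free_k <- which(free_k)
  if (length(free_k) >= nrow(data))
    stop("at least one locus must remain neutral")
  n <- attr(data, "n")
  a_n <- harmonic_number(n - 1)
  nk <- length(free_k)

  ## k is constrained to [0.01, 100]: beyond that the likelihood flattens
  ## onto the (theta -> 0, k -> Inf) ridge where only k * theta is
  ## identifiable
  k_bound <- log(100)
  obj <- function(par) {
    if (any(!is.finite(par)) || par[1] < -10 || par[1] > 10) return(1e12)
    if (nk && any(abs(par[-1]) > k_bound)) return(1e12)
    T <- exp(par[1])
    k <- rep(1, nrow(data))
    if (nk) k[free_k] <- exp(par[-1])
    theta <- hka_profile_theta(data, T, k, a_n)
    ll <- hka_loglik(data, theta, T, k)
    if (!is.finite(ll)) return(1e12)
    -ll
  }

  set.seed(seed)
  best <- NULL
  for (s in seq_len(n_starts)) {
    start <- c(stats::runif(1, -1, 2.5), stats::runif(nk, -1.5, 1.5))
    fit <- if (nk == 0)
      stats::optim(start, obj, method = "Brent", lower = -10, upper = 10,
                   control = list(maxit = 2000))
    else
      stats::optim(start, obj, method = "Nelder-Mead",
                   control = list(maxit = 2000, reltol = 1e-12))
    if (is.null(best) || fit$value < best$value - 1e-12) best <- fit
  }
  T_hat <- exp(best$par[1])
  k_hat <- rep(1, nrow(data))
  if (nk) k_hat[free_k] <- exp(best$par[-1])
  theta_hat <- hka_profile_theta(data, T_hat, k_hat, a_n)
  ll <- hka_loglik(data, theta_hat, T_hat, k_hat)
  structure(list(theta = theta_hat, T = T_hat, k = k_hat, logL = ll,
                 converged = best$convergence == 0, n_free_k = nk,
                 free_k = free_k),
            class = "HKAFit")
}

#' @export
print.HKAFit <- function(x, ...) {
  cat(sprintf("HKAFit: logL = %.4f, T = %.4f, %d free selection parameter(s)%s\n",
              x$logL, x$T, x$n_free_k,
              if (x$converged) "" else " [NOT CONVERGED]"))
  if (x$n_free_k)
    cat("k at selected loci:", paste(signif(x$k[x$free_k], 5), collapse = " "), "\n")
  invisible(x)
}

#' Likelihood-ratio test for selection at designated loci
#'
#' Fits the neutral model (all `k_i = 1`) and the selection model (free
#' `k_i` at the designated loci) and compares them:
#' `LRT = 2 (logL_sel - logL_neutral)`, chi-square with df = number of
#' selected loci.
#'
#' @param data an [hka_dataset()]
#' @param selected indices (or logical) of loci tested for selection;
#'   must be a non-empty proper subset
#' @param n_starts,seed passed to [fit_hka()]
#' @return list: `lrt`, `df`, `p`, `fit_neutral`, `fit_selection`,
#'   `converged` (`p` is `NA` when either fit failed to converge)
#' @export
hka_lrt <- function(data, selected = NULL, n_starts = 20, seed = 1) {
  if (is.null(selected)) selected <- which(data$is_selected)
  if (is.logical(selected)) selected <- which(selected)
  if (!length(selected)) stop("selected must be non-empty")
  if (length(selected) >= nrow(data))
    stop("selected must be a proper subset of loci")
  fit0 <- fit_hka(data, free_k = integer(0), n_starts = n_starts, seed = seed)
  fit1 <- fit_hka(data, free_k = selected, n_starts = n_starts, seed = seed + 1)
  lrt <- max(0, 2 * (fit1$logL - fit0$logL))
  ok <- fit0$converged && fit1$converged
  p <- if (ok) stats::pchisq(lrt, df = length(selected), lower.tail = FALSE)
       else NA_real_
  list(lrt = lrt, df = length(selected), p = p,
       fit_neutral = fit0, fit_selection = fit1, converged = ok)
}
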