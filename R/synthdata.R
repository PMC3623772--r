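## Coalescent generator of every input the pipeline consumes: neutral
## background windows, an ancient-substructure locus with two deeply
## diverged haplogroups, a linked deletion allele, an archaic lineage,
## expression vectors and read-depth profiles. Infinite-sites mutation, no
## intra-window recombination (the strong-LD block premise); windows are
## mutually independent. Times are in coalescent units of 2N generations.

## Hudson coalescent for n tips, recording for every branch its subtended
## tip set and length. O(n) events; lengths via birth/death times.
sim_coalescent_tips <- function(n) {
  tips <- as.list(seq_len(n))
  birth <- rep(0, n)
  alive <- seq_len(n)
  branches <- vector("list", 2L * (n - 1L))
  nb <- 0L
  t <- 0
  for (k in n:2) {
    t <- t + stats::rexp(1L, rate = k * (k - 1) / 2)
    pick <- sample(length(alive), 2L)
    i <- alive[pick[1L]]; j <- alive[pick[2L]]
    branches[[nb + 1L]] <- list(tips = tips[[i]], length = t - birth[i])
    branches[[nb + 2L]] <- list(tips = tips[[j]], length = t - birth[j])
    nb <- nb + 2L
    tips[[i]] <- c(tips[[i]], tips[[j]])
    birth[i] <- t
    alive <- alive[-pick[2L]]
  }
  list(branches = branches, tmrca = t)
}

## Neutral infinite-sites sample: 0/1 matrix (n x S), mutations
## Poisson(theta/2 * total branch length), placed proportionally to branch
## length. Column order is arbitrary here; positions are assigned by the
## callers.
sim_neutral_alleles <- function(n, theta) {
  if (n < 2) stop("need n >= 2")
  g <- sim_coalescent_tips(n)
  lens <- vapply(g$branches, `[[`, numeric(1), "length")
  total <- sum(lens)
  n_mut <- stats::rpois(1L, theta / 2 * total)
  mat <- matrix(0L, n, n_mut)
  if (n_mut > 0) {
    br <- sample.int(length(lens), n_mut, replace = TRUE, prob = lens)
    for (j in seq_len(n_mut)) mat[g$branches[[br[j]]]$tips, j] <- 1L
  }
  list(alleles = mat, tmrca = g$tmrca)
}

## Draw m distinct integer positions from [lo, hi] excluding `reserved`.
draw_positions <- function(m, lo, hi, reserved = integer(0)) {
  pool_size <- hi - lo + 1L - length(reserved)
  if (m > pool_size) stop("more mutations than available positions in window")
  if (m == 0) return(integer(0))
  ## rejection sampling keeps memory O(m) even for wide windows
  got <- integer(0)
  excl <- c(reserved)
  while (length(got) < m) {
    cand <- lo + sample.int(hi - lo + 1L, m - length(got), replace = TRUE) - 1L
    cand <- setdiff(unique(cand), excl)
    got <- c(got, cand)
    excl <- c(excl, cand)
  }
  got[seq_len(m)]
}

#' Simulate a neutral coalescent sample
#'
#' Hudson coalescent with infinite-sites mutation: exponential coalescence
#' times with rate `choose(k, 2)` (time in units of 2N generations) and
#' `Poisson(theta/2 * total branch length)` mutations placed uniformly on
#' branches, with positions uniform over the window.
#'
#' @param n number of haplotypes (even, so rows pair into diploids)
#' @param theta scaled mutation rate (4N mu) for the whole window
#' @param seed optional RNG seed
#' @param window_bp window width in bp (positions are drawn inside it)
#' @param start 1-based coordinate of the window's first base
#' @param contig contig name
#' @param sample_prefix prefix for generated sample ids
#' @return a `HaplotypeMatrix`
#' @export
simulate_neutral_sample <- function(n, theta, seed = NULL, window_bp = 10000,
                                    start = 1L, contig = "chr_sim",
                                    sample_prefix = "s") {
  if (n %% 2 != 0) stop("n must be even (two haplotypes per diploid sample)")
  if (theta < 0) stop("theta must be >= 0")
  if (!is.null(seed)) set.seed(seed)
  sim <- sim_neutral_alleles(n, theta)
  n_mut <- ncol(sim$alleles)
  ## positions are exchangeable across mutations; sorted draw, columns as-is
  pos <- sort(draw_positions(n_mut, start, start + window_bp - 1L))
  m <- haplotype_matrix(sim$alleles, pos, contig,
                        paste0(sample_prefix, seq_len(n / 2)))
  attr(m, "tmrca") <- sim$tmrca
  m
}

#' Configuration for the ancient-substructure locus
#'
#' Defines the assumed history of the locus: two haplogroups (NE1-like and
#' nonNE1-like) that diverged `t_split` coalescent units ago, population
#' target frequencies for the NE1 haplogroup that are hit exactly by label
#' assignment, a panel of fixed tag SNPs on the NE1 stem (hence in perfect
#' LD with clade membership), a deletion allele carried by every NE1
#' haplotype, and an archaic lineage sampled from the NE1 stem.
#'
#' Default history: `t_split = 11.5` (the dated haplogroup coalescence of
#' ~4.6 My at N = 1e4 and 20-year generations, one unit = 0.4 My), clade
#' roots at 3, locus analog of 36 kb with theta 10 per clade, NE1
#' frequencies 3% in AFR, 36% in EUR, 30% in EAS (the sub-Saharan versus
#' European contrast of the deletion allele), and a 3x within-clade theta
#' multiplier for African NE1 haplotypes (the deep African clade).
#'
#' @param n_per_pop haplotypes per population (even)
#' @param pops named vector of NE1 target frequencies per population;
#'   `freq * n_per_pop` must be whole numbers
#' @param t_split haplogroup divergence time (2N-generation units)
#' @param t_clade_root named times (`NE1`, `nonNE1`) at which each clade's
#'   per-population subclades join; must be < `t_split`
#' @param theta_locus scaled mutation rate of the locus per clade
#' @param n_tag_snps number of planted fixed tag SNPs (>= 1)
#' @param locus_bp locus width in bp
#' @param locus_start first coordinate of the locus
#' @param deletion_interval optional [genomic_interval()] for the deletion
#'   carried by NE1 haplotypes; default a 4,580-bp interval inside the locus
#' @param archaic_from clade the archaic lineage is sampled from
#' @param african_pop population whose NE1 subclade is deepened
#' @param african_theta_multiplier within-clade theta multiplier for the
#'   African NE1 subclade
#' @param clade_size_scaling if `TRUE` (default) each clade's internal
#'   coalescence is sped up by its pooled frequency, as in the structured
#'   coalescent for a balanced polymorphism at equilibrium (lineages within
#'   an allelic class of frequency x coalesce as in a population of size
#'   x N). This reproduces the shallow within-haplogroup coalescence
#'   observed at such loci; `FALSE` gives each clade a full-size neutral
#'   genealogy.
#' @param contig contig name
#' @param seed RNG seed
#' @return list of class `SubstructureConfig`
#' @export
substructure_config <- function(n_per_pop = 100,
                                pops = c(AFR = 0.03, EUR = 0.36, EAS = 0.30),
                                t_split = 11.5,
                                t_clade_root = c(NE1 = 3, nonNE1 = 3),
                                theta_locus = 10,
                                n_tag_snps = 12,
                                locus_bp = 36000,
                                locus_start = 1L,
                                deletion_interval = NULL,
                                archaic_from = "NE1",
                                african_pop = "AFR",
                                african_theta_multiplier = 3,
                                clade_size_scaling = TRUE,
                                contig = "chr_sim",
                                seed = 1) {
  if (n_per_pop %% 2 != 0) stop("n_per_pop must be even")
  if (any(pops < 0 | pops > 1)) stop("frequencies must be in [0, 1]")
  counts <- pops * n_per_pop
  if (any(abs(counts - round(counts)) > 1e-9))
    stop("target frequency x n_per_pop must be a whole number for every population")
  if (t_split <= 0) stop("t_split must be positive")
  if (any(t_clade_root >= t_split)) stop("clade roots must predate t_split")
  if (n_tag_snps < 1) stop("need at least one tag SNP")
  if (is.null(deletion_interval)) {
    del_len <- min(4580L, max(2L, floor(locus_bp / 3)))
    del_start <- locus_start + floor((locus_bp - del_len) / 2)
    deletion_interval <- genomic_interval(contig, del_start,
                                          del_start + del_len - 1L)
  }
  structure(list(n_per_pop = n_per_pop, pops = pops, t_split = t_split,
                 t_clade_root = t_clade_root, theta_locus = theta_locus,
                 n_tag_snps = n_tag_snps, locus_bp = locus_bp,
                 locus_start = as.integer(locus_start),
                 deletion_interval = deletion_interval,
                 archaic_from = archaic_from, african_pop = african_pop,
                 african_theta_multiplier = african_theta_multiplier,
                 clade_size_scaling = clade_size_scaling,
                 contig = contig, seed = seed),
            class = "SubstructureConfig")
}

## Clade simulation with rejection so the clade TMRCA predates the clade
## root time; returns alleles plus realized TMRCA.
sim_clade_conditioned <- function(n, theta, t_max, max_tries = 1000) {
  if (n == 1) return(list(alleles = matrix(0L, 1, 0), tmrca = 0))
  for (i in seq_len(max_tries)) {
    sim <- sim_neutral_alleles(n, theta)
    if (sim$tmrca < t_max) return(sim)
  }
  stop("could not simulate a clade with TMRCA < ", t_max,
       "; increase t_clade_root or reduce sample size")
}

#' Simulate the ancient-substructure locus
#'
#' Generates the locus the pipeline is designed to detect: two clades that
#' coalesce internally (neutral coalescent per population subclade, joined
#' at the clade root) and join at `t_split`; tag SNPs planted as fixed
#' differences on the NE1 stem (perfect LD with clade membership); the
#' deletion carried by all NE1 haplotypes; an archaic haplotype drawn from
#' the NE1 stem; NE1 population frequencies hit exactly by construction.
#'
#' @param cfg a [substructure_config()]
#' @return list: `matrix` (a `HaplotypeMatrix` with populations attached),
#'   `truth` (per-haplotype clade labels, tag positions, deletion carriers
#'   and per-sample deletion genotype classes, realized clade TMRCAs),
#'   `panel` (a [tag_snp_panel()]), `archaic` (0/1 vector over the matrix
#'   sites), `config`
#' @export
simulate_substructure_locus <- function(cfg) {
  stopifnot(inherits(cfg, "SubstructureConfig"))
  set.seed(cfg$seed)
  pops <- names(cfg$pops)
  ne1_counts <- as.integer(round(cfg$pops * cfg$n_per_pop))
  names(ne1_counts) <- pops
  non_counts <- cfg$n_per_pop - ne1_counts

  ## haplotype bookkeeping: global row index per (pop, clade)
  n_total <- cfg$n_per_pop * length(pops)
  pop_of_hap <- rep(pops, each = cfg$n_per_pop)
  clade <- character(n_total)
  idx <- split(seq_len(n_total), pop_of_hap)[pops]
  members <- list(NE1 = list(), nonNE1 = list())
  for (p in pops) {
    rows <- idx[[p]]
    pick <- sample(rows, ne1_counts[[p]])
    members$NE1[[p]] <- sort(pick)
    members$nonNE1[[p]] <- sort(setdiff(rows, pick))
    clade[members$NE1[[p]]] <- "NE1"
    clade[members$nonNE1[[p]]] <- "nonNE1"
  }

  cols <- list()   # each: list(carriers = global rows, n = multiplicity of columns)
  add_cols <- function(carriers, k) {
    if (k > 0) cols[[length(cols) + 1L]] <<- list(carriers = carriers, k = k)
  }

  ## Simulate one subclade genealogy over `rows` with internal time scaled
  ## by `f` (clade-frequency scaling), conditioned to coalesce before
  ## t_root, then add its stem (t_root back to the subclade TMRCA)
  ## mutations. Mutation counts scale with the same factor because branch
  ## lengths do.
  sim_subclade <- function(rows, theta, f, t_root, t_join) {
    np <- length(rows)
    tm <- 0
    if (np >= 2) {
      sim <- sim_clade_conditioned(np, theta * f, t_root / f)
      for (j in seq_len(ncol(sim$alleles)))
        add_cols(rows[sim$alleles[, j] == 1L], 1L)
      tm <- sim$tmrca * f
    }
    if (np >= 1)
      add_cols(rows, stats::rpois(1L, cfg$theta_locus / 2 * (t_join - tm)))
    tm
  }

  clade_tmrca <- c(NE1 = 0, nonNE1 = 0)
  for (cl in c("NE1", "nonNE1")) {
    all_rows <- sort(unlist(members[[cl]]))
    if (!length(all_rows)) next
    f <- if (cfg$clade_size_scaling) length(all_rows) / n_total else 1
    t_root <- cfg$t_clade_root[[cl]]
    if (cl == "NE1" && cfg$african_theta_multiplier != 1) {
      ## deep African NE1 subclade: African and non-African NE1 haplotypes
      ## coalesce separately (African ones at elevated theta) and join at
      ## the clade root
      afr <- members[[cl]][[cfg$african_pop]]
      rest <- sort(setdiff(all_rows, afr))
      tm_a <- if (length(afr))
        sim_subclade(afr, cfg$theta_locus * cfg$african_theta_multiplier,
                     f, t_root, t_root) else 0
      tm_r <- if (length(rest))
        sim_subclade(rest, cfg$theta_locus, f, t_root, t_root) else 0
      clade_tmrca[[cl]] <- if (length(afr) && length(rest)) t_root
                           else max(tm_a, tm_r)
    } else {
      clade_tmrca[[cl]] <- sim_subclade(all_rows, cfg$theta_locus, f,
                                        t_root, t_root)
    }
    ## clade stem from the clade root up to the haplogroup split
    add_cols(all_rows, stats::rpois(1L, cfg$theta_locus / 2 *
                                      (cfg$t_split - t_root)))
  }

  ne1_rows <- which(clade == "NE1")
  non_rows <- which(clade == "nonNE1")

  ## expand multiplicities into one column per mutation
  carriers <- unlist(lapply(cols, function(cl) rep(list(cl$carriers), cl$k)),
                     recursive = FALSE)
  n_rand <- length(carriers)

  ## tag SNPs: evenly spaced reserved positions, derived allele fixed in NE1
  lo <- cfg$locus_start; hi <- cfg$locus_start + cfg$locus_bp - 1L
  tag_pos <- as.integer(round(seq(lo + cfg$locus_bp * 0.05,
                                  hi - cfg$locus_bp * 0.05,
                                  length.out = cfg$n_tag_snps)))
  rand_pos <- draw_positions(n_rand, lo, hi, reserved = tag_pos)

  pos_all <- c(tag_pos, rand_pos)
  carriers_all <- c(rep(list(ne1_rows), cfg$n_tag_snps), carriers)
  is_tag <- c(rep(TRUE, cfg$n_tag_snps), rep(FALSE, n_rand))
  ## archaic lineage: the clade-stem sequence of the chosen clade — carries
  ## the tag SNPs (if NE1) and that clade's stem/subclade-shared mutations
  ## present in all clade members, none of the private variation
  arch_rows <- if (cfg$archaic_from == "NE1") ne1_rows else non_rows
  archaic_all <- vapply(carriers_all, function(cr) all(arch_rows %in% cr),
                        logical(1))

  ord <- order(pos_all)
  pos_all <- pos_all[ord]
  carriers_all <- carriers_all[ord]
  is_tag <- is_tag[ord]
  archaic <- as.integer(archaic_all[ord])

  alle <- matrix(0L, n_total, length(pos_all))
  for (j in seq_along(carriers_all)) alle[carriers_all[[j]], j] <- 1L

  sample_ids <- paste0(rep(pops, each = cfg$n_per_pop / 2), "_",
                       sprintf("%03d", sequence(rep(cfg$n_per_pop / 2,
                                                    length(pops)))))
  population_of <- stats::setNames(rep(pops, each = cfg$n_per_pop / 2),
                                   sample_ids)
  m <- haplotype_matrix(alle, pos_all, cfg$contig, sample_ids,
                        population_of = population_of)

  panel <- tag_snp_panel(pos_all[is_tag],
                         consensus_a = rep(1L, cfg$n_tag_snps),
                         consensus_b = rep(0L, cfg$n_tag_snps))

  ## deletion genotype class per sample = NE1 haplotype copies (0/1/2)
  hap_sample <- rep(seq_len(n_total / 2), each = 2)
  del_geno <- tapply(clade == "NE1", hap_sample, sum)
  del_geno <- stats::setNames(as.integer(del_geno), sample_ids)

  truth <- list(
    clade = stats::setNames(clade, m$haplotype_ids),
    tag_positions = pos_all[is_tag],
    deletion_interval = cfg$deletion_interval,
    deletion_carriers = m$haplotype_ids[ne1_rows],
    deletion_genotype = del_geno,
    clade_tmrca = clade_tmrca,
    t_split = cfg$t_split)
  list(matrix = m, truth = truth, panel = panel, archaic = archaic,
       config = cfg)
}

#' Simulate a genome of neutral background windows
#'
#' Independent neutral coalescent windows on one contig (implicit free
#' recombination between windows), optionally with the substructure locus
#' planted into one window — the synthetic genome used to calibrate
#' empirical nulls and measure quadrant-filter power.
#'
#' @param n_windows number of windows (>= 1)
#' @param n haplotypes per window (even); ignored when `plant` is given
#'   (the plant's sample set is used genome-wide)
#' @param theta scaled mutation rate per window
#' @param seed RNG seed
#' @param window_bp window width in bp
#' @param plant optional [substructure_config()]; its `locus_bp`,
#'   `locus_start` and `contig` are overridden to fit the chosen window
#' @param plant_window index of the window receiving the planted locus
#' @param contig contig name
#' @return list: `matrix` (all windows combined), `windows` (data frame with
#'   `is_planted` flag), and when planted `truth`, `panel`, `archaic`
#' @export
simulate_genome_background <- function(n_windows, n, theta, seed = NULL,
                                       window_bp = 10000, plant = NULL,
                                       plant_window = NULL,
                                       contig = "chr_sim") {
  if (n_windows < 1) stop("need at least one window")
  if (!is.null(seed)) set.seed(seed)
  plant_res <- NULL
  if (!is.null(plant)) {
    if (is.null(plant_window)) plant_window <- sample.int(n_windows, 1)
    ## refit the locus geometry (incl. default deletion interval) to the
    ## chosen window
    plant <- substructure_config(
      n_per_pop = plant$n_per_pop, pops = plant$pops, t_split = plant$t_split,
      t_clade_root = plant$t_clade_root, theta_locus = plant$theta_locus,
      n_tag_snps = plant$n_tag_snps, locus_bp = window_bp,
      locus_start = as.integer((plant_window - 1) * window_bp + 1),
      archaic_from = plant$archaic_from, african_pop = plant$african_pop,
      african_theta_multiplier = plant$african_theta_multiplier,
      contig = contig, seed = sample.int(2^31 - 1, 1))
    plant_res <- simulate_substructure_locus(plant)
    n <- n_haplotypes(plant_res$matrix)
  }
  pos <- list(); alle <- list()
  for (w in seq_len(n_windows)) {
    if (!is.null(plant_window) && w == plant_window) {
      pos[[w]] <- plant_res$matrix$positions
      alle[[w]] <- plant_res$matrix$alleles
      next
    }
    sim <- sim_neutral_alleles(n, theta)
    k <- ncol(sim$alleles)
    pw <- sort(draw_positions(k, (w - 1L) * window_bp + 1L, w * window_bp))
    pos[[w]] <- pw
    alle[[w]] <- sim$alleles
  }
  if (!is.null(plant_res)) {
    sample_ids <- plant_res$matrix$sample_ids
    population_of <- plant_res$matrix$population_of
  } else {
    sample_ids <- paste0("s", seq_len(n / 2))
    population_of <- NULL
  }
  m <- haplotype_matrix(do.call(cbind, alle), unlist(pos), contig, sample_ids,
                        population_of = population_of)
  windows <- data.frame(contig = contig,
                        start = as.integer((seq_len(n_windows) - 1) * window_bp + 1),
                        end = as.integer(seq_len(n_windows) * window_bp),
                        is_planted = seq_len(n_windows) %in%
                          (if (is.null(plant_window)) integer(0) else plant_window),
                        stringsAsFactors = FALSE)
  out <- list(matrix = m, windows = windows)
  if (!is.null(plant_res)) {
    out$truth <- plant_res$truth
    out$panel <- plant_res$panel
    out$archaic_window <- plant_window
    ## archaic consensus over the full matrix: defined at the planted
    ## locus, NA (undefined, dropped pairwise downstream) elsewhere
    arch <- rep(NA_integer_, n_sites(m))
    arch[match(plant_res$matrix$positions, m$positions)] <- plant_res$archaic
    out$archaic <- arch
  }
  out
}

#' Simulate expression values coupled to genotype
#'
#' `expression = beta * genotype + N(0, sigma^2)` — the linear eQTL model
#' behind the Spearman association stage.
#'
#' @param genotypes allele counts 0/1/2 per sample
#' @param beta effect size per allele copy
#' @param sigma noise standard deviation (>= 0)
#' @param seed optional RNG seed
#' @return numeric expression vector
#' @export
simulate_expression <- function(genotypes, beta, sigma, seed = NULL) {
  if (sigma < 0) stop("sigma must be >= 0")
  if (!is.null(seed)) set.seed(seed)
  beta * genotypes + stats::rnorm(length(genotypes), 0, sigma)
}

#' Simulate a read-depth profile over a candidate deletion
#'
#' Per-position depth is Poisson(coverage * dose) with dose 0, 0.5 or 1
#' inside the interval for hom_del / het_del / no_del and dose 1 in the
#' flanks.
#'
#' @param interval a [genomic_interval()] (the candidate deletion)
#' @param coverage mean haploid-pair coverage (> 0)
#' @param zygosity `"hom_del"`, `"het_del"` or `"no_del"`
#' @param seed optional RNG seed
#' @param flank_bp flank width on each side
#' @return data frame with `pos`, `depth`
#' @export
simulate_depth_profile <- function(interval, coverage,
                                   zygosity = c("no_del", "het_del", "hom_del"),
                                   seed = NULL, flank_bp = 1000) {
  zygosity <- match.arg(zygosity)
  if (coverage <= 0) stop("coverage must be positive")
  if (!is.null(seed)) set.seed(seed)
  pos <- seq.int(max(1L, interval$start - flank_bp), interval$end + flank_bp)
  dose <- rep(1, length(pos))
  inside <- pos >= interval$start & pos <= interval$end
  dose[inside] <- switch(zygosity, hom_del = 0, het_del = 0.5, no_del = 1)
  data.frame(pos = pos, depth = stats::rpois(length(pos), coverage * dose))
}

#' Simulate an HKA dataset from the model's Poisson family
#'
#' Draws `S_i ~ Poisson(k_i theta_i L_i a_n)` and
#' `D_i ~ Poisson(theta_i L_i (T + k_i))` — the parametric generator used
#' to calibrate the likelihood-ratio test.
#'
#' @param n_loci number of loci
#' @param theta per-locus theta (recycled)
#' @param T divergence time (coalescent units)
#' @param n sampled chromosomes
#' @param L locus lengths (recycled)
#' @param k selection parameters (recycled; 1 = neutral)
#' @param selected indices marked as selected in the dataset
#' @param seed optional RNG seed
#' @return an [hka_dataset()]
#' @export
simulate_hka_dataset <- function(n_loci, theta, T, n, L = 1, k = 1,
                                 selected = integer(0), seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  theta <- rep_len(theta, n_loci)
  L <- rep_len(L, n_loci)
  k <- rep_len(k, n_loci)
  a_n <- harmonic_number(n - 1)
  S <- stats::rpois(n_loci, k * theta * L * a_n)
  D <- stats::rpois(n_loci, theta * L * (T + k))
  hka_dataset(paste0("locus", seq_len(n_loci)), L, S, D, n,
              seq_len(n_loci) %in% selected)
}

#' Synthesize a reference/sample sequence pair with a planted deletion
#'
#' Generates a random A/C/G/T reference spanning `[origin, origin +
#' ref_length - 1]` and a sample sequence with the given interval deleted —
#' input material for [map_deletion_breakpoints()]. Synthetic stand-in for
#' resequenced breakpoint amplicons.
#'
#' @param ref_length reference length in bp
#' @param deletion a [genomic_interval()] inside the reference span
#' @param origin genomic coordinate of the first reference base
#' @param seed optional RNG seed
#' @return list: `reference`, `sample` (character strings), `deletion`,
#'   `origin`
#' @export
synthesize_deletion_sequences <- function(ref_length, deletion, origin = 1L,
                                          seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (deletion$start < origin || deletion$end > origin + ref_length - 1L)
    stop("deletion interval outside the reference span")
  ref <- paste(sample(c("A", "C", "G", "T"), ref_length, replace = TRUE),
               collapse = "")
  list(reference = ref, sample = apply_deletion(ref, deletion, origin),
       deletion = deletion, origin = origin)
}

#' Convert coalescent time to years
#'
#' Times in this package's simulations are in units of 2N generations; this
#' makes the conversion to calendar years explicit.
#' @param t time in 2N-generation units
#' @param N diploid effective population size
#' @param generation_time years per generation
#' @export
coalescent_time_to_years <- function(t, N, generation_time) {
  t * 2 * N * generation_time
}
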