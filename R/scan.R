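## Genome-scale window machinery: tiling, per-window statistics, empirical
## outlier p-values against a genome-wide background, stratified
## comparisons, the four-statistic quadrant filter, and inter-statistic
## correlations.

#' Tile contigs into windows
#'
#' @param contig_lengths named numeric vector (contig -> length in bp)
#' @param size window size in bp (>= 1)
#' @param step step in bp (>= 1); `step = size` gives a non-overlapping
#'   tiling. The last window is truncated at the contig end.
#' @return data frame with `contig`, `start`, `end` (1-based inclusive)
#' @export
make_windows <- function(contig_lengths, size, step = size) {
  if (size < 1 || step < 1) stop("size and step must be >= 1")
  out <- lapply(names(contig_lengths), function(ctg) {
    len <- contig_lengths[[ctg]]
    starts <- seq.int(1L, len, by = step)
    starts <- starts[starts <= len]
    data.frame(contig = ctg, start = as.integer(starts),
               end = as.integer(pmin(starts + size - 1, len)),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Per-window diversity and selection statistics
#'
#' For each window computes pi, S, Watterson's theta, Tajima's D (with an
#' optional coalescent-simulation p-value), Hudson's FST for a population
#' pair, and mean pairwise r-squared. Monomorphic/empty windows carry `NA`
#' for the undefined statistics.
#'
#' @param m a `HaplotypeMatrix` (population assignments required when
#'   `pops` or `focal_pop` is given)
#' @param windows data frame from [make_windows()], sorted by start
#' @param pops optional ordered pair of population labels for FST (always
#'   computed on the full matrix)
#' @param focal_pop optional population label; when given, pi, S, D and
#'   r-squared are computed within that population only, as in scans that
#'   profile diversity in one panel while contrasting two panels for FST
#' @param maf_min MAF filter for the LD statistic
#' @param tajima_reps coalescent replicates for the per-window D p-value;
#'   0 (the default) skips the simulation
#' @param seed RNG seed used (once) when `tajima_reps > 0`
#' @return data frame with one row per window: `contig`, `start`, `end`,
#'   `n`, `S`, `pi_total`, `pi_per_site`, `theta_w`, `tajima_D`, `tajima_p`,
#'   `fst`, `mean_r2`, `pair_count`
#' @export
window_scan <- function(m, windows, pops = NULL, focal_pop = NULL,
                        maf_min = 0.05, tajima_reps = 0, seed = NULL) {
  if (is.unsorted(windows$start)) stop("windows must be sorted")
  if (!is.null(seed)) set.seed(seed)
  mf <- if (is.null(focal_pop)) m else subset_population(m, focal_pop)
  n <- n_haplotypes(mf)
  rows <- lapply(seq_len(nrow(windows)), function(i) {
    iv <- genomic_interval(windows$contig[i], windows$start[i], windows$end[i])
    mw <- suppressWarnings(extract_region(mf, iv))
    len <- interval_length(iv)
    div <- nucleotide_diversity(mw, region_length = len)
    D <- tajimas_d_from_summary(div$pi_total, div$S, n)
    taj_p <- NA_real_
    if (tajima_reps > 0 && is.finite(D))
      taj_p <- tajima_p_by_simulation(D, n, div$S, reps = tajima_reps)
    fst <- NA_real_
    if (!is.null(pops)) {
      mw_full <- suppressWarnings(extract_region(m, iv))
      if (n_sites(mw_full) > 0) fst <- hudson_fst(mw_full, pops)$region_fst
    }
    ld <- mean_pairwise_r2(mw, maf_min = maf_min)
    data.frame(contig = iv$contig, start = iv$start, end = iv$end, n = n,
               S = div$S, pi_total = div$pi_total,
               pi_per_site = div$pi_total / len, theta_w = div$theta_w,
               tajima_D = D, tajima_p = taj_p, fst = fst,
               mean_r2 = ld$mean_r2, pair_count = ld$n_pairs,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Write a window-scan table as TSV
#' @param rows data frame from [window_scan()]
#' @param path output path
#' @export
write_window_stats <- function(rows, path) {
  utils::write.table(rows, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Empirical outlier p-value against a background distribution
#'
#' Add-one rank convention: `p = (1 + #\{b >= observed\}) / (1 + |background|)`
#' for the upper tail (mirrored for the lower), so p is never 0 and lies in
#' (0, 1]. Non-finite background entries are excluded first.
#'
#' @param observed observed statistic
#' @param background numeric vector of background values
#' @param tail `"upper"` or `"lower"`
#' @export
empirical_pvalue <- function(observed, background, tail = c("upper", "lower")) {
  tail <- match.arg(tail)
  background <- background[is.finite(background)]
  if (!length(background)) stop("empty background after removing undefined values")
  hits <- if (tail == "upper") sum(background >= observed)
          else sum(background <= observed)
  (1 + hits) / (1 + length(background))
}

#' Empirical p-value within a stratum of windows
#'
#' Restricts the background to the rows satisfying `predicate` (e.g. windows
#' in the top LD or segregating-site percentile) before ranking the observed
#' value — the control used to show that an outlier is not explained by LD
#' or SNP density alone.
#'
#' @param observed observed statistic value
#' @param rows window-scan data frame
#' @param stat column name of the statistic
#' @param predicate function taking `rows` and returning a logical vector
#' @param tail `"upper"` or `"lower"`
#' @export
stratified_empirical_pvalue <- function(observed, rows, stat, predicate,
                                        tail = c("upper", "lower")) {
  keep <- predicate(rows)
  if (!any(keep, na.rm = TRUE))
    stop("empty stratum for predicate: ", deparse1(substitute(predicate)))
  empirical_pvalue(observed, rows[[stat]][which(keep)], tail = match.arg(tail))
}

#' Quadrant filter for balanced-polymorphism candidate regions
#'
#' Selects windows simultaneously exceeding thresholds on pi (per site),
#' mean r-squared, Tajima's D and FST, and merges maximal runs of abutting
#' qualifying windows into candidate regions. Defaults are the scan
#' thresholds used to recover the chr22 locus and its four genome-wide
#' companions (pi > 0.002, r^2 > 0.5, D > 4.5, FST > 0.2).
#'
#' @param rows window-scan data frame
#' @param pi_min,r2_min,d_min,fst_min thresholds (strict inequalities)
#' @return data frame of disjoint sorted regions (`contig`, `start`, `end`);
#'   zero rows when no window qualifies
#' @export
quadrant_filter <- function(rows, pi_min = 0.002, r2_min = 0.5,
                            d_min = 4.5, fst_min = 0.2) {
  ok <- !is.na(rows$pi_per_site) & rows$pi_per_site > pi_min &
    !is.na(rows$mean_r2) & rows$mean_r2 > r2_min &
    !is.na(rows$tajima_D) & rows$tajima_D > d_min &
    !is.na(rows$fst) & rows$fst > fst_min
  q <- rows[ok, c("contig", "start", "end")]
  if (!nrow(q)) return(q)
  q <- q[order(q$contig, q$start), ]
  out <- q[1, ]
  for (i in seq_len(nrow(q))[-1]) {
    last <- nrow(out)
    if (q$contig[i] == out$contig[last] && q$start[i] == out$end[last] + 1L)
      out$end[last] <- q$end[i]
    else out <- rbind(out, q[i, ])
  }
  rownames(out) <- NULL
  out
}

#' Pearson correlation between two window statistics
#'
#' @param rows window-scan data frame
#' @param statA,statB column names; rows where either is undefined are
#'   dropped. Fewer than 10 usable rows is an error.
#' @return list: `r`, `p`, `n`
#' @export
stat_correlation <- function(rows, statA, statB) {
  a <- rows[[statA]]; b <- rows[[statB]]
  use <- is.finite(a) & is.finite(b)
  if (sum(use) < 10) stop("need at least 10 windows with both statistics defined")
  ct <- stats::cor.test(a[use], b[use], method = "pearson")
  list(r = unname(ct$estimate), p = ct$p.value, n = sum(use))
}
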