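## Haplotype networks and rho-statistic coalescence dating.
##
## The median-joining construction follows Bandelt, Forster & Roehl (1999)
## for binary characters with epsilon = 0: iterate (i) build the minimum
## spanning network (union of all minimum spanning trees) over the current
## node set, (ii) for every pair of network edges sharing a node, propose
## the per-site majority (median/Steiner) vector of the triplet, (iii) add
## the new median vectors of minimal connection cost; stop when no median
## is new. Median vectors of degree <= 2 in the final network are pruned
## (they lie on geodesics and add nothing).

hamming_matrix <- function(x) {
  d <- as.matrix(stats::dist(x, method = "manhattan"))
  dimnames(d) <- NULL
  d
}

## Minimum spanning network: edge (u,v) belongs iff u and v are not already
## connected using only strictly shorter edges (Kruskal with ties kept).
msn_edges <- function(d) {
  n <- nrow(d)
  if (n < 2) return(matrix(integer(0), 0, 3))
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) { parent[i] <<- parent[parent[i]]; i <- parent[i] }; i }
  ut <- which(upper.tri(d), arr.ind = TRUE)
  w <- d[upper.tri(d)]
  ord <- order(w)
  edges <- matrix(integer(0), 0, 3)
  k <- 1
  while (k <= length(ord)) {
    ## process all edges of equal weight together, testing connectivity
    ## against the state before this weight class
    wk <- w[ord[k]]
    grp <- k
    while (grp < length(ord) && w[ord[grp + 1]] == wk) grp <- grp + 1
    batch <- ord[k:grp]
    keep <- batch[vapply(batch, function(e)
      find(ut[e, 1]) != find(ut[e, 2]), logical(1))]
    for (e in keep) {
      edges <- rbind(edges, c(ut[e, 1], ut[e, 2], wk))
    }
    for (e in keep) {
      ri <- find(ut[e, 1]); rj <- find(ut[e, 2])
      if (ri != rj) parent[ri] <- rj
    }
    if (all(vapply(seq_len(n), function(i) find(i) == find(1), logical(1))))
      break
    k <- grp + 1
  }
  colnames(edges) <- c("from", "to", "weight")
  edges
}

#' Build a haplotype network
#'
#' Median-joining network (default) or minimum spanning network over
#' distinct binary haplotypes. Inferred median (Steiner) vectors are added
#' with multiplicity 0 and flagged.
#'
#' @param haps matrix of 0/1 alleles with one row per distinct haplotype, or
#'   a character vector of equal-length 0/1 strings
#' @param counts observed multiplicity per haplotype (default 1 each;
#'   0 is allowed, e.g. for an inferred ancestral sequence supplied as a
#'   node)
#' @param method `"mjn"` (median-joining, epsilon = 0) or `"msn"`
#' @param max_iter safety cap on median-addition rounds
#' @return list of class `HaplotypeNetwork`: `nodes` (matrix incl. medians),
#'   `counts`, `is_median` (logical), `edges` (from, to, weight = mutational
#'   steps), `graph` (igraph object)
#' @export
build_network <- function(haps, counts = NULL, method = c("mjn", "msn"),
                          max_iter = 25L) {
  method <- match.arg(method)
  if (is.character(haps))
    haps <- do.call(rbind, lapply(strsplit(haps, ""), as.integer))
  haps <- as.matrix(haps)
  if (nrow(haps) < 2) stop("need at least 2 distinct haplotypes")
  if (anyDuplicated(apply(haps, 1, paste, collapse = "")))
    stop("haplotypes must be distinct; aggregate duplicates into counts")
  if (is.null(counts)) counts <- rep(1L, nrow(haps))
  n_sampled <- nrow(haps)
  nodes <- haps
  is_median <- rep(FALSE, nrow(nodes))

  key <- function(v) paste(v, collapse = "")
  seen <- new.env(parent = emptyenv())
  for (i in seq_len(nrow(nodes))) assign(key(nodes[i, ]), TRUE, envir = seen)

  if (method == "mjn") {
    for (iter in seq_len(max_iter)) {
      d <- hamming_matrix(nodes)
      ed <- msn_edges(d)
      ## adjacency list of the current MSN
      adj <- vector("list", nrow(nodes))
      for (r in seq_len(nrow(ed))) {
        adj[[ed[r, 1]]] <- c(adj[[ed[r, 1]]], ed[r, 2])
        adj[[ed[r, 2]]] <- c(adj[[ed[r, 2]]], ed[r, 1])
      }
      cand <- list(); cand_cost <- numeric(0)
      for (u in seq_len(nrow(nodes))) {
        nb <- adj[[u]]
        if (length(nb) < 2) next
        prs <- utils::combn(nb, 2)
        for (cix in seq_len(ncol(prs))) {
          v <- prs[1, cix]; w <- prs[2, cix]
          trip <- nodes[c(u, v, w), , drop = FALSE]
          med <- as.integer(colSums(trip) >= 2)
          if (!is.null(seen[[key(med)]])) next
          cost <- (d[u, v] + d[u, w] + d[v, w]) / 2
          cand[[length(cand) + 1L]] <- med
          cand_cost <- c(cand_cost, cost)
        }
      }
      if (!length(cand)) break
      ## epsilon = 0: only medians of minimal connection cost this round
      lam <- min(cand_cost)
      add <- unique(lapply(which(cand_cost <= lam), function(i) cand[[i]]))
      for (med in add) {
        if (!is.null(seen[[key(med)]])) next
        nodes <- rbind(nodes, med)
        is_median <- c(is_median, TRUE)
        counts <- c(counts, 0L)
        assign(key(med), TRUE, envir = seen)
      }
    }
    ## prune median vectors that ended with degree <= 2 (on a geodesic);
    ## repeat until stable
    repeat {
      d <- hamming_matrix(nodes)
      ed <- msn_edges(d)
      deg <- tabulate(c(ed[, 1], ed[, 2]), nbins = nrow(nodes))
      drop <- which(is_median & deg <= 2)
      if (!length(drop)) break
      nodes <- nodes[-drop, , drop = FALSE]
      counts <- counts[-drop]
      is_median <- is_median[-drop]
    }
  }
  d <- hamming_matrix(nodes)
  ed <- msn_edges(d)
  g <- igraph::graph_from_data_frame(
    data.frame(from = ed[, 1], to = ed[, 2], weight = ed[, 3]),
    directed = FALSE,
    vertices = data.frame(name = seq_len(nrow(nodes))))
  rownames(nodes) <- paste0("node", seq_len(nrow(nodes)))
  structure(list(nodes = nodes, counts = counts, is_median = is_median,
                 edges = ed, graph = g, n_sampled = n_sampled),
            class = "HaplotypeNetwork")
}

#' @export
print.HaplotypeNetwork <- function(x, ...) {
  cat(sprintf("HaplotypeNetwork: %d nodes (%d sampled, %d median), %d edges\n",
              nrow(x$nodes), sum(!x$is_median), sum(x$is_median),
              nrow(x$edges)))
  invisible(x)
}

#' Export network edges as a TSV edge list
#' @param net a `HaplotypeNetwork`
#' @param path output path
#' @export
write_network_edges <- function(net, path) {
  ed <- as.data.frame(net$edges)
  ed$from <- rownames(net$nodes)[ed$from]
  ed$to <- rownames(net$nodes)[ed$to]
  utils::write.table(ed, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Rho statistic: mean mutational distance to an ancestral node
#'
#' Multiplicity-weighted mean of the shortest-path mutational distance
#' through the network from the designated ancestral node to each derived
#' sampled haplotype.
#'
#' @param net a `HaplotypeNetwork`
#' @param ancestral index of the ancestral node
#' @param derived indices of the derived sampled nodes (default: all
#'   sampled nodes, including individuals carrying the ancestral type,
#'   which contribute distance 0)
#' @return rho (dimensionless, mutations)
#' @export
rho_statistic <- function(net, ancestral, derived = NULL) {
  if (is.null(derived)) {
    derived <- which(!net$is_median & net$counts > 0)
  }
  dist <- igraph::distances(net$graph, v = as.character(ancestral),
                            to = as.character(derived))
  if (any(!is.finite(dist))) stop("derived node disconnected from the ancestor")
  w <- net$counts[derived]
  sum(dist * w) / sum(w)
}

#' Convert a rho statistic to an age in years
#'
#' With a mutation rate per site per year, `age = rho / (mu * L)`; with a
#' rate per site per generation, `age = generation_time * rho / (mu * L)`.
#' The unit flag is mandatory — it is never guessed.
#'
#' @param rho rho statistic (mean mutations from the ancestral node)
#' @param L locus length in bp
#' @param mu mutation rate per site, in the units given by `mu_units`
#' @param mu_units `"per_site_per_year"` or `"per_site_per_generation"`
#' @param generation_time generation time in years (required for
#'   per-generation rates)
#' @return age in years
#' @export
rho_to_age <- function(rho, L, mu, mu_units, generation_time = NULL) {
  if (missing(mu_units))
    stop("mu_units must be given explicitly ('per_site_per_year' or ",
         "'per_site_per_generation')")
  mu_units <- match.arg(mu_units, c("per_site_per_year",
                                    "per_site_per_generation"))
  if (L <= 0 || mu <= 0) stop("L and mu must be positive")
  if (rho < 0) stop("rho must be non-negative")
  if (mu_units == "per_site_per_year") return(rho / (mu * L))
  if (is.null(generation_time))
    stop("generation_time required for per-generation mutation rates")
  generation_time * rho / (mu * L)
}

#' Dating report across mutation-rate settings
#'
#' Convenience wrapper evaluating [rho_to_age()] for several mutation rates
#' side by side (the conventional fast/slow human rate pair).
#'
#' @param rho rho statistic
#' @param L locus length bp
#' @param mu_values named vector of per-site-per-year rates
#' @return data frame: `mu`, `age_years`
#' @export
rho_dating_table <- function(rho, L,
                             mu_values = c(fast = 2.5e-8, slow = 1.1e-8)) {
  data.frame(rate = names(mu_values), mu = unname(mu_values),
             age_years = vapply(mu_values, function(mu)
               rho_to_age(rho, L, mu, mu_units = "per_site_per_year"),
               numeric(1)),
             stringsAsFactors = FALSE)
}
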