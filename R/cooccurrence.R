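#' Normalized mutual information of two binary vectors
#'
#' Mutual information of two binary (presence/absence) variables, normalized
#' by the arithmetic mean of their marginal entropies (a geometric-mean
#' variant is available), so that identical or complementary vectors score 1
#' and independent vectors score 0. All logarithms are base 2 and
#' `0 * log 0` is treated as 0; when either vector is constant the NMI is
#' defined as 0.
#'
#' @param x,y binary (logical or 0/1) vectors of equal length >= 2.
#' @param normalization `"arithmetic"` (default) or `"geometric"` mean of
#'   the two entropies.
#' @return NMI in \[0, 1\].
#' @export
nmi <- function(x, y, normalization = c("arithmetic", "geometric")) {
  normalization <- match.arg(normalization)
  if (length(x) != length(y))
    stop("vectors differ in length", call. = FALSE)
  if (length(x) < 2) stop("need at least 2 observations", call. = FALSE)
  x <- as.integer(as.logical(x)); y <- as.integer(as.logical(y))
  n <- length(x)
  hx <- entropy2(tabulate(x + 1L, 2L) / n)
  hy <- entropy2(tabulate(y + 1L, 2L) / n)
  if (hx == 0 || hy == 0) return(0)
  joint <- tabulate(2L * x + y + 1L, 4L) / n
  hxy <- entropy2(joint)
  mi <- hx + hy - hxy
  norm <- switch(normalization,
                 arithmetic = (hx + hy) / 2,
                 geometric = sqrt(hx * hy))
  min(1, max(0, mi / norm))
}

#' Presence/absence co-occurrence network
#'
#' Builds the taxon co-occurrence network from a presence matrix: the NMI is
#' computed for every taxon pair and edges are the pairs whose NMI lies in
#' the top `percentile` of all pairwise values (default: top quarter). Each
#' edge carries the NMI and the sign of the Pearson correlation of the two
#' presence vectors, distinguishing co-occurrence from mutual exclusion.
#' Taxa with constant presence carry no information and are excluded from
#' pairing with a warning.
#'
#' @param presence binary taxa x samples matrix, or a [cohort].
#' @param percentile fraction of top NMI pairs kept as edges, in (0, 1\].
#' @param normalization passed to [nmi()].
#' @return an object of class `cooccurrence_network`: list with `edges`
#'   (data.frame `a`, `b`, `nmi`, `sign`), `nodes` (taxon identifiers),
#'   `cutoff` and `percentile`.
#' @export
cooccurrence_network <- function(presence, percentile = 0.25,
                                 normalization = "arithmetic") {
  if (inherits(presence, "cohort")) {
    ids <- presence$taxon_ids
    presence <- presence$presence
  } else {
    presence <- as.matrix(presence)
    ids <- rownames(presence) %||% paste0("taxon_", seq_len(nrow(presence)))
  }
  if (percentile <= 0 || percentile > 1)
    stop("'percentile' must be in (0, 1]", call. = FALSE)
  storage.mode(presence) <- "integer"
  const <- apply(presence, 1, function(r) all(r == r[1]))
  if (any(const))
    warning(sum(const), " taxa with constant presence excluded from pairing")
  keep <- which(!const)
  if (length(keep) < 3) stop("need at least 3 non-constant taxa",
                             call. = FALSE)
  pairs <- utils::combn(keep, 2)
  vals <- apply(pairs, 2, function(ij)
    nmi(presence[ij[1], ], presence[ij[2], ], normalization))
  signs <- apply(pairs, 2, function(ij) {
    s <- suppressWarnings(stats::cor(presence[ij[1], ], presence[ij[2], ]))
    if (is.na(s)) 0 else sign(s)
  })
  cutoff <- stats::quantile(vals, probs = 1 - percentile, names = FALSE)
  sel <- vals >= cutoff
  edges <- data.frame(a = ids[pairs[1, sel]], b = ids[pairs[2, sel]],
                      nmi = vals[sel], sign = signs[sel])
  out <- list(edges = edges, nodes = ids[keep], cutoff = cutoff,
              percentile = percentile, normalization = normalization)
  class(out) <- "cooccurrence_network"
  out
}

#' @export
print.cooccurrence_network <- function(x, ...) {
  cat("Co-occurrence network: ", length(x$nodes), " taxa, ",
      nrow(x$edges), " edges (top ", 100 * x$percentile,
      "% of pairwise NMI, cutoff = ", format(x$cutoff, digits = 4), ")\n",
      sep = "")
  invisible(x)
}

#' Neighbor EPI correlation with a shuffle null
#'
#' Tests whether taxa connected in the co-occurrence network share similar
#' EPI values — the signature of keystone modules. The observed statistic is
#' the Pearson correlation over the symmetrized edge list of the endpoint
#' EPI pairs (each undirected edge contributes both (i, j) and (j, i), so
#' the statistic is symmetric in the endpoints). The null distribution is
#' obtained by reshuffling the EPI values over the nodes; the permutation
#' p-value is one-sided for positive correlation.
#'
#' @param network a [cooccurrence_network()].
#' @param epi_values numeric vector of EPI values named by taxon (or in node
#'   order).
#' @param n_shuffles number of label permutations.
#' @param seed integer seed for the permutations.
#' @return an object of class `neighbor_correlation`: list with `r`,
#'   `p` (permutation), `null_mean`, `null_sd`, `null_q95`, `n_edges`.
#' @export
neighbor_epi_correlation <- function(network, epi_values, n_shuffles = 1000,
                                     seed = 1) {
  stopifnot(inherits(network, "cooccurrence_network"))
  if (nrow(network$edges) < 10)
    stop("network has fewer than 10 edges", call. = FALSE)
  if (is.null(names(epi_values))) {
    if (length(epi_values) != length(network$nodes))
      stop("'epi_values' length does not match node count", call. = FALSE)
    names(epi_values) <- network$nodes
  }
  ia <- match(network$edges$a, network$nodes)
  ib <- match(network$edges$b, network$nodes)
  if (any(is.na(ia)) || any(is.na(ib)))
    stop("edge endpoints missing from node set", call. = FALSE)
  v <- epi_values[network$nodes]
  if (any(is.na(v)))
    stop("missing EPI values for some network nodes", call. = FALSE)
  if (stats::sd(v) == 0) {
    warning("constant EPI values: correlation undefined")
    return(structure(list(r = NA_real_, p = NA_real_, null_mean = NA_real_,
                          null_sd = NA_real_, null_q95 = NA_real_,
                          n_edges = nrow(network$edges)),
                     class = "neighbor_correlation"))
  }
  edge_cor <- function(vals) {
    ex <- c(vals[ia], vals[ib])
    ey <- c(vals[ib], vals[ia])
    if (stats::sd(ex) == 0 || stats::sd(ey) == 0) return(NA_real_)
    stats::cor(ex, ey)
  }
  obs <- edge_cor(v)
  null <- with_seed(seed, {
    vapply(seq_len(n_shuffles), function(s) edge_cor(sample(v)), numeric(1))
  })
  null <- null[!is.na(null)]
  p <- (1 + sum(null >= obs)) / (1 + length(null))
  out <- list(r = obs, p = p, null_mean = mean(null), null_sd = stats::sd(null),
              null_q95 = stats::quantile(null, 0.95, names = FALSE),
              n_edges = nrow(network$edges), n_shuffles = length(null))
  class(out) <- "neighbor_correlation"
  out
}

#' @export
print.neighbor_correlation <- function(x, ...) {
  cat("Neighbor EPI correlation over ", x$n_edges, " edges: r = ",
      format(x$r, digits = 4), " (permutation p = ",
      format(x$p, digits = 3), "; null 95th percentile = ",
      format(x$null_q95, digits = 3), ")\n", sep = "")
  invisible(x)
}

#' Exploratory module extraction
#'
#' Convenience partition of the co-occurrence network into modules by greedy
#' modularity optimization ([igraph::cluster_fast_greedy()]) on the
#' NMI-weighted graph. This is exploratory: it groups taxa with correlated
#' presence patterns but cannot by itself distinguish true keystones from
#' satellite taxa within a module.
#'
#' @param network a [cooccurrence_network()].
#' @return a data.frame with columns `taxon` and `module`.
#' @export
keystone_modules <- function(network) {
  stopifnot(inherits(network, "cooccurrence_network"))
  g <- igraph::graph_from_data_frame(network$edges[, c("a", "b")],
                                     directed = FALSE,
                                     vertices = network$nodes)
  igraph::E(g)$weight <- network$edges$nmi
  cl <- igraph::cluster_fast_greedy(igraph::simplify(g))
  data.frame(taxon = igraph::V(g)$name,
             module = as.integer(igraph::membership(cl)))
}
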