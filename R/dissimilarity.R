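#' Renormalize a profile after excluding one taxon
#'
#' Drops the focal taxon from a relative-abundance profile and rescales the
#' remaining entries to unit sum. Working on these reduced, renormalized
#' profiles removes the purely compositional (unit-sum) coupling between the
#' focal taxon and the rest of the community, which would otherwise induce
#' spurious dissimilarity.
#'
#' @param profile non-negative numeric vector summing to 1 (tolerance 1e-6).
#' @param taxon index of the taxon to exclude.
#' @return numeric vector of length `length(profile) - 1` summing to 1.
#' @export
#' @examples
#' renormalize_excluding(c(0.2, 0.3, 0.5), 1) # 0.375 0.625
renormalize_excluding <- function(profile, taxon) {
  if (taxon < 1 || taxon > length(profile))
    stop("taxon index out of range", call. = FALSE)
  rest <- profile[-taxon]
  s <- sum(rest)
  if (s <= 0)
    stop("degenerate profile: all mass on the excluded taxon", call. = FALSE)
  rest / s
}

#' Bray-Curtis dissimilarity between two relative-abundance profiles
#'
#' For unit-sum vectors the Bray-Curtis dissimilarity reduces to
#' `1 - sum(pmin(p, q))`, ranging from 0 (identical) to 1 (disjoint support).
#'
#' @param p,q non-negative numeric vectors of equal length, each summing to 1.
#' @return dissimilarity in \[0, 1\].
#' @export
bray_curtis <- function(p, q) {
  if (length(p) != length(q))
    stop("profiles differ in length", call. = FALSE)
  1 - sum(pmin(p, q))
}

#' Root Jensen-Shannon divergence
#'
#' Square root of the Jensen-Shannon divergence with base-2 logarithms, so
#' the value lies in \[0, 1\] and satisfies the triangle inequality (it is a
#' metric on the probability simplex). `0 * log(0)` terms are treated as 0.
#'
#' @inheritParams bray_curtis
#' @return dissimilarity in \[0, 1\].
#' @export
root_jsd <- function(p, q) {
  if (length(p) != length(q))
    stop("profiles differ in length", call. = FALSE)
  m <- (p + q) / 2
  sqrt(pmax(0, (kl2(p, m) + kl2(q, m)) / 2))
}

kl2 <- function(p, q) {
  i <- p > 0
  sum(p[i] * (log2(p[i]) - log2(q[i])))
}

#' Pairwise profile dissimilarities
#'
#' Dissimilarity matrix between the columns of a profile matrix. Bray-Curtis
#' distances are delegated to [vegan::vegdist()]; the root Jensen-Shannon
#' divergence is computed directly.
#'
#' @param profiles numeric matrix with one unit-sum profile per column.
#' @param metric `"bray"` (default) or `"rjsd"`.
#' @return a `dist` object over columns.
#' @export
profile_dist <- function(profiles, metric = c("bray", "rjsd")) {
  metric <- match.arg(metric)
  if (metric == "bray") {
    vegan::vegdist(t(profiles), method = "bray")
  } else {
    n <- ncol(profiles)
    # JSD(p,q) = H((p+q)/2) - (H(p)+H(q))/2 with base-2 entropies
    H <- apply(profiles, 2, entropy2)
    d <- matrix(0, n, n)
    for (a in seq_len(n - 1)) {
      pa <- profiles[, a]
      for (b in seq(a + 1, n)) {
        m <- (pa + profiles[, b]) / 2
        jsd <- entropy2(m) - (H[a] + H[b]) / 2
        d[a, b] <- d[b, a] <- sqrt(pmax(0, jsd))
      }
    }
    stats::as.dist(d)
  }
}

entropy2 <- function(p) {
  i <- p > 0
  -sum(p[i] * log2(p[i]))
}

# distance between two single profiles under a metric name
pair_dist <- function(p, q, metric) {
  switch(metric, bray = bray_curtis(p, q), rjsd = root_jsd(p, q),
         stop("unknown metric: ", metric, call. = FALSE))
}
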