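#' Split a cohort by presence of a focal taxon
#'
#' Partitions the samples into the subset where the focal taxon is present
#' and the subset where it is absent, and builds the reduced profiles: each
#' sample's abundances with the focal taxon excluded and renormalized to
#' unit sum, which removes the compositional coupling between the focal
#' taxon and the rest of the community.
#'
#' @param cohort a [cohort].
#' @param taxon focal taxon index.
#' @param presence optional logical matrix overriding the cohort's presence
#'   mask (used by shuffle null models); abundances are untouched.
#' @return an object of class `presence_split`: list with `taxon`, `present`
#'   and `absent` (sample index sets), and `reduced` (the (n-1) x m matrix of
#'   reduced profiles).
#' @export
presence_split <- function(cohort, taxon, presence = NULL) {
  stopifnot(inherits(cohort, "cohort"))
  if (taxon < 1 || taxon > length(cohort$taxon_ids))
    stop("taxon index out of range", call. = FALSE)
  if (is.null(presence)) presence <- cohort$presence
  presence <- presence != 0
  pres <- unname(which(presence[taxon, ]))
  abs_ <- unname(which(!presence[taxon, ]))
  if (length(pres) == 0 || length(abs_) == 0)
    stop("EPI undefined: taxon ", taxon,
         " is present in all samples or in none", call. = FALSE)
  reduced <- reduce_profiles(cohort$abundances, taxon)
  out <- list(taxon = taxon, present = pres, absent = abs_, reduced = reduced)
  class(out) <- "presence_split"
  out
}

reduce_profiles <- function(abundances, taxon) {
  rest <- abundances[-taxon, , drop = FALSE]
  s <- colSums(rest)
  if (any(s <= 0))
    stop("degenerate sample(s) with all mass on taxon ", taxon, call. = FALSE)
  sweep(rest, 2, s, "/")
}

#' Mean cross-group distance, D1
#'
#' The first cross-sectional EPI measure: the average dissimilarity between
#' all pairs of reduced profiles taken one from the present group and one
#' from the absent group.
#'
#' @param split a [presence_split].
#' @param metric `"bray"` (default) or `"rjsd"`.
#' @return scalar D1.
#' @export
epi_d1 <- function(split, metric = c("bray", "rjsd")) {
  metric <- match.arg(metric)
  stopifnot(inherits(split, "presence_split"))
  d <- as.matrix(profile_dist(split$reduced, metric))
  mean(d[split$present, split$absent])
}

#' Distance between group means, D2
#'
#' The second cross-sectional EPI measure: the dissimilarity between the
#' arithmetic mean reduced profile of the present group and that of the
#' absent group.
#'
#' @inheritParams epi_d1
#' @return scalar D2.
#' @export
epi_d2 <- function(split, metric = c("bray", "rjsd")) {
  metric <- match.arg(metric)
  stopifnot(inherits(split, "presence_split"))
  mp <- rowMeans(split$reduced[, split$present, drop = FALSE])
  ma <- rowMeans(split$reduced[, split$absent, drop = FALSE])
  pair_dist(mp, ma, metric)
}

#' Sample-similarity network for one focal taxon
#'
#' Builds the binary sample-to-sample similarity network used by the
#' modularity EPI: nodes are the samples' reduced profiles; an edge connects
#' a pair whose dissimilarity is at most the threshold `T`, chosen as the
#' `p_q` empirical quantile of all pairwise dissimilarities, so that a
#' fraction `p_q` of the sample pairs is connected (ties at `T` are all
#' admitted). Nodes are labelled +1 where the focal taxon is present and -1
#' where it is absent.
#'
#' @inheritParams presence_split
#' @param p_q fraction of sample pairs to connect, in (0, 1).
#' @param metric dissimilarity, `"bray"` or `"rjsd"`.
#' @return an object of class `similarity_network`: list with `adjacency`
#'   (symmetric binary m x m matrix, zero diagonal), `labels` (+1/-1),
#'   `threshold`, `p_q`, `taxon`.
#' @export
similarity_network <- function(cohort, taxon, p_q = 0.1,
                               metric = c("bray", "rjsd"), presence = NULL) {
  metric <- match.arg(metric)
  if (p_q <= 0 || p_q > 1) stop("'p_q' must be in (0, 1]", call. = FALSE)
  split <- presence_split(cohort, taxon, presence = presence)
  m <- ncol(split$reduced)
  if (m < 3) stop("too few samples (need >= 3)", call. = FALSE)
  d <- profile_dist(split$reduced, metric)
  labels <- rep(-1L, m)
  labels[split$present] <- 1L
  network_from_dist(d, labels, p_q, taxon)
}

network_from_dist <- function(d, labels, p_q, taxon = NA_integer_) {
  thr <- stats::quantile(as.numeric(d), probs = p_q, names = FALSE)
  adj <- (as.matrix(d) <= thr) * 1L
  diag(adj) <- 0L
  out <- list(adjacency = adj, labels = labels, threshold = thr, p_q = p_q,
              taxon = taxon)
  class(out) <- "similarity_network"
  out
}

#' @export
print.similarity_network <- function(x, ...) {
  m <- nrow(x$adjacency)
  cat("Sample-similarity network: ", m, " samples, ",
      sum(x$adjacency) / 2, " edges (p_q = ", x$p_q,
      ", threshold = ", format(x$threshold, digits = 4), ")\n", sep = "")
  invisible(x)
}

#' Two-group modularity of a labelled network
#'
#' Modularity of a network whose nodes carry binary labels `s` in \{+1, -1\}:
#' \deqn{Q = \frac{1}{2w} \sum_{\alpha\beta} \left[ b_{\alpha\beta} -
#'   \frac{d_\alpha d_\beta}{2w} \right] \frac{s_\alpha s_\beta + 1}{2},}
#' where the double sum runs over all node pairs (including the
#' \eqn{\alpha = \beta} null-model term), `d` are node degrees and `w` the
#' number of edges. Q lies in \[-0.5, 1\]: 0 when labels are uncorrelated
#' with structure (or uniform), 1 when edges only ever join equal labels in
#' vanishing-density modules, and -0.5 for perfectly anti-modular labels.
#' Isolated nodes contribute only through the null-model term.
#'
#' @param network a [similarity_network()], or a symmetric binary adjacency
#'   matrix if `labels` is given.
#' @param labels +1/-1 node labels (ignored when `network` is a
#'   `similarity_network`).
#' @return scalar Q, or `NA` (with a warning) for an edgeless network.
#' @export
modularity_q <- function(network, labels = NULL) {
  if (inherits(network, "similarity_network")) {
    b <- network$adjacency
    labels <- network$labels
  } else {
    b <- as.matrix(network)
    if (is.null(labels)) stop("'labels' required with a raw adjacency matrix",
                              call. = FALSE)
  }
  if (!isTRUE(all.equal(b, t(b)))) stop("adjacency must be symmetric",
                                        call. = FALSE)
  if (any(diag(b) != 0)) stop("adjacency must have zero diagonal",
                              call. = FALSE)
  if (length(labels) != nrow(b))
    stop("labels length does not match the network", call. = FALSE)
  two_w <- sum(b)
  if (two_w == 0) {
    warning("edgeless network: modularity undefined")
    return(NA_real_)
  }
  deg <- rowSums(b)
  same <- (tcrossprod(labels) + 1) / 2
  sum((b - tcrossprod(deg) / two_w) * same) / two_w
}

#' Cross-sectional EPI screen for candidate keystones
#'
#' Computes the requested empirical presence-abundance interrelation (EPI)
#' measures for every eligible taxon of a cohort and flags candidate
#' keystones. Eligibility requires the taxon's relative frequency to lie in
#' `[freq_lo, freq_hi]` and strictly inside (0, 1) — a taxon present in all
#' samples (or none) has no presence contrast, so its EPI is undefined. A
#' taxon is a candidate under a measure when its value exceeds the mean of
#' that measure over eligible taxa by more than two standard deviations.
#'
#' @param cohort a [cohort].
#' @param measures subset of `c("d1", "d2", "q")`.
#' @param metric dissimilarity, `"bray"` or `"rjsd"`.
#' @param p_q connected pair fraction for the modularity network.
#' @param freq_lo,freq_hi frequency window (inclusive). The defaults keep
#'   every taxon with a presence contrast; for real surveys \[0.25, 0.75\]
#'   is recommended.
#' @param n_top optionally restrict to the `n_top` most abundant taxa first
#'   (values for dropped taxa are reported as missing).
#' @param presence optional presence-mask override (shuffle nulls).
#' @return an object of class `epi_table`: list with `table` (data.frame
#'   with `taxon`, `frequency`, `eligible`, one value column and one
#'   `candidate_*` flag column per measure) and the screen parameters.
#' @export
epi_screen <- function(cohort, measures = c("d1", "d2", "q"),
                       metric = c("bray", "rjsd"), p_q = 0.1,
                       freq_lo = 0, freq_hi = 1, n_top = NULL,
                       presence = NULL) {
  metric <- match.arg(metric)
  measures <- match.arg(measures, c("d1", "d2", "q"), several.ok = TRUE)
  stopifnot(inherits(cohort, "cohort"))
  if (!is.null(n_top)) cohort <- filter_top_taxa(cohort, n_top)
  if (is.null(presence)) presence <- cohort$presence
  presence <- presence != 0
  n <- length(cohort$taxon_ids)
  freq <- rowMeans(presence)
  eligible <- seq_len(n) %in% frequency_filter_mask(freq, freq_lo, freq_hi) &
    freq > 0 & freq < 1
  if (sum(eligible) < 3)
    stop("too few eligible taxa (", sum(eligible), "); need >= 3",
         call. = FALSE)

  vals <- matrix(NA_real_, n, 3, dimnames = list(NULL, c("d1", "d2", "q")))
  for (i in which(eligible)) {
    split <- tryCatch(presence_split(cohort, i, presence = presence),
                      error = function(e) NULL)
    if (is.null(split)) { eligible[i] <- FALSE; next }
    d <- as.matrix(profile_dist(split$reduced, metric))
    if ("d1" %in% measures)
      vals[i, "d1"] <- mean(d[split$present, split$absent])
    if ("d2" %in% measures)
      vals[i, "d2"] <- epi_d2(split, metric)
    if ("q" %in% measures) {
      labels <- rep(-1L, ncol(split$reduced))
      labels[split$present] <- 1L
      net <- network_from_dist(stats::as.dist(d), labels, p_q, i)
      vals[i, "q"] <- modularity_q(net)
    }
  }

  tab <- data.frame(taxon = cohort$taxon_ids, frequency = freq,
                    eligible = eligible)
  for (mname in measures) {
    v <- vals[, mname]
    tab[[mname]] <- v
    mu <- mean(v[eligible], na.rm = TRUE)
    s <- stats::sd(v[eligible], na.rm = TRUE)
    flag <- rep(NA, n)
    flag[eligible] <- if (is.na(s) || s == 0) FALSE
                      else v[eligible] > mu + 2 * s
    tab[[paste0("candidate_", mname)]] <- flag
  }
  out <- list(table = tab, measures = measures, metric = metric, p_q = p_q,
              freq_lo = freq_lo, freq_hi = freq_hi)
  class(out) <- "epi_table"
  out
}

frequency_filter_mask <- function(freq, lo, hi) {
  if (!(lo >= 0 && lo < hi && hi <= 1))
    stop("need 0 <= lo < hi <= 1", call. = FALSE)
  which(freq >= lo & freq <= hi)
}

#' @export
print.epi_table <- function(x, ...) {
  cat("EPI screen (", x$metric, "; measures: ",
      paste(x$measures, collapse = ", "), ") over ",
      sum(x$table$eligible), " eligible of ", nrow(x$table), " taxa\n",
      sep = "")
  flags <- x$table[, grep("^candidate_", names(x$table)), drop = FALSE]
  any_flag <- apply(flags, 1, function(r) isTRUE(any(r)))
  if (!any(any_flag)) {
    cat("No candidate keystones (no EPI above mean + 2 SD)\n")
  } else {
    cat("Candidate keystones:\n")
    print(x$table[any_flag, , drop = FALSE], row.names = FALSE, digits = 4)
  }
  invisible(x)
}

#' @export
summary.epi_table <- function(object, ...) {
  for (mname in object$measures) {
    cat("EPI ", mname, ":\n", sep = "")
    print(summary(object$table[[mname]][object$table$eligible]))
  }
  invisible(object)
}

#' @export
plot.epi_table <- function(x, measure = x$measures[1], ...) {
  v <- x$table[[measure]][x$table$eligible]
  graphics::hist(v, breaks = 30, main = paste("EPI", measure),
                 xlab = paste("EPI", measure), col = "grey85", ...)
  graphics::abline(v = mean(v) + 2 * stats::sd(v), lty = 2, col = "red")
  invisible(x)
}
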