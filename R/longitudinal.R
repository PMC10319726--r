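#' Longitudinal EPI from paired two-time-point cohorts
#'
#' For each taxon, finds the subjects whose presence state of that taxon
#' reversed between the two collections (present at one visit, absent at the
#' other) and measures, within each such subject, the dissimilarity between
#' the two visits' reduced profiles (the focal taxon excluded, renormalized
#' to unit sum). The longitudinal EPI `L` of the taxon is the mean over
#' those subjects. Because the comparison is within-subject, inter-personal
#' confounders largely cancel.
#'
#' Taxa whose `L` would rest on `min_subjects` or fewer reversals are marked
#' ineligible (default: more than 10 reversal subjects required), since few
#' reversals make `L` strongly biased.
#'
#' @param paired a [paired_cohort].
#' @param metric `"bray"` (default) or `"rjsd"`.
#' @param min_subjects taxa with this many reversal subjects or fewer are
#'   ineligible.
#' @return an object of class `longitudinal_epi`: list with `table`
#'   (data.frame with `taxon`, `l`, `n_reversals`, `eligible`) and `metric`.
#' @export
longitudinal_epi <- function(paired, metric = c("bray", "rjsd"),
                             min_subjects = 10) {
  metric <- match.arg(metric)
  stopifnot(inherits(paired, "paired_cohort"))
  first <- paired$first; second <- paired$second
  n <- length(first$taxon_ids)
  h <- length(first$sample_ids)
  l <- rep(NA_real_, n)
  n_rev <- integer(n)
  for (i in seq_len(n)) {
    rev_subj <- which(first$presence[i, ] != second$presence[i, ])
    n_rev[i] <- length(rev_subj)
    if (length(rev_subj) == 0) next
    vals <- vapply(rev_subj, function(s) {
      p1 <- tryCatch(renormalize_excluding(first$abundances[, s], i),
                     error = function(e) NULL)
      p2 <- tryCatch(renormalize_excluding(second$abundances[, s], i),
                     error = function(e) NULL)
      if (is.null(p1) || is.null(p2)) return(NA_real_)
      pair_dist(p1, p2, metric)
    }, numeric(1))
    if (all(is.na(vals))) next
    l[i] <- mean(vals, na.rm = TRUE)
  }
  eligible <- n_rev > min_subjects & !is.na(l)
  if (!any(eligible))
    warning("no taxon has more than ", min_subjects, " presence reversals")
  out <- list(table = data.frame(taxon = first$taxon_ids, l = l,
                                 n_reversals = n_rev, eligible = eligible),
              metric = metric, min_subjects = min_subjects, n_subjects = h)
  class(out) <- "longitudinal_epi"
  out
}

#' @export
print.longitudinal_epi <- function(x, ...) {
  cat("Longitudinal EPI over ", x$n_subjects, " subjects; ",
      sum(x$table$eligible), " of ", nrow(x$table),
      " taxa eligible (> ", x$min_subjects, " reversals)\n", sep = "")
  invisible(x)
}

#' Compare cross-sectional and longitudinal EPI
#'
#' Correlates a cross-sectional EPI measure with the longitudinal EPI over
#' the taxa eligible in both, and tests whether the two candidate sets (the
#' top `top_fraction` of each ranking) overlap more than chance by a
#' one-sided Fisher exact test. Agreement between the two supports that the
#' cross-sectional EPI captures within-subject presence-impact rather than
#' between-subject confounding.
#'
#' @param epi an [epi_screen()] result or a named numeric vector of EPI
#'   values.
#' @param longitudinal a [longitudinal_epi()] result.
#' @param measure which EPI column to use when `epi` is an `epi_table`.
#' @param top_fraction fraction of taxa forming each candidate set
#'   (default 0.05); ties broken by taxon order.
#' @return an object of class `epi_longitudinal_comparison`: list with
#'   `r`, `p` (Pearson), `overlap`, `fisher_p`, `n_common`, and the two
#'   candidate sets.
#' @export
compare_epi_longitudinal <- function(epi, longitudinal, measure = "d1",
                                     top_fraction = 0.05) {
  stopifnot(inherits(longitudinal, "longitudinal_epi"))
  if (inherits(epi, "epi_table")) {
    ok <- epi$table$eligible & !is.na(epi$table[[measure]])
    ev <- stats::setNames(epi$table[[measure]][ok], epi$table$taxon[ok])
  } else {
    ev <- epi
    if (is.null(names(ev))) stop("'epi' vector must be named", call. = FALSE)
  }
  lt <- longitudinal$table[longitudinal$table$eligible, ]
  lv <- stats::setNames(lt$l, lt$taxon)
  common <- intersect(names(ev), names(lv))
  if (length(common) < 10)
    stop("fewer than 10 taxa eligible in both measures", call. = FALSE)
  x <- ev[common]; y <- lv[common]

  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    r <- NA_real_; p <- NA_real_
  } else {
    ct <- stats::cor.test(x, y)
    r <- unname(ct$estimate); p <- ct$p.value
  }

  k <- max(1L, floor(top_fraction * length(common)))
  top_x <- common[order(-x, seq_along(x))[seq_len(k)]]
  top_y <- common[order(-y, seq_along(y))[seq_len(k)]]
  overlap <- length(intersect(top_x, top_y))
  tab <- matrix(c(overlap, k - overlap, k - overlap,
                  length(common) - 2 * k + overlap), 2, 2)
  fisher_p <- stats::fisher.test(tab, alternative = "greater")$p.value

  out <- list(r = r, p = p, overlap = overlap, fisher_p = fisher_p,
              n_common = length(common), top_fraction = top_fraction,
              candidates_epi = top_x, candidates_longitudinal = top_y)
  class(out) <- "epi_longitudinal_comparison"
  out
}

#' @export
print.epi_longitudinal_comparison <- function(x, ...) {
  cat("Cross-sectional vs longitudinal EPI over ", x$n_common,
      " shared taxa\n", sep = "")
  cat("  Pearson r = ", format(x$r, digits = 4), " (p = ",
      format(x$p, digits = 3), ")\n", sep = "")
  cat("  shared candidates in top ", 100 * x$top_fraction, "%: ", x$overlap,
      " (one-sided Fisher p = ", format(x$fisher_p, digits = 3), ")\n",
      sep = "")
  invisible(x)
}
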