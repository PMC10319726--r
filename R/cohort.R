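#' Cross-sectional abundance cohort
#'
#' A `cohort` holds a taxa-by-samples matrix of relative abundances together
#' with the derived presence/absence mask. It is the common data object for
#' both simulated communities and real sequencing surveys: every sample
#' (column) is normalized to unit sum, so only relative abundances are
#' analysed downstream.
#'
#' @param abundances numeric matrix, taxa in rows, samples in columns. All
#'   entries must be non-negative and finite; each column must have positive
#'   sum. Raw counts are accepted and normalized.
#' @param taxon_ids,sample_ids character vectors of unique identifiers;
#'   default to the dimnames of `abundances` or generated labels.
#' @param detection_threshold abundance (after normalization) above which a
#'   taxon counts as present. The default 0 treats any strictly positive
#'   abundance as presence; absence is read as "below the detection limit".
#'
#' @return An object of class `cohort`: a list with elements `abundances`
#'   (normalized matrix), `presence` (logical matrix), `taxon_ids`,
#'   `sample_ids` and `detection_threshold`.
#' @seealso [read_cohort()], [filter_top_taxa()], [frequency_filter()]
#' @export
#' @examples
#' x <- matrix(c(10, 30, 60, 0, 5, 5), nrow = 3)
#' co <- cohort(x)
#' colSums(co$abundances)
cohort <- function(abundances, taxon_ids = NULL, sample_ids = NULL,
                   detection_threshold = 0) {
  abundances <- as.matrix(abundances)
  storage.mode(abundances) <- "double"
  if (any(!is.finite(abundances)))
    stop("malformed abundance table: non-finite values", call. = FALSE)
  if (any(abundances < 0))
    stop("malformed abundance table: negative abundances", call. = FALSE)
  if (detection_threshold < 0)
    stop("'detection_threshold' must be non-negative", call. = FALSE)

  if (is.null(taxon_ids))
    taxon_ids <- rownames(abundances) %||% paste0("taxon_", seq_len(nrow(abundances)))
  if (is.null(sample_ids))
    sample_ids <- colnames(abundances) %||% paste0("sample_", seq_len(ncol(abundances)))
  taxon_ids <- as.character(taxon_ids)
  sample_ids <- as.character(sample_ids)
  if (anyDuplicated(taxon_ids))
    stop("duplicate taxon identifiers: ",
         paste(unique(taxon_ids[duplicated(taxon_ids)]), collapse = ", "),
         call. = FALSE)
  if (anyDuplicated(sample_ids))
    stop("duplicate sample identifiers: ",
         paste(unique(sample_ids[duplicated(sample_ids)]), collapse = ", "),
         call. = FALSE)
  if (length(taxon_ids) != nrow(abundances) ||
      length(sample_ids) != ncol(abundances))
    stop("identifier lengths do not match the abundance matrix", call. = FALSE)

  cs <- colSums(abundances)
  if (any(cs == 0))
    stop("degenerate sample(s) with zero total abundance: ",
         paste(sample_ids[cs == 0], collapse = ", "), call. = FALSE)
  abundances <- sweep(abundances, 2, cs, "/")
  dimnames(abundances) <- list(taxon_ids, sample_ids)

  out <- list(
    abundances = abundances,
    presence = abundances > detection_threshold,
    taxon_ids = taxon_ids,
    sample_ids = sample_ids,
    detection_threshold = detection_threshold
  )
  class(out) <- "cohort"
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.cohort <- function(x, ...) {
  cat("Cohort: ", length(x$taxon_ids), " taxa x ", length(x$sample_ids),
      " samples\n", sep = "")
  f <- taxon_frequency(x)
  cat("  detection threshold: ", format(x$detection_threshold),
      "; mean taxon frequency: ", format(round(mean(f), 3)), "\n", sep = "")
  conv <- attr(x, "converged")
  if (!is.null(conv))
    cat("  simulated cohort; converged samples: ", sum(conv), "/",
        length(conv), "\n", sep = "")
  invisible(x)
}

#' @export
summary.cohort <- function(object, ...) {
  f <- taxon_frequency(object)
  cat("Cohort with", length(object$taxon_ids), "taxa and",
      length(object$sample_ids), "samples\n")
  cat("Taxon relative frequencies:\n")
  print(summary(f))
  cat("Per-sample richness (taxa present):\n")
  print(summary(colSums(object$presence)))
  invisible(object)
}

#' Relative frequency of each taxon
#'
#' The fraction of samples in which each taxon is detected as present.
#'
#' @param x a [cohort].
#' @return named numeric vector of frequencies in \[0, 1\].
#' @export
taxon_frequency <- function(x) {
  stopifnot(inherits(x, "cohort"))
  rowMeans(x$presence)
}

#' Read an abundance table into a cohort
#'
#' Reads a delimited (TSV or CSV, by file extension) abundance table with one
#' header row and one leading identifier column. Lines starting with `#` are
#' treated as comments, so tables written by [write_cohort()] round-trip.
#'
#' @param path file path.
#' @param orientation `"taxa_by_samples"` (default: taxa in rows) or
#'   `"samples_by_taxa"` (table is transposed after reading).
#' @param detection_threshold passed to [cohort()].
#' @return a [cohort].
#' @export
read_cohort <- function(path, orientation = c("taxa_by_samples", "samples_by_taxa"),
                        detection_threshold = 0) {
  orientation <- match.arg(orientation)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  tab <- utils::read.table(path, header = TRUE, sep = sep, comment.char = "#",
                           row.names = 1, check.names = FALSE)
  m <- as.matrix(tab)
  if (!is.numeric(m))
    stop("malformed abundance table: non-numeric entries in ", path,
         call. = FALSE)
  if (orientation == "samples_by_taxa") m <- t(m)
  cohort(m, detection_threshold = detection_threshold)
}

#' Write a cohort as a TSV abundance table
#'
#' Writes the normalized taxa-by-samples matrix as tab-separated text with a
#' `# params:` comment header recording run metadata, so downstream stages
#' can trace provenance.
#'
#' @param x a [cohort].
#' @param path output file path.
#' @param params optional named list recorded in the header comment.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(x, path, params = list()) {
  stopifnot(inherits(x, "cohort"))
  params <- c(list(package = paste0("keystone ",
                                    as.character(utils::packageVersion("keystone"))),
                   detection_threshold = x$detection_threshold),
              params)
  hdr <- paste0("# params: ",
                paste(names(params), unlist(lapply(params, format)),
                      sep = "=", collapse = " "))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(hdr, con)
  writeLines(paste(c("taxon_id", x$sample_ids), collapse = "\t"), con)
  utils::write.table(x$abundances, con, sep = "\t", quote = FALSE,
                     col.names = FALSE, row.names = TRUE)
  invisible(path)
}

#' Keep the most abundant taxa
#'
#' Retains the `n_top` taxa with the highest mean relative abundance across
#' samples and renormalizes every sample to unit sum. Ties at the cutoff are
#' broken by input order (stable sort), so the result is deterministic.
#'
#' @param x a [cohort].
#' @param n_top number of taxa to keep; must not exceed the number of taxa.
#' @return a [cohort] over the retained taxa.
#' @export
filter_top_taxa <- function(x, n_top) {
  stopifnot(inherits(x, "cohort"))
  n <- length(x$taxon_ids)
  if (n_top < 1 || n_top > n)
    stop("'n_top' must be between 1 and the number of taxa (", n, ")",
         call. = FALSE)
  mu <- rowMeans(x$abundances)
  keep <- sort(order(mu, decreasing = TRUE)[seq_len(n_top)])
  cohort(x$abundances[keep, , drop = FALSE],
         taxon_ids = x$taxon_ids[keep],
         sample_ids = x$sample_ids,
         detection_threshold = x$detection_threshold)
}

#' Frequency window filter
#'
#' Selects taxa whose relative frequency (fraction of samples where present)
#' lies inside a window, inclusive at both ends. Taxa present in every sample
#' carry no presence/absence contrast, so the EPI of such a taxon is
#' undefined; for real surveys a window such as \[0.25, 0.75\] additionally
#' avoids the frequency bias of very rare or very common taxa.
#'
#' @param x a [cohort].
#' @param lo,hi window bounds, `0 <= lo < hi <= 1`.
#' @return integer vector of taxon indices with `lo <= f <= hi`.
#' @export
frequency_filter <- function(x, lo = 0.25, hi = 0.75) {
  stopifnot(inherits(x, "cohort"))
  if (!(lo >= 0 && lo < hi && hi <= 1))
    stop("need 0 <= lo < hi <= 1", call. = FALSE)
  f <- taxon_frequency(x)
  unname(which(f >= lo & f <= hi))
}

#' Fixed-margin shuffle of a presence matrix
#'
#' Randomizes a binary presence matrix while preserving both margins: each
#' taxon's relative frequency (row sums) and each sample's richness (column
#' sums). Randomization proceeds by repeated checkerboard swaps: a random
#' 2x2 submatrix equal to `[[1,0],[0,1]]` or `[[0,1],[1,0]]` has its ones and
#' zeros exchanged. This is the null model used to test whether
#' presence-abundance interrelations exceed what margins alone explain.
#'
#' @param presence logical or 0/1 matrix (taxa x samples), or a [cohort]
#'   (its presence mask is used).
#' @param n_swaps number of attempted swaps; default `10 * number of ones`.
#' @param seed integer seed controlling the randomization.
#' @return a matrix of the same shape and margins, with attribute `swapped`
#'   (`FALSE`, with a warning, when the matrix admits no checkerboard and is
#'   returned unchanged).
#' @export
shuffle_presence <- function(presence, n_swaps = NULL, seed = 1) {
  if (inherits(presence, "cohort")) presence <- presence$presence
  m <- matrix(as.integer(as.logical(presence)), nrow = nrow(presence),
              dimnames = dimnames(presence))
  nr <- nrow(m); nc <- ncol(m)
  if (is.null(n_swaps)) n_swaps <- 10L * sum(m)
  if (n_swaps < 1) stop("'n_swaps' must be positive", call. = FALSE)
  if (nr < 2 || nc < 2 || !has_checkerboard(m)) {
    warning("presence matrix admits no checkerboard swap; returned unchanged")
    attr(m, "swapped") <- FALSE
    return(m)
  }
  m <- with_seed(seed, {
    done <- 0L
    for (s in seq_len(n_swaps)) {
      rr <- sample.int(nr, 2L)
      cc <- sample.int(nc, 2L)
      sub <- m[rr, cc]
      if (sub[1, 1] == sub[2, 2] && sub[1, 2] == sub[2, 1] &&
          sub[1, 1] != sub[1, 2]) {
        m[rr, cc] <- 1L - sub
        done <- done + 1L
      }
    }
    attr(m, "swaps_performed") <- done
    m
  })
  attr(m, "swapped") <- TRUE
  m
}

# exhaustive search is only used to certify the degenerate "no checkerboard"
# case; O(choose(nr,2) * nc^2) but fine at the sizes where it triggers
has_checkerboard <- function(m) {
  nr <- nrow(m)
  for (i in seq_len(nr - 1L)) {
    for (j in seq(i + 1L, nr)) {
      d <- m[i, ] - m[j, ]
      if (any(d == 1L) && any(d == -1L)) return(TRUE)
    }
  }
  FALSE
}

# evaluate code under a temporary RNG state seeded with `seed`
with_seed <- function(seed, code) {
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    set.seed(NULL)
  }
  old <- get(".Random.seed", envir = globalenv(), inherits = FALSE)
  on.exit(assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  force(code)
}
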