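#' Presence-impact of one taxon in one community
#'
#' Performs a single in-silico perturbation experiment: the presence state of
#' the focal taxon is reversed (removed if present, introduced at the
#' inoculum abundance if absent), the community is re-integrated to its new
#' steady state, and the impact is the dissimilarity between the
#' pre- and post-perturbation profiles of all *other* taxa, each excluded of
#' the focal taxon and renormalized to unit sum. Re-integration starts from
#' the perturbed steady state itself, i.e. the same community is perturbed.
#'
#' @param model the `glv_model` that generated the sample.
#' @param state absolute steady-state abundance vector of the sample.
#' @param taxon focal taxon index.
#' @param metric `"bray"` (default) or `"rjsd"`.
#' @param inoculum abundance at which an absent taxon is introduced
#'   (default 0.5, the midpoint of the U(0, 1) initial-condition law).
#' @inheritParams glv_steady_state
#' @return impact value in \[0, 1\] for Bray-Curtis, with attribute `valid`
#'   (`FALSE` when the perturbed integration did not converge; such values
#'   are excluded from cohort averages).
#' @export
presence_impact_single <- function(model, state, taxon,
                                   metric = c("bray", "rjsd"),
                                   inoculum = 0.5, t_max = 5000, tol = 1e-8) {
  metric <- match.arg(metric)
  stopifnot(inherits(model, "glv_model"))
  if (taxon < 1 || taxon > model$n)
    stop("taxon index out of range", call. = FALSE)
  state <- as.numeric(state)
  pre_rest <- state[-taxon]
  if (sum(pre_rest) <= 0)
    stop("degenerate sample: all mass on the focal taxon", call. = FALSE)

  perturbed <- state
  perturbed[taxon] <- if (state[taxon] > 0) 0 else inoculum
  post <- glv_steady_state(model, perturbed, t_max = t_max, tol = tol)
  post_rest <- post[-taxon]
  if (sum(post_rest) <= 0)
    stop("degenerate post-perturbation state: community collapsed",
         call. = FALSE)

  val <- pair_dist(pre_rest / sum(pre_rest), post_rest / sum(post_rest), metric)
  attr(val, "valid") <- isTRUE(attr(post, "converged"))
  val
}

#' Presence-impact of one taxon over a cohort
#'
#' The cohort-level presence-impact is the arithmetic mean of the per-sample
#' impacts over all samples whose perturbed integration converged.
#'
#' @param model the `glv_model` that generated the cohort.
#' @param cohort a [glv_cohort()] result (its `absolute` attribute holds the
#'   pre-perturbation steady states).
#' @inheritParams presence_impact_single
#' @return mean impact, with attribute `n_valid`.
#' @export
presence_impact <- function(model, cohort, taxon, metric = c("bray", "rjsd"),
                            inoculum = 0.5, t_max = 5000, tol = 1e-8) {
  metric <- match.arg(metric)
  states <- cohort_states(cohort)
  vals <- vapply(seq_len(ncol(states)), function(k) {
    v <- tryCatch(
      presence_impact_single(model, states[, k], taxon, metric,
                             inoculum = inoculum, t_max = t_max, tol = tol),
      error = function(e) structure(NA_real_, valid = FALSE))
    if (!isTRUE(attr(v, "valid"))) NA_real_ else as.numeric(v)
  }, numeric(1))
  if (all(is.na(vals)))
    stop("no valid perturbation experiments for taxon ", taxon, call. = FALSE)
  out <- mean(vals, na.rm = TRUE)
  attr(out, "n_valid") <- sum(!is.na(vals))
  attr(out, "per_sample") <- vals
  out
}

cohort_states <- function(cohort) {
  stopifnot(inherits(cohort, "cohort"))
  states <- attr(cohort, "absolute")
  if (is.null(states))
    stop("cohort carries no absolute abundances; use glv_cohort()",
         call. = FALSE)
  states
}

#' Perturbation screen for keystone taxa
#'
#' Measures the presence-impact of every taxon in the community by
#' addition/removal experiments on each sample of a cohort, then flags
#' keystones: a taxon is a keystone when its impact exceeds the mean impact
#' of all taxa by more than two standard deviations. One-tailed z-test
#' p-values are reported with the focal taxon excluded from the background
#' mean and standard deviation.
#'
#' @inheritParams presence_impact
#' @return an object of class `impact_screen`: list with `table` (data.frame
#'   with columns `taxon`, `impact`, `n_valid`, `z`, `p`, `keystone`),
#'   `per_sample` (taxa x samples matrix of per-sample impacts), `metric`.
#' @export
impact_screen <- function(model, cohort, metric = c("bray", "rjsd"),
                          inoculum = 0.5, t_max = 5000, tol = 1e-8) {
  metric <- match.arg(metric)
  stopifnot(inherits(model, "glv_model"))
  if (model$n < 3) stop("need at least 3 taxa", call. = FALSE)
  states <- cohort_states(cohort)
  n <- model$n
  per_sample <- matrix(NA_real_, n, ncol(states))
  impact <- numeric(n)
  n_valid <- integer(n)
  for (i in seq_len(n)) {
    v <- presence_impact(model, cohort, i, metric, inoculum = inoculum,
                         t_max = t_max, tol = tol)
    impact[i] <- as.numeric(v)
    n_valid[i] <- attr(v, "n_valid")
    per_sample[i, ] <- attr(v, "per_sample")
  }
  z <- p <- rep(NA_real_, n)
  for (i in seq_len(n)) {
    bg <- impact[-i]
    s <- stats::sd(bg)
    if (s > 0) {
      z[i] <- (impact[i] - mean(bg)) / s
      p[i] <- stats::pnorm(z[i], lower.tail = FALSE)
    }
  }
  s_all <- stats::sd(impact)
  keystone <- if (s_all > 0) impact > mean(impact) + 2 * s_all
              else rep(FALSE, n)
  out <- list(
    table = data.frame(taxon = cohort$taxon_ids, impact = impact,
                       n_valid = n_valid, z = z, p = p, keystone = keystone),
    per_sample = per_sample,
    metric = metric
  )
  class(out) <- "impact_screen"
  out
}

#' @export
print.impact_screen <- function(x, ...) {
  cat("Presence-impact screen (", x$metric, " dissimilarity) over ",
      nrow(x$table), " taxa, ", ncol(x$per_sample), " samples\n", sep = "")
  ks <- x$table[x$table$keystone, , drop = FALSE]
  if (nrow(ks) == 0) {
    cat("No keystone taxa (no impact above mean + 2 SD)\n")
  } else {
    cat("Keystone taxa (impact > mean + 2 SD):\n")
    print(ks, row.names = FALSE, digits = 4)
  }
  invisible(x)
}

#' @export
summary.impact_screen <- function(object, ...) {
  cat("Presence-impact values:\n")
  print(summary(object$table$impact))
  cat(sum(object$table$keystone), "keystone taxa out of",
      nrow(object$table), "\n")
  invisible(object)
}

#' @export
plot.impact_screen <- function(x, ...) {
  imp <- x$table$impact
  thr <- mean(imp) + 2 * stats::sd(imp)
  plot(seq_along(imp), imp, xlab = "taxon", ylab = "presence-impact I",
       pch = ifelse(x$table$keystone, 17, 1),
       col = ifelse(x$table$keystone, "red", "black"), ...)
  graphics::abline(h = thr, lty = 2, col = "grey40")
  invisible(x)
}

#' @export
coef.impact_screen <- function(object, ...) {
  stats::setNames(object$table$impact, object$table$taxon)
}
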