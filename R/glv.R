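#' Generalized Lotka-Volterra community models
#'
#' A `glv_model` defines the intrinsic dynamics of `n` interacting taxa,
#' `dx_i/dt = x_i (r_i + sum_j a_ij x_j)`, with self-regulation fixed at
#' `a_ii = -1` (logistic growth). Growth rates `r_i` are drawn from
#' U(0, 1) and the non-zero off-diagonal interaction strengths from
#' U(-sigma_a, sigma_a), where `sigma_a` is a scale chosen small enough for
#' ecological stability. The non-zero pattern of `a` is the interaction
#' network, generated from either an Erdos-Renyi or a directed
#' Barabasi-Albert topology.
#'
#' `glv_er()` draws each directed off-diagonal interaction independently
#' with probability `mean_degree / (n - 1)`, so each taxon is affected by
#' `mean_degree` others on average.
#'
#' `glv_ba()` builds an undirected scale-free skeleton by preferential
#' attachment (`n0` fully connected seed nodes; every later node attaches to
#' `n0` existing nodes with probability proportional to degree) and then
#' orients each edge: with probability `directionality` the interaction
#' points out of the higher-degree endpoint, otherwise the orientation is
#' uniform. Positive `directionality` couples out-degree to hubness, so the
#' natural hubs become structure-based keystones.
#'
#' @param n number of taxa.
#' @param mean_degree expected number of in-coming interactions per taxon
#'   (Erdos-Renyi).
#' @param sigma_a interaction strength scale; non-zero entries are
#'   U(-sigma_a, sigma_a). Default `0.5 / sqrt(mean_degree)` (or of the mean
#'   skeleton degree for `glv_ba`), a scale at which almost all simulated
#'   samples reach a stable steady state.
#' @param seed integer seed; the model is a deterministic function of it.
#' @return an object of class `glv_model`: list with `r` (growth rates), `a`
#'   (interaction matrix), `n`, `sigma_a`, `topology` and `seed`.
#' @export
#' @examples
#' mod <- glv_er(20, mean_degree = 5, seed = 1)
#' diag(mod$a)
glv_er <- function(n, mean_degree, sigma_a = 0.5 / sqrt(mean_degree), seed = 1) {
  if (mean_degree <= 0 || mean_degree >= n)
    stop("'mean_degree' must be in (0, n)", call. = FALSE)
  if (sigma_a < 0) stop("'sigma_a' must be non-negative", call. = FALSE)
  with_seed(seed, {
    p <- mean_degree / (n - 1)
    mask <- matrix(stats::runif(n * n) < p, n, n)
    diag(mask) <- FALSE
    a <- matrix(0, n, n)
    a[mask] <- stats::runif(sum(mask), -sigma_a, sigma_a)
    diag(a) <- -1
    r <- stats::runif(n)
    new_glv(r, a, sigma_a, list(type = "er", mean_degree = mean_degree), seed)
  })
}

#' @rdname glv_er
#' @param n0 number of fully connected seed nodes; also the number of edges
#'   each later node attaches with.
#' @param directionality probability that an edge is oriented out of its
#'   higher-degree endpoint (0 = uniform orientation, 1 = always out of the
#'   hub).
#' @export
glv_ba <- function(n, n0 = 3, directionality = 0.1, sigma_a = NULL, seed = 1) {
  if (n0 < 1 || n0 > n) stop("need 1 <= n0 <= n", call. = FALSE)
  if (directionality < 0 || directionality > 1)
    stop("'directionality' must be in [0, 1]", call. = FALSE)
  with_seed(seed, {
    edges <- ba_skeleton(n, n0)
    deg <- tabulate(c(edges[, 1], edges[, 2]), nbins = n)
    if (is.null(sigma_a)) sigma_a <- 0.5 / sqrt(mean(deg))
    a <- matrix(0, n, n)
    for (e in seq_len(nrow(edges))) {
      u <- edges[e, 1]; v <- edges[e, 2]
      # orient: source = taxon exerting the interaction
      if (stats::runif(1) < directionality) {
        src <- if (deg[u] >= deg[v]) u else v
      } else {
        src <- if (stats::runif(1) < 0.5) u else v
      }
      dst <- if (src == u) v else u
      a[dst, src] <- stats::runif(1, -sigma_a, sigma_a)
    }
    diag(a) <- -1
    r <- stats::runif(n)
    new_glv(r, a, sigma_a,
            list(type = "ba", n0 = n0, directionality = directionality,
                 skeleton = edges), seed)
  })
}

# undirected preferential-attachment edge list; seed clique of n0 nodes,
# each new node attaches to min(n0, existing) distinct nodes by degree
ba_skeleton <- function(n, n0) {
  edges <- if (n0 > 1) t(utils::combn(n0, 2)) else matrix(nrow = 0, ncol = 2)
  deg <- tabulate(c(edges[, 1], edges[, 2]), nbins = n)
  if (n0 == 1) deg[1] <- 1  # give the lone seed node attachment weight
  if (n0 == n) return(unname(edges))
  for (v in seq(n0 + 1, n)) {
    k <- min(n0, v - 1)
    targets <- sample.int(v - 1, k, prob = deg[seq_len(v - 1)] + 1e-12)
    edges <- rbind(edges, cbind(targets, v))
    deg[v] <- deg[v] + k
    deg[targets] <- deg[targets] + 1
  }
  unname(edges)
}

new_glv <- function(r, a, sigma_a, topology, seed) {
  out <- list(r = r, a = a, n = length(r), sigma_a = sigma_a,
              topology = topology, seed = seed)
  class(out) <- "glv_model"
  out
}

#' @export
print.glv_model <- function(x, ...) {
  off <- x$a; diag(off) <- 0
  cat("GLV model: ", x$n, " taxa, ", x$topology$type, " topology, ",
      sum(off != 0), " interactions (sigma_a = ", format(x$sigma_a), ")\n",
      sep = "")
  boosted <- attr(x, "boost")
  if (!is.null(boosted))
    cat("  boosted taxa: ",
        paste0(boosted$taxon, " (K=", format(boosted$k, digits = 3), ")",
               collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' Boost a taxon's out-going interactions
#'
#' Multiplies all out-going interaction strengths of the focal taxa
#' (`a[j, i]` for `j != i`) by a positive constant `k`, turning them into
#' designated interaction-strength-based keystones. Self-regulation
#' `a[i, i] = -1` is left untouched, so carrying capacity is not conflated
#' with keystone strength. `k` may be a vector (one boost per taxon), e.g.
#' drawn from a log-normal distribution to create a wide range of impacts.
#'
#' @param model a [glv_er()]/[glv_ba()] model.
#' @param taxon index or vector of indices of taxa to boost.
#' @param k positive boost factor(s), recycled against `taxon`.
#' @return the modified `glv_model`.
#' @export
boost_species <- function(model, taxon, k) {
  stopifnot(inherits(model, "glv_model"))
  if (any(k <= 0)) stop("boost factor 'k' must be positive", call. = FALSE)
  if (any(taxon < 1 | taxon > model$n))
    stop("taxon index out of range", call. = FALSE)
  if (anyDuplicated(taxon)) stop("duplicate taxon indices", call. = FALSE)
  k <- rep_len(k, length(taxon))
  for (ii in seq_along(taxon)) {
    i <- taxon[ii]
    keep <- model$a[i, i]
    model$a[, i] <- model$a[, i] * k[ii]
    model$a[i, i] <- keep
  }
  prev <- attr(model, "boost")
  attr(model, "boost") <- list(taxon = c(prev$taxon, taxon),
                               k = c(prev$k, k))
  model
}

#' Log-normal keystone boosts
#'
#' Draws one boost factor per taxon from a log-normal distribution
#' (default meanlog 0.5, sdlog 1), generating a few strongly boosted taxa
#' while most stay near neutral. Used to create ensembles with a wide range
#' of presence-impact values.
#'
#' @param n number of taxa.
#' @param meanlog,sdlog log-normal parameters.
#' @param seed integer seed.
#' @return numeric vector of positive boost factors.
#' @export
lognormal_boosts <- function(n, meanlog = 0.5, sdlog = 1, seed = 1) {
  with_seed(seed, stats::rlnorm(n, meanlog, sdlog))
}

#' Integrate a GLV model to steady state
#'
#' Integrates the GLV equations with [deSolve::lsoda()] in chunks of
#' `t_chunk` time units from a given initial condition, stopping early once
#' the relative derivative norm `max|dx/dt| / max(max|x|, 1e-12)` drops
#' below `tol`, and declaring instability when any abundance exceeds
#' `blowup_cap`. Between chunks, abundances that fell below `extinction_eps`
#' are clipped to exactly 0, so extinct taxa stop contributing stiffness and
#' presence/absence of the steady state is binary. Taxa starting at 0 remain
#' at 0 (the GLV dynamics cannot create mass on an absent taxon).
#'
#' @param model a `glv_model`.
#' @param x0 non-negative initial abundance vector of length `model$n`.
#' @param t_max maximum integration time (default 1000 time units).
#' @param tol steady-state criterion on the relative derivative norm.
#' @param t_chunk time units integrated between convergence checks.
#' @param extinction_eps absolute abundance below which a taxon is extinct.
#' @param blowup_cap abundance at which the integration is declared unstable.
#' @return numeric vector of absolute steady-state abundances with attribute
#'   `converged` (logical: `FALSE` when `t_max` was reached before the
#'   criterion).
#' @export
glv_steady_state <- function(model, x0, t_max = 5000, tol = 1e-8,
                             t_chunk = 250, extinction_eps = 1e-8,
                             blowup_cap = 1e6) {
  stopifnot(inherits(model, "glv_model"))
  if (length(x0) != model$n || any(x0 < 0))
    stop("'x0' must be a non-negative vector of length n", call. = FALSE)
  r <- model$r; a <- model$a
  relnorm <- function(x) {
    dx <- x * (r + drop(a %*% x))
    max(abs(dx)) / max(max(abs(x)), 1e-12)
  }
  x <- as.numeric(x0)
  t_done <- 0
  stalls <- 0L
  converged <- relnorm(x) < tol
  while (!converged && t_done < t_max) {
    step <- min(t_chunk, t_max - t_done)
    parms <- c(blowup_cap, r, a, as.double(x > 0))
    sol <- try(suppressWarnings(
      deSolve::lsodar(y = x, times = seq(0, step, length.out = 6),
                      func = "glv_derivs", parms = parms,
                      dllname = "keystone", initfunc = "glv_initmod",
                      rootfunc = "glv_root", nroot = 1,
                      rtol = 1e-8, atol = 1e-10, maxsteps = 20000)),
      silent = TRUE)
    if (inherits(sol, "try-error") ||
        any(!is.finite(sol[nrow(sol), -1])))
      stop("unstable GLV integration (divergence); model seed ", model$seed,
           call. = FALSE)
    istate <- attr(sol, "istate")[1]
    last <- sol[nrow(sol), -1]
    if (!is.null(attr(sol, "iroot")) || istate == 3 ||
        max(abs(last)) >= blowup_cap)
      stop("unstable GLV integration (abundance exceeded ",
           format(blowup_cap), "); model seed ", model$seed, call. = FALSE)
    t_reached <- sol[nrow(sol), 1]
    if (istate < 0) {
      # early solver return with bounded state: stiff transient, not
      # divergence; retry once from where it got to, then give up
      if (max(abs(last)) > 100)
        stop("unstable GLV integration (runaway abundance); model seed ",
             model$seed, call. = FALSE)
      stalls <- stalls + 1L
      if (stalls > 2L || t_reached <= 0) break
    }
    x <- pmax(last, 0)
    x[x < extinction_eps] <- 0
    t_done <- t_done + max(t_reached, 1e-6)
    converged <- relnorm(x) < tol
  }
  x <- unname(x)
  attr(x, "converged") <- converged
  x
}

#' Simulate a cross-sectional cohort from a GLV model
#'
#' Generates `m` alternative steady states ("samples") of one GLV model by
#' drawing independent initial conditions: each taxon is initially present
#' with probability `presence_prob` (default 0.8) with initial abundance
#' U(0, 1), absent taxa start at exactly 0. Each sample is integrated to
#' steady state and the resulting profiles are normalized to unit sum.
#'
#' The returned [cohort] keeps the absolute steady-state abundances in
#' attribute `absolute` (needed by the perturbation assay), per-sample
#' convergence flags in `converged`, and the generating seed in `seed`.
#'
#' @param model a `glv_model`.
#' @param m number of samples (>= 2).
#' @param presence_prob probability that a taxon is initially present.
#' @param seed integer seed.
#' @param on_instability `"error"` (default) aborts on a diverging sample;
#'   `"drop"` drops it from the cohort; `"resample"` draws replacement
#'   initial conditions until `m` stable samples are collected (only steady
#'   states constitute samples).
#' @inheritParams glv_steady_state
#' @return a [cohort] with attributes `absolute`, `converged`, `seed`.
#' @export
glv_cohort <- function(model, m, presence_prob = 0.8, seed = 1,
                       t_max = 5000, tol = 1e-8,
                       on_instability = c("error", "drop", "resample")) {
  stopifnot(inherits(model, "glv_model"))
  if (m < 2) stop("'m' must be at least 2", call. = FALSE)
  on_instability <- match.arg(on_instability)
  n <- model$n
  n_draw <- if (on_instability == "resample") 3L * m else m
  inits <- with_seed(seed, {
    pres <- matrix(stats::runif(n * n_draw) < presence_prob, n, n_draw)
    matrix(stats::runif(n * n_draw), n, n_draw) * pres
  })
  states <- matrix(0, n, m)
  conv <- logical(m)
  got <- 0L
  for (k in seq_len(n_draw)) {
    if (got == m) break
    x <- NULL
    ok <- sum(inits[, k]) > 0
    if (ok) {
      x <- tryCatch(glv_steady_state(model, inits[, k], t_max = t_max,
                                     tol = tol),
                    error = function(e) e)
      ok <- !inherits(x, "error") && sum(x) > 0
    }
    if (!ok) {
      if (on_instability == "error")
        stop("sample ", k, ": ",
             if (inherits(x, "error")) conditionMessage(x)
             else "degenerate initial condition", call. = FALSE)
      next  # "drop" skips it; "resample" keeps drawing
    }
    got <- got + 1L
    states[, got] <- x
    conv[got] <- isTRUE(attr(x, "converged"))
  }
  if (got < 2)
    stop("fewer than 2 stable samples obtained; model seed ", model$seed,
         call. = FALSE)
  if (on_instability == "resample" && got < m)
    stop("could not collect ", m, " stable samples after ", n_draw,
         " initial conditions; model seed ", model$seed, call. = FALSE)
  states <- states[, seq_len(got), drop = FALSE]
  conv <- conv[seq_len(got)]
  out <- cohort(states,
                taxon_ids = paste0("taxon_", seq_len(n)),
                sample_ids = paste0("sample_", seq_len(got)))
  attr(out, "absolute") <- states
  attr(out, "converged") <- conv
  attr(out, "seed") <- seed
  attr(out, "model_seed") <- model$seed
  out
}

#' Simulate a paired two-time-point cohort
#'
#' Generates two collections for the same GLV model ("subjects" sampled at
#' two visits): each collection is an independent set of steady states with
#' presence resampled at the same probability, emulating the community
#' reassembly of a subject between visits. Subject `h` is column `h` in both
#' collections.
#'
#' @inheritParams glv_cohort
#' @param h number of subjects.
#' @return an object of class `paired_cohort`: list with cohorts `first` and
#'   `second` sharing taxon order and subject order.
#' @export
glv_paired_cohort <- function(model, h, presence_prob = 0.8, seed = 1,
                              on_instability = c("error", "drop")) {
  on_instability <- match.arg(on_instability)
  seeds <- with_seed(seed, sample.int(2^30, 2))
  first <- glv_cohort(model, h, presence_prob, seed = seeds[1],
                      on_instability = on_instability)
  second <- glv_cohort(model, h, presence_prob, seed = seeds[2],
                       on_instability = on_instability)
  # align subjects present in both collections (relevant under "drop")
  common <- intersect(first$sample_ids, second$sample_ids)
  paired_cohort(subset_samples(first, common), subset_samples(second, common))
}

subset_samples <- function(x, ids) {
  j <- match(ids, x$sample_ids)
  out <- cohort(x$abundances[, j, drop = FALSE], taxon_ids = x$taxon_ids,
                sample_ids = ids,
                detection_threshold = x$detection_threshold)
  out
}

#' Pair two cohorts collected from the same subjects
#'
#' @param first,second [cohort]s over identical taxa with identically
#'   ordered subject (sample) identifiers.
#' @return an object of class `paired_cohort`.
#' @export
paired_cohort <- function(first, second) {
  stopifnot(inherits(first, "cohort"), inherits(second, "cohort"))
  if (!identical(first$taxon_ids, second$taxon_ids))
    stop("collections differ in taxa", call. = FALSE)
  if (length(first$sample_ids) != length(second$sample_ids))
    stop("collections differ in number of subjects", call. = FALSE)
  out <- list(first = first, second = second)
  class(out) <- "paired_cohort"
  out
}

#' @export
print.paired_cohort <- function(x, ...) {
  cat("Paired cohort: ", length(x$first$taxon_ids), " taxa, ",
      length(x$first$sample_ids), " subjects at 2 time points\n", sep = "")
  invisible(x)
}
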