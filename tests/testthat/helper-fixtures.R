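# Shared fixtures built in code: small cohorts, random profiles, and
# independent brute-force oracles used to cross-check the implementation.

# random unit-sum profiles (columns), optionally sparse
random_profiles <- function(n_taxa, n_samples, seed, sparsity = 0) {
  set.seed(seed)
  m <- matrix(stats::rexp(n_taxa * n_samples), n_taxa, n_samples)
  if (sparsity > 0) m[matrix(stats::runif(length(m)) < sparsity,
                             nrow(m), ncol(m))] <- 0
  # avoid all-zero columns
  for (j in which(colSums(m) == 0)) m[sample(n_taxa, 1), j] <- 1
  sweep(m, 2, colSums(m), "/")
}

random_cohort <- function(n_taxa = 10, n_samples = 8, seed = 1,
                          sparsity = 0.3) {
  cohort(random_profiles(n_taxa, n_samples, seed, sparsity))
}

# brute-force two-group modularity: literal double loop over ordered pairs
brute_modularity <- function(b, s) {
  m <- nrow(b)
  deg <- rowSums(b)
  two_w <- sum(deg)
  q <- 0
  for (a in seq_len(m)) {
    for (bb in seq_len(m)) {
      q <- q + (b[a, bb] - deg[a] * deg[bb] / two_w) * (s[a] * s[bb] + 1) / 2
    }
  }
  q / two_w
}

# brute-force Bray-Curtis from the general definition sum|x-y|/sum(x+y)
brute_bray <- function(p, q) sum(abs(p - q)) / sum(p + q)

# brute-force D1: explicit loop over cross pairs of renormalized profiles
brute_d1 <- function(abund, taxon, metric = "bray") {
  pres <- abund[taxon, ] > 0
  red <- apply(abund, 2, renormalize_excluding, taxon = taxon)
  tot <- 0; cnt <- 0
  for (k in which(pres)) {
    for (kp in which(!pres)) {
      tot <- tot + pair_dist_test(red[, k], red[, kp], metric)
      cnt <- cnt + 1
    }
  }
  tot / cnt
}

pair_dist_test <- function(p, q, metric) {
  if (metric == "bray") bray_curtis(p, q) else root_jsd(p, q)
}

# small ER-with-keystone test system shared by slower tests
make_keystone_system <- function(n = 30, m = 25, keystone = 3, k = 10,
                                 seed = 42) {
  mod <- boost_species(glv_er(n, mean_degree = 6, seed = seed),
                       taxon = keystone, k = k)
  co <- glv_cohort(mod, m, seed = seed + 1000)
  list(model = mod, cohort = co, keystone = keystone)
}
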