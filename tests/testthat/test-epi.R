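test_that("presence_split partitions samples and renormalizes profiles", {
  ab <- cbind(c(.2, .3, .5), c(0, .4, .6), c(.1, .9, 0), c(0, .5, .5))
  co <- cohort(ab)
  sp <- presence_split(co, 1)
  expect_equal(sp$present, c(1, 3))
  expect_equal(sp$absent, c(2, 4))
  expect_equal(unname(colSums(sp$reduced)), rep(1, 4))
  expect_equal(sp$reduced[, 1], c(.3, .5) / .8, ignore_attr = TRUE)
  # a taxon present everywhere (or nowhere) has no EPI
  expect_error(presence_split(co, 2), "present in all")
})

test_that("D1 and D2 match hand-computed values", {
  # two copies of p in the present group, two of q in the absent group:
  # after excluding taxon 1 every cross pair is the same (p, q) pair
  p <- c(0.5, 0.3, 0.2); q <- c(0, 0.1, 0.9)
  co <- cohort(matrix(c(p, p, q, q), nrow = 3))
  sp <- presence_split(co, 1)
  pq <- bray_curtis(c(0.3, 0.2) / 0.5, c(0.1, 0.9))
  expect_equal(epi_d1(sp), pq)
  expect_equal(epi_d2(sp), pq)

  # the worked D2 example: group means [.5,.5] vs [.25,.75] -> BC 0.25
  g1 <- c(0.5, 0.5); g2 <- c(0.25, 0.75)
  expect_equal(bray_curtis(g1, g2), 0.25)

  # identical reduced profiles on both sides -> D1 = D2 = 0
  same <- cohort(cbind(c(.4, .3, .3), c(.4, .3, .3), c(0, .5, .5)))
  sps <- presence_split(same, 1)
  expect_equal(epi_d1(sps), 0)
  expect_equal(epi_d2(sps), 0)
})

test_that("D1 equals D2 for singleton groups and matches the brute force", {
  set.seed(33)
  for (rep in 1:5) {
    ab <- random_profiles(6, 9, seed = 100 + rep, sparsity = 0.35)
    # ensure taxon 1 is present somewhere and absent somewhere
    ab[1, 1] <- 0.2; ab[1, 2] <- 0
    ab <- sweep(ab, 2, colSums(ab), "/")
    co <- cohort(ab)
    sp <- presence_split(co, 1)
    expect_equal(epi_d1(sp), brute_d1(co$abundances, 1), tolerance = 1e-12)
    expect_equal(epi_d1(sp, "rjsd"), brute_d1(co$abundances, 1, "rjsd"),
                 tolerance = 1e-12)
  }
  # |G| = |G-bar| = 1: both reduce to the single pair distance
  two <- cohort(cbind(c(.3, .3, .4), c(0, .6, .4)))
  sp2 <- presence_split(two, 1)
  expect_equal(epi_d1(sp2), epi_d2(sp2))
})

test_that("D1 and D2 are invariant to sample and taxon order", {
  ab <- random_profiles(8, 10, seed = 44, sparsity = 0.3)
  ab[2, 1:5] <- 0; ab[2, 6:10] <- pmax(ab[2, 6:10], 0.05)
  ab <- sweep(ab, 2, colSums(ab), "/")
  co <- cohort(ab)
  d1 <- epi_d1(presence_split(co, 2)); d2 <- epi_d2(presence_split(co, 2))
  perm <- sample(10)
  cop <- cohort(ab[, perm])
  expect_equal(epi_d1(presence_split(cop, 2)), d1, tolerance = 1e-12)
  expect_equal(epi_d2(presence_split(cop, 2)), d2, tolerance = 1e-12)
  tperm <- c(3, 1, 2, 8, 4, 6, 5, 7)
  cot <- cohort(ab[tperm, ])
  expect_equal(epi_d1(presence_split(cot, which(tperm == 2))), d1,
               tolerance = 1e-12)
})

test_that("similarity networks connect the requested pair fraction", {
  co <- random_cohort(10, 20, seed = 55, sparsity = 0.3)
  co$presence[3, ] <- c(rep(TRUE, 12), rep(FALSE, 8))
  net <- similarity_network(co, 3, p_q = 0.1)
  m <- 20
  expect_true(isSymmetric(net$adjacency))
  expect_true(all(diag(net$adjacency) == 0))
  n_edges <- sum(net$adjacency) / 2
  expect_gte(n_edges, floor(0.1 * choose(m, 2)))
  expect_lte(n_edges, ceiling(0.1 * choose(m, 2)) + 2)  # ties admitted
  expect_equal(sum(net$labels == 1), 12)
  # p_q -> 1 gives the complete graph
  full <- similarity_network(co, 3, p_q = 1)
  expect_equal(sum(full$adjacency) / 2, choose(m, 2))
})

test_that("modularity matches closed forms", {
  # all labels identical: the structural and null terms cancel exactly
  b <- matrix(0, 6, 6)
  b[cbind(c(1, 2, 3, 4, 5), c(2, 3, 4, 5, 6))] <- 1
  b <- b + t(b)
  expect_equal(modularity_q(b, rep(1, 6)), 0)
  # two disconnected equal cliques with matching labels: Q = 1/2
  clique <- function(k) { m <- matrix(1, k, k); diag(m) <- 0; m }
  b2 <- rbind(cbind(clique(5), matrix(0, 5, 5)),
              cbind(matrix(0, 5, 5), clique(5)))
  expect_equal(modularity_q(b2, rep(c(1, -1), each = 5)), 0.5)
  # anti-modular labels on a complete bipartite pairing
  expect_lt(modularity_q(b2, rep(c(1, -1), 5)), 0)
})

test_that("modularity agrees exactly with the brute-force double loop", {
  set.seed(66)
  for (rep in 1:20) {
    m <- 10
    b <- matrix(as.integer(runif(m * m) < 0.3), m, m)
    b[lower.tri(b)] <- t(b)[lower.tri(b)]
    diag(b) <- 0L
    if (sum(b) == 0) next
    s <- sample(c(-1, 1), m, replace = TRUE)
    expect_equal(modularity_q(b, s), brute_modularity(b, s),
                 tolerance = 1e-14)
  }
})

test_that("modularity stays within its theoretical bounds", {
  set.seed(77)
  for (rep in 1:200) {
    m <- sample(5:25, 1)
    b <- matrix(as.integer(runif(m * m) < runif(1, 0.05, 0.5)), m, m)
    b[lower.tri(b)] <- t(b)[lower.tri(b)]
    diag(b) <- 0L
    if (sum(b) == 0) next
    s <- sample(c(-1, 1), m, replace = TRUE)
    q <- modularity_q(b, s)
    expect_gte(q, -0.5)
    expect_lte(q, 1)
  }
  # edgeless network: undefined with a warning
  expect_warning(q0 <- modularity_q(matrix(0, 4, 4), rep(1, 4)), "edgeless")
  expect_true(is.na(q0))
})

test_that("epi_screen marks a designated keystone under strong coupling", {
  # cross-sectional demo conditions: dense ER, unit growth rates, K = 10
  mod <- glv_er(100, 50, seed = 1)
  mod$r <- rep(1, 100)
  mod <- boost_species(mod, taxon = 7, k = 10)
  co <- glv_cohort(mod, 100, seed = 501, on_instability = "drop")
  ep <- epi_screen(co)
  t <- ep$table
  expect_true(t$candidate_d1[7])
  expect_true(t$candidate_d2[7])
  expect_true(t$candidate_q[7])
  expect_equal(which.max(t$d1), 7L)
  expect_equal(which.max(t$d2), 7L)
  # the three measures rank-agree on this cohort
  el <- t$eligible
  expect_gt(cor(t$d1[el], t$d2[el], method = "spearman"), 0)
  expect_gt(cor(t$d1[el], t$q[el], method = "spearman"), 0)
})

test_that("epi_screen on independent random profiles flags at chance level", {
  rates <- c()
  flagged <- list()
  for (s in 1:4) {
    co <- random_cohort(40, 40, seed = 800 + s, sparsity = 0.4)
    ep <- epi_screen(co)
    el <- ep$table$eligible
    fl <- ep$table$candidate_d1[el]
    rates <- c(rates, mean(fl))
    flagged[[s]] <- which(ep$table$candidate_d1)
  }
  expect_lt(mean(rates), 0.1)
  # no taxon is flagged consistently across seeds
  expect_equal(length(Reduce(intersect, flagged)), 0)
})

test_that("epi_screen propagates missing values for ineligible taxa", {
  co <- random_cohort(12, 10, seed = 90, sparsity = 0.3)
  co$presence[1, ] <- TRUE   # no absence contrast
  ep <- epi_screen(co, presence = co$presence)
  expect_false(ep$table$eligible[1])
  expect_true(is.na(ep$table$d1[1]))
  expect_true(is.na(ep$table$candidate_d1[1]))
  expect_error(epi_screen(co, freq_lo = 0.49, freq_hi = 0.5), "too few")
})
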