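test_that("NMI of binary vectors matches information-theoretic anchors", {
  x <- c(1, 1, 0, 0, 1, 0)
  expect_equal(nmi(x, x), 1)
  expect_equal(nmi(x, 1 - x), 1)          # relabelling-invariant
  expect_equal(nmi(c(1, 1, 0, 0), c(1, 0, 1, 0)), 0)  # independent
  expect_equal(nmi(x, rep(1, 6)), 0)      # constant partner
  expect_equal(nmi(x, c(1, 0, 1, 0, 1, 0)), nmi(c(1, 0, 1, 0, 1, 0), x))
  expect_error(nmi(c(1, 0), c(1, 0, 1)), "length")
  # geometric normalization agrees at the extremes
  expect_equal(nmi(x, x, normalization = "geometric"), 1)
})

test_that("NMI is symmetric and bounded on random binary pairs", {
  set.seed(14)
  for (rep in 1:50) {
    x <- runif(30) < runif(1, 0.2, 0.8)
    y <- runif(30) < runif(1, 0.2, 0.8)
    v <- nmi(x, y)
    expect_gte(v, 0); expect_lte(v, 1)
    expect_equal(v, nmi(y, x), tolerance = 1e-12)
  }
})

test_that("co-occurrence networks keep the top NMI pairs with signs", {
  set.seed(41)
  base <- matrix(runif(4 * 40) < 0.5, 4, 40)
  pres <- rbind(base[1, ], base[1, ],            # identical pair
                !base[1, ],                      # complement of taxon 1
                base[2, ], base[3, ], base[4, ])
  rownames(pres) <- paste0("t", 1:6)
  net <- cooccurrence_network(pres, percentile = 0.2)
  key <- paste(net$edges$a, net$edges$b)
  expect_true("t1 t2" %in% key)  # NMI = 1 pair always retained
  expect_true(all(net$edges$nmi >= net$cutoff))
  # anti-correlated pair keeps a negative sign
  i3 <- which(key == "t1 t3" | key == "t2 t3")
  expect_true(length(i3) > 0)
  expect_true(all(net$edges$sign[i3] == -1))
  expect_equal(net$edges$sign[key == "t1 t2"], 1)
  # percentile = 1 connects every non-constant pair
  full <- cooccurrence_network(pres, percentile = 1)
  expect_equal(nrow(full$edges), choose(6, 2))
})

test_that("constant taxa are excluded from pairing with a warning", {
  pres <- rbind(c(1, 1, 1, 1), c(1, 0, 1, 0), c(0, 1, 1, 0), c(1, 1, 0, 0))
  expect_warning(net <- cooccurrence_network(pres, percentile = 1),
                 "constant")
  expect_equal(length(net$nodes), 3)
})

test_that("edge retention does not depend on taxon ordering", {
  set.seed(52)
  pres <- matrix(runif(8 * 30) < 0.5, 8, 30,
                 dimnames = list(paste0("t", 1:8), NULL))
  net <- cooccurrence_network(pres, percentile = 0.3)
  perm <- sample(8)
  net2 <- cooccurrence_network(pres[perm, ], percentile = 0.3)
  canon <- function(n) {
    e <- n$edges
    sorted <- t(apply(e[, 1:2], 1, sort))
    paste(sorted[, 1], sorted[, 2])
  }
  expect_setequal(canon(net), canon(net2))
})

test_that("neighbor EPI correlation is 1 for component-constant values", {
  # two groups of 5 taxa; within-group presence almost identical, across
  # groups independent, so the top NMI pairs all lie within a group
  set.seed(3)
  a <- as.integer(runif(40) < 0.5)
  b <- as.integer(runif(40) < 0.5)
  pres <- rbind(matrix(rep(a, 5), 5, byrow = TRUE),
                matrix(rep(b, 5), 5, byrow = TRUE))
  for (i in 1:10) pres[i, i] <- 1L - pres[i, i]  # break exact ties
  rownames(pres) <- paste0("t", 1:10)
  net <- cooccurrence_network(pres, percentile = 20 / 45)
  within <- xor(net$edges$a %in% paste0("t", 1:5),
                net$edges$b %in% paste0("t", 1:5))
  expect_false(any(within))           # no cross-group edges retained
  expect_gte(nrow(net$edges), 10)
  vals <- stats::setNames(rep(c(0.1, 0.9), each = 5), rownames(pres))
  out <- neighbor_epi_correlation(net, vals, n_shuffles = 200, seed = 1)
  expect_equal(out$r, 1, tolerance = 1e-12)
  expect_lt(out$p, 0.05)
})

test_that("permutation null is well-behaved under label shuffling", {
  set.seed(61)
  pres <- matrix(runif(12 * 40) < 0.5, 12, 40,
                 dimnames = list(paste0("t", 1:12), NULL))
  net <- cooccurrence_network(pres, percentile = 0.4)
  vals <- stats::setNames(runif(12), paste0("t", 1:12))
  ps <- sapply(1:30, function(s) {
    shuffled <- stats::setNames(sample(vals), names(vals))
    neighbor_epi_correlation(net, shuffled, n_shuffles = 100,
                             seed = s)$p
  })
  # under the null, permutation p-values spread over (0, 1)
  expect_gt(mean(ps > 0.05), 0.6)
  expect_gt(stats::sd(ps), 0.1)
})

test_that("a keystone module stands out against the shuffle null", {
  # module of 4 mutualistic, boosted taxa: correlated presence, high EPI
  module <- 1:4
  mod <- boost_species(glv_er(30, 6, seed = 83), taxon = module, k = 6)
  for (i in module) for (j in module) if (i != j) mod$a[i, j] <- 0.3
  co <- glv_cohort(mod, 60, seed = 830, on_instability = "resample")
  ep <- epi_screen(co, measures = "d1")
  vals <- stats::setNames(ep$table$d1, ep$table$taxon)
  vals[is.na(vals)] <- stats::median(vals, na.rm = TRUE)
  net <- cooccurrence_network(co, percentile = 0.25)
  out <- neighbor_epi_correlation(net, vals[net$nodes], n_shuffles = 300,
                                  seed = 7)
  expect_gt(out$r, out$null_q95)
  expect_lt(out$p, 0.05)
})

test_that("greedy module extraction groups correlated taxa", {
  set.seed(95)
  block <- matrix(runif(40) < 0.5, 1, 40)
  pres <- rbind(block, block, block,
                matrix(runif(3 * 40) < 0.5, 3, 40))
  # add a little noise so the block is not literally constant-identical
  pres[2, 1:2] <- !pres[2, 1:2]
  rownames(pres) <- paste0("t", 1:6)
  net <- cooccurrence_network(pres, percentile = 0.3)
  mods <- keystone_modules(net)
  expect_equal(length(unique(mods$module[mods$taxon %in% c("t1", "t2", "t3")])),
               1L)
})
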