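# Within-genotype permutations and the fixed/adaptive schemes.

test_that("within-genotype shuffling conserves each stratum's values exactly", {
  set.seed(20)
  for (rep in 1:20) {
    g <- sample(0:2, 40, replace = TRUE)
    x <- rnorm(40)
    px <- permute_within_genotype(x, g)
    for (lev in unique(g)) {
      expect_equal(sort(px[g == lev]), sort(x[g == lev]))
    }
  }
})

test_that("singleton strata are fixed points; one stratum is a free permutation", {
  x <- c(1.5, -2, 0.3, 9)
  # strata of sizes 2,1,1: the singleton positions never move
  set.seed(19)
  for (r in 1:10) {
    px <- permute_within_genotype(x, c(0, 1, 2, 0))
    expect_identical(px[2:3], x[2:3])
    expect_equal(sort(px[c(1, 4)]), sort(x[c(1, 4)]))
  }
  # strictly singleton strata: identity
  expect_identical(permute_within_genotype(x[1:3], c(0, 1, 2)), x[1:3])
  # all one stratum: multiset preserved
  set.seed(21)
  px <- permute_within_genotype(x, rep(0, 4))
  expect_equal(sort(px), sort(x))
})

test_that("the permutation support for G=(0,0,1,1) is exactly the four stratum products", {
  g <- c(0, 0, 1, 1)
  x <- c(10, 20, 30, 40)
  expected <- c("10 20 30 40", "20 10 30 40", "10 20 40 30", "20 10 40 30")
  set.seed(22)
  seen <- replicate(400, paste(permute_within_genotype(x, g), collapse = " "))
  expect_setequal(unique(seen), expected)
  counts <- table(factor(seen, levels = expected))
  expect_gt(chisq.test(counts)$p.value, 0.001)   # roughly uniform
})

test_that("p_fixed honors its bounds and the tie-inclusive counting rule", {
  null100 <- seq(0.01, 1, length.out = 100)
  expect_equal(p_fixed(2, null100)$p_value, 1 / 101)        # M = 0
  expect_equal(p_fixed(0, null100)$p_value, 1)              # M = N
  nulls9 <- c(1, 2, 3, 4, 5, 6, 7, 8, 9)
  expect_equal(p_fixed(5.5, nulls9)$p_value, 5 / 10)        # 4 larger
  expect_equal(p_fixed(5, nulls9)$p_value, 6 / 10)          # tie counts
  # monotone non-increasing in |z|
  zs <- seq(0, 10, by = 0.5)
  ps <- vapply(zs, function(z) p_fixed(z, nulls9)$p_value, numeric(1))
  expect_true(all(diff(ps) <= 0))
})

test_that("null_statistics validates inputs and matches the analytic |t| null", {
  trio <- toy_trio(n = 150, beta3 = 0, seed = 23)
  expect_error(null_statistics(trio$g, trio$c, trio$t, n = 0), "at least 1")
  set.seed(24)
  ns <- null_statistics(trio$g, trio$c, trio$t, n = 2000)
  expect_s3_class(ns, "null_stats")
  expect_equal(ns$n_executed, 2000L)
  dof <- 150 - 3
  ks <- ks.test(ns$values, function(q) 2 * pt(q, dof) - 1)
  expect_gt(ks$p.value, 0.01)
})

test_that("batched permutation statistics equal direct refits (Frisch-Waugh path)", {
  trio <- toy_trio(n = 40, seed = 25)
  cov <- matrix(rnorm(80), ncol = 2, dimnames = list(NULL, c("a", "b")))
  ctx <- triomed:::perm_context(trio$g, trio$c, trio$t, cov)
  set.seed(26)
  cmat <- sapply(1:5, function(i) permute_within_genotype(trio$c, trio$g))
  fast <- triomed:::perm_batch_stats(ctx, cmat)
  direct <- apply(cmat, 2, function(cp) {
    abs(mediation_statistic(trio$g, cp, trio$t, cov)$z)
  })
  expect_equal(fast, direct, tolerance = 1e-8)
})

test_that("a separated signal beats 1000 null statistics", {
  set.seed(27)
  g <- rep(0:2, each = 40)
  c_expr <- g + rnorm(120, sd = 0.3)
  t_expr <- 3 * c_expr + rnorm(120, sd = 0.1)
  z <- abs(mediation_statistic(g, c_expr, t_expr)$z)
  ns <- null_statistics(g, c_expr, t_expr, n = 1000)
  expect_gt(z, max(ns$values))
  expect_equal(p_fixed(z, ns)$p_value, 1 / 1001)
})

test_that("adaptive scheme stops early on weak signals and reduces to fixed otherwise", {
  plan <- permutation_plan(n_perm = 1000, alpha = 0.05, scheme = "adaptive",
                           seed = 1)
  expect_equal(plan$K, 50L)
  trio <- toy_trio(n = 100, beta3 = 0, seed = 28)
  z <- abs(mediation_statistic(trio$g, trio$c, trio$t)$z)

  set.seed(29)
  ad <- p_adaptive(z, trio$g, trio$c, trio$t, plan = plan)
  expect_true(ad$p$early_stopped)
  expect_equal(ad$p$M, plan$K)
  expect_lt(ad$p$n_executed, plan$n_perm)
  expect_equal(ad$p$p_value,
               min(plan$K + 1, ad$p$M + 1) / min(ad$p$n_executed + 1, 1001))
  expect_equal(length(ad$null$values), ad$p$n_executed)

  # a strong signal never prunes: identical to p_fixed on the same stream
  strong <- toy_trio(n = 100, beta3 = 2, seed = 30)
  zs <- abs(mediation_statistic(strong$g, strong$c, strong$t)$z)
  set.seed(31)
  ad2 <- p_adaptive(zs, strong$g, strong$c, strong$t, plan = plan)
  expect_false(ad2$p$early_stopped)
  expect_equal(ad2$p$n_executed, 1000L)
  expect_equal(ad2$p$p_value, p_fixed(zs, ad2$null)$p_value)
})

test_that("identical seeds give bit-identical adaptive results", {
  plan <- permutation_plan(500, 0.05, "adaptive", seed = 1)
  trio <- toy_trio(n = 60, beta3 = 0.2, seed = 32)
  z <- abs(mediation_statistic(trio$g, trio$c, trio$t)$z)
  set.seed(1234); a <- p_adaptive(z, trio$g, trio$c, trio$t, plan = plan)
  set.seed(1234); b <- p_adaptive(z, trio$g, trio$c, trio$t, plan = plan)
  expect_identical(a$p$p_value, b$p$p_value)
  expect_identical(a$null$values, b$null$values)
})

test_that("adaptive and fixed p-values agree stochastically across replicate trios", {
  set.seed(33)
  n <- 80
  plan <- permutation_plan(500, 0.05, "adaptive", seed = 1)
  pf <- pa <- gam <- numeric(60)
  for (r in 1:60) {
    g <- sample(0:2, n, replace = TRUE, prob = c(0.4, 0.45, 0.15))
    c_expr <- 0.7 * g + rnorm(n)
    t_expr <- 0.15 * c_expr + rnorm(n)
    z <- abs(mediation_statistic(g, c_expr, t_expr)$z)
    ad <- p_adaptive(z, g, c_expr, t_expr, plan = plan)
    pa[r] <- ad$p$p_value
    gam[r] <- ad$p$n_executed
    pf[r] <- p_fixed(z, null_statistics(g, c_expr, t_expr, n = 500))$p_value
  }
  expect_gt(cor(pa, pf), 0.95)
  expect_lt(mean(gam), 500)   # pruning saves permutations on average
})

test_that("permutation plans validate their parameters", {
  expect_error(permutation_plan(0), "positive")
  expect_error(permutation_plan(100, alpha = 0), "alpha")
  expect_error(permutation_plan(100, alpha = 1), "alpha")
  expect_equal(permutation_plan(10, alpha = 0.99)$K, 9L)   # floor keeps K < N
  expect_equal(permutation_plan(10, alpha = 0.01)$K, 1L)   # floor with min 1
})
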