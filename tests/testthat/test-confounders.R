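# Hidden-covariate pool construction and per-trio adaptive selection.

test_that("PC pool matches an independent eigendecomposition up to sign", {
  set.seed(50)
  expr <- matrix(rnorm(100 * 50), 100, 50)   # genes x samples
  pool <- build_pc_pool(expr, n_pcs = 10)
  expect_s3_class(pool, "confounder_pool")
  expect_equal(dim(pool$components), c(50L, 10L))

  xc <- scale(t(expr), center = TRUE, scale = FALSE)
  eig <- eigen(crossprod(xc) / (nrow(xc) - 1))
  scores_oracle <- xc %*% eig$vectors[, 1:10]
  for (j in 1:10) {
    expect_equal(abs(pool$components[, j]), abs(scores_oracle[, j]),
                 tolerance = 1e-8)
  }
  ev_oracle <- eig$values / sum(eig$values)
  expect_equal(pool$explained_variance, ev_oracle[1:10], tolerance = 1e-8)
})

test_that("rank-2 matrices concentrate explained variance on two components", {
  set.seed(51)
  u <- matrix(rnorm(60 * 2), 60, 2)
  v <- matrix(rnorm(2 * 30), 2, 30)
  expr <- u %*% v                              # genes x samples, rank 2
  pool <- build_pc_pool(expr, n_pcs = 2)
  expect_gt(sum(pool$explained_variance), 0.999)

  # duplicating every gene row rescales but does not rotate the scores
  pool2 <- build_pc_pool(rbind(expr, expr), n_pcs = 2)
  cors <- abs(diag(cor(pool$components, pool2$components)))
  expect_equal(unname(cors), c(1, 1), tolerance = 1e-8)
})

test_that("selection picks components correlated with either trait", {
  set.seed(52)
  n <- 100
  c_expr <- rnorm(n)
  t_expr <- rnorm(n)
  pool <- as_confounder_pool(cbind(exactC = c_expr,
                                   noise1 = rnorm(n), noise2 = rnorm(n)))
  sel <- select_confounders(pool, c_expr, t_expr)
  expect_true(1L %in% sel)

  # a pure-noise pool selects almost nothing under BH at FDR 0.05
  set.seed(53)
  rates <- replicate(100, {
    pool_n <- as_confounder_pool(matrix(rnorm(n * 10), n, 10))
    length(select_confounders(pool_n, rnorm(n), rnorm(n)))
  })
  expect_lt(mean(rates), 1)   # well below the 10-column pool size
})

test_that("selection is deterministic and adjusting a planted confounder reduces bias", {
  set.seed(54)
  n <- 150
  h <- rnorm(n)                                 # hidden confounder
  g <- sample(0:2, n, replace = TRUE, prob = c(0.36, 0.48, 0.16))
  c_expr <- 0.8 * g + 1.2 * h + rnorm(n)
  t_expr <- 1.5 * h + rnorm(n)                  # no true mediation
  pool <- as_confounder_pool(cbind(H1 = h, H2 = rnorm(n)))

  s1 <- select_confounders(pool, c_expr, t_expr)
  s2 <- select_confounders(pool, c_expr, t_expr)
  expect_identical(s1, s2)
  expect_true(1L %in% s1)

  cov_adj <- assemble_cov(NULL, pool, mode = "adaptive", c_expr = c_expr,
                          t_expr = t_expr)
  b_raw <- abs(mediation_statistic(g, c_expr, t_expr)$beta)
  b_adj <- abs(mediation_statistic(g, c_expr, t_expr, cov_adj)$beta)
  expect_lt(b_adj, b_raw)                       # confounding bias removed
})

test_that("assemble_cov composes known and hidden covariates correctly", {
  n <- 30
  known <- matrix(rnorm(n * 2), n, 2, dimnames = list(NULL, c("age", "sex")))
  pool <- as_confounder_pool(matrix(rnorm(n * 3), n, 3))

  expect_equal(ncol(assemble_cov(known, NULL, mode = "fixed")), 2L)
  expect_equal(ncol(assemble_cov(known, pool, mode = "fixed")), 5L)
  # empty adaptive selection falls back to known covariates only
  set.seed(55)
  out <- assemble_cov(known, pool, mode = "adaptive",
                      c_expr = rnorm(n), t_expr = rnorm(n))
  expect_lte(ncol(out), 5L)
  expect_true(all(c("age", "sex") %in% colnames(out)))

  bad <- matrix(rnorm(n), n, 1, dimnames = list(NULL, "age"))
  expect_error(assemble_cov(known, as_confounder_pool(bad), mode = "fixed"),
               "duplicate")
  expect_error(assemble_cov(known, NULL, mode = "adaptive"), "pool")
})

test_that("every scheme accepts both adjustment strategies", {
  cfg <- simulation_config(n_samples = 80, n_trios = 2, fraction_null = 0,
                           beta3 = 0.8, n_hidden = 2, loading_sd = 0.5,
                           seed = 56)
  sim <- simulate_trio_data(cfg)
  for (sch in c("fixed", "adaptive", "gpd", "adaptive+gpd")) {
    for (adj in c("fixed", "adaptive")) {
      res <- suppressMessages(run_mediate(
        sim$genotypes, sim$expression, sim$trios,
        covariates = sim$covariates, scheme = sch, n_perm = 100,
        adjust = adj, n_pcs = 3, seed = 1, qvalues = FALSE,
        progress_every = 0))
      expect_true(all(is.na(res$error)), info = paste(sch, adj))
      expect_true(all(res$p_perm > 0 | res$beyond_support),
                  info = paste(sch, adj))
    }
  }
})
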