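test_that("AVE is the mean over spots of replicate means", {
  t1 <- make_tensor(list(g1 = rbind(c(2, 2, 2, 2), c(4, 4, 4, 4)),
                         g2 = matrix(5, 1, 4)))
  expect_equal(unname(average_expression(t1)), c(3, 5))
  t2 <- tensor_from_profiles(list(g1 = c(8, 10, 10, 12)))
  expect_equal(unname(average_expression(t2)), 10)
  expect_error(average_expression(t1, "zz"), "zz")
})

test_that("REV reproduces the chi-square-corrected worked value", {
  t1 <- tensor_from_profiles(list(g1 = c(8, 10, 10, 12)))
  rev <- unname(expression_variability(t1))
  cv <- sd(c(8, 10, 10, 12)) / 10
  corr <- (sqrt(3 / qchisq(0.975, 3)) + sqrt(3 / qchisq(0.025, 3))) / 2
  expect_equal(rev, corr * cv * 100, tolerance = 1e-12)
  expect_equal(rev, 35.07, tolerance = 1e-3)
  # zero replicate variance on every spot
  t0 <- tensor_from_profiles(list(g1 = c(3, 3, 3, 3)))
  expect_equal(unname(expression_variability(t0)), 0)
})

test_that("the chi-square correction shrinks to 1 with degrees of freedom", {
  r <- c(3, 7, 39, 399, 39999)
  corr <- chisq_cv_correction(r)
  expect_true(all(diff(corr) < 0))
  expect_true(all(corr > 1))
  expect_equal(corr[5], 1, tolerance = 1e-3)
})

test_that("REV is scale invariant while AVE scales", {
  set.seed(2)
  m <- matrix(rlnorm(8, 1, 0.3), 2, 4)
  t1 <- make_tensor(list(g1 = m))
  t2 <- make_tensor(list(g1 = 7 * m))
  expect_equal(expression_variability(t1), expression_variability(t2))
  expect_equal(7 * average_expression(t1), average_expression(t2))
})

test_that("COR classifies perfectly aligned and anti-aligned profiles", {
  t1 <- tensor_from_profiles(list(a = c(1, 2, 3, 4), b = c(2, 4, 6, 8),
                                  c = c(4, 3, 2, 1)))
  syn <- expression_correlation(t1, "a", "b")
  expect_equal(syn$cor, 1)
  expect_equal(syn$p, 0)
  expect_equal(syn$class, "synergistic")
  ant <- expression_correlation(t1, "a", "c")
  expect_equal(ant$cor, -1)
  expect_equal(ant$class, "antagonistic")
  expect_error(expression_correlation(t1, "a", "a"), "self")
})

test_that("the significance threshold at n = 4 is |COR| = 0.950", {
  tstar <- qt(0.975, 2)
  rstar <- tstar / sqrt(tstar^2 + 2)
  expect_equal(rstar, 0.950, tolerance = 5e-4)
  expect_lt(cor_pvalue(rstar + 1e-6, 4), 0.05)
  expect_gt(cor_pvalue(rstar - 1e-6, 4), 0.05)
})

test_that("dense and streaming correlation agree with the pairwise oracle", {
  set.seed(31)
  t1 <- random_tensor(n_genes = 50)
  m <- correlation_matrix(t1)
  expect_equal(m, t(m))
  expect_true(all(abs(m) <= 1 + 1e-12))
  values <- split(as.data.frame(t1$a), t1$gene_id)
  values <- lapply(values, as.matrix)
  for (pair in list(c(1, 2), c(7, 33), c(49, 50))) {
    i <- t1$genes[pair[1]]; j <- t1$genes[pair[2]]
    expect_equal(m[i, j], oracle_cor(values[[i]], values[[j]]),
                 tolerance = 1e-12)
  }
  # streamed row sums of squares match dense recomputation
  s_stream <- gfabric:::.cor_sq_sums(t1, block_size = 7)
  m0 <- m; diag(m0) <- 0
  expect_equal(unname(s_stream), unname(rowSums(m0^2)), tolerance = 1e-12)
  # streaming callback sees every pair once per row
  n_cols <- c()
  correlation_apply(t1, function(rows, blk) n_cols <<- c(n_cols, ncol(blk)),
                    block_size = 13)
  expect_true(all(n_cols == 50))
})

test_that("GCH matches direct substitution and is monotone in REV", {
  # profiles built so every pairwise correlation is exactly zero:
  # orthogonal contrasts around a common mean
  prof <- list(a = c(10, 10, 12, 12), b = c(10, 12, 12, 10),
               c = c(10, 12, 10, 12))
  t1 <- tensor_from_profiles(prof)
  m <- correlation_matrix(t1)
  expect_true(all(abs(m[upper.tri(m)]) < 1e-12))
  gch <- gene_commanding_height(t1)
  revs <- expression_variability(t1)
  # all three genes have identical REV here, so REV_med/REV = 1 and the
  # exponent collapses to -1
  expect_equal(unname(gch), rep(exp(-1), 3), tolerance = 1e-12)
  # scaling one gene's dispersion up lowers its GCH
  prof2 <- prof
  prof2$a <- c(8, 8, 14, 14)  # same mean, larger spread, same correlations
  t2 <- tensor_from_profiles(prof2)
  gch2 <- gene_commanding_height(t2)
  expect_lt(gch2[["a"]], gch[["a"]])
})

test_that("GCH agrees with the dense loop oracle on random data", {
  set.seed(77)
  values <- list()
  for (i in 1:15)
    values[[sprintf("g%02d", i)]] <- matrix(rlnorm(8, 1, 0.4), 2, 4)
  t1 <- make_tensor(values)
  expect_equal(unname(gene_commanding_height(t1)),
               unname(oracle_gch(values)[t1$genes]), tolerance = 1e-9)
})

test_that("a strong hub with low REV approaches the theoretical GCH ceiling", {
  # REV_i = REV_med / 10 and |COR| = 1 with every other gene would give
  # 10 * exp(3) at large N; check the formula algebraically
  n <- 4; N <- 1000
  s <- N - 1                                # all squared correlations 1
  gch_limit <- 10 * exp(n / N * s - 1)
  expect_equal(gch_limit, 10 * exp(3), tolerance = 2e-2)
})

test_that("hierarchy ranking is stable and names the GMR", {
  h <- rank_hierarchy(c(a = 5, b = 2, c = 9))
  expect_equal(h$gene_id, c("c", "a", "b"))
  expect_equal(attr(h, "GMR"), "c")
  flat <- rank_hierarchy(c(a = 1, b = 1, c = 1))
  expect_equal(flat$gene_id, c("a", "b", "c"))  # ties broken by gene id
})

test_that("REV separates simulated CV classes almost perfectly", {
  cfg <- sim_config(n_genes = 500, regions = "r1", phenotypes = "p1",
                    spots_per_gene = 1,
                    cv_range = c(0.1, 0.1),
                    cv_overrides = setNames(rep(0.4, 250),
                                            sprintf("g%03d", 1:250)),
                    frac_corrupted_spots = 0, frac_low_signal_spots = 0,
                    seed = 17)
  fit <- gfp(simulate_experiment(cfg), gch = FALSE)
  s <- fit$summaries[[1]]
  hi <- s$gene_id %in% sprintf("g%03d", 1:250)
  # AUC by rank sum
  r <- rank(s$REV)
  auc <- (sum(r[hi]) - sum(hi) * (sum(hi) + 1) / 2) /
    (sum(hi) * sum(!hi))
  expect_gt(auc, 0.95)
})
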