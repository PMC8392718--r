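# Independent brute-force oracles, written as plain loops so they share no
# code path with the package implementations they check.

# build a tensor directly from a named list of spot-by-replica matrices
make_tensor <- function(values, region = "r1", phenotype = "p1") {
  expression_tensor(values, region = region, phenotype = phenotype)
}

# per-replica profiles with a loading-1.0 co-regulation block: gene i has
# lognormal baseline and multiplicative noise with its own CV; block genes
# share the per-replica latent draw
hub_profiles <- function(n_genes = 200, block = 50, cv_hub = 0.02,
                         cv_rest = 0.3, n_rep = 4) {
  m <- rlnorm(n_genes, 4, 1.5)
  cv <- c(cv_hub, rep(cv_rest, n_genes - 1))
  sigma <- sqrt(log(1 + cv^2))
  latent <- rnorm(n_rep)
  vals <- lapply(seq_len(n_genes), function(i) {
    z <- if (i <= block) latent else rnorm(n_rep)
    matrix(m[i] * exp(sigma[i] * z - sigma[i]^2 / 2), 1)
  })
  names(vals) <- sprintf("g%03d", seq_len(n_genes))
  vals
}

# random small tensor with R_i spots per gene
random_tensor <- function(n_genes = 20, n_replicas = 4, max_spots = 3,
                          region = "r1", phenotype = "p1") {
  values <- list()
  for (i in seq_len(n_genes)) {
    r <- sample(max_spots, 1)
    values[[sprintf("g%03d", i)]] <-
      matrix(rlnorm(r * n_replicas, 1, 0.6), r, n_replicas)
  }
  make_tensor(values, region, phenotype)
}

oracle_ave <- function(values_gene) {
  mu <- numeric(nrow(values_gene))
  for (k in seq_len(nrow(values_gene))) mu[k] <- mean(values_gene[k, ])
  mean(mu)
}

oracle_rev <- function(values_gene, alpha = 0.05) {
  R <- nrow(values_gene)
  n <- ncol(values_gene)
  acc <- 0
  for (k in seq_len(R)) {
    mu <- mean(values_gene[k, ])
    s <- sd(values_gene[k, ])
    acc <- acc + (s / mu)^2
  }
  r <- n * R - 1
  corr <- (sqrt(r / qchisq(1 - alpha / 2, r)) +
           sqrt(r / qchisq(alpha / 2, r))) / 2
  corr * sqrt(acc / R) * 100
}

oracle_profile <- function(values_gene) {
  v <- numeric(ncol(values_gene))
  for (xi in seq_len(ncol(values_gene)))
    v[xi] <- mean(values_gene[, xi])
  v
}

oracle_cor <- function(values_i, values_j)
  cor(oracle_profile(values_i), oracle_profile(values_j))

oracle_cor_p <- function(r, n) {
  if (abs(r) >= 1) return(0)
  tt <- abs(r) * sqrt((n - 2) / (1 - r^2))
  2 * (1 - pt(tt, n - 2))
}

# GCH for every gene, dense loops (default "offset" variant, median norm)
oracle_gch <- function(values, alpha = 0.05) {
  genes <- names(values)
  N <- length(genes)
  n <- ncol(values[[1]])
  revs <- vapply(values, oracle_rev, 0, alpha = alpha)
  out <- numeric(N)
  for (i in seq_len(N)) {
    ssq <- 0
    for (j in seq_len(N)) {
      if (i == j) next
      ssq <- ssq + oracle_cor(values[[i]], values[[j]])^2
    }
    out[i] <- (median(revs) / revs[i]) * exp(n / N * ssq - 1)
  }
  names(out) <- genes
  out
}

oracle_welch_p <- function(x, y) t.test(x, y)$p.value

oracle_wir <- function(ave_ref, x, p) {
  s <- if (x > 0) 1 else -1
  ave_ref * s * (abs(x) - 1) * (1 - p)
}

# spot table for one gene measured directly (R_i = 1 spot), given per-replica
# signals; background 0 so normalization by a single-spot median is identity
# when all arrays also carry reference spots
tensor_from_profiles <- function(profiles) {
  # profiles: named list gene -> numeric vector over replicas
  values <- lapply(profiles, function(v) matrix(v, nrow = 1))
  make_tensor(values)
}
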