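## Per-gene fabric characteristics: AVE, REV (chi-square interval-corrected
## pooled CV), pairwise COR across biological replicas, and the GCH hierarchy.

.tensor_gene_factor <- function(tensor)
  factor(tensor$gene_id, levels = tensor$genes)

.check_genes <- function(tensor, genes) {
  unknown <- setdiff(genes, tensor$genes)
  if (length(unknown))
    stop("gene(s) not in tensor: ", paste(unknown, collapse = ", "),
         call. = FALSE)
  genes
}

#' Average expression level (AVE)
#'
#' Mean over a gene's redundant spots of the per-spot replicate means, in
#' multiples of the array median (the tensor holds median-normalized
#' signals).
#'
#' @param tensor a `gfp_tensor`.
#' @param genes optional character vector; default all genes.
#' @return named numeric vector of AVE values.
#' @export
average_expression <- function(tensor, genes = NULL) {
  gf <- .tensor_gene_factor(tensor)
  ave <- as.numeric(rowsum(tensor$mu, gf, reorder = FALSE)) / tensor$R
  names(ave) <- tensor$genes
  if (is.null(genes)) ave else ave[.check_genes(tensor, genes)]
}

#' Chi-square interval correction for a pooled coefficient of variation
#'
#' Midpoint of the chi-square confidence-interval multipliers for a standard
#' deviation estimated with `r` degrees of freedom:
#' `(sqrt(r/chisq_upper) + sqrt(r/chisq_lower)) / 2`, where the upper and
#' lower quantiles are at `1 - alpha/2` and `alpha/2`.  Tends to 1 as `r`
#' grows.
#'
#' @param r degrees of freedom (vectorized).
#' @param alpha interval level, default 0.05.
#' @return numeric vector of correction coefficients (>= 1).
#' @export
chisq_cv_correction <- function(r, alpha = 0.05) {
  0.5 * (sqrt(r / stats::qchisq(1 - alpha / 2, r)) +
         sqrt(r / stats::qchisq(alpha / 2, r)))
}

#' Relative expression variability (REV)
#'
#' Pooled per-gene coefficient of variation across biological replicas,
#' `sqrt(mean over spots of (s_ik / mu_ik)^2)`, multiplied by the chi-square
#' interval correction for `r_i = n_replicas * R_i - 1` degrees of freedom
#' and expressed in percent.  `s_ik` is the sample standard deviation of
#' spot k over replicas and `mu_ik` its replicate mean.
#'
#' @inheritParams average_expression
#' @param alpha chi-square interval level (default 0.05).
#' @return named numeric vector of REV values (percent).
#' @export
expression_variability <- function(tensor, genes = NULL, alpha = 0.05) {
  gf <- .tensor_gene_factor(tensor)
  if (any(tensor$mu == 0))
    stop("zero replicate mean encountered; CV undefined", call. = FALSE)
  cv2 <- (tensor$s / tensor$mu)^2
  pooled <- sqrt(as.numeric(rowsum(cv2, gf, reorder = FALSE)) / tensor$R)
  r <- tensor$n_replicas * tensor$R - 1
  rev <- chisq_cv_correction(r, alpha) * pooled * 100
  names(rev) <- tensor$genes
  if (is.null(genes)) rev else rev[.check_genes(tensor, genes)]
}

## Rows of `profiles` centred and scaled to unit norm; rows with zero
## variance become NA.  crossprod of the result is the correlation matrix.
.std_profiles <- function(profiles) {
  x <- profiles - rowMeans(profiles)
  d <- sqrt(rowSums(x^2))
  d[d == 0] <- NA_real_
  x / d
}

#' Two-tailed p-value for a Pearson correlation
#'
#' Student t transform `t = r sqrt((n-2)/(1-r^2))` with `n - 2` degrees of
#' freedom; `|r| = 1` gives p = 0.
#'
#' @param r correlation coefficient(s).
#' @param n number of paired observations.
#' @return p-value(s) in `[0, 1]`.
#' @export
cor_pvalue <- function(r, n) {
  p <- rep(NA_real_, length(r))
  one <- !is.na(r) & abs(r) >= 1
  p[one] <- 0
  ok <- !is.na(r) & !one
  t <- abs(r[ok]) * sqrt((n - 2) / (1 - r[ok]^2))
  p[ok] <- 2 * stats::pt(t, n - 2, lower.tail = FALSE)
  p
}

.classify_edge <- function(r, p, alpha,
                           labels = c("synergistic", "antagonistic",
                                      "independent")) {
  cls <- rep(labels[3], length(r))
  cls[!is.na(p) & p < alpha & r > 0] <- labels[1]
  cls[!is.na(p) & p < alpha & r < 0] <- labels[2]
  cls[is.na(r)] <- NA_character_
  cls
}

#' Expression correlation (COR) between two genes
#'
#' Pearson correlation of the two genes' per-replica profiles
#' `v = (1/R_i) sum_k a_ikx` across the biological replicas, with the
#' t-transform p-value and a sign classification: synergistic
#' (significantly positive), antagonistic (significantly negative) or
#' independent.
#'
#' @inheritParams average_expression
#' @param gene_i,gene_j gene identifiers.
#' @param alpha significance level for the sign classification.
#' @return one-row data frame `gene_i, gene_j, cor, n, p, class`.
#' @export
expression_correlation <- function(tensor, gene_i, gene_j, alpha = 0.05) {
  .check_genes(tensor, c(gene_i, gene_j))
  if (gene_i == gene_j)
    stop("self-correlation is excluded", call. = FALSE)
  v1 <- tensor$profiles[gene_i, ]
  v2 <- tensor$profiles[gene_j, ]
  r <- if (stats::sd(v1) == 0 || stats::sd(v2) == 0) NA_real_ else
    stats::cor(v1, v2)
  p <- if (is.na(r)) NA_real_ else cor_pvalue(r, tensor$n_replicas)
  data.frame(gene_i = gene_i, gene_j = gene_j, cor = r,
             n = tensor$n_replicas, p = p,
             class = .classify_edge(r, p, alpha),
             stringsAsFactors = FALSE)
}

#' Dense pairwise correlation matrix
#'
#' Correlation of per-replica profiles for every gene pair of (a subset of)
#' the tensor.  Intended for moderate gene counts; use
#' [correlation_apply()] to stream over blocks when N is large.
#'
#' @inheritParams average_expression
#' @return symmetric N x N matrix with unit diagonal; rows of zero variance
#'   give NA.
#' @export
correlation_matrix <- function(tensor, genes = NULL) {
  p <- tensor$profiles
  if (!is.null(genes)) p <- p[.check_genes(tensor, genes), , drop = FALSE]
  x <- .std_profiles(p)
  m <- tcrossprod(x)
  diag(m)[!is.na(diag(m))] <- 1
  m
}

#' Stream the correlation matrix in row blocks
#'
#' Computes the full N x N correlation structure block by block and passes
#' each block to an accumulator, so the O(N^2) pairs never need simultaneous
#' residence.  The callback receives the integer row indices of the block
#' and the `length(rows) x N` correlation slice (self-correlations on the
#' diagonal positions included, as 1).
#'
#' @inheritParams average_expression
#' @param f `function(rows, cor_block)`; its return values are collected in
#'   a list.
#' @param block_size rows per block.
#' @return list of the callback's return values, invisibly.
#' @export
correlation_apply <- function(tensor, f, genes = NULL, block_size = 512L) {
  p <- tensor$profiles
  if (!is.null(genes)) p <- p[.check_genes(tensor, genes), , drop = FALSE]
  x <- .std_profiles(p)
  n <- nrow(x)
  out <- list()
  start <- 1L
  while (start <= n) {
    rows <- start:min(start + block_size - 1L, n)
    blk <- tcrossprod(x[rows, , drop = FALSE], x)
    blk[cbind(seq_along(rows), rows)] <-
      ifelse(is.na(x[rows, 1]), NA_real_, 1)
    out[[length(out) + 1L]] <- f(rows, blk)
    start <- start + block_size
  }
  invisible(out)
}

## Sum over j != i of COR_ij^2, streamed.  Zero-variance genes contribute
## nothing and get NA themselves.
.cor_sq_sums <- function(tensor, block_size = 512L) {
  x <- .std_profiles(tensor$profiles)
  n <- nrow(x)
  ok <- !is.na(x[, 1])
  xok <- x[ok, , drop = FALSE]
  s <- rep(NA_real_, n)
  idx <- which(ok)
  start <- 1L
  while (start <= length(idx)) {
    rows <- start:min(start + block_size - 1L, length(idx))
    blk <- tcrossprod(xok[rows, , drop = FALSE], xok)
    ## numerical guard: |r| can exceed 1 by rounding
    blk[blk > 1] <- 1; blk[blk < -1] <- -1
    s[idx[rows]] <- rowSums(blk^2) - 1  # remove the self term
    start <- start + length(rows)
  }
  names(s) <- tensor$genes
  s
}

#' Gene Commanding Height (GCH)
#'
#' Composite score ranking genes by strong homeostatic control (low REV)
#' and strong coordination with all other genes:
#' `GCH_i = (REV_center / REV_i) * exp(n_rep/N * sum_{j != i} COR_ij^2 - 1)`
#' (variant `"offset"`, the default), or with the exponent
#' `n_rep * (mean_{j != i} COR_ij^2 - 1)` (variant `"scaled"`).  The REV
#' numerator is the dataset median (or mean) REV.
#'
#' @inheritParams expression_variability
#' @param variant exponent parenthesization, `"offset"` or `"scaled"`.
#' @param rev_center `"median"` (default) or `"mean"` dataset REV norm.
#' @param block_size rows per correlation block.
#' @return named numeric vector of GCH scores.
#' @export
gene_commanding_height <- function(tensor, alpha = 0.05,
                                   variant = c("offset", "scaled"),
                                   rev_center = c("median", "mean"),
                                   block_size = 512L) {
  variant <- match.arg(variant)
  rev_center <- match.arg(rev_center)
  rev <- expression_variability(tensor, alpha = alpha)
  if (any(rev == 0)) {
    pos <- rev[rev > 0]
    if (!length(pos))
      stop("all REV values are zero; GCH undefined", call. = FALSE)
    warning("REV = 0 for ", sum(rev == 0),
            " gene(s); substituting smallest positive REV")
    rev[rev == 0] <- min(pos)
  }
  center <- if (rev_center == "median") stats::median(rev) else mean(rev)
  s <- .cor_sq_sums(tensor, block_size)
  n <- length(tensor$genes)
  k <- tensor$n_replicas
  expo <- switch(variant,
                 offset = k / n * s - 1,
                 scaled = k * (s / (n - 1) - 1))
  gch <- (center / rev) * exp(expo)
  names(gch) <- tensor$genes
  gch
}

#' Rank the gene hierarchy by GCH
#'
#' Orders genes by descending GCH, ties broken by gene id; the rank-1 gene
#' is the Gene Master Regulator (GMR) of the dataset.
#'
#' @param gch named numeric vector of GCH scores.
#' @return data frame `gene_id, GCH, rank` in hierarchy order, with
#'   attribute `GMR`.
#' @export
rank_hierarchy <- function(gch) {
  if (is.null(names(gch))) stop("`gch` must be named by gene", call. = FALSE)
  ord <- order(-gch, names(gch))
  out <- data.frame(gene_id = names(gch)[ord], GCH = as.numeric(gch[ord]),
                    rank = seq_along(gch), stringsAsFactors = FALSE)
  attr(out, "GMR") <- out$gene_id[1]
  out
}

#' Per-gene summary of one (region, phenotype) dataset
#'
#' @inheritParams gene_commanding_height
#' @param gch compute GCH (O(N^2) correlations) as well?
#' @return data frame `gene_id, AVE, REV, df, correction` plus, when
#'   `gch = TRUE`, `GCH` and `rank`.
#' @export
gene_summary <- function(tensor, alpha = 0.05, gch = TRUE,
                         variant = c("offset", "scaled"),
                         rev_center = c("median", "mean"),
                         block_size = 512L) {
  out <- data.frame(gene_id = tensor$genes,
                    AVE = as.numeric(average_expression(tensor)),
                    REV = as.numeric(expression_variability(tensor,
                                                            alpha = alpha)),
                    df = tensor$n_replicas * as.integer(tensor$R) - 1,
                    stringsAsFactors = FALSE)
  out$correction <- chisq_cv_correction(out$df, alpha)
  if (gch) {
    g <- gene_commanding_height(tensor, alpha = alpha, variant = variant,
                                rev_center = rev_center,
                                block_size = block_size)
    out$GCH <- as.numeric(g)
    out$rank <- match(out$gene_id, rank_hierarchy(g)$gene_id)
  }
  out
}
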