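## Composite differential-expression calling between two phenotypes and the
## weighted individual / pathway regulation scores (WIR / WPR).

#' Signed expression ratio
#'
#' Fold change oriented so its sign tells the direction in the test
#' phenotype: `AVE_test / AVE_ref` when the test expression is at least the
#' reference, otherwise `-AVE_ref / AVE_test` (negative = down-regulated in
#' the test phenotype).  `|x| >= 1` always.
#'
#' @param ave_test,ave_ref positive average expression levels (vectorized).
#' @return signed ratio(s).
#' @export
expression_ratio <- function(ave_test, ave_ref) {
  if (any(ave_test <= 0) || any(ave_ref <= 0))
    stop("AVE values must be positive", call. = FALSE)
  ifelse(ave_test >= ave_ref, ave_test / ave_ref, -ave_ref / ave_test)
}

#' Variability-adjusted fold-change cutoff
#'
#' The fold change a gene must exceed to be called regulated grows with the
#' combined relative expression variabilities of the two compared datasets:
#' `CUT = 1 + sqrt(2 (REV_test^2 + REV_ref^2)) / 100` (REV in percent).
#'
#' @param rev_test,rev_ref REV values in percent (vectorized).
#' @return cutoff(s) `>= 1`.
#' @export
regulation_cut <- function(rev_test, rev_ref) {
  if (any(rev_test < 0) || any(rev_ref < 0))
    stop("REV values must be non-negative", call. = FALSE)
  1 + sqrt(2 * (rev_test^2 + rev_ref^2)) / 100
}

## Row-wise Welch test on two matrices of per-replica profiles.
.welch_rows <- function(a, b) {
  nx <- ncol(a); ny <- ncol(b)
  mx <- rowMeans(a); my <- rowMeans(b)
  vx <- rowSums((a - mx)^2) / (nx - 1)
  vy <- rowSums((b - my)^2) / (ny - 1)
  se2 <- vx / nx + vy / ny
  t <- (mx - my) / sqrt(se2)
  df <- se2^2 / ((vx / nx)^2 / (nx - 1) + (vy / ny)^2 / (ny - 1))
  p <- 2 * stats::pt(abs(t), df, lower.tail = FALSE)
  degen <- se2 == 0
  p[degen] <- ifelse(mx[degen] == my[degen], 1, 0)
  p
}

#' Heteroscedastic (Welch) t-test p-value
#'
#' Two-tailed Welch t-test with Welch-Satterthwaite degrees of freedom on
#' the per-replica profiles of a gene in two groups.  By convention, two
#' zero-variance groups give p = 1 when the means are equal and p = 0
#' otherwise.
#'
#' @param x,y numeric vectors of per-replica values (>= 2 each).
#' @return two-tailed p-value.
#' @export
welch_p <- function(x, y) {
  if (length(x) < 2 || length(y) < 2)
    stop("need at least 2 values per group", call. = FALSE)
  .welch_rows(matrix(x, 1), matrix(y, 1))
}

#' Composite regulation call
#'
#' A gene is significantly regulated when its absolute expression ratio
#' strictly exceeds the variability-adjusted cutoff AND the Welch p-value is
#' strictly below `alpha`.  The uniform contribution is the conventional
#' +1/-1 tally of significant up/down calls (0 otherwise).
#'
#' @param x signed expression ratio(s).
#' @param cut cutoff(s) from [regulation_cut()].
#' @param p Welch p-value(s).
#' @param alpha significance level, default 0.05.
#' @return data frame `significant` (logical), `contribution` (+1/-1/0).
#' @export
call_regulation <- function(x, cut, p, alpha = 0.05) {
  sig <- abs(x) > cut & p < alpha
  data.frame(significant = sig,
             contribution = ifelse(sig, sign(x), 0))
}

#' Weighted individual regulation (WIR)
#'
#' Scores every gene (significant or not) by the product of its reference
#' expression level, its net fold change and the statistical confidence of
#' the regulation: `WIR = AVE_ref * sign(x) * (|x| - 1) * (1 - p)`.
#'
#' @param ave_ref reference-phenotype AVE (vectorized).
#' @param x signed expression ratio.
#' @param p Welch p-value.
#' @return signed WIR score(s), in AVE units.
#' @export
weighted_individual_regulation <- function(ave_ref, x, p) {
  ave_ref * sign(x) * (abs(x) - 1) * (1 - p)
}

#' Compare two phenotypes within a region
#'
#' Computes, for every gene of the common universe, the signed expression
#' ratio, the variability-adjusted cutoff, the Welch p-value on per-replica
#' profiles, the composite significance call and WIR, for
#' `test` vs `ref` ("A vs B" means A is the test and B the reference; a
#' positive ratio is up-regulation in A).
#'
#' @param object a fitted [gfp()] object.
#' @param test,ref phenotype labels.
#' @param region region label (may be omitted when the fit has one region).
#' @param alpha significance level; defaults to the fit's alpha.
#' @return data frame of class `gfp_regulation` (one row per gene, ordered
#'   by decreasing `|WIR|`) with columns `gene_id, AVE_test, AVE_ref, x,
#'   CUT, p, significant, contribution, WIR` and attributes `test`, `ref`,
#'   `region`, `alpha`.
#' @export
compare_phenotypes <- function(object, test, ref, region = NULL,
                               alpha = NULL) {
  stopifnot(inherits(object, "gfp"))
  if (is.null(alpha)) alpha <- object$alpha
  if (is.null(region)) {
    region <- unique(vapply(object$tensors, `[[`, "", "region"))
    if (length(region) > 1)
      stop("multiple regions in fit; specify `region`", call. = FALSE)
  }
  kt <- paste(region, test, sep = "|")
  kr <- paste(region, ref, sep = "|")
  if (!kt %in% names(object$tensors))
    stop("no dataset for region ", region, ", phenotype ", test,
         call. = FALSE)
  if (!kr %in% names(object$tensors))
    stop("no dataset for region ", region, ", phenotype ", ref,
         call. = FALSE)
  tt <- object$tensors[[kt]]
  tr <- object$tensors[[kr]]
  genes <- tt$genes  # common universe guarantees identity with tr$genes
  ave_t <- average_expression(tt)[genes]
  ave_r <- average_expression(tr)[genes]
  rev_t <- expression_variability(tt)[genes]
  rev_r <- expression_variability(tr)[genes]
  x <- expression_ratio(ave_t, ave_r)
  cut <- regulation_cut(rev_t, rev_r)
  p <- .welch_rows(tt$profiles[genes, , drop = FALSE],
                   tr$profiles[genes, , drop = FALSE])
  call <- call_regulation(x, cut, p, alpha)
  wir <- weighted_individual_regulation(ave_r, x, p)
  out <- data.frame(gene_id = genes, AVE_test = as.numeric(ave_t),
                    AVE_ref = as.numeric(ave_r), x = as.numeric(x),
                    CUT = as.numeric(cut), p = as.numeric(p),
                    significant = call$significant,
                    contribution = call$contribution,
                    WIR = as.numeric(wir), stringsAsFactors = FALSE)
  out <- out[order(-abs(out$WIR), out$gene_id), , drop = FALSE]
  rownames(out) <- NULL
  structure(out, test = test, ref = ref, region = region, alpha = alpha,
            class = c("gfp_regulation", "data.frame"))
}

#' @export
print.gfp_regulation <- function(x, n = 10, ...) {
  cat(sprintf("Regulation: %s vs %s (%s), alpha = %g\n",
              attr(x, "test"), attr(x, "ref"), attr(x, "region"),
              attr(x, "alpha")))
  cat(sprintf("%d genes, %d significant (%d up, %d down)\n",
              nrow(x), sum(x$significant), sum(x$contribution == 1),
              sum(x$contribution == -1)))
  print.data.frame(utils::head(x, n), digits = 4)
  if (nrow(x) > n) cat("... (", nrow(x) - n, " more genes)\n", sep = "")
  invisible(x)
}

#' Read / write gene sets in GMT format
#'
#' Standard tab-separated gene-set format: one set per line as
#' `name <tab> description <tab> gene1 <tab> gene2 ...`.
#'
#' @param path file path.
#' @return `read_gmt()`: named list of character gene vectors with a
#'   `descriptions` attribute.
#' @export
read_gmt <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  bad <- lengths(parts) < 3
  if (any(bad))
    stop("malformed GMT line(s): ", paste(which(bad), collapse = ", "),
         call. = FALSE)
  sets <- lapply(parts, function(p) unique(p[-(1:2)]))
  names(sets) <- vapply(parts, `[[`, "", 1)
  attr(sets, "descriptions") <-
    stats::setNames(vapply(parts, `[[`, "", 2), names(sets))
  sets
}

#' @rdname read_gmt
#' @param sets named list of character gene vectors.
#' @param descriptions optional character vector recycled across sets.
#' @export
write_gmt <- function(sets, path, descriptions = "") {
  descriptions <- rep_len(descriptions, length(sets))
  lines <- vapply(seq_along(sets), function(i)
    paste(c(names(sets)[i], descriptions[i], sets[[i]]), collapse = "\t"),
    "")
  writeLines(lines, path)
  invisible(path)
}

#' Percent up- and down-regulated genes in a gene set
#'
#' Percentages are over the quantified members of the set (`Card`), i.e.
#' genes present in the regulation table.
#'
#' @param regulation a [compare_phenotypes()] result.
#' @param genes character vector of pathway gene ids.
#' @return list `card`, `percent_up`, `percent_down`.
#' @export
percent_up_down <- function(regulation, genes) {
  hit <- regulation[regulation$gene_id %in% genes, , drop = FALSE]
  card <- nrow(hit)
  if (card == 0)
    return(list(card = 0L, percent_up = NA_real_, percent_down = NA_real_))
  list(card = card,
       percent_up = 100 * sum(hit$contribution == 1) / card,
       percent_down = 100 * sum(hit$contribution == -1) / card)
}

#' Weighted pathway regulation (WPR)
#'
#' Aggregates per-gene WIR magnitudes over a pathway: the mean absolute WIR
#' (default) or the root-mean-square.
#'
#' @param wir numeric WIR values of the pathway's quantified genes.
#' @param variant `"mean_abs"` (default) or `"rms"`.
#' @return non-negative WPR score.
#' @export
weighted_pathway_regulation <- function(wir, variant = c("mean_abs", "rms")) {
  variant <- match.arg(variant)
  if (!length(wir)) return(NA_real_)
  switch(variant,
         mean_abs = mean(abs(wir)),
         rms = sqrt(mean(wir^2)))
}

#' Pathway-level regulation summary
#'
#' @param regulation a [compare_phenotypes()] result.
#' @param pathways named list of gene-id vectors (e.g. from [read_gmt()]).
#' @param variant WPR variant, see [weighted_pathway_regulation()].
#' @return data frame `pathway, card, percent_up, percent_down, WPR`;
#'   pathways with no quantified gene get NA scores and are also listed in
#'   the `empty` attribute.
#' @export
pathway_regulation <- function(regulation, pathways,
                               variant = c("mean_abs", "rms")) {
  variant <- match.arg(variant)
  rows <- lapply(names(pathways), function(nm) {
    genes <- pathways[[nm]]
    ud <- percent_up_down(regulation, genes)
    wir <- regulation$WIR[regulation$gene_id %in% genes]
    data.frame(pathway = nm, card = ud$card, percent_up = ud$percent_up,
               percent_down = ud$percent_down,
               WPR = weighted_pathway_regulation(wir, variant),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  attr(out, "empty") <- out$pathway[out$card == 0]
  out
}
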