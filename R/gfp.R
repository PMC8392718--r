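## The central estimator: filter, normalize, assemble, and characterise
## every (region, phenotype) dataset of a spot-level experiment.

#' Fit the genomic fabric characteristics of an experiment
#'
#' Runs the full per-dataset characterisation: quality filtering
#' ([filter_spots()]), per-array median normalization
#' ([normalize_to_median()]), tensor assembly on the common gene universe
#' ([assemble_tensors()]) and the per-gene summaries (AVE, REV and, when
#' `gch = TRUE`, the GCH hierarchy) for every (region, phenotype) dataset.
#'
#' @param spots a spot table (see [validate_spot_table()]), a
#'   [simulate_experiment()] result, or a path to a spot TSV.
#' @param alpha significance level used for downstream calls and for the
#'   REV chi-square interval.
#' @param gch compute the O(N^2)-correlation GCH scores (default TRUE).
#' @param gch_variant GCH exponent parenthesization, see
#'   [gene_commanding_height()].
#' @param rev_center dataset REV norm for GCH, `"median"` or `"mean"`.
#' @param block_size correlation streaming block size.
#' @return object of class `gfp`: a list with `tensors` (named
#'   `region|phenotype`), `summaries` (per-dataset data frames), `n_genes`,
#'   `regions`, `phenotypes`, `n_replicas`, `counts` (closed-form
#'   bookkeeping, see [gfp_counts()]), `filter_report`, `alpha`,
#'   `gch_variant`.
#' @seealso [compare_phenotypes()], [coordination_network()],
#'   [cross_region_phase()], [pathway_regulation()]
#' @export
gfp <- function(spots, alpha = 0.05, gch = TRUE,
                gch_variant = c("offset", "scaled"),
                rev_center = c("median", "mean"), block_size = 512L) {
  gch_variant <- match.arg(gch_variant)
  rev_center <- match.arg(rev_center)
  if (inherits(spots, "gfp_sim")) spots <- spots$spots
  if (is.character(spots)) spots <- read_spot_table(spots)
  validate_spot_table(spots)
  fl <- filter_spots(spots)
  norm <- normalize_to_median(fl$spots)
  tensors <- assemble_tensors(norm)
  summaries <- lapply(tensors, gene_summary, alpha = alpha, gch = gch,
                      variant = gch_variant, rev_center = rev_center,
                      block_size = block_size)
  regions <- unique(vapply(tensors, `[[`, "", "region"))
  phenotypes <- unique(vapply(tensors, `[[`, "", "phenotype"))
  n_genes <- attr(tensors, "n_genes")
  counts <- gfp_counts(n_genes, length(regions), length(phenotypes),
                       tensors[[1]]$n_replicas)
  structure(list(tensors = tensors, summaries = summaries,
                 n_genes = n_genes, regions = regions,
                 phenotypes = phenotypes,
                 n_replicas = tensors[[1]]$n_replicas, counts = counts,
                 filter_report = list(
                   spots = fl$report,
                   dropped_nonpositive = attr(norm, "dropped_nonpositive"),
                   array_medians = attr(norm, "medians"),
                   dropped_genes = attr(tensors, "dropped_genes")),
                 alpha = alpha, gch_variant = gch_variant,
                 rev_center = rev_center, call = match.call()),
            class = "gfp")
}

#' @export
print.gfp <- function(x, ...) {
  cat("Genomic fabric fit\n")
  cat(sprintf("  %d genes (common universe) in %d dataset(s): %s x %s\n",
              x$n_genes, length(x$tensors),
              paste(x$regions, collapse = "/"),
              paste(x$phenotypes, collapse = "/")))
  cat(sprintf("  %d biological replicas; alpha = %g; GCH variant '%s'\n",
              x$n_replicas, x$alpha, x$gch_variant))
  fr <- x$filter_report$spots
  cat(sprintf("  spots: %d in, %d corrupted, %d low-signal, %d retained\n",
              fr$input, fr$corrupted, fr$low_signal, fr$retained))
  invisible(x)
}

#' Extract the per-gene fabric coefficients
#'
#' @param object a `gfp` fit.
#' @param ... unused.
#' @return data frame stacking the per-dataset gene summaries with
#'   `region` and `phenotype` columns.
#' @export
coef.gfp <- function(object, ...) {
  out <- do.call(rbind, lapply(names(object$summaries), function(k) {
    s <- object$summaries[[k]]
    t <- object$tensors[[k]]
    cbind(region = t$region, phenotype = t$phenotype, s,
          stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' @export
summary.gfp <- function(object, top_k = 10, ...) {
  has_gch <- "GCH" %in% names(object$summaries[[1]])
  tops <- lapply(object$summaries, function(s) {
    ord_ave <- s[order(-s$AVE, s$gene_id), c("gene_id", "AVE")]
    out <- list(top_ave = utils::head(ord_ave, top_k))
    if (has_gch) {
      ord_gch <- s[order(s$rank), c("gene_id", "GCH", "rank")]
      out$top_gch <- utils::head(ord_gch, top_k)
      out$GMR <- ord_gch$gene_id[1]
    }
    out
  })
  structure(list(fit = object, tops = tops, top_k = top_k,
                 has_gch = has_gch),
            class = "summary.gfp")
}

#' @export
print.summary.gfp <- function(x, ...) {
  print(x$fit)
  cts <- x$fit$counts
  cat(sprintf(paste0("  bookkeeping: %d samples; %s AVE; %s REV; %s ",
                     "within-dataset COR pairs; %s cross-region\n"),
              cts$n_samples, format(cts$n_ave, big.mark = ","),
              format(cts$n_rev, big.mark = ","),
              format(cts$n_cor_within, big.mark = ","),
              format(cts$n_cor_cross, big.mark = ",")))
  for (k in names(x$tops)) {
    cat("\nDataset ", k, ":\n", sep = "")
    if (x$has_gch) {
      cat("  GMR: ", x$tops[[k]]$GMR, "; top GCH:\n", sep = "")
      print(x$tops[[k]]$top_gch, digits = 3, row.names = FALSE)
    } else {
      cat("  top AVE:\n")
      print(x$tops[[k]]$top_ave, digits = 3, row.names = FALSE)
    }
  }
  invisible(x)
}

#' Plot the fabric characteristics
#'
#' One panel per (region, phenotype) dataset: REV (percent, log scale)
#' against AVE (multiples of the array median, log scale), the two
#' independent per-gene axes of the fabric characterisation.
#'
#' @param x a `gfp` fit.
#' @param ... passed to [graphics::plot()].
#' @export
plot.gfp <- function(x, ...) {
  nd <- length(x$tensors)
  nc <- ceiling(sqrt(nd))
  nr <- ceiling(nd / nc)
  op <- graphics::par(mfrow = c(nr, nc), mar = c(4, 4, 2, 1))
  on.exit(graphics::par(op))
  for (k in names(x$summaries)) {
    s <- x$summaries[[k]]
    graphics::plot(s$AVE, s$REV, log = "xy", pch = 16, cex = 0.4,
                   col = grDevices::grey(0.3, alpha = 0.6),
                   xlab = "AVE (multiples of array median)",
                   ylab = "REV (%)", main = gsub("\\|", " / ", k), ...)
  }
  invisible(x)
}
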