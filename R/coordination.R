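## Signed coordination networks within a dataset, concordance with declared
## stimulator/inhibitor expectations, and cross-region expression synchrony.

#' Signed coordination network over a gene set
#'
#' Classifies every within-set gene pair of one (region, phenotype) dataset
#' as synergistic (significantly positive COR), antagonistic (significantly
#' negative) or independent.
#'
#' @param tensor a `gfp_tensor`.
#' @param genes gene ids to include; genes absent from the tensor are
#'   skipped and reported.
#' @param alpha significance level for edge calls.
#' @return data frame `gene_i, gene_j, cor, n, p, class` with one row per
#'   unordered pair (gene_i < gene_j) and attribute `skipped`.
#' @export
coordination_network <- function(tensor, genes = NULL, alpha = 0.05) {
  if (is.null(genes)) genes <- tensor$genes
  skipped <- setdiff(genes, tensor$genes)
  genes <- sort(intersect(genes, tensor$genes))
  if (length(genes) < 2)
    stop("need at least two genes present in the tensor", call. = FALSE)
  m <- correlation_matrix(tensor, genes)
  idx <- which(upper.tri(m), arr.ind = TRUE)
  r <- m[idx]
  p <- cor_pvalue(r, tensor$n_replicas)
  out <- data.frame(gene_i = genes[idx[, 1]], gene_j = genes[idx[, 2]],
                    cor = r, n = tensor$n_replicas, p = p,
                    class = .classify_edge(r, p, alpha),
                    stringsAsFactors = FALSE)
  structure(out, skipped = skipped, alpha = alpha)
}

#' Read declared expected relations
#'
#' Tab-separated file with header `group, member_gene, target_gene,
#' expected_sign`; the sign is `+` (expected synergistic) or `-` (expected
#' antagonistic).  A local stand-in for, e.g., KEGG-derived activator and
#' inhibitor relations.
#'
#' @param path file path.
#' @return data frame of expectations.
#' @export
read_expected_relations <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  x <- utils::read.delim(path, header = TRUE, sep = "\t",
                         stringsAsFactors = FALSE)
  need <- c("group", "member_gene", "target_gene", "expected_sign")
  missing_cols <- setdiff(need, names(x))
  if (length(missing_cols))
    stop("expectations file missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  if (!all(x$expected_sign %in% c("+", "-")))
    stop("`expected_sign` must be '+' or '-'", call. = FALSE)
  x
}

#' Compare observed edges with expected relations
#'
#' For each declared relation, looks up the observed coordination class of
#' the (member, target) pair and flags whether it matches the expected sign
#' (`+` must be synergistic, `-` antagonistic; an independent or absent
#' pair is "not detected").
#'
#' @param edges a [coordination_network()] result.
#' @param expectations data frame from [read_expected_relations()].
#' @return the expectations with added `observed` and `match` columns, a
#'   `summary` attribute (counts of matched/total per expected sign) and an
#'   `unknown_genes` attribute listing relations whose genes are absent
#'   from the network.
#' @export
compare_expected_relations <- function(edges, expectations) {
  pair_key <- function(a, b)
    paste(pmin(a, b), pmax(a, b), sep = "\r")
  obs <- stats::setNames(edges$class, pair_key(edges$gene_i, edges$gene_j))
  k <- pair_key(expectations$member_gene, expectations$target_gene)
  observed <- unname(obs[k])
  observed[is.na(observed) & !k %in% names(obs)] <- "absent"
  match_flag <- ifelse(observed == "absent", NA,
                       (expectations$expected_sign == "+" &
                          observed == "synergistic") |
                       (expectations$expected_sign == "-" &
                          observed == "antagonistic"))
  out <- expectations
  out$observed <- observed
  out$match <- as.logical(match_flag)
  smry <- do.call(rbind, lapply(split(out, out$expected_sign), function(d)
    data.frame(expected_sign = d$expected_sign[1], n = nrow(d),
               matched = sum(d$match, na.rm = TRUE),
               not_detected = sum(!d$match, na.rm = TRUE),
               absent = sum(is.na(d$match)))))
  rownames(smry) <- NULL
  genes_in_net <- unique(c(edges$gene_i, edges$gene_j))
  unknown <- unique(c(out$member_gene[!out$member_gene %in% genes_in_net],
                      out$target_gene[!out$target_gene %in% genes_in_net]))
  structure(out, summary = smry, unknown_genes = unknown)
}

#' Cross-region expression synchrony
#'
#' Correlates, gene by gene, the per-animal expression profiles of two
#' regions within one phenotype (replicas are paired by animal: the same
#' replica index in both regions is the same animal) and classifies each
#' gene as in-phase (significantly positive), anti-phase (significantly
#' negative) or unsynchronized.
#'
#' @param object a fitted [gfp()] object covering both regions.
#' @param phenotype phenotype label.
#' @param genes gene ids to test; default all genes of the common universe.
#' @param regions the two region labels; defaults to the fit's regions.
#' @param alpha significance level for phase calls.
#' @return data frame `gene_id, cor, n, p, class` with attributes
#'   `percent_in_phase`, `percent_anti_phase`, `phenotype`, `regions`.
#' @export
cross_region_phase <- function(object, phenotype, genes = NULL,
                               regions = NULL, alpha = NULL) {
  stopifnot(inherits(object, "gfp"))
  if (is.null(alpha)) alpha <- object$alpha
  if (is.null(regions)) {
    regions <- unique(vapply(object$tensors, `[[`, "", "region"))
  }
  if (length(regions) != 2)
    stop("need exactly two regions (got ",
         paste(regions, collapse = ", "), ")", call. = FALSE)
  k1 <- paste(regions[1], phenotype, sep = "|")
  k2 <- paste(regions[2], phenotype, sep = "|")
  if (!k1 %in% names(object$tensors) || !k2 %in% names(object$tensors))
    stop("phenotype ", phenotype, " not present in both regions",
         call. = FALSE)
  t1 <- object$tensors[[k1]]
  t2 <- object$tensors[[k2]]
  if (!identical(t1$replicas, t2$replicas))
    stop("replica (animal) identifiers differ between regions: ",
         paste(setdiff(union(t1$replicas, t2$replicas),
                       intersect(t1$replicas, t2$replicas)),
               collapse = ", "), call. = FALSE)
  if (is.null(genes)) genes <- t1$genes
  .check_genes(t1, genes)
  x1 <- .std_profiles(t1$profiles[genes, , drop = FALSE])
  x2 <- .std_profiles(t2$profiles[genes, , drop = FALSE])
  r <- rowSums(x1 * x2)
  r[r > 1] <- 1; r[r < -1] <- -1
  p <- cor_pvalue(r, t1$n_replicas)
  cls <- .classify_edge(r, p, alpha,
                        labels = c("in_phase", "anti_phase",
                                   "unsynchronized"))
  out <- data.frame(gene_id = genes, cor = as.numeric(r),
                    n = t1$n_replicas, p = p, class = cls,
                    stringsAsFactors = FALSE)
  n_ok <- sum(!is.na(cls))
  structure(out,
            percent_in_phase = 100 * sum(cls == "in_phase", na.rm = TRUE) /
              n_ok,
            percent_anti_phase = 100 * sum(cls == "anti_phase",
                                           na.rm = TRUE) / n_ok,
            phenotype = phenotype, regions = regions, alpha = alpha)
}
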