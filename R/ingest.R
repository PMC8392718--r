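## Spot-level ingest: validation, quality filtering, per-array median
## normalization and assembly into per-(region, phenotype) expression tensors.

.SPOT_COLUMNS <- c("gene_id", "spot_id", "region", "phenotype", "replica",
                   "foreground", "background", "flag_corrupted")

#' Validate a spot-level expression table
#'
#' A spot table has one row per (gene, spot, region, phenotype, replica) with
#' raw foreground and background fluorescence and a corrupted-pixel flag.
#'
#' @param spots data frame with columns `gene_id`, `spot_id`, `region`,
#'   `phenotype`, `replica`, `foreground`, `background`, `flag_corrupted`.
#' @return `spots`, invisibly, after checks.
#' @export
validate_spot_table <- function(spots) {
  if (!is.data.frame(spots))
    stop("`spots` must be a data frame", call. = FALSE)
  missing_cols <- setdiff(.SPOT_COLUMNS, names(spots))
  if (length(missing_cols))
    stop("spot table is missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  if (nrow(spots)) {
    if (any(!is.finite(spots$foreground)) || any(spots$foreground < 0))
      stop("`foreground` must be finite and >= 0", call. = FALSE)
    if (any(!is.finite(spots$background)) || any(spots$background < 0))
      stop("`background` must be finite and >= 0", call. = FALSE)
    if (!all(spots$flag_corrupted %in% c(0L, 1L)))
      stop("`flag_corrupted` must be 0 or 1", call. = FALSE)
    key <- paste(spots$gene_id, spots$spot_id, spots$region,
                 spots$phenotype, spots$replica, sep = "\r")
    if (anyDuplicated(key))
      stop("duplicated (gene, spot, region, phenotype, replica) rows",
           call. = FALSE)
  }
  invisible(spots)
}

#' Read / write a spot table
#'
#' Tab-separated text with a header line; columns as in
#' [validate_spot_table()].
#'
#' @param path file path.
#' @return `read_spot_table()`: the validated data frame.
#' @export
read_spot_table <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  spots <- utils::read.delim(path, header = TRUE, sep = "\t",
                             colClasses = c(gene_id = "character",
                                            spot_id = "character",
                                            region = "character",
                                            phenotype = "character"),
                             stringsAsFactors = FALSE)
  validate_spot_table(spots)
  spots
}

#' @rdname read_spot_table
#' @param spots spot table.
#' @export
write_spot_table <- function(spots, path) {
  validate_spot_table(spots)
  utils::write.table(spots[.SPOT_COLUMNS], path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Remove corrupted and low-signal spots
#'
#' Discards spots flagged as corrupted and spots whose foreground
#' fluorescence is less than twice the background (the boundary
#' foreground = 2 x background is retained).  Corrupted spots are counted
#' under the corrupted rule even when they are also low-signal.
#'
#' @param spots spot table.
#' @return list with `spots` (retained rows) and `report`, a list with
#'   counts `input`, `corrupted`, `low_signal`, `retained`.
#' @export
filter_spots <- function(spots) {
  validate_spot_table(spots)
  corrupted <- spots$flag_corrupted == 1L
  low <- !corrupted & spots$foreground < 2 * spots$background
  keep <- !corrupted & !low
  list(spots = spots[keep, , drop = FALSE],
       report = list(input = nrow(spots),
                     corrupted = sum(corrupted),
                     low_signal = sum(low),
                     retained = sum(keep)))
}

#' Background-subtract and normalize each array to its median
#'
#' Computes `foreground - background` per spot and divides, within each array
#' (one (region, phenotype, replica) hybridization), by the median of that
#' array's positive background-subtracted signals, so every array has output
#' median 1.  Non-positive background-subtracted signals are dropped.
#'
#' @param spots filtered spot table.
#' @return the spot table with an added `signal` column; attributes
#'   `medians` (data frame of per-array medians) and `dropped_nonpositive`
#'   (row count).
#' @export
normalize_to_median <- function(spots) {
  validate_spot_table(spots)
  raw <- spots$foreground - spots$background
  array_id <- interaction(spots$region, spots$phenotype, spots$replica,
                          drop = TRUE, lex.order = TRUE, sep = "\r")
  has_pos <- tapply(raw > 0, array_id, any)
  if (!all(has_pos)) {
    bad <- names(has_pos)[!has_pos]
    stop("array(s) with no positive signal: ",
         paste(gsub("\r", "/", bad), collapse = ", "), call. = FALSE)
  }
  pos <- raw > 0
  dropped <- sum(!pos)
  spots <- spots[pos, , drop = FALSE]
  raw <- raw[pos]
  array_id <- array_id[pos]
  med <- tapply(raw, array_id, stats::median)
  spots$signal <- raw / as.numeric(med[array_id])
  parts <- do.call(rbind, strsplit(names(med), "\r", fixed = TRUE))
  attr(spots, "medians") <- data.frame(region = parts[, 1],
                                       phenotype = parts[, 2],
                                       replica = parts[, 3],
                                       median = as.numeric(med),
                                       row.names = NULL)
  attr(spots, "dropped_nonpositive") <- dropped
  spots
}

## Build one gfp_tensor from vectors of aligned spot rows.
new_tensor <- function(region, phenotype, a, gene, spot, replicas) {
  ord <- order(gene, spot)
  a <- a[ord, , drop = FALSE]
  gene <- gene[ord]
  spot <- spot[ord]
  n <- ncol(a)
  gf <- factor(gene, levels = unique(gene))
  R <- as.integer(table(gf))
  names(R) <- levels(gf)
  mu <- rowMeans(a)
  s <- sqrt(rowSums((a - mu)^2) / (n - 1))
  profiles <- rowsum(a, gf, reorder = FALSE) / R
  colnames(profiles) <- replicas
  structure(list(region = region, phenotype = phenotype,
                 a = a, gene_id = gene, spot_id = spot,
                 replicas = replicas, n_replicas = n,
                 genes = levels(gf), R = R, mu = mu, s = s,
                 profiles = profiles),
            class = "gfp_tensor")
}

#' Assemble normalized spots into per-(region, phenotype) tensors
#'
#' For each (region, phenotype) dataset, keeps the (gene, spot) series that
#' have a value in every replica (spot sets inconsistent across replicas are
#' intersected down), computes the per-spot replicate means and the per-gene
#' spot redundancy, then restricts all datasets to the common gene universe
#' so a single gene count N applies to the whole experiment.
#'
#' @param spots normalized spot table (from [normalize_to_median()]).
#' @return named list of `gfp_tensor` objects, keyed `region|phenotype`,
#'   with attributes `n_genes` (common N) and `dropped_genes` (per-dataset
#'   genes lost to incomplete replica coverage plus those cut by the common
#'   universe rule).
#' @export
assemble_tensors <- function(spots) {
  if (!"signal" %in% names(spots))
    stop("`spots` must be normalized first (missing `signal` column)",
         call. = FALSE)
  ds <- unique(spots[c("region", "phenotype")])
  ds <- ds[order(ds$region, ds$phenotype), , drop = FALSE]
  tensors <- list()
  dropped <- list()
  for (d in seq_len(nrow(ds))) {
    B <- ds$region[d]; P <- ds$phenotype[d]
    sub <- spots[spots$region == B & spots$phenotype == P, , drop = FALSE]
    reps <- sort(unique(sub$replica))
    key <- paste(sub$gene_id, sub$spot_id, sep = "\r")
    ukey <- unique(key)
    ri <- match(key, ukey)
    ci <- match(sub$replica, reps)
    a <- matrix(NA_real_, length(ukey), length(reps))
    a[cbind(ri, ci)] <- sub$signal
    first <- match(ukey, key)
    row_gene <- sub$gene_id[first]
    row_spot <- sub$spot_id[first]
    complete <- rowSums(is.na(a)) == 0
    lost <- setdiff(unique(row_gene), unique(row_gene[complete]))
    dropped[[paste(B, P, sep = "|")]] <- lost
    tensors[[paste(B, P, sep = "|")]] <-
      list(region = B, phenotype = P, a = a[complete, , drop = FALSE],
           gene = row_gene[complete], spot = row_spot[complete],
           replicas = reps)
  }
  universe <- Reduce(intersect, lapply(tensors, function(t) unique(t$gene)))
  universe <- sort(universe)
  out <- lapply(tensors, function(t) {
    keep <- t$gene %in% universe
    new_tensor(t$region, t$phenotype, t$a[keep, , drop = FALSE],
               t$gene[keep], t$spot[keep], t$replicas)
  })
  structure(out, n_genes = length(universe), dropped_genes = dropped)
}

#' Build an expression tensor from normalized values
#'
#' Constructs the per-(region, phenotype) container used by all fabric
#' statistics directly from already-normalized expression values, bypassing
#' spot-level ingest.  Useful for data normalized elsewhere and for
#' simulation studies of the estimators themselves.
#'
#' @param x either a numeric matrix with one row per gene (single-spot
#'   genes) and one column per biological replica, with gene ids as
#'   rownames, or a named list of spot-by-replica matrices (one per gene).
#' @param region,phenotype dataset labels.
#' @param replicas replica (animal) identifiers; default `1:n`.
#' @return a `gfp_tensor`.
#' @export
expression_tensor <- function(x, region = "r1", phenotype = "p1",
                              replicas = NULL) {
  if (is.matrix(x)) {
    if (is.null(rownames(x)))
      stop("matrix input needs gene ids as rownames", call. = FALSE)
    genes <- rownames(x)
    spots <- rep("s1", nrow(x))
    a <- unname(x)
  } else if (is.list(x)) {
    if (is.null(names(x)))
      stop("list input must be named by gene", call. = FALSE)
    nr <- vapply(x, NROW, 0L)
    genes <- rep(names(x), nr)
    spots <- unlist(lapply(nr, function(k) paste0("s", seq_len(k))),
                    use.names = FALSE)
    a <- do.call(rbind, lapply(x, function(m) unname(as.matrix(m))))
  } else {
    stop("`x` must be a matrix or a named list of matrices", call. = FALSE)
  }
  if (any(!is.finite(a)) || any(a <= 0))
    stop("expression values must be finite and positive", call. = FALSE)
  if (is.null(replicas)) replicas <- seq_len(ncol(a))
  if (length(replicas) != ncol(a))
    stop("`replicas` must match the number of columns", call. = FALSE)
  new_tensor(region, phenotype, a, genes, spots, replicas)
}

#' @export
print.gfp_tensor <- function(x, ...) {
  cat(sprintf("<gfp_tensor> %s / %s: %d genes, %d spot series, %d replicas\n",
              x$region, x$phenotype, length(x$genes), nrow(x$a), x$n_replicas))
  invisible(x)
}
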