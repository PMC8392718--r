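## Seeded spot-level microarray simulator.  Emulates a replicated two-region,
## multi-phenotype design with redundant spots per gene, lognormal
## abundances, gene-specific replicate CV, co-regulation blocks, per-animal
## latent factors shared across regions, and corrupted / low-signal spots.

#' Configuration for a synthetic spot-level experiment
#'
#' Defaults describe a 2-region x 3-phenotype x 4-replica design with two
#' redundant spots per gene, lognormal abundances spanning roughly three
#' decades, and per-gene biological coefficients of variation drawn
#' uniformly from `cv_range`.
#'
#' @param n_genes number of genes.
#' @param regions,phenotypes character labels (no tabs/newlines).
#' @param n_replicas biological replicas per dataset (>= 2); the replica
#'   index identifies the same animal across regions.
#' @param spots_per_gene scalar or named per-gene integer vector of
#'   redundant spots.
#' @param baseline_log_mean,baseline_log_sd lognormal abundance parameters
#'   (natural log).
#' @param cv_range interval for the per-gene biological CV.
#' @param cv_overrides,baseline_overrides optional named numeric vectors
#'   pinning the CV / baseline abundance of specific genes.
#' @param regulated_genes optional data frame `gene_id, phenotype, fold`
#'   (fold > 0): the gene's mean abundance is multiplied by `fold` in that
#'   phenotype (both regions), so the true expression ratio between two
#'   phenotypes is the ratio of their folds.
#' @param coregulation_blocks list of `list(genes =, loading =)`; genes of
#'   a block share a latent factor per (region, phenotype, replica) with
#'   amplitude weight `loading` in `[0, 1]` (see Details).
#' @param cross_region_shared list of `list(genes =, loading =)`; genes
#'   driven by a per-animal latent factor shared by both regions within
#'   each phenotype.
#' @param frac_corrupted_spots,frac_low_signal_spots proportions in
#'   `[0, 1]` of spots flagged corrupted / given foreground below twice the
#'   background.
#' @param spot_noise_sd log-scale sd of the spot-within-replicate noise
#'   (smaller than the biological term).
#' @param background_level mean background fluorescence (arbitrary units).
#' @param gain fluorescence units per expression unit.
#' @param gene_ids optional explicit gene identifiers.
#' @param seed integer RNG seed; identical configs give identical tables.
#'
#' @details A latent factor with loading `l` replaces a gene's standard
#' normal log-deviate `e` by `(l L + (1 - l) e) / sqrt(l^2 + (1 - l)^2)`,
#' an amplitude mixture that keeps the log-variance (hence the CV) at its
#' configured value; two genes sharing `L` at loading `l` have population
#' correlation `l^2 / (l^2 + (1 - l)^2)`.
#'
#' @return object of class `gfp_sim_config`.
#' @export
sim_config <- function(n_genes = 100,
                       regions = c("cortex", "hippocampus"),
                       phenotypes = c("MRL_lpr", "Fn14ko", "MRL_plus"),
                       n_replicas = 4,
                       spots_per_gene = 2,
                       baseline_log_mean = 4,
                       baseline_log_sd = 1.5,
                       cv_range = c(0.05, 0.5),
                       cv_overrides = NULL,
                       baseline_overrides = NULL,
                       regulated_genes = NULL,
                       coregulation_blocks = list(),
                       cross_region_shared = list(),
                       frac_corrupted_spots = 0.01,
                       frac_low_signal_spots = 0.02,
                       spot_noise_sd = 0.05,
                       background_level = 1,
                       gain = 100,
                       gene_ids = NULL,
                       seed = 1L) {
  fail <- function(field, why)
    stop("invalid `", field, "`: ", why, call. = FALSE)
  if (!is.numeric(n_genes) || length(n_genes) != 1 || n_genes < 1)
    fail("n_genes", "must be a positive count")
  n_genes <- as.integer(n_genes)
  if (is.null(gene_ids))
    gene_ids <- sprintf("g%0*d", nchar(n_genes), seq_len(n_genes))
  if (length(gene_ids) != n_genes || anyDuplicated(gene_ids))
    fail("gene_ids", "must be n_genes unique identifiers")
  for (f in c("regions", "phenotypes")) {
    v <- get(f)
    if (!is.character(v) || !length(v) || anyDuplicated(v) ||
        any(grepl("[\t\r\n]", v)))
      fail(f, "must be unique labels without tabs/newlines")
  }
  if (!is.numeric(n_replicas) || length(n_replicas) != 1 || n_replicas < 2)
    fail("n_replicas", "must be >= 2")
  n_replicas <- as.integer(n_replicas)
  if (is.null(names(spots_per_gene))) {
    if (length(spots_per_gene) != 1 || spots_per_gene < 1)
      fail("spots_per_gene", "must be a positive count or named vector")
    spots_per_gene <- stats::setNames(rep(as.integer(spots_per_gene),
                                          n_genes), gene_ids)
  } else {
    if (!all(names(spots_per_gene) %in% gene_ids))
      fail("spots_per_gene", "names must be known gene ids")
    full <- stats::setNames(rep(2L, n_genes), gene_ids)
    full[names(spots_per_gene)] <- as.integer(spots_per_gene)
    if (any(full < 1)) fail("spots_per_gene", "counts must be >= 1")
    spots_per_gene <- full
  }
  if (!is.numeric(cv_range) || length(cv_range) != 2 ||
      any(cv_range <= 0) || cv_range[1] > cv_range[2])
    fail("cv_range", "must be an increasing positive interval")
  check_named <- function(v, field, positive = TRUE) {
    if (is.null(v)) return(invisible())
    if (is.null(names(v)) || !all(names(v) %in% gene_ids))
      fail(field, "must be named by known gene ids")
    if (positive && any(v <= 0)) fail(field, "values must be > 0")
  }
  check_named(cv_overrides, "cv_overrides")
  check_named(baseline_overrides, "baseline_overrides")
  if (!is.null(regulated_genes)) {
    need <- c("gene_id", "phenotype", "fold")
    if (!is.data.frame(regulated_genes) ||
        !all(need %in% names(regulated_genes)))
      fail("regulated_genes", "needs columns gene_id, phenotype, fold")
    if (!all(regulated_genes$gene_id %in% gene_ids))
      fail("regulated_genes", "unknown gene id(s)")
    if (!all(regulated_genes$phenotype %in% phenotypes))
      fail("regulated_genes", "unknown phenotype(s)")
    if (any(regulated_genes$fold <= 0))
      fail("regulated_genes", "true fold-changes must be > 0")
  }
  check_blocks <- function(blocks, field) {
    for (b in blocks) {
      if (!is.list(b) || is.null(b$genes) || is.null(b$loading))
        fail(field, "each block needs `genes` and `loading`")
      if (!all(b$genes %in% gene_ids)) fail(field, "unknown gene id(s)")
      if (b$loading < 0 || b$loading > 1)
        fail(field, "loading must be in [0, 1]")
    }
  }
  check_blocks(coregulation_blocks, "coregulation_blocks")
  check_blocks(cross_region_shared, "cross_region_shared")
  for (f in c("frac_corrupted_spots", "frac_low_signal_spots")) {
    v <- get(f)
    if (!is.numeric(v) || length(v) != 1 || v < 0 || v > 1)
      fail(f, "must be a proportion in [0, 1]")
  }
  if (!is.numeric(spot_noise_sd) || spot_noise_sd < 0)
    fail("spot_noise_sd", "must be >= 0")
  if (!is.numeric(seed) || length(seed) != 1 || !is.finite(seed))
    fail("seed", "must be a single integer")
  structure(list(n_genes = n_genes, gene_ids = gene_ids, regions = regions,
                 phenotypes = phenotypes, n_replicas = n_replicas,
                 spots_per_gene = spots_per_gene,
                 baseline_log_mean = baseline_log_mean,
                 baseline_log_sd = baseline_log_sd, cv_range = cv_range,
                 cv_overrides = cv_overrides,
                 baseline_overrides = baseline_overrides,
                 regulated_genes = regulated_genes,
                 coregulation_blocks = coregulation_blocks,
                 cross_region_shared = cross_region_shared,
                 frac_corrupted_spots = frac_corrupted_spots,
                 frac_low_signal_spots = frac_low_signal_spots,
                 spot_noise_sd = spot_noise_sd,
                 background_level = background_level, gain = gain,
                 seed = as.integer(seed)),
            class = "gfp_sim_config")
}

#' @export
print.gfp_sim_config <- function(x, ...) {
  cat(sprintf(paste0("<gfp_sim_config> %d genes, %d region(s) x %d ",
                     "phenotype(s) x %d replicas, seed %d\n"),
              x$n_genes, length(x$regions), length(x$phenotypes),
              x$n_replicas, x$seed))
  invisible(x)
}

## amplitude-weighted latent mixing, unit-variance preserving
.mix_latent <- function(z, latent, loading) {
  if (loading == 0) return(z)
  (loading * latent + (1 - loading) * z) /
    sqrt(loading^2 + (1 - loading)^2)
}

#' Simulate a spot-level experiment
#'
#' Draws one hybridization array per (region, phenotype, replica).  Gene
#' baselines are lognormal; per-replica biological noise is multiplicative
#' lognormal with gene-specific CV (optionally structured by latent
#' factors); spot-within-replicate noise is a smaller multiplicative term.
#' Spots carry foreground and background fluorescence; a configured
#' fraction is flagged corrupted, another is forced below the
#' foreground >= 2 x background detection rule.
#'
#' @param config a [sim_config()].
#' @return list of class `gfp_sim` with elements `spots` (spot table, one
#'   row per spot and array) and `truth` (ground truth: per-gene CV and
#'   baseline, fold matrix, block structure, per-animal latent values, and
#'   per-spot validity labels aligned with `spots`).
#' @export
simulate_experiment <- function(config) {
  if (!inherits(config, "gfp_sim_config"))
    stop("`config` must be a gfp_sim_config", call. = FALSE)
  set.seed(config$seed)
  genes <- config$gene_ids
  nG <- config$n_genes
  nrep <- config$n_replicas
  combos <- expand.grid(replica = seq_len(nrep),
                        phenotype = config$phenotypes,
                        region = config$regions,
                        stringsAsFactors = FALSE,
                        KEEP.OUT.ATTRS = FALSE)
  nC <- nrow(combos)

  m <- stats::rlnorm(nG, config$baseline_log_mean, config$baseline_log_sd)
  names(m) <- genes
  cv <- stats::runif(nG, config$cv_range[1], config$cv_range[2])
  names(cv) <- genes
  if (!is.null(config$cv_overrides))
    cv[names(config$cv_overrides)] <- config$cv_overrides
  if (!is.null(config$baseline_overrides))
    m[names(config$baseline_overrides)] <- config$baseline_overrides
  sigma <- sqrt(log(1 + cv^2))

  z <- matrix(stats::rnorm(nG * nC), nG, nC)
  for (b in config$coregulation_blocks) {
    latent <- stats::rnorm(nC)  # one draw per dataset-replica
    idx <- match(b$genes, genes)
    z[idx, ] <- .mix_latent(z[idx, , drop = FALSE],
                            matrix(latent, length(idx), nC, byrow = TRUE),
                            b$loading)
  }
  animal_latents <- list()
  if (length(config$cross_region_shared)) {
    pidx <- match(combos$phenotype, config$phenotypes)
    for (si in seq_along(config$cross_region_shared)) {
      b <- config$cross_region_shared[[si]]
      lat <- matrix(stats::rnorm(nrep * length(config$phenotypes)),
                    nrep, length(config$phenotypes),
                    dimnames = list(NULL, config$phenotypes))
      per_combo <- lat[cbind(combos$replica, pidx)]  # same in both regions
      idx <- match(b$genes, genes)
      z[idx, ] <- .mix_latent(z[idx, , drop = FALSE],
                              matrix(per_combo, length(idx), nC,
                                     byrow = TRUE),
                              b$loading)
      animal_latents[[si]] <- lat
    }
  }

  fold <- matrix(1, nG, length(config$phenotypes),
                 dimnames = list(genes, config$phenotypes))
  if (!is.null(config$regulated_genes))
    fold[cbind(match(config$regulated_genes$gene_id, genes),
               match(config$regulated_genes$phenotype,
                     config$phenotypes))] <- config$regulated_genes$fold

  expr <- m * fold[, match(combos$phenotype, config$phenotypes),
                   drop = FALSE] *
    exp(sigma * z - sigma^2 / 2)

  rg <- config$spots_per_gene[genes]
  row_gene <- rep(seq_len(nG), times = rg)
  spot_ids <- paste0("s", sequence(rg))
  nSp <- length(row_gene)
  tau <- config$spot_noise_sd
  a <- expr[row_gene, , drop = FALSE] *
    exp(tau * matrix(stats::rnorm(nSp * nC), nSp, nC) - tau^2 / 2)
  bg <- matrix(stats::runif(nSp * nC, 0.8, 1.2), nSp, nC) *
    config$background_level
  fg <- bg + config$gain * a
  corrupted <- matrix(stats::runif(nSp * nC) < config$frac_corrupted_spots,
                      nSp, nC)
  low <- matrix(stats::runif(nSp * nC) < config$frac_low_signal_spots,
                nSp, nC)
  fg[low] <- bg[low] * stats::runif(sum(low), 1.0, 1.99)

  spots <- data.frame(
    gene_id = rep(genes[row_gene], nC),
    spot_id = rep(spot_ids, nC),
    region = rep(combos$region, each = nSp),
    phenotype = rep(combos$phenotype, each = nSp),
    replica = rep(combos$replica, each = nSp),
    foreground = as.vector(fg),
    background = as.vector(bg),
    flag_corrupted = as.integer(as.vector(corrupted)),
    stringsAsFactors = FALSE)

  labels <- rep("valid", nSp * nC)
  labels[as.vector(low)] <- "low_signal"
  labels[as.vector(corrupted)] <- "corrupted"

  truth <- list(genes = genes,
                cv = cv,
                baseline = m,
                fold = data.frame(gene_id = genes, fold,
                                  check.names = FALSE,
                                  stringsAsFactors = FALSE),
                coregulation_blocks = config$coregulation_blocks,
                cross_region_shared = config$cross_region_shared,
                animal_latents = animal_latents,
                spot_labels = labels)
  structure(list(spots = spots, truth = truth, config = config),
            class = "gfp_sim")
}

#' @export
print.gfp_sim <- function(x, ...) {
  cat(sprintf("<gfp_sim> %d spot rows over %d arrays (%d genes)\n",
              nrow(x$spots),
              length(x$config$regions) * length(x$config$phenotypes) *
                x$config$n_replicas,
              x$config$n_genes))
  invisible(x)
}

#' Write / read a simulated experiment fixture
#'
#' Writes the spot table as TSV, the ground truth as JSON and the
#' configuration as YAML; the spot TSV round-trips losslessly through
#' [read_spot_table()].
#'
#' @param sim a [simulate_experiment()] result.
#' @param dir output directory (created if needed).
#' @return named character vector of the written paths, invisibly.
#' @export
write_fixture <- function(sim, dir) {
  stopifnot(inherits(sim, "gfp_sim"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(spots = file.path(dir, "spots.tsv"),
             truth = file.path(dir, "truth.json"),
             config = file.path(dir, "config.yaml"))
  write_spot_table(sim$spots, paths[["spots"]])
  jsonlite::write_json(sim$truth, paths[["truth"]], auto_unbox = TRUE,
                       digits = NA, null = "null")
  cfg <- unclass(sim$config)
  cfg$spots_per_gene <- as.list(cfg$spots_per_gene)
  yaml::write_yaml(cfg, paths[["config"]])
  invisible(paths)
}

#' @rdname write_fixture
#' @param path path to a `truth.json` file.
#' @export
read_ground_truth <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  jsonlite::fromJSON(path, simplifyVector = TRUE)
}
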