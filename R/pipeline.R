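## End-to-end orchestration: simulate/read -> fit -> regulation -> pathways
## -> coordination -> reports, plus the closed-form dataset bookkeeping.

#' Closed-form dataset bookkeeping
#'
#' Counts, without enumeration, the workable quantities a fabric analysis
#' extracts from an experiment: per-dataset AVE and REV values, distinct
#' within-dataset gene-pair correlations, and between-region correlations
#' of the same gene (one per gene, phenotype and region pair).  The
#' amplification ratio is the total divided by the AVE count, i.e. how many
#' times the workable data exceed an expression-level-only analysis.
#'
#' @param n_genes common-universe gene count N.
#' @param n_regions,n_phenotypes,n_replicas design dimensions.
#' @return list of class `gfp_counts`: `n_samples`, `n_datasets`, `n_ave`,
#'   `n_rev`, `n_cor_within`, `n_cor_cross`, `n_workable`,
#'   `amplification`.
#' @export
gfp_counts <- function(n_genes, n_regions = 2, n_phenotypes = 3,
                       n_replicas = 4) {
  n_datasets <- n_regions * n_phenotypes
  n_ave <- n_genes * n_datasets
  n_cor_within <- n_datasets * n_genes * (n_genes - 1) / 2
  n_cor_cross <- n_genes * n_phenotypes * choose(n_regions, 2)
  n_workable <- 2 * n_ave + n_cor_within + n_cor_cross
  structure(list(n_samples = n_datasets * n_replicas,
                 n_datasets = n_datasets,
                 n_ave = n_ave, n_rev = n_ave,
                 n_cor_within = n_cor_within,
                 n_cor_cross = n_cor_cross,
                 n_workable = n_workable,
                 amplification = n_workable / n_ave),
            class = "gfp_counts")
}

#' @export
print.gfp_counts <- function(x, ...) {
  fmt <- function(v) format(v, big.mark = ",", scientific = FALSE)
  cat("Dataset bookkeeping\n",
      "  samples:                 ", fmt(x$n_samples), "\n",
      "  AVE / REV values:        ", fmt(x$n_ave), " each\n",
      "  within-dataset COR pairs:", fmt(x$n_cor_within), "\n",
      "  between-region CORs:     ", fmt(x$n_cor_cross), "\n",
      "  amplification ratio:     ", format(x$amplification, digits = 5),
      "\n", sep = "")
  invisible(x)
}

.safe_label <- function(x) gsub("[^A-Za-z0-9._-]", "_", x)

#' Write tabular reports for a fitted experiment
#'
#' Emits, under `outdir`: per-dataset gene summaries; per-region top-AVE
#' tables (the most expressed genes of the leading phenotype, with their
#' values in every phenotype); per-region GCH hierarchy tables (top genes
#' of each phenotype side by side); the regulation tables ordered by
#' decreasing `|WIR|`; pathway summaries; and cross-region phase tables
#' with a JSON percentage summary.
#'
#' @param fit a [gfp()] object.
#' @param regulations list of [compare_phenotypes()] results.
#' @param pathway_tables list of [pathway_regulation()] results, named like
#'   the regulation entries.
#' @param phases list of [cross_region_phase()] results.
#' @param outdir output directory (created if needed).
#' @param top_k rows in the top-gene tables.
#' @return character vector of written files, invisibly.
#' @export
write_reports <- function(fit, regulations = list(), pathway_tables = list(),
                          phases = list(), outdir, top_k = 20) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  files <- character()
  emit <- function(df, name) {
    path <- file.path(outdir, name)
    utils::write.table(df, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    files <<- c(files, path)
  }
  for (k in names(fit$summaries)) {
    t <- fit$tensors[[k]]
    emit(fit$summaries[[k]],
         sprintf("gene_summary_%s_%s.tsv", .safe_label(t$region),
                 .safe_label(t$phenotype)))
  }
  has_gch <- "GCH" %in% names(fit$summaries[[1]])
  for (B in fit$regions) {
    keys <- paste(B, fit$phenotypes, sep = "|")
    keys <- keys[keys %in% names(fit$summaries)]
    lead <- fit$summaries[[keys[1]]]
    top <- utils::head(lead$gene_id[order(-lead$AVE, lead$gene_id)], top_k)
    ave_tab <- data.frame(gene_id = top, stringsAsFactors = FALSE)
    for (k in keys) {
      s <- fit$summaries[[k]]
      ave_tab[[fit$tensors[[k]]$phenotype]] <-
        s$AVE[match(top, s$gene_id)]
    }
    emit(ave_tab, sprintf("top_ave_%s.tsv", .safe_label(B)))
    if (has_gch) {
      picks <- unique(unlist(lapply(keys, function(k) {
        s <- fit$summaries[[k]]
        utils::head(s$gene_id[order(s$rank)], top_k)
      })))
      gch_tab <- data.frame(gene_id = picks, stringsAsFactors = FALSE)
      for (k in keys) {
        s <- fit$summaries[[k]]
        gch_tab[[fit$tensors[[k]]$phenotype]] <-
          s$GCH[match(picks, s$gene_id)]
      }
      emit(gch_tab, sprintf("hierarchy_%s.tsv", .safe_label(B)))
    }
  }
  for (nm in names(regulations)) {
    r <- regulations[[nm]]
    emit(as.data.frame(r), sprintf("regulation_%s.tsv", .safe_label(nm)))
  }
  for (nm in names(pathway_tables))
    emit(pathway_tables[[nm]], sprintf("pathways_%s.tsv", .safe_label(nm)))
  if (length(phases)) {
    pct <- list()
    for (nm in names(phases)) {
      ph <- phases[[nm]]
      emit(as.data.frame(ph), sprintf("phase_%s.tsv", .safe_label(nm)))
      pct[[nm]] <- list(percent_in_phase = attr(ph, "percent_in_phase"),
                        percent_anti_phase = attr(ph, "percent_anti_phase"))
    }
    path <- file.path(outdir, "phase_summary.json")
    jsonlite::write_json(pct, path, auto_unbox = TRUE, digits = NA)
    files <- c(files, path)
  }
  invisible(files)
}

#' Run the full analysis pipeline
#'
#' Generates (or reads) a spot-level experiment, fits the fabric
#' characteristics, calls regulation for each requested phenotype
#' comparison in every region, scores pathways, checks declared expected
#' relations against the coordination network, classifies cross-region
#' synchrony when two regions are present, and writes all reports plus a
#' JSON run manifest.  Deterministic given the seed.
#'
#' @param config a [sim_config()] or a path to a spot TSV fixture.
#' @param comparisons list of `c(test, ref)` phenotype pairs; default: the
#'   first phenotype against each other one.
#' @param pathways named list of gene-id vectors or a GMT file path.
#' @param expectations expected-relations data frame or TSV path (see
#'   [read_expected_relations()]).
#' @param outdir output directory.
#' @param alpha significance level.
#' @param gch_variant,wpr_variant formula-variant switches, stamped into
#'   the manifest.
#' @param seed overrides the config seed when given.
#' @param top_k rows in top-gene report tables.
#' @param gch compute GCH scores (TRUE by default).
#' @return invisibly, a list with `fit`, `regulations`, `pathways`,
#'   `relations`, `phases`, `files`, `manifest`.
#' @export
run_pipeline <- function(config, comparisons = NULL, pathways = NULL,
                         expectations = NULL, outdir, alpha = 0.05,
                         gch_variant = c("offset", "scaled"),
                         wpr_variant = c("mean_abs", "rms"), seed = NULL,
                         top_k = 20, gch = TRUE) {
  gch_variant <- match.arg(gch_variant)
  wpr_variant <- match.arg(wpr_variant)
  from_fixture <- is.character(config)
  if (from_fixture) {
    spots <- read_spot_table(config)
    phen <- sort(unique(spots$phenotype))
  } else {
    if (!inherits(config, "gfp_sim_config"))
      stop("`config` must be a gfp_sim_config or a spot TSV path",
           call. = FALSE)
    if (!is.null(seed)) config$seed <- as.integer(seed)
    phen <- config$phenotypes
  }
  if (is.null(comparisons) && length(phen) > 1)
    comparisons <- lapply(phen[-1], function(p) c(phen[1], p))
  for (cmp in comparisons)
    if (length(cmp) != 2 || !all(cmp %in% phen))
      stop("comparison references unknown phenotype: ",
           paste(cmp, collapse = " vs "), call. = FALSE)
  if (is.character(pathways)) pathways <- read_gmt(pathways)
  if (is.character(expectations))
    expectations <- read_expected_relations(expectations)

  if (!from_fixture) spots <- simulate_experiment(config)$spots
  fit <- gfp(spots, alpha = alpha, gch = gch, gch_variant = gch_variant)

  regulations <- list()
  pathway_tables <- list()
  for (B in fit$regions) {
    for (cmp in comparisons) {
      nm <- paste(B, paste(cmp, collapse = "_vs_"), sep = "_")
      reg <- compare_phenotypes(fit, cmp[1], cmp[2], region = B)
      regulations[[nm]] <- reg
      if (!is.null(pathways))
        pathway_tables[[nm]] <- pathway_regulation(reg, pathways,
                                                   variant = wpr_variant)
    }
  }

  relations <- list()
  if (!is.null(expectations)) {
    rel_genes <- unique(c(expectations$member_gene,
                          expectations$target_gene))
    for (k in names(fit$tensors)) {
      present <- intersect(rel_genes, fit$tensors[[k]]$genes)
      if (length(present) >= 2) {
        net <- coordination_network(fit$tensors[[k]], rel_genes,
                                    alpha = alpha)
        relations[[k]] <- compare_expected_relations(net, expectations)
      }
    }
  }

  phases <- list()
  if (length(fit$regions) == 2)
    for (P in fit$phenotypes)
      phases[[P]] <- cross_region_phase(fit, P, alpha = alpha)

  files <- write_reports(fit, regulations, pathway_tables, phases,
                         outdir = outdir, top_k = top_k)
  cfg_path <- file.path(outdir, "run_config.yaml")
  if (from_fixture) {
    yaml::write_yaml(list(fixture = normalizePath(config)), cfg_path)
  } else {
    cfg <- unclass(config)
    cfg$spots_per_gene <- as.list(cfg$spots_per_gene)
    yaml::write_yaml(cfg, cfg_path)
  }
  manifest <- list(
    package = "gfabric",
    version = as.character(utils::packageVersion("gfabric")),
    config_hash = unname(tools::md5sum(cfg_path)),
    input = if (from_fixture) "fixture" else "synthetic",
    seed = if (from_fixture) NULL else config$seed,
    alpha = alpha, gch_variant = gch_variant, wpr_variant = wpr_variant,
    comparisons = lapply(comparisons, function(cmp)
      list(test = cmp[1], ref = cmp[2])),
    n_arrays = length(unique(paste(spots$region, spots$phenotype,
                                   spots$replica))),
    n_tensors = length(fit$tensors),
    n_genes = fit$n_genes,
    counts = unclass(fit$counts),
    filter = fit$filter_report$spots,
    dropped_nonpositive = fit$filter_report$dropped_nonpositive,
    files = basename(c(files, cfg_path)))
  manifest_path <- file.path(outdir, "manifest.json")
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE,
                       digits = NA, null = "null")
  invisible(list(fit = fit, regulations = regulations,
                 pathways = pathway_tables, relations = relations,
                 phases = phases,
                 files = c(files, cfg_path, manifest_path),
                 manifest = manifest))
}
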