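test_that("generated experiment has the configured dimensions", {
  cfg <- sim_config(n_genes = 100, n_replicas = 4, spots_per_gene = 2,
                    frac_corrupted_spots = 0, frac_low_signal_spots = 0,
                    seed = 11)
  sim <- simulate_experiment(cfg)
  arrays <- unique(sim$spots[c("region", "phenotype", "replica")])
  expect_equal(nrow(arrays), 2 * 3 * 4)
  per_array <- table(paste(sim$spots$region, sim$spots$phenotype,
                           sim$spots$replica))
  expect_true(all(per_array == 100 * 2))
  expect_equal(length(sim$truth$genes), 100)
  expect_equal(sort(unique(sim$spots$gene_id)), sort(sim$truth$genes))
})

test_that("identical seeds give identical tables, different seeds differ", {
  cfg <- sim_config(n_genes = 30, seed = 42)
  s1 <- simulate_experiment(cfg)
  s2 <- simulate_experiment(cfg)
  expect_identical(s1$spots, s2$spots)
  expect_identical(s1$truth, s2$truth)
  s3 <- simulate_experiment(sim_config(n_genes = 30, seed = 43))
  expect_false(identical(s1$spots, s3$spots))
})

test_that("invalid configuration fields are rejected by name", {
  expect_error(sim_config(n_replicas = 1), "n_replicas")
  expect_error(sim_config(frac_corrupted_spots = 1.5),
               "frac_corrupted_spots")
  expect_error(sim_config(n_genes = 10,
                          regulated_genes = data.frame(
                            gene_id = "nope", phenotype = "MRL_lpr",
                            fold = 2)),
               "regulated_genes")
  expect_error(sim_config(n_genes = 10,
                          regulated_genes = data.frame(
                            gene_id = "g01", phenotype = "MRL_lpr",
                            fold = -2)),
               "regulated_genes")
  expect_error(sim_config(n_genes = 10,
                          coregulation_blocks = list(
                            list(genes = "g01", loading = 2))),
               "coregulation_blocks")
  expect_error(sim_config(cv_range = c(0.5, 0.1)), "cv_range")
})

test_that("realized replicate CV is centred on the configured CV", {
  cfg <- sim_config(n_genes = 1000, regions = "r1", phenotypes = "p1",
                    spots_per_gene = 1, cv_range = c(0.2, 0.2),
                    frac_corrupted_spots = 0, frac_low_signal_spots = 0,
                    spot_noise_sd = 0, seed = 5)
  sim <- simulate_experiment(cfg)
  fit <- gfp(sim, gch = FALSE)
  t1 <- fit$tensors[[1]]
  cv <- apply(t1$profiles, 1, sd) / rowMeans(t1$profiles)
  # sample CV at n = 4 is slightly biased low; the mean over 1000 genes
  # must still sit within 10% of the configured 0.2
  expect_gt(mean(cv), 0.18)
  expect_lt(mean(cv), 0.22)
})

test_that("per-animal latent factors are shared across regions and not across replicas", {
  shared <- sprintf("g%03d", 1:10)
  cfg <- sim_config(n_genes = 500, phenotypes = "p1", spots_per_gene = 1,
                    cv_range = c(0.3, 0.3), spot_noise_sd = 0,
                    frac_corrupted_spots = 0, frac_low_signal_spots = 0,
                    cross_region_shared = list(
                      list(genes = shared, loading = 1)),
                    seed = 9)
  sim <- simulate_experiment(cfg)
  fit <- gfp(sim, gch = FALSE)
  ph <- cross_region_phase(fit, "p1", genes = shared)
  # loading 1 makes the per-animal factor the whole biological signal, so
  # the two regions' profiles agree up to the per-array median jitter
  expect_gt(min(ph$cor), 0.9)
  expect_gte(sum(ph$class == "in_phase"), 8)
  # the remaining genes are independent across regions
  ph0 <- cross_region_phase(fit, "p1",
                            genes = sprintf("g%03d", 101:500))
  expect_lt(mean(abs(ph0$cor)), 0.7)
  expect_lt(mean(ph0$class != "unsynchronized"), 0.10)
  # latent values vary across replicas (animals)
  expect_gt(sd(sim$truth$animal_latents[[1]]), 0)
})

test_that("configured fold-change is recovered by the pipeline ratio", {
  folds <- numeric(5)
  for (s in 1:5) {
    cfg <- sim_config(n_genes = 40, regions = "r1",
                      phenotypes = c("case", "ctrl"),
                      cv_range = c(0.05, 0.1),
                      frac_corrupted_spots = 0, frac_low_signal_spots = 0,
                      regulated_genes = data.frame(gene_id = "g01",
                                                   phenotype = "case",
                                                   fold = 8),
                      seed = 100 + s)
    fit <- gfp(simulate_experiment(cfg), gch = FALSE)
    reg <- compare_phenotypes(fit, "case", "ctrl", region = "r1")
    folds[s] <- reg$x[reg$gene_id == "g01"]
  }
  expect_true(all(abs(folds - 8) / 8 < 0.25))
})

test_that("fixtures round-trip through the ingest readers", {
  cfg <- sim_config(n_genes = 20, seed = 3)
  sim <- simulate_experiment(cfg)
  dir <- withr::local_tempdir()
  paths <- write_fixture(sim, dir)
  back <- read_spot_table(paths[["spots"]])
  expect_equal(back, sim$spots)
  truth <- read_ground_truth(paths[["truth"]])
  expect_equal(truth$genes, sim$truth$genes)
  expect_equal(length(truth$genes), 20)
  # byte identity under the same seed
  dir2 <- withr::local_tempdir()
  write_fixture(simulate_experiment(cfg), dir2)
  expect_identical(readLines(file.path(dir, "spots.tsv")),
                   readLines(file.path(dir2, "spots.tsv")))
})

test_that("an empty table writes a header-only file", {
  cfg <- sim_config(n_genes = 2, seed = 1)
  sim <- simulate_experiment(cfg)
  sim$spots <- sim$spots[0, ]
  dir <- withr::local_tempdir()
  paths <- write_fixture(sim, dir)
  lines <- readLines(paths[["spots"]])
  expect_length(lines, 1)
  expect_match(lines, "^gene_id\t")
})
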