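test_that("expression ratio is signed, symmetric and at least 1 in magnitude", {
  expect_equal(expression_ratio(20, 5), 4)
  expect_equal(expression_ratio(5, 20), -4)
  expect_equal(expression_ratio(7, 7), 1)
  set.seed(4)
  a <- rlnorm(50); b <- rlnorm(50)
  x <- expression_ratio(a, b)
  expect_true(all(abs(x) >= 1))
  expect_equal(x, -expression_ratio(b, a))  # antisymmetry
  expect_error(expression_ratio(0, 1), "positive")
})

test_that("the regulation cutoff combines the two variabilities", {
  expect_equal(regulation_cut(0, 0), 1)
  expect_equal(regulation_cut(10, 10), 1.2)
  expect_equal(regulation_cut(30, 40), 1 + sqrt(5000) / 100)
  expect_equal(regulation_cut(30, 40), 1.7071, tolerance = 1e-4)
  expect_error(regulation_cut(-1, 5), "non-negative")
})

test_that("Welch p-values match the t-test oracle and the conventions", {
  expect_equal(welch_p(c(1, 2, 3, 4), c(2, 3, 4, 5)),
               oracle_welch_p(c(1, 2, 3, 4), c(2, 3, 4, 5)),
               tolerance = 1e-12)
  expect_equal(welch_p(c(1, 2, 3, 4), c(2, 3, 4, 5)), 0.3153,
               tolerance = 1e-3)
  set.seed(6)
  for (i in 1:20) {
    x <- rnorm(4); y <- rnorm(4, 1)
    expect_equal(welch_p(x, y), oracle_welch_p(x, y), tolerance = 1e-12)
  }
  expect_equal(welch_p(c(3, 3, 3), c(3, 3, 3)), 1)
  expect_equal(welch_p(c(0, 0, 0, 0), c(5, 5, 5, 5)), 0)
  expect_error(welch_p(1, c(1, 2)), "at least 2")
})

test_that("the composite call requires both strict clauses", {
  expect_true(call_regulation(3, 1.2, 0.01)$significant)
  expect_equal(call_regulation(3, 1.2, 0.01)$contribution, 1)
  expect_equal(call_regulation(-3, 1.2, 0.01)$contribution, -1)
  expect_false(call_regulation(3, 3.0, 0.01)$significant)   # |x| = CUT
  expect_false(call_regulation(3, 1.2, 0.07)$significant)
  expect_false(call_regulation(3, 1.2, 0.05)$significant)   # p = alpha
})

test_that("WIR weighs fold change by reference level and confidence", {
  expect_equal(weighted_individual_regulation(10, 2, 0), 10)
  expect_equal(weighted_individual_regulation(6, -3, 0.5), -6)
  expect_equal(weighted_individual_regulation(5, 1, 0.2), 0)  # |x| = 1
  expect_equal(weighted_individual_regulation(5, -4, 1), 0)   # p = 1
  set.seed(8)
  ave <- rlnorm(30); x <- expression_ratio(rlnorm(30), ave)
  p <- runif(30)
  wir <- weighted_individual_regulation(ave, x, p)
  for (i in 1:30)
    expect_equal(wir[i], oracle_wir(ave[i], x[i], p[i]), tolerance = 1e-12)
  # the implied confidence factor is recovered exactly
  nz <- abs(x) > 1
  expect_equal(wir[nz] / (ave[nz] * (abs(x[nz]) - 1)) * sign(x[nz]),
               1 - p[nz], tolerance = 1e-12)
})

test_that("WPR aggregates |WIR| with both variants", {
  expect_equal(weighted_pathway_regulation(c(3, -4)), 3.5)
  expect_equal(weighted_pathway_regulation(c(0, 0, 0)), 0)
  expect_equal(weighted_pathway_regulation(c(3, -4), variant = "rms"),
               sqrt(12.5))
})

test_that("pathway percentages count significant calls over Card", {
  reg <- data.frame(gene_id = sprintf("g%02d", 1:10),
                    contribution = c(1, 1, -1, rep(0, 7)),
                    WIR = c(5, 4, -3, rep(0.1, 7)),
                    stringsAsFactors = FALSE)
  ud <- percent_up_down(reg, sprintf("g%02d", 1:10))
  expect_equal(ud$percent_up, 20)
  expect_equal(ud$percent_down, 10)
  expect_lte(ud$percent_up + ud$percent_down, 100)
  none <- percent_up_down(reg, sprintf("g%02d", 5:10))
  expect_equal(none$percent_up, 0)
  # only quantified genes count towards Card
  part <- percent_up_down(reg, c("g01", "unmeasured"))
  expect_equal(part$card, 1)
  expect_equal(part$percent_up, 100)
  empty <- percent_up_down(reg, "unmeasured")
  expect_equal(empty$card, 0)
  expect_true(is.na(empty$percent_up))
})

test_that("phenotype comparison is antisymmetric and internally consistent", {
  cfg <- sim_config(n_genes = 60, regions = "r1",
                    phenotypes = c("case", "ctrl"),
                    regulated_genes = data.frame(
                      gene_id = c("g01", "g02"), phenotype = "case",
                      fold = c(6, 1 / 6)),
                    frac_corrupted_spots = 0, frac_low_signal_spots = 0,
                    seed = 23)
  fit <- gfp(simulate_experiment(cfg), gch = FALSE)
  fwd <- compare_phenotypes(fit, "case", "ctrl", region = "r1")
  bwd <- compare_phenotypes(fit, "ctrl", "case", region = "r1")
  m <- match(fwd$gene_id, bwd$gene_id)
  expect_equal(fwd$x, -bwd$x[m])
  expect_equal(fwd$p, bwd$p[m])
  expect_equal(fwd$CUT, bwd$CUT[m])
  expect_equal(sign(fwd$WIR), -sign(bwd$WIR[m]))
  # significance clause holds row by row
  expect_equal(fwd$significant, abs(fwd$x) > fwd$CUT & fwd$p < 0.05)
  expect_equal(fwd$contribution, ifelse(fwd$significant, sign(fwd$x), 0))
  # WIR identity: implied confidence equals 1 - p wherever |x| > 1
  nz <- abs(fwd$x) > 1
  expect_equal(fwd$WIR[nz] / (fwd$AVE_ref[nz] * (abs(fwd$x[nz]) - 1)) *
                 sign(fwd$x[nz]),
               1 - fwd$p[nz], tolerance = 1e-9)
  # the strongly regulated genes are found with the right signs
  expect_equal(fwd$contribution[fwd$gene_id == "g01"], 1)
  expect_equal(fwd$contribution[fwd$gene_id == "g02"], -1)
  # ordered by decreasing |WIR|
  expect_true(all(diff(abs(fwd$WIR)) <= 1e-12))
})

test_that("GMT files round-trip", {
  sets <- list(AKT = sprintf("g%02d", 1:5), CHS = sprintf("g%02d", 4:9))
  path <- withr::local_tempfile(fileext = ".gmt")
  write_gmt(sets, path, descriptions = c("pi3k-akt", "chemokine"))
  back <- read_gmt(path)
  expect_equal(back[["AKT"]], sets$AKT)
  expect_equal(back[["CHS"]], sets$CHS)
  expect_equal(unname(attr(back, "descriptions")["AKT"]), "pi3k-akt")
  bad <- withr::local_tempfile(fileext = ".gmt")
  writeLines("only_name", bad)
  expect_error(read_gmt(bad), "malformed")
})

test_that("pathway regulation table flags empty pathways", {
  reg <- data.frame(gene_id = c("a", "b"), contribution = c(1, 0),
                    WIR = c(4, -1), stringsAsFactors = FALSE)
  out <- pathway_regulation(reg, list(P1 = c("a", "b"), P2 = "zz"))
  expect_equal(out$WPR[1], 2.5)
  expect_true(is.na(out$WPR[2]))
  expect_equal(attr(out, "empty"), "P2")
})
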