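test_that("simulated library composition matches the design", {
  cfg <- sim_config(n_target_genes = 101, guides_per_gene = 4,
                    n_safe_guides = 108, n_nontarget_guides = 108,
                    effect_map = null_effect_map(), seed = 3)
  lib <- simulate_library(cfg)
  expect_equal(nrow(lib), 620)
  per_gene <- table(lib$target_gene[lib$category == "targeting"])
  expect_equal(length(per_gene), 101)
  expect_true(all(per_gene == 4))
  expect_false(anyDuplicated(lib$guide_id) > 0)
  expect_true(all(grepl("^[ACGT]{20}$", lib$spacer)))

  one <- simulate_library(sim_config(n_target_genes = 1, guides_per_gene = 1,
                                     n_safe_guides = 0,
                                     n_nontarget_guides = 0,
                                     n_expression_genes = 30,
                                     effect_map = null_effect_map()))
  expect_equal(nrow(one), 1)

  # determinism: identical config => byte-identical tables
  expect_identical(simulate_library(cfg), simulate_library(cfg))
  cfg2 <- cfg
  cfg2$seed <- 4L
  expect_false(identical(simulate_library(cfg), simulate_library(cfg2)))
})

test_that("flow screen conserves depth and partitions retained cells", {
  cfg <- tiny_sim_config(seed = 8)
  lib <- simulate_library(cfg)
  fs <- simulate_flow_screen(cfg, lib)

  # each sequenced sample sums exactly to the configured depth
  expect_true(all(colSums(fs$counts$counts) == cfg$flow_depth))
  expect_equal(ncol(fs$counts$counts), 4 * cfg$n_flow_replicates)

  # sorted bins partition the retained (single-guide) cells: every cell
  # has exactly one bin label (the gap between medium and high gates is
  # the empty label), and each appears exactly once
  cells <- fs$truth$cells
  expect_false(anyDuplicated(cells$cell_id) > 0)
  for (r in unique(cells$replicate_id)) {
    cr <- cells[cells$replicate_id == r, ]
    expect_equal(sum(cr$bin %in% c("low", "medium", "high", "")), nrow(cr))
    expect_equal(sum(cr$bin == "low") + sum(cr$bin == "medium") +
                   sum(cr$bin == "high") + sum(cr$bin == ""), nrow(cr))
    # gate fractions follow the configured reporter quantiles
    expect_equal(mean(cr$bin == "low"), cfg$bin_quantiles[1], tolerance = 0.02)
    expect_equal(mean(cr$bin == "high"), 1 - cfg$bin_quantiles[3],
                 tolerance = 0.02)
  }

  # determinism
  expect_identical(fs$counts$counts,
                   simulate_flow_screen(cfg, lib)$counts$counts)
})

test_that("null guides are balanced across bins; planted effects move them", {
  lfc_null <- numeric(20)
  lfc_hit <- numeric(20)
  for (s in 1:20) {
    # null screen: all reporter effects zero, equal representation expected
    cfg0 <- tiny_sim_config(seed = s)
    cfg0$effect_map <- null_effect_map()
    lib <- simulate_library(cfg0)
    m0 <- simulate_flow_screen(cfg0, lib)$counts$counts
    null_guides <- lib$guide_id[lib$target_gene == "GENE004"]
    lfc_null[s] <- mean(log2((m0[null_guides, "rep1_low"] + 1) /
                               (m0[null_guides, "rep1_high"] + 1)))
    # planted screen: the reporter-lowering target piles into the low bin
    cfg1 <- tiny_sim_config(seed = s)
    m1 <- simulate_flow_screen(cfg1, lib)$counts$counts
    hit_guides <- lib$guide_id[lib$target_gene == "GENE001"]
    lfc_hit[s] <- mean(log2((m1[hit_guides, "rep1_low"] + 1) /
                              (m1[hit_guides, "rep1_high"] + 1)))
  }
  # zero reporter effect: mean low-vs-high log2FC within +-0.1 of 0
  expect_lt(abs(mean(lfc_null)), 0.1)
  # strong reporter-lowering effect: enriched in the low bin
  expect_true(all(lfc_hit > 0))
})

test_that("perturb-seq simulation honors shapes, MOI and null structure", {
  cfg <- tiny_sim_config(seed = 5)
  lib <- simulate_library(cfg)
  ps <- simulate_perturb_seq(cfg, lib)
  expect_equal(dim(ps$dataset$counts),
               c(cfg$n_expression_genes, cfg$n_cells))
  expect_equal(nrow(ps$truth$cells), cfg$n_cells)

  # multiplet fraction among guide-carrying cells ~ truncated Poisson
  big <- sim_config(n_target_genes = 4, n_cells = 20000,
                    n_expression_genes = 30, n_progenitor_markers = 3,
                    n_differentiation_markers = 3, n_safe_guides = 4,
                    n_nontarget_guides = 2, effect_map = null_effect_map(),
                    seed = 9)
  pb <- simulate_perturb_seq(big, simulate_library(big))
  n_guides_per_cell <- table(factor(pb$dataset$guide_umis$cell_id,
                                    levels = pb$truth$cells$cell_id))
  frac_multi <- mean(n_guides_per_cell >= 2)
  lam <- 0.3
  expected <- (1 - exp(-lam) - lam * exp(-lam)) / (1 - exp(-lam))
  expect_equal(frac_multi, expected, tolerance = 0.02)

  # a zero-delta target's cells share the global latent-time distribution
  cfg0 <- tiny_sim_config(seed = 6)
  cfg0$effect_map <- null_effect_map()
  ps0 <- simulate_perturb_seq(cfg0, simulate_library(cfg0))
  tr <- ps0$truth$cells
  g1 <- grepl("GENE001", tr$guides)
  ks <- suppressWarnings(stats::ks.test(tr$true_t[g1], tr$true_t[!g1]))
  expect_gt(ks$p.value, 0.01)

  # determinism
  ps2 <- simulate_perturb_seq(cfg, lib)
  expect_identical(ps$dataset$counts, ps2$dataset$counts)
  expect_identical(ps$dataset$guide_umis, ps2$dataset$guide_umis)
})

test_that("larger planted shifts yield stochastically larger shift Z", {
  mean_absz <- vapply(c(0, -0.2, -0.4), function(delta) {
    zs <- numeric(10)
    for (s in 1:10) {
      cfg <- sim_config(n_target_genes = 6, n_cells = 1500,
                        n_expression_genes = 40, n_progenitor_markers = 4,
                        n_differentiation_markers = 4, n_safe_guides = 8,
                        n_nontarget_guides = 4,
                        effect_map = data.frame(gene = "GENE001",
                                                delta = delta,
                                                reporter_effect = 0),
                        seed = 100 + s)
      ps <- simulate_perturb_seq(cfg, simulate_library(cfg))
      tr <- ps$truth$cells
      single <- !grepl(",", tr$guides)
      target <- single & grepl("GENE001_", tr$guides)
      pt <- stats::setNames(tr$true_t, tr$cell_id)
      zs[s] <- pseudotime_shift_test(pt, tr$cell_id[target],
                                     tr$cell_id[single & !target])$z_shift
    }
    mean(abs(zs))
  }, numeric(1))
  expect_true(all(diff(mean_absz) > 0))
})

test_that("config invariants are enforced and YAML round-trips", {
  expect_error(sim_config(bin_quantiles = c(0.5, 0.4, 0.9)), "increasing")
  expect_error(sim_config(moi = 0), "moi")
  expect_error(sim_config(nb_dispersion = -1), "dispersion")
  expect_error(sim_config(effect_map = data.frame(
    gene = "NOPE", delta = 0.1, reporter_effect = 0)), "subset")

  path <- withr::local_tempfile(fileext = ".yaml")
  yaml::write_yaml(list(n_target_genes = 6, n_cells = 500,
                        n_expression_genes = 60, n_safe_guides = 4,
                        n_nontarget_guides = 2, seed = 7,
                        effect_map = list(list(gene = "GENE002",
                                               delta = -0.5,
                                               reporter_effect = -1))),
                   path)
  cfg <- sim_config_from_yaml(path)
  expect_equal(cfg$n_target_genes, 6L)
  expect_equal(cfg$effect_map$gene, "GENE002")
  yaml::write_yaml(list(not_a_key = 1), path)
  expect_error(sim_config_from_yaml(path), "unknown")
})
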