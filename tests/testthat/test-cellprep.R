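test_that("guide assignment thresholds detection and sets status", {
  counts <- matrix(5, 3, 4,
                   dimnames = list(c("gA", "gB", "MT-1"),
                                   paste0("c", 1:4)))
  lib <- make_library(n_genes = 2, gpg = 1, safe = 0, nt = 0)
  gu <- data.frame(
    cell_id = c("c1", "c2", "c2", "c3"),
    guide_id = c("GENE001_g1", "GENE001_g1", "GENE002_g1", "GENE001_g1"),
    umis = c(10, 10, 8, 2))
  ds <- make_dataset(counts, mito_genes = "MT-1", guide_umis = gu,
                     library = lib)
  a <- assign_guides(ds, min_umis = 3)
  expect_equal(a$status, c("single", "multiple", "none", "none"))
  expect_equal(a$target_gene[1], "GENE001")
  expect_equal(a$target_gene[2], "")
})

test_that("QC filtering applies the documented boundary semantics", {
  # five cells: single/2%/500, multiple/1%/500, single/7%/500,
  # single/2%/150, none/0%/500 -> exactly one kept
  mk_counts <- function(total, mito_frac) {
    c(total - round(total * mito_frac), round(total * mito_frac))
  }
  counts <- sapply(list(mk_counts(500, 0.02), mk_counts(500, 0.01),
                        mk_counts(500, 0.07), mk_counts(150, 0.02),
                        mk_counts(500, 0)), identity)
  dimnames(counts) <- list(c("gA", "MT-1"), paste0("c", 1:5))
  lib <- make_library(n_genes = 2, gpg = 1, safe = 0, nt = 0)
  gu <- data.frame(
    cell_id = c("c1", "c2", "c2", "c3", "c4"),
    guide_id = c("GENE001_g1", "GENE001_g1", "GENE002_g1", "GENE001_g1",
                 "GENE002_g1"),
    umis = 10)
  ds <- make_dataset(counts, "MT-1", gu, lib)
  a <- assign_guides(ds)
  kept <- qc_filter(ds, a)
  expect_equal(colnames(kept$counts), "c1")
  expect_equal(unname(attr(kept, "qc_tallies")["kept"]), 1)

  # boundary: exactly 5.0% mito removed (strict <), exactly 200 RNAs kept
  b_counts <- cbind(c1 = mk_counts(500, 0.05), c2 = mk_counts(200, 0.02))
  rownames(b_counts) <- c("gA", "MT-1")
  bds <- make_dataset(b_counts, "MT-1",
                      data.frame(cell_id = c("c1", "c2"),
                                 guide_id = "GENE001_g1", umis = 10), lib)
  bk <- qc_filter(bds, assign_guides(bds))
  expect_equal(colnames(bk$counts), "c2")

  # empty dataset passes through with zero tallies
  eds <- make_dataset(matrix(0, 2, 0,
                             dimnames = list(c("gA", "MT-1"), NULL)),
                      "MT-1", library = lib)
  ek <- qc_filter(eds, assign_guides(eds))
  expect_equal(ncol(ek$counts), 0)
  expect_true(all(attr(ek, "qc_tallies") == 0))
})

test_that("QC filtering equals brute-force predicate evaluation and is
           idempotent", {
  set.seed(9)
  n <- 60
  counts <- rbind(gA = rpois(n, 300), gB = rpois(n, 100),
                  `MT-1` = rpois(n, 12))
  colnames(counts) <- sprintf("c%02d", 1:n)
  lib <- make_library(n_genes = 2, gpg = 1, safe = 0, nt = 0)
  gu <- do.call(rbind, lapply(1:n, function(i) {
    k <- sample(0:2, 1)
    if (k == 0) return(NULL)
    data.frame(cell_id = sprintf("c%02d", i),
               guide_id = sample(lib$guide_id, k),
               umis = sample(c(1, 5, 10), k, replace = TRUE))
  }))
  ds <- make_dataset(counts, "MT-1", gu, lib)
  a <- assign_guides(ds)
  kept <- qc_filter(ds, a, max_mito = 0.05, min_rnas = 350)

  total <- colSums(counts)
  mito <- counts["MT-1", ] / total
  oracle <- vapply(colnames(counts), function(cid) {
    st <- a$status[a$cell_id == cid]
    st == "single" && mito[cid] < 0.05 && total[cid] >= 350
  }, logical(1))
  expect_equal(colnames(kept$counts), names(which(oracle)))

  again <- qc_filter(kept, a, max_mito = 0.05, min_rnas = 350)
  expect_equal(again$counts, kept$counts)
  expect_equal(again$cell_meta, kept$cell_meta)
})

test_that("expression normalization is depth-invariant and deterministic", {
  counts <- cbind(c1 = c(10, 20, 0), c2 = c(30, 60, 0), c3 = c(5, 8, 0))
  rownames(counts) <- c("gA", "gB", "gC")
  ds <- make_dataset(counts)
  norm <- normalize_expression(ds)
  expect_equal(unname(norm["gC", ]), c(0, 0, 0))
  # c2 = 3 x c1: identical after depth scaling
  expect_equal(norm[, "c1"], norm[, "c2"])

  single <- make_dataset(matrix(c(1, 3), 2,
                                dimnames = list(c("gA", "gB"), "c1")))
  # median depth equals the cell's own depth, so scaling is identity
  expect_equal(unname(normalize_expression(single)[, 1]),
               c(log1p(1), log1p(3)))
})

test_that("variable-feature selection keeps dispersed genes and markers", {
  m <- matrix(1, 5, 40, dimnames = list(paste0("g", 1:5), NULL))
  expect_setequal(select_variable_features(m, n = 10), rownames(m))

  set.seed(2)
  flat <- matrix(rpois(30 * 60, 5), 30)
  bimodal <- rep(c(0, 100), 30)
  mm <- rbind(flat, bimodal)
  rownames(mm) <- c(sprintf("flat%02d", 1:30), "bimodal")
  colnames(mm) <- sprintf("c%02d", 1:60)
  expect_true("bimodal" %in% select_variable_features(mm, n = 5))

  cfg <- tiny_sim_config(seed = 2)
  ps <- simulate_perturb_seq(cfg, simulate_library(cfg))
  a <- assign_guides(ps$dataset)
  norm <- normalize_expression(qc_filter(ps$dataset, a))
  top <- select_variable_features(norm, n = 30)
  markers <- c(progenitor_markers(cfg), differentiation_markers(cfg))
  expect_gte(sum(markers %in% top), 15)
})

test_that("knockout-efficiency test detects planted knockdown", {
  # identical groups: no evidence of reduction
  lib <- make_library(n_genes = 1, gpg = 1, safe = 0, nt = 1)
  counts <- matrix(7, 2, 8, dimnames = list(c("GENE001", "gB"),
                                            paste0("c", 1:8)))
  gu <- data.frame(cell_id = paste0("c", 1:8),
                   guide_id = rep(c("GENE001_g1", "NT001"), 4), umis = 10)
  ds <- make_dataset(counts, guide_umis = gu, library = lib)
  a <- assign_guides(ds)
  expect_gte(knockout_efficiency(ds, a, "GENE001")$p, 0.5)
  expect_error(knockout_efficiency(ds, a, "absent"), "panel")

  # simulated ~50% knockdown: significant in >= 18/20 seeds
  hits <- 0
  for (s in 1:20) {
    cfg <- tiny_sim_config(seed = 400 + s, knockdown_factor = 0.5)
    cfg$effect_map <- null_effect_map()
    ps <- simulate_perturb_seq(cfg, simulate_library(cfg))
    a <- assign_guides(ps$dataset)
    f <- qc_filter(ps$dataset, a)
    hits <- hits + (knockout_efficiency(f, a, "GENE001")$p < 0.01)
  }
  expect_gte(hits, 18)
})

test_that("cell datasets round-trip through the MatrixMarket dialect", {
  cfg <- tiny_sim_config(seed = 3)
  ps <- simulate_perturb_seq(cfg, simulate_library(cfg))
  dir <- withr::local_tempdir()
  write_cell_dataset(ps$dataset, dir)
  back <- read_cell_dataset(dir)
  expect_equal(as.matrix(back$counts), as.matrix(ps$dataset$counts))
  expect_equal(back$cell_meta, ps$dataset$cell_meta)
  expect_equal(back$gene_meta$is_mito, ps$dataset$gene_meta$is_mito)
  expect_equal(back$guide_umis, ps$dataset$guide_umis)
})
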