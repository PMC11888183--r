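# Ground-truth evaluation drivers: run the full method on simulated data
# with planted effects and measure recovery, calibration and ranking.
# These power both the test suite and the reproducibility script.

#' Run both screen arms once on simulated data (in memory)
#'
#' Simulates a library, a sorted-bin screen and a Perturb-seq experiment
#' under one configuration, runs both scoring arms and the integration,
#' and returns all result tables together with the ground truth.
#'
#' @param config A `sim_config`.
#' @param flow_n_perm Permutation draws for the flow arm.
#' @param run_flow,run_perturb Arm toggles.
#' @param curve_max_iter Principal-curve iteration budget; the curve
#'   plateaus within ~15 sweeps at these problem sizes, so the driver uses
#'   a 30-iteration budget.
#' @return A list: `flow`, `perturb`, `integrated`, `truth_targets`,
#'   `pseudotime`, `assignments`.
#' @export
run_dual_arm <- function(config, flow_n_perm = 1000, run_flow = TRUE,
                         run_perturb = TRUE, curve_max_iter = 30) {
  library <- simulate_library(config)
  flow_res <- NULL
  if (run_flow) {
    fs <- simulate_flow_screen(config, library)
    flow_res <- score_screen(fs$counts, library, n_perm = flow_n_perm,
                             seed = derive_seed(config$seed, "rra"))
  }
  perturb_res <- NULL
  pt <- NULL
  assignments <- NULL
  truth <- NULL
  if (run_perturb) {
    ps <- simulate_perturb_seq(config, library)
    truth <- ps$truth
    assignments <- assign_guides(ps$dataset)
    filtered <- qc_filter(ps$dataset, assignments)
    norm <- normalize_expression(filtered)
    feats <- select_variable_features(norm)
    pt <- infer_pseudotime(
      norm, features = feats,
      progenitor_markers = progenitor_markers(config),
      differentiation_markers = differentiation_markers(config),
      seed = derive_seed(config$seed, "trajectory"),
      max_iter = curve_max_iter)
    perturb_res <- target_phenotypes(pt$pseudotime, assignments)
  }
  integ <- if (run_flow && run_perturb) {
    integrate_screens(flow_res, perturb_res)
  }
  list(flow = flow_res, perturb = perturb_res, integrated = integ,
       truth_targets = truth$targets,
       pseudotime = if (!is.null(pt)) pt$pseudotime,
       assignments = assignments)
}

#' Planted-effect recovery study
#'
#' Runs the full dual-arm pipeline over `n_seeds` independent simulations
#' at the default study conditions (50 target genes, 5 planted
#' pro-differentiation knockouts at delta = -0.3, ~200 single-guide cells
#' per target) and measures: the fraction of runs in which every planted
#' target is classified `pro_differentiation`; the per-gene false-positive
#' rate among null targets; and the fraction of runs in which all planted
#' targets occupy top-10 combined ranks.
#'
#' @param n_seeds Number of independent simulations (default 20).
#' @param seed Base seed; run i uses a sub-seed derived from it.
#' @param config Optional `sim_config` template (its seed is replaced per
#'   run).
#' @param flow_n_perm Permutation draws for the flow arm.
#' @return A list: `all_planted_rate`, `null_fpr`, `top10_rate`,
#'   `mean_planted_recovery`, `per_seed` (data.frame).
#' @export
evaluate_recovery <- function(n_seeds = 20, seed = 1, config = NULL,
                              flow_n_perm = 1000) {
  per_seed <- vector("list", n_seeds)
  for (i in seq_len(n_seeds)) {
    cfg <- if (is.null(config)) sim_config() else config
    cfg$seed <- derive_seed(seed, paste0("recovery", i))
    res <- run_dual_arm(cfg, flow_n_perm = flow_n_perm)
    planted <- res$truth_targets$gene[res$truth_targets$delta != 0]
    nulls <- setdiff(res$truth_targets$gene, planted)
    ph <- res$perturb
    cls <- stats::setNames(ph$classification, ph$gene)
    planted_called <- sum(cls[planted] == "pro_differentiation",
                          na.rm = TRUE)
    null_fp <- sum(cls[nulls] != "none", na.rm = TRUE)
    tab <- res$integrated$table
    top10 <- tab$gene[order(tab$combined_rank)][seq_len(min(10, nrow(tab)))]
    per_seed[[i]] <- data.frame(
      seed_index = i,
      planted_called = planted_called,
      n_planted = length(planted),
      null_fp = null_fp,
      n_null_tested = sum(nulls %in% ph$gene),
      all_planted_top10 = all(planted %in% top10),
      spearman_rho = res$integrated$spearman_rho
    )
  }
  per_seed <- do.call(rbind, per_seed)
  list(
    all_planted_rate = mean(per_seed$planted_called == per_seed$n_planted),
    mean_planted_recovery = mean(per_seed$planted_called /
                                   per_seed$n_planted),
    null_fpr = sum(per_seed$null_fp) / sum(per_seed$n_null_tested),
    top10_rate = mean(per_seed$all_planted_top10),
    per_seed = per_seed
  )
}

#' Sorted-bin arm recovery study
#'
#' Simulates a screen with a single strong reporter-lowering knockout and
#' measures how often that gene ranks first by psi-P with a
#' pro-differentiation direction call.
#'
#' @param n_seeds Number of simulations (default 20).
#' @param seed Base seed.
#' @param reporter_effect Planted reporter effect in log-units.
#' @param delta Planted latent-time shift.
#' @param n_perm Permutation draws.
#' @return A list: `top_rank_rate`, `per_seed`.
#' @export
evaluate_flow_recovery <- function(n_seeds = 20, seed = 1,
                                   reporter_effect = -2, delta = -0.4,
                                   n_perm = 1000) {
  hits <- logical(n_seeds)
  for (i in seq_len(n_seeds)) {
    cfg <- sim_config(
      effect_map = data.frame(gene = "GENE001", delta = delta,
                              reporter_effect = reporter_effect),
      seed = derive_seed(seed, paste0("flowrec", i)))
    lib <- simulate_library(cfg)
    fs <- simulate_flow_screen(cfg, lib)
    res <- score_screen(fs$counts, lib, n_perm = n_perm,
                        seed = derive_seed(cfg$seed, "rra"))
    best <- res$gene[order(res$psi_p, -abs(res$beta_score))][1]
    hits[i] <- best == "GENE001" &&
      res$direction[res$gene == "GENE001"] == "pro_differentiation"
  }
  list(top_rank_rate = mean(hits),
       per_seed = data.frame(seed_index = seq_len(n_seeds), hit = hits))
}

#' Type-I error of the alpha-RRA permutation test under uniform ranks
#'
#' Simulates `n_genes` null genes whose guides occupy a uniform random
#' permutation of the normalized ranks, scores them with [alpha_rra()],
#' and reports the fraction with p <= `level`.
#'
#' @param n_genes Null genes (default 1000).
#' @param guides_per_gene Guides per gene (default 4).
#' @param n_perm Permutation draws (default 1000).
#' @param level Nominal level (default 0.05).
#' @param alpha RRA cutoff.
#' @param seed Integer seed.
#' @return A list: `type1_error`, `level`, `n_genes`.
#' @export
evaluate_rra_calibration <- function(n_genes = 1000, guides_per_gene = 4,
                                     n_perm = 1000, level = 0.05,
                                     alpha = 0.25, seed = 1) {
  n <- n_genes * guides_per_gene
  ranks <- with_seed(derive_seed(seed, "ranks"), sample.int(n)) / n
  gene_ranks <- split(ranks, rep(seq_len(n_genes), each = guides_per_gene))
  names(gene_ranks) <- sprintf("null%04d", seq_len(n_genes))
  res <- alpha_rra(gene_ranks, alpha = alpha, n_perm = n_perm,
                   seed = derive_seed(seed, "perm"), n_guides = n)
  list(type1_error = mean(res$p_perm <= level), level = level,
       n_genes = n_genes)
}
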