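# Seeded synthetic-data generator for both screen arms. Defaults encode the
# study conditions: 50 target genes x 4 guides plus controls, 5 planted
# pro-differentiation knockouts (latent-time shift -0.3, reporter effect
# -1.5 log-units), ~200 single-guide cells per target, MOI 0.3, and a
# KRT10-like reporter whose top 13.5% defines the high sorting bin.

#' Simulation configuration
#'
#' Bundles every tunable of the synthetic dual-screen generator, validated
#' against its invariants. The defaults are the study conditions used by the
#' package's recovery experiments; any field can be overridden.
#'
#' @param n_target_genes Number of targeted genes in the library.
#' @param guides_per_gene Guides designed per targeted gene.
#' @param n_safe_guides Safe-targeting control guides (cut neutral loci).
#' @param n_nontarget_guides Non-targeting control guides.
#' @param n_positive_control_genes Positive-control genes (each gets
#'   `guides_per_gene` guides); 0 by default.
#' @param n_cells Cells in the Perturb-seq arm (post-selection, so every
#'   cell carries at least one integration).
#' @param n_expression_genes Genes in the expression panel. The panel is
#'   laid out as progenitor markers, differentiation markers, the targeted
#'   genes themselves (so on-target knockdown is observable),
#'   mitochondrial genes, then flat filler genes.
#' @param n_progenitor_markers,n_differentiation_markers Trajectory marker
#'   counts; progenitor markers fall along latent time, differentiation
#'   markers rise.
#' @param mito_gene_fraction Fraction of the expression panel designated
#'   mitochondrial.
#' @param mito_mean_fraction Mean mitochondrial read share per cell (per-cell
#'   lognormal spread `mito_sd_log` pushes a tail of cells past QC).
#' @param moi Mean lentiviral integrations per cell (Poisson, conditioned
#'   positive by drug selection).
#' @param nb_dispersion Negative-binomial dispersion of expression counts
#'   (`size = 1/nb_dispersion`).
#' @param mean_depth Mean UMIs per cell; per-cell depth is lognormal with
#'   log-sd `depth_sd_log`.
#' @param knockdown_factor Residual on-target expression in cells carrying a
#'   gene's guides (0.3 = 70% knockdown).
#' @param guide_umi_mean Mean capture UMIs per integrated guide.
#' @param effect_map data.frame (`gene`, `delta`, `reporter_effect`): planted
#'   knockout effects. `delta` in [-1, 1] shifts latent time (negative =
#'   cells fail to progress); `reporter_effect` shifts the sorting reporter
#'   in log-units.
#' @param bin_quantiles Three strictly increasing fractions (a, b, c): the
#'   low bin is the bottom `a` of the reporter distribution, medium is
#'   (a, b], high is the top `1 - c`.
#' @param n_flow_cells,n_flow_replicates,flow_depth Sorted-bin arm: cells
#'   per replicate, biological replicates, and sequencing depth (total
#'   guide UMIs) per bin sample.
#' @param reporter_amplitude,reporter_midpoint,reporter_steepness,reporter_noise_sd
#'   Logistic reporter baseline in latent time plus Gaussian noise, all in
#'   log-units.
#' @param marker_midpoint,marker_steepness Logistic response of trajectory
#'   markers to latent time.
#' @param depth_sd_log,mito_sd_log Lognormal spreads of per-cell depth and
#'   mitochondrial share.
#' @param seed Integer seed; identical configurations reproduce outputs
#'   byte-for-byte.
#' @return A validated list of class `sim_config`.
#' @export
sim_config <- function(n_target_genes = 50L,
                       guides_per_gene = 4L,
                       n_safe_guides = 72L,
                       n_nontarget_guides = 16L,
                       n_positive_control_genes = 0L,
                       n_cells = 16800L,
                       n_expression_genes = 160L,
                       n_progenitor_markers = 10L,
                       n_differentiation_markers = 10L,
                       mito_gene_fraction = 0.05,
                       mito_mean_fraction = 0.025,
                       moi = 0.3,
                       nb_dispersion = 0.15,
                       mean_depth = 2000,
                       knockdown_factor = 0.3,
                       guide_umi_mean = 15,
                       effect_map = NULL,
                       bin_quantiles = c(0.30, 0.70, 0.865),
                       n_flow_cells = 30000L,
                       n_flow_replicates = 2L,
                       flow_depth = 200000L,
                       reporter_amplitude = 3,
                       reporter_midpoint = 0.55,
                       reporter_steepness = 0.12,
                       reporter_noise_sd = 0.5,
                       marker_midpoint = 0.5,
                       marker_steepness = 0.1,
                       depth_sd_log = 0.35,
                       mito_sd_log = 0.35,
                       seed = 1L) {
  if (is.null(effect_map)) {
    n_eff <- min(5L, n_target_genes)
    effect_map <- data.frame(
      gene = sprintf("GENE%03d", seq_len(n_eff)),
      delta = rep(-0.3, n_eff),
      reporter_effect = rep(-1.5, n_eff)
    )
  }
  cfg <- list(
    n_target_genes = as.integer(n_target_genes),
    guides_per_gene = as.integer(guides_per_gene),
    n_safe_guides = as.integer(n_safe_guides),
    n_nontarget_guides = as.integer(n_nontarget_guides),
    n_positive_control_genes = as.integer(n_positive_control_genes),
    n_cells = as.integer(n_cells),
    n_expression_genes = as.integer(n_expression_genes),
    n_progenitor_markers = as.integer(n_progenitor_markers),
    n_differentiation_markers = as.integer(n_differentiation_markers),
    mito_gene_fraction = mito_gene_fraction,
    mito_mean_fraction = mito_mean_fraction,
    moi = moi,
    nb_dispersion = nb_dispersion,
    mean_depth = mean_depth,
    knockdown_factor = knockdown_factor,
    guide_umi_mean = guide_umi_mean,
    effect_map = as.data.frame(effect_map),
    bin_quantiles = bin_quantiles,
    n_flow_cells = as.integer(n_flow_cells),
    n_flow_replicates = as.integer(n_flow_replicates),
    flow_depth = as.integer(flow_depth),
    reporter_amplitude = reporter_amplitude,
    reporter_midpoint = reporter_midpoint,
    reporter_steepness = reporter_steepness,
    reporter_noise_sd = reporter_noise_sd,
    marker_midpoint = marker_midpoint,
    marker_steepness = marker_steepness,
    depth_sd_log = depth_sd_log,
    mito_sd_log = mito_sd_log,
    seed = as.integer(seed)
  )
  class(cfg) <- "sim_config"
  validate_sim_config(cfg)
  cfg
}

#' Validate a simulation configuration
#' @param config A `sim_config`.
#' @return The config, invisibly, or an error naming the violated invariant.
#' @export
validate_sim_config <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  with(config, {
    if (n_target_genes < 1 || guides_per_gene < 1) {
      stop("need at least one target gene and one guide per gene")
    }
    if (n_safe_guides < 0 || n_nontarget_guides < 0 ||
        n_positive_control_genes < 0) {
      stop("control counts must be non-negative")
    }
    if (n_cells < 1 || n_flow_cells < 1 || n_flow_replicates < 1) {
      stop("cell and replicate counts must be >= 1")
    }
    if (moi <= 0) stop("moi must be positive")
    if (nb_dispersion <= 0) stop("nb_dispersion must be positive")
    if (mean_depth <= 0) stop("mean_depth must be positive")
    if (mito_gene_fraction < 0 || mito_gene_fraction > 1) {
      stop("mito_gene_fraction must lie in [0, 1]")
    }
    if (length(bin_quantiles) != 3 || any(diff(bin_quantiles) <= 0) ||
        any(bin_quantiles <= 0) || any(bin_quantiles >= 1)) {
      stop("bin_quantiles must be three strictly increasing fractions in (0, 1)")
    }
    if (nrow(effect_map) > 0) {
      targets <- sprintf("GENE%03d", seq_len(n_target_genes))
      if (!all(effect_map$gene %in% targets)) {
        stop("effect_map genes must be a subset of the target genes")
      }
      if (any(abs(effect_map$delta) > 1)) stop("delta must lie in [-1, 1]")
    }
    n_panel <- n_progenitor_markers + n_differentiation_markers +
      n_target_genes + ceiling(mito_gene_fraction * n_expression_genes)
    if (n_expression_genes < n_panel) {
      stop("n_expression_genes too small for markers + targets + mito genes")
    }
  })
  invisible(config)
}

#' Load a simulation configuration from YAML
#' @param path YAML file whose keys are `sim_config()` arguments
#'   (`effect_map` as a list of `{gene, delta, reporter_effect}` records).
#' @return A `sim_config`.
#' @export
sim_config_from_yaml <- function(path) {
  raw <- yaml::read_yaml(path)
  allowed <- names(formals(sim_config))
  unknown <- setdiff(names(raw), allowed)
  if (length(unknown)) {
    stop("unknown sim_config keys: ", paste(unknown, collapse = ", "))
  }
  if (!is.null(raw$effect_map)) {
    raw$effect_map <- do.call(rbind, lapply(raw$effect_map, as.data.frame))
  }
  if (!is.null(raw$bin_quantiles)) raw$bin_quantiles <- unlist(raw$bin_quantiles)
  do.call(sim_config, raw)
}

random_spacers <- function(n) {
  repeat {
    sp <- vapply(seq_len(n), function(i) {
      paste(sample(c("A", "C", "G", "T"), 20, replace = TRUE), collapse = "")
    }, character(1))
    if (!anyDuplicated(sp)) return(sp)
  }
}

#' Simulate a guide library
#'
#' Designs `n_target_genes x guides_per_gene` targeting guides plus the
#' configured safe-targeting, non-targeting and positive-control guides,
#' with unique ids and random 20-nt ACGT spacers.
#'
#' @param config A `sim_config`.
#' @return A `guide_library`.
#' @export
simulate_library <- function(config) {
  validate_sim_config(config)
  with_seed(derive_seed(config$seed, "library"), {
    targets <- sprintf("GENE%03d", seq_len(config$n_target_genes))
    rows <- list(
      data.frame(
        guide_id = paste0(rep(targets, each = config$guides_per_gene), "_g",
                          rep(seq_len(config$guides_per_gene),
                              times = config$n_target_genes)),
        target_gene = rep(targets, each = config$guides_per_gene),
        category = "targeting"
      )
    )
    if (config$n_positive_control_genes > 0) {
      pc <- sprintf("POSCTRL%02d", seq_len(config$n_positive_control_genes))
      rows <- c(rows, list(data.frame(
        guide_id = paste0(rep(pc, each = config$guides_per_gene), "_g",
                          rep(seq_len(config$guides_per_gene),
                              times = config$n_positive_control_genes)),
        target_gene = rep(pc, each = config$guides_per_gene),
        category = "positive_control"
      )))
    }
    if (config$n_safe_guides > 0) {
      rows <- c(rows, list(data.frame(
        guide_id = sprintf("SAFE%03d", seq_len(config$n_safe_guides)),
        target_gene = "", category = "safe_targeting"
      )))
    }
    if (config$n_nontarget_guides > 0) {
      rows <- c(rows, list(data.frame(
        guide_id = sprintf("NT%03d", seq_len(config$n_nontarget_guides)),
        target_gene = "", category = "non_targeting"
      )))
    }
    df <- do.call(rbind, rows)
    df$spacer <- random_spacers(nrow(df))
    guide_library(df[c("guide_id", "spacer", "target_gene", "category")])
  })
}

#' Latent-time shift of a knockout
#'
#' Negative delta compresses latent time toward 0 (cells fail to progress
#' along differentiation); positive delta compresses toward 1.
#' @noRd
shift_latent_time <- function(t, delta) {
  ifelse(delta < 0, t * (1 + delta),
         ifelse(delta > 0, 1 - (1 - t) * (1 - delta), t))
}

guide_effects <- function(library, effect_map) {
  delta <- stats::setNames(numeric(nrow(library)), library$guide_id)
  reporter <- delta
  if (nrow(effect_map) > 0) {
    hit <- library$target_gene %in% effect_map$gene
    idx <- match(library$target_gene[hit], effect_map$gene)
    delta[hit] <- effect_map$delta[idx]
    reporter[hit] <- effect_map$reporter_effect[idx]
  }
  list(delta = delta, reporter = reporter)
}

#' Simulate a sorted-bin (CRISPR-Flow) screen
#'
#' Per replicate: cells receive Poisson(moi) integrations (conditioned
#' positive); multi-guide cells are dropped before sorting (rare at
#' MOI <= 0.3); each retained cell draws a reporter level equal to a
#' logistic baseline in its latent time plus its guide's planted reporter
#' effect plus Gaussian noise; cells are cut into low/medium/high bins at
#' the configured reporter quantiles (the unsorted sample is a uniform
#' subsample of all retained cells); guide UMI counts per bin are drawn
#' multinomially at the configured depth, so each sample's counts sum
#' exactly to `flow_depth`.
#'
#' @param config A `sim_config`.
#' @param library The `guide_library` from [simulate_library()].
#' @return A list with `counts` (a `guide_counts` with 4 samples per
#'   replicate) and `truth` (per-cell latent times, guides, bins; per-target
#'   planted effects).
#' @export
simulate_flow_screen <- function(config, library) {
  validate_sim_config(config)
  stopifnot(inherits(library, "guide_library"))
  eff <- guide_effects(library, config$effect_map)
  with_seed(derive_seed(config$seed, "flow"), {
    cols <- list(); meta <- list(); truth_cells <- list()
    for (rep_i in seq_len(config$n_flow_replicates)) {
      n <- config$n_flow_cells
      k <- rpois_positive(n, config$moi)
      single <- k == 1L
      guide <- sample(library$guide_id, n, replace = TRUE)[single]
      m <- length(guide)
      t0 <- stats::runif(m)
      t_true <- shift_latent_time(t0, eff$delta[guide])
      reporter <- config$reporter_amplitude *
        stats::plogis((t_true - config$reporter_midpoint) /
                        config$reporter_steepness) +
        eff$reporter[guide] + stats::rnorm(m, 0, config$reporter_noise_sd)
      q <- stats::quantile(reporter, config$bin_quantiles, names = FALSE)
      bin <- rep(NA_character_, m)
      bin[reporter <= q[1]] <- "low"
      bin[reporter > q[1] & reporter <= q[2]] <- "medium"
      bin[reporter > q[3]] <- "high"
      n_unsorted <- max(1L, round(m * (1 - config$bin_quantiles[3])))
      unsorted_idx <- sample.int(m, n_unsorted)
      pools <- list(unsorted = unsorted_idx,
                    low = which(bin == "low"),
                    medium = which(bin == "medium"),
                    high = which(bin == "high"))
      if (any(lengths(pools) == 0)) {
        stop("a sorting bin is empty at the configured n_flow_cells")
      }
      for (b in names(pools)) {
        tab <- table(factor(guide[pools[[b]]], levels = library$guide_id))
        cols[[paste0("rep", rep_i, "_", b)]] <-
          as.vector(stats::rmultinom(1, config$flow_depth, prob = tab))
        meta[[paste0("rep", rep_i, "_", b)]] <-
          data.frame(sample_id = paste0("rep", rep_i, "_", b),
                     replicate_id = paste0("rep", rep_i), bin = b)
      }
      truth_cells[[rep_i]] <- data.frame(
        replicate_id = paste0("rep", rep_i),
        cell_id = sprintf("r%d_c%06d", rep_i, seq_len(m)),
        true_t = t_true, guide_id = guide, bin = ifelse(is.na(bin), "", bin)
      )
    }
    counts <- do.call(cbind, cols)
    rownames(counts) <- library$guide_id
    truth_targets <- data.frame(
      gene = sprintf("GENE%03d", seq_len(config$n_target_genes))
    )
    idx <- match(truth_targets$gene, config$effect_map$gene)
    truth_targets$delta <- ifelse(is.na(idx), 0, config$effect_map$delta[idx])
    truth_targets$reporter_effect <-
      ifelse(is.na(idx), 0, config$effect_map$reporter_effect[idx])
    list(counts = guide_counts(counts, do.call(rbind, meta)),
         truth = list(cells = do.call(rbind, truth_cells),
                      targets = truth_targets))
  })
}

#' Simulate a Perturb-seq experiment
#'
#' Cells draw latent differentiation time t ~ Uniform(0, 1), shifted toward
#' 0 or 1 by their guides' planted delta. Progenitor markers decay
#' logistically in t, differentiation markers rise, targeted genes are flat
#' but knocked down in cells carrying their guides, mitochondrial genes
#' contribute a lognormally varying read share, and all counts are negative
#' binomial around a lognormal per-cell depth. Guide capture UMIs are
#' Poisson around `guide_umi_mean` per integration.
#'
#' @param config A `sim_config`.
#' @param library The matching `guide_library`.
#' @return A list with `dataset` (a `cell_dataset`) and `truth` (per-cell
#'   realized latent time and guides; per-target planted effects).
#' @export
simulate_perturb_seq <- function(config, library) {
  validate_sim_config(config)
  stopifnot(inherits(library, "guide_library"))
  eff <- guide_effects(library, config$effect_map)
  with_seed(derive_seed(config$seed, "perturb"), {
    n <- config$n_cells
    cell_id <- sprintf("cell%06d", seq_len(n))
    k <- rpois_positive(n, config$moi)
    guide_of <- lapply(k, function(ki) sample(library$guide_id, ki))
    delta_eff <- pmin(1, pmax(-1, vapply(guide_of, function(g) {
      sum(eff$delta[g])
    }, numeric(1))))
    t_true <- shift_latent_time(stats::runif(n), delta_eff)

    # Expression panel layout
    n_mito <- ceiling(config$mito_gene_fraction * config$n_expression_genes)
    targets <- sprintf("GENE%03d", seq_len(config$n_target_genes))
    gene_id <- c(sprintf("PRG%02d", seq_len(config$n_progenitor_markers)),
                 sprintf("DIF%02d", seq_len(config$n_differentiation_markers)),
                 targets,
                 sprintf("MT-%02d", seq_len(n_mito)))
    n_fill <- config$n_expression_genes - length(gene_id)
    gene_id <- c(gene_id, sprintf("FIL%03d", seq_len(n_fill)))
    gene_class <- c(rep("progenitor", config$n_progenitor_markers),
                    rep("differentiation", config$n_differentiation_markers),
                    rep("target", config$n_target_genes),
                    rep("mito", n_mito),
                    rep("filler", n_fill))
    g <- length(gene_id)
    base <- exp(stats::rnorm(g, 0, 0.8))
    # fix total mitochondrial share at mito_mean_fraction on average
    is_mito <- gene_class == "mito"
    base[is_mito] <- base[is_mito] / sum(base[is_mito]) *
      sum(base[!is_mito]) * config$mito_mean_fraction /
      (1 - config$mito_mean_fraction)

    lo <- 0.15
    up_curve <- lo + (1 - lo) *
      stats::plogis((t_true - config$marker_midpoint) / config$marker_steepness)
    down_curve <- lo + (1 - lo) *
      stats::plogis(-(t_true - config$marker_midpoint) / config$marker_steepness)

    w <- matrix(base, nrow = g, ncol = n)
    w[gene_class == "progenitor", ] <-
      outer(base[gene_class == "progenitor"], down_curve)
    w[gene_class == "differentiation", ] <-
      outer(base[gene_class == "differentiation"], up_curve)
    mito_mult <- exp(stats::rnorm(n, 0, config$mito_sd_log))
    w[is_mito, ] <- w[is_mito, , drop = FALSE] *
      rep(mito_mult, each = sum(is_mito))
    # on-target knockdown in cells carrying a target's guides
    target_of_guide <- stats::setNames(library$target_gene, library$guide_id)
    for (ci in seq_len(n)) {
      tg <- intersect(target_of_guide[guide_of[[ci]]], targets)
      if (length(tg)) {
        w[match(tg, gene_id), ci] <- w[match(tg, gene_id), ci] *
          config$knockdown_factor
      }
    }
    depth <- config$mean_depth *
      exp(stats::rnorm(n, -config$depth_sd_log^2 / 2, config$depth_sd_log))
    mu <- sweep(w, 2, depth / colSums(w), "*")
    counts <- matrix(stats::rnbinom(g * n, mu = as.vector(mu),
                                    size = 1 / config$nb_dispersion),
                     nrow = g, dimnames = list(gene_id, cell_id))

    umis <- lapply(guide_of, function(gg) {
      stats::rpois(length(gg), config$guide_umi_mean)
    })
    guide_umis <- data.frame(
      cell_id = rep(cell_id, lengths(guide_of)),
      guide_id = unlist(guide_of),
      umis = unlist(umis)
    )
    dataset <- cell_dataset(counts,
                            gene_meta = data.frame(gene_id = gene_id,
                                                   class = gene_class,
                                                   is_mito = is_mito),
                            guide_umis = guide_umis,
                            guide_meta = as.data.frame(library))
    truth_targets <- data.frame(gene = targets)
    idx <- match(targets, config$effect_map$gene)
    truth_targets$delta <- ifelse(is.na(idx), 0, config$effect_map$delta[idx])
    truth_targets$reporter_effect <-
      ifelse(is.na(idx), 0, config$effect_map$reporter_effect[idx])
    list(dataset = dataset,
         truth = list(cells = data.frame(
           cell_id = cell_id, true_t = t_true, delta = delta_eff,
           guides = vapply(guide_of, paste, character(1), collapse = ",")),
           targets = truth_targets))
  })
}

#' Marker gene ids used by the generator
#'
#' Convenience accessors for orienting pseudotime on simulated data.
#' @param config A `sim_config`.
#' @return Character vector of gene ids.
#' @export
progenitor_markers <- function(config) {
  sprintf("PRG%02d", seq_len(config$n_progenitor_markers))
}

#' @rdname progenitor_markers
#' @export
differentiation_markers <- function(config) {
  sprintf("DIF%02d", seq_len(config$n_differentiation_markers))
}

#' Write generator ground truth as TSV
#' @param truth The `truth` element returned by a simulator.
#' @param cells_path,targets_path Output paths.
#' @export
write_ground_truth <- function(truth, cells_path, targets_path) {
  utils::write.table(truth$cells, cells_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(truth$targets, targets_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(cells_path)
}
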