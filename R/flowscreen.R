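# Gene-level scoring of sorted-bin screens: median-of-ratios normalization,
# guide log fold changes, alpha-robust rank aggregation with a permutation
# null, beta scores, and the Fisher-combined pseudo p-value (psi-P).

#' Normalize a guide count table
#'
#' Median-of-ratios size factors computed over guides with nonzero counts
#' in every sample (the stable core of the library); when fewer than
#' `min_ratio_guides` such guides exist the table falls back to
#' total-count scaling.
#'
#' @param x A `guide_counts` object or a plain guides x samples matrix
#'   (>= 2 samples).
#' @param min_ratio_guides Minimum number of all-nonzero guides required
#'   for the median-of-ratios estimator (default 100).
#' @return A list with `normalized` (matrix), `size_factors`, and `method`.
#' @export
normalize_counts <- function(x, min_ratio_guides = 100) {
  m <- if (inherits(x, "guide_counts")) x$counts else as.matrix(x)
  if (ncol(m) < 2) stop("need at least two samples")
  totals <- colSums(m)
  if (any(totals == 0)) stop("sample(s) with all-zero counts: ",
                             paste(colnames(m)[totals == 0], collapse = ", "))
  all_pos <- rowSums(m > 0) == ncol(m)
  if (sum(all_pos) >= min_ratio_guides) {
    lg <- log(m[all_pos, , drop = FALSE])
    ref <- exp(rowMeans(lg))
    sf <- apply(m[all_pos, , drop = FALSE], 2,
                function(col) stats::median(col / ref))
    method <- "median_of_ratios"
  } else {
    sf <- totals / mean(totals)
    method <- "total_count"
  }
  if (any(sf <= 0)) stop("non-positive size factor")
  list(normalized = sweep(m, 2, sf, "/"), size_factors = sf, method = method)
}

#' Guide log2 fold change
#'
#' @param treatment,reference Aligned normalized count vectors.
#' @param pseudocount Added to both sides before the ratio (default 1).
#' @return log2((treatment + pc) / (reference + pc)) per guide.
#' @export
guide_lfc <- function(treatment, reference, pseudocount = 1) {
  if (length(treatment) != length(reference)) {
    stop("treatment and reference must be aligned")
  }
  log2((treatment + pseudocount) / (reference + pseudocount))
}

#' Alpha-RRA rho for one gene
#'
#' For sorted normalized ranks r_1 <= ... <= r_m, only ranks within the
#' top `alpha` fraction qualify; rho is the minimum over qualifying k of
#' the Beta(k, m - k + 1) CDF at r_k (the probability that the k-th order
#' statistic of m uniforms falls that low). rho = 1 when no guide
#' qualifies.
#'
#' @param ranks Normalized ranks in (0, 1] of one gene's guides.
#' @param alpha Qualification cutoff (default 0.25).
#' @return rho in (0, 1].
#' @export
rra_rho <- function(ranks, alpha = 0.25) {
  if (length(ranks) == 0) stop("gene has no guides")
  r <- sort(ranks)
  m <- length(r)
  k <- which(r <= alpha)
  if (length(k) == 0) return(1)
  min(stats::pbeta(r[k], k, m - k + 1))
}

#' Alpha-robust rank aggregation with a permutation null
#'
#' Scores each gene by [rra_rho()] and assigns a permutation p-value by
#' drawing gene-sized rank sets (without replacement) from the background:
#' p = (1 + #\{rho* <= rho\}) / (n_perm + 1). Null draws depend only on the
#' number of guides, so one null distribution per distinct gene size is
#' shared across genes.
#'
#' @param gene_ranks Named list; each element holds one gene's normalized
#'   guide ranks over all `n_guides` guides in the comparison.
#' @param alpha Rank qualification cutoff in (0, 1].
#' @param n_perm Number of permutation draws (>= 1).
#' @param seed Integer seed for the permutation stream.
#' @param n_guides Total guides ranked in the comparison (defines the
#'   uniform background `1/N ... N/N` when `background` is NULL).
#' @param background Optional vector of normalized ranks to draw from
#'   instead (e.g. the ranks of safe-targeting control guides).
#' @return data.frame with `gene`, `m`, `rho`, `p_perm`.
#' @export
alpha_rra <- function(gene_ranks, alpha = 0.25, n_perm = 1000, seed = 1,
                      n_guides = NULL, background = NULL) {
  if (n_perm < 1) stop("n_perm must be >= 1")
  if (length(gene_ranks) == 0) stop("no genes supplied")
  if (alpha <= 0 || alpha > 1) stop("alpha must lie in (0, 1]")
  if (is.null(background)) {
    if (is.null(n_guides)) stop("supply n_guides or background")
    background <- seq_len(n_guides) / n_guides
  }
  rho <- vapply(gene_ranks, rra_rho, numeric(1), alpha = alpha)
  sizes <- lengths(gene_ranks)
  null_by_m <- list()
  with_seed(seed, {
    for (m in sort(unique(sizes))) {
      if (m > length(background)) {
        stop("gene size exceeds the background rank pool")
      }
      null_by_m[[as.character(m)]] <- vapply(seq_len(n_perm), function(i) {
        rra_rho(sample(background, m), alpha = alpha)
      }, numeric(1))
    }
  })
  p <- vapply(seq_along(gene_ranks), function(i) {
    nd <- null_by_m[[as.character(sizes[i])]]
    (1 + sum(nd <= rho[i])) / (n_perm + 1)
  }, numeric(1))
  data.frame(gene = names(gene_ranks), m = as.integer(sizes),
             rho = unname(rho), p_perm = p, row.names = NULL)
}

#' Gene-level beta score
#'
#' Effect-size summary of a gene's guides: the median guide log2 fold
#' change. It flips sign when treatment and reference are swapped.
#'
#' @param lfcs The gene's guide log2 fold changes (>= 1 value).
#' @return The median LFC.
#' @export
beta_score <- function(lfcs) {
  if (length(lfcs) == 0) stop("need at least one guide LFC")
  stats::median(lfcs)
}

#' Combine two sorting-arm p-values into a pseudo p-value (psi-P)
#'
#' Fisher's method: the survival function of chi-squared with 4 df at
#' -2(ln p_a + ln p_b). The two inputs share background samples (each
#' sorting bin sits in the other's reference pool), so the combination is
#' reported as a pseudo p-value rather than a calibrated one.
#'
#' @param p_a,p_b p-values in (0, 1].
#' @return psi-P in (0, 1].
#' @export
combine_pseudo_p <- function(p_a, p_b) {
  if (any(c(p_a, p_b) <= 0) || any(c(p_a, p_b) > 1)) {
    stop("p-values must lie in (0, 1]")
  }
  stats::pchisq(-2 * (log(p_a) + log(p_b)), df = 4, lower.tail = FALSE)
}

default_flow_design <- function() {
  list(high = list(treatment = "high",
                   reference = c("unsorted", "low", "medium")),
       low = list(treatment = "low",
                  reference = c("unsorted", "medium", "high")))
}

#' Score a sorted-bin screen at the gene level
#'
#' Per paired replicate, guides are compared high-vs-rest and low-vs-rest
#' on normalized counts; within-replicate ranks are averaged across
#' replicates and re-ranked before alpha-RRA. Each gene is tested in both
#' orientations and the two directional hypotheses are combined:
#' enrichment in high + depletion in low (knockout raises the reporter:
#' `pro_progenitor`) and depletion in high + enrichment in low (knockout
#' blocks reporter induction: `pro_differentiation`). psi-P is the smaller
#' Fisher combination; direction is its label, or `none` above
#' `psi_alpha`. Safe-targeting guides supply the permutation background.
#'
#' @param counts A `guide_counts` with bins `unsorted`, `low`, `medium`,
#'   `high` for >= 2 replicates.
#' @param library The `guide_library` (must contain safe-targeting guides).
#' @param design Named list of comparisons (`treatment` bin, `reference`
#'   bins); default high-vs-rest and low-vs-rest.
#' @param alpha RRA rank cutoff (default 0.25).
#' @param n_perm Permutation draws per comparison.
#' @param seed Integer seed.
#' @param psi_alpha Significance cutoff for the direction call.
#' @param min_ratio_guides Passed to [normalize_counts()].
#' @return data.frame with one row per gene: `gene`, `n_guides`,
#'   `beta_score`, `rra_rho`, `p_high` (enrichment in the high bin),
#'   `p_low` (depletion in the low bin), `p_high_depleted`,
#'   `p_low_enriched` (the converse comparisons), `psi_p`, `direction`.
#' @export
score_screen <- function(counts, library, design = NULL, alpha = 0.25,
                         n_perm = 1000, seed = 1, psi_alpha = 0.05,
                         min_ratio_guides = 100) {
  stopifnot(inherits(counts, "guide_counts"), inherits(library, "guide_library"))
  if (is.null(design)) design <- default_flow_design()
  samples <- counts$samples
  reps <- unique(samples$replicate_id)
  if (length(reps) < 2) stop("need at least two paired replicates")
  needed <- unique(unlist(lapply(design, function(d) c(d$treatment, d$reference))))
  for (r in reps) {
    have <- samples$bin[samples$replicate_id == r]
    missing <- setdiff(needed, have)
    if (length(missing)) {
      stop("replicate ", r, " lacks bins named in the design: ",
           paste(missing, collapse = ", "))
    }
  }
  safe <- library$guide_id[library$category == "safe_targeting"]
  if (length(safe) == 0) stop("library has no safe_targeting guides")

  norm <- normalize_counts(counts, min_ratio_guides = min_ratio_guides)$normalized
  guides <- rownames(norm)
  n_g <- length(guides)

  # per-replicate LFCs and ranks for each comparison
  lfc <- list(); rank_up <- list(); rank_dn <- list()
  for (cmp in names(design)) {
    lfc_mat <- sapply(reps, function(r) {
      tcol <- samples$sample_id[samples$replicate_id == r &
                                  samples$bin == design[[cmp]]$treatment]
      rcols <- samples$sample_id[samples$replicate_id == r &
                                   samples$bin %in% design[[cmp]]$reference]
      guide_lfc(norm[, tcol], rowMeans(norm[, rcols, drop = FALSE]))
    })
    # average within-replicate ranks, then re-rank to a permutation of i/N
    avg_up <- rowMeans(apply(lfc_mat, 2, function(v) rank(-v)))
    avg_dn <- rowMeans(apply(lfc_mat, 2, function(v) rank(v)))
    lfc[[cmp]] <- rowMeans(lfc_mat)
    rank_up[[cmp]] <- rank(avg_up, ties.method = "average") / n_g
    rank_dn[[cmp]] <- rank(avg_dn, ties.method = "average") / n_g
  }

  gene_of <- stats::setNames(library$target_gene, library$guide_id)
  scored_cat <- library$category %in% c("targeting", "positive_control")
  genes <- unique(library$target_gene[scored_cat])
  split_ranks <- function(rv) {
    lapply(stats::setNames(genes, genes), function(g) {
      unname(rv[guides[gene_of[guides] == g & guides %in%
                         library$guide_id[scored_cat]]])
    })
  }
  run_rra <- function(rv, tag) {
    alpha_rra(split_ranks(rv), alpha = alpha, n_perm = n_perm,
              seed = derive_seed(seed, tag), background = unname(rv[safe]))
  }
  high_up <- run_rra(rank_up$high, "high_up")   # enriched in high
  high_dn <- run_rra(rank_dn$high, "high_dn")   # depleted in high
  low_up <- run_rra(rank_up$low, "low_up")      # enriched in low
  low_dn <- run_rra(rank_dn$low, "low_dn")      # depleted in low

  psi_prog <- combine_pseudo_p(high_up$p_perm, low_dn$p_perm)
  psi_diff <- combine_pseudo_p(high_dn$p_perm, low_up$p_perm)
  prog_wins <- psi_prog <= psi_diff
  psi <- ifelse(prog_wins, psi_prog, psi_diff)
  direction <- ifelse(psi > psi_alpha, "none",
                      ifelse(prog_wins, "pro_progenitor", "pro_differentiation"))
  beta <- vapply(genes, function(g) {
    beta_score(lfc$high[gene_of[guides] == g &
                          guides %in% library$guide_id[scored_cat]])
  }, numeric(1))

  data.frame(
    gene = genes,
    n_guides = high_up$m,
    beta_score = unname(beta),
    rra_rho = ifelse(prog_wins, high_up$rho, high_dn$rho),
    p_high = high_up$p_perm,
    p_low = low_dn$p_perm,
    p_high_depleted = high_dn$p_perm,
    p_low_enriched = low_up$p_perm,
    psi_p = psi,
    direction = direction,
    row.names = NULL
  )
}
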