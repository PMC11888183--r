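# Combine the sorted-bin and Perturb-seq arms into one ranked candidate
# table with a cross-arm concordance correlation.

#' Integrate the two screen arms
#'
#' Joins gene-level results from the sorted-bin arm ([score_screen()]) and
#' the pseudotime arm ([target_phenotypes()]) over their shared genes,
#' reports the Spearman correlation between flow beta scores and
#' pseudotime shift Z scores, and ranks candidates by the mean of the two
#' within-arm effect-size ranks (most pro-differentiation first: negative
#' beta and negative Z rank low). Rank averaging is used instead of a
#' p-value combination because psi-P and the shift p are dependent,
#' differently calibrated quantities.
#'
#' @param flow_results data.frame from [score_screen()].
#' @param perturb_results data.frame from [target_phenotypes()].
#' @return A list: `table` (gene, beta_score, psi_p, z_shift, p_shift_adj,
#'   flow_rank, perturb_rank, combined_rank, concordant) sorted by
#'   combined rank, and `spearman_rho`.
#' @export
integrate_screens <- function(flow_results, perturb_results) {
  shared <- intersect(flow_results$gene, perturb_results$gene)
  if (length(shared) < 3) stop("fewer than 3 genes shared between arms")
  f <- flow_results[match(shared, flow_results$gene), ]
  p <- perturb_results[match(shared, perturb_results$gene), ]
  rho <- stats::cor(f$beta_score, p$z_shift, method = "spearman")
  flow_rank <- rank(f$beta_score, ties.method = "average")
  perturb_rank <- rank(p$z_shift, ties.method = "average")
  tab <- data.frame(
    gene = shared,
    beta_score = f$beta_score,
    psi_p = f$psi_p,
    z_shift = p$z_shift,
    p_shift_adj = p$p_shift_adj,
    flow_rank = flow_rank,
    perturb_rank = perturb_rank,
    combined_rank = (flow_rank + perturb_rank) / 2,
    concordant = sign(f$beta_score) == sign(p$z_shift),
    row.names = NULL
  )
  tab <- tab[order(tab$combined_rank, tab$gene), ]
  rownames(tab) <- NULL
  list(table = tab, spearman_rho = rho)
}
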