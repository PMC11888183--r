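# Shared fixtures, all generated in code.

# Deterministic 20-nt spacer from an index (base-4 encoding).
fixed_spacer <- function(i) {
  digits <- integer(20)
  for (j in seq_len(20)) {
    digits[j] <- i %% 4
    i <- i %/% 4
  }
  paste(c("A", "C", "G", "T")[digits + 1], collapse = "")
}

# Small hand-built guide library: n_genes x gpg targeting guides plus
# safe-targeting and non-targeting controls.
make_library <- function(n_genes = 2, gpg = 2, safe = 2, nt = 1) {
  genes <- sprintf("GENE%03d", seq_len(n_genes))
  df <- data.frame(
    guide_id = c(paste0(rep(genes, each = gpg), "_g",
                        rep(seq_len(gpg), n_genes)),
                 sprintf("SAFE%03d", seq_len(safe)),
                 sprintf("NT%03d", seq_len(nt))),
    target_gene = c(rep(genes, each = gpg), rep("", safe + nt)),
    category = c(rep("targeting", n_genes * gpg),
                 rep("safe_targeting", safe),
                 rep("non_targeting", nt))
  )
  df$spacer <- vapply(seq_len(nrow(df)), fixed_spacer, character(1))
  guide_library(df[c("guide_id", "spacer", "target_gene", "category")])
}

# Small simulation configuration used across module tests.
tiny_sim_config <- function(seed = 1, ...) {
  sim_config(n_target_genes = 6, n_cells = 900, n_expression_genes = 60,
             n_safe_guides = 10, n_nontarget_guides = 6,
             n_flow_cells = 6000, flow_depth = 40000,
             effect_map = data.frame(gene = "GENE001", delta = -0.4,
                                     reporter_effect = -1.8),
             seed = seed, ...)
}

null_effect_map <- function() {
  data.frame(gene = character(), delta = numeric(),
             reporter_effect = numeric())
}

# Build a cell_dataset directly from a dense counts matrix.
make_dataset <- function(counts, mito_genes = character(),
                         guide_umis = NULL, library = NULL) {
  gene_meta <- data.frame(gene_id = rownames(counts),
                          is_mito = rownames(counts) %in% mito_genes)
  if (is.null(guide_umis)) {
    guide_umis <- data.frame(cell_id = character(), guide_id = character(),
                             umis = numeric())
  }
  cell_dataset(counts, gene_meta, guide_umis,
               guide_meta = if (is.null(library)) NULL else
                 as.data.frame(library))
}

# Exhaustive Mann-Whitney oracle: p = fraction of equally likely rank
# assignments whose U is at least as extreme as observed.
enumerate_mw_p <- function(x, y, alternative) {
  n1 <- length(x)
  pooled <- c(x, y)
  r <- rank(pooled)
  u_obs <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  combos <- utils::combn(length(pooled), n1)
  u_all <- apply(combos, 2, function(idx) sum(r[idx]) - n1 * (n1 + 1) / 2)
  if (alternative == "less") mean(u_all <= u_obs) else mean(u_all >= u_obs)
}
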