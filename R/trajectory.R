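# Pseudotime inference: correlation distance -> classical MDS (10 dims by
# default) -> iterative principal curve -> oriented pseudotime in [0, 1].

#' Pearson correlation distance between cells
#'
#' d(i, j) = 1 - Pearson(x_i, x_j) over the feature profiles of cells i
#' and j; symmetric, zero diagonal, range [0, 2].
#'
#' @param x Features x cells matrix (>= 2 features; every cell must vary
#'   across features).
#' @return Cells x cells distance matrix.
#' @export
correlation_distance <- function(x) {
  if (nrow(x) < 2) stop("need at least two features")
  s <- apply(x, 2, stats::sd)
  if (any(s == 0)) stop("cell(s) with zero variance across features")
  d <- 1 - stats::cor(x)
  diag(d) <- 0
  d
}

#' Classical multidimensional scaling of a distance matrix
#'
#' Double-centers the squared distances into a Gram matrix and
#' eigen-decomposes it; coordinates are the top-k eigenvectors scaled by
#' the square roots of their (non-negative) eigenvalues. Dimensions whose
#' eigenvalue is not positive collapse to zero columns. Each axis is given
#' a deterministic sign: the largest-magnitude loading is positive.
#'
#' @param d Symmetric distance matrix.
#' @param k Number of embedding dimensions (default 10; at most n - 1).
#' @return A list of class `embedding`: `coords` (n x k),
#'   `eigenvalues` (length k).
#' @export
reduce_dims <- function(d, k = 10) {
  d <- as.matrix(d)
  n <- nrow(d)
  if (n != ncol(d)) stop("distance matrix must be square")
  if (k > n - 1) stop("k must be at most n - 1")
  b <- -0.5 * d^2
  b <- sweep(b, 1, rowMeans(b))
  b <- sweep(b, 2, colMeans(b))
  b <- b + mean(-0.5 * d^2)  # correct double subtraction of the grand mean
  e <- eigen((b + t(b)) / 2, symmetric = TRUE)
  ev <- e$values[seq_len(k)]
  coords <- matrix(0, n, k, dimnames = list(rownames(d), NULL))
  pos <- which(ev > max(ev[1], 0) * 1e-12 & ev > 0)
  for (j in pos) {
    v <- e$vectors[, j] * sqrt(ev[j])
    if (v[which.max(abs(v))] < 0) v <- -v
    coords[, j] <- v
  }
  structure(list(coords = coords, eigenvalues = pmax(ev, 0)),
            class = "embedding")
}

#' Embed cells by correlation distance, scaling to large n with landmarks
#'
#' For up to `n_landmarks` cells this is exactly
#' `reduce_dims(correlation_distance(x), k)`. Beyond that, a seeded
#' landmark subset is embedded by classical MDS and the remaining cells
#' are projected onto the same axes from their squared distances to the
#' landmarks (Nystrom projection), so the full n x n distance matrix is
#' never formed.
#'
#' @param x Features x cells normalized matrix.
#' @param k Embedding dimensions (default 10).
#' @param n_landmarks Landmark budget (default 500).
#' @param seed Seed for the landmark draw.
#' @return An `embedding` (coords carry cell names).
#' @export
embed_cells <- function(x, k = 10, n_landmarks = 500, seed = 1) {
  n <- ncol(x)
  if (n <= n_landmarks) {
    emb <- reduce_dims(correlation_distance(x), k = min(k, n - 1))
    rownames(emb$coords) <- colnames(x)
    return(emb)
  }
  lm_idx <- with_seed(seed, sort(sample.int(n, n_landmarks)))
  # correlation between cell columns = crossprod of standardized profiles
  cs <- scale(x, center = TRUE, scale = TRUE)
  cs[is.na(cs)] <- 0
  p <- nrow(x)
  cor_al <- crossprod(cs, cs[, lm_idx, drop = FALSE]) / (p - 1)
  d2_al <- (1 - cor_al)^2
  d_ll <- 1 - cor_al[lm_idx, , drop = FALSE]
  diag(d_ll) <- 0
  emb_l <- reduce_dims(d_ll, k = k)
  pos <- emb_l$eigenvalues > 0
  v <- matrix(0, n_landmarks, k)
  v[, pos] <- sweep(emb_l$coords[, pos, drop = FALSE], 2,
                    sqrt(emb_l$eigenvalues[pos]), "/")
  mu <- colMeans(d_ll^2)
  coords <- matrix(0, n, k, dimnames = list(colnames(x), NULL))
  proj <- -0.5 * sweep(d2_al, 2, mu) %*% v
  coords[, pos] <- sweep(proj[, pos, drop = FALSE], 2,
                         sqrt(emb_l$eigenvalues[pos]), "/")
  structure(list(coords = coords, eigenvalues = emb_l$eigenvalues,
                 landmarks = lm_idx), class = "embedding")
}

project_polyline <- function(x, nodes) {
  n <- nrow(x)
  nseg <- nrow(nodes) - 1
  seg <- diff(nodes)
  seglen <- sqrt(rowSums(seg^2))
  cum <- c(0, cumsum(seglen))
  rx2 <- rowSums(x^2)
  best_d2 <- rep(Inf, n)
  best_arc <- numeric(n)
  for (s in seq_len(nseg)) {
    a <- nodes[s, ]
    d <- seg[s, ]
    l2 <- sum(d^2)
    xa <- as.vector(x %*% a)
    if (l2 == 0) {
      xd <- numeric(n)
      tt <- numeric(n)
    } else {
      xd <- as.vector(x %*% d)
      tt <- pmin(1, pmax(0, (xd - sum(a * d)) / l2))
    }
    # |x - a - t d|^2 = |x|^2 - 2 x.a + |a|^2 - 2 t (x.d - a.d) + t^2 |d|^2
    d2 <- rx2 - 2 * xa + sum(a^2) -
      2 * tt * (xd - sum(a * d)) + tt^2 * l2
    upd <- d2 < best_d2
    best_d2[upd] <- d2[upd]
    best_arc[upd] <- cum[s] + tt[upd] * seglen[s]
  }
  list(arclength = best_arc, total = cum[nseg + 1], dist2 = best_d2)
}

#' Fit a principal curve and read off pseudotime
#'
#' Iterates the classic projection/smoothing loop: order cells along the
#' current curve position (initialized from the first embedding axis),
#' smooth each embedding coordinate against that order with a centered
#' rolling mean spanning `smooth_frac` of the cells, downsample the
#' smoothed path to `n_nodes` nodes, and project every cell onto the
#' resulting piecewise-linear curve. Convergence is declared when the mean
#' absolute change in normalized arc-length position drops below `tol`;
#' otherwise the best iterate is returned with `converged = FALSE`.
#' Pseudotime is the arc-length position min-max rescaled to [0, 1].
#'
#' @param embedding An `embedding` or a plain cells x k coordinate matrix
#'   (>= 3 cells).
#' @param max_iter,tol Iteration cap and convergence tolerance.
#' @param smooth_frac Rolling-mean span as a fraction of cells.
#' @param n_nodes Curve nodes after downsampling.
#' @param seed Unused by the deterministic fit; kept so callers can thread
#'   a seed uniformly through the pipeline.
#' @return A list of class `pseudotime_result`: `pseudotime` (named,
#'   in [0, 1]), `nodes` (ordered curve coordinates), `orientation_flipped`,
#'   `iterations`, `converged`.
#' @export
fit_principal_curve <- function(embedding, max_iter = 100, tol = 1e-4,
                                smooth_frac = 0.1, n_nodes = 100,
                                seed = NULL) {
  x <- if (inherits(embedding, "embedding")) embedding$coords else
    as.matrix(embedding)
  n <- nrow(x)
  if (n < 3) stop("need at least three cells")
  pos <- (rank(x[, 1], ties.method = "first") - 1) / (n - 1)
  w <- max(3L, round(smooth_frac * n))
  nodes <- NULL
  iterations <- 0L
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    iterations <- it
    ord <- order(pos, x[, 1])
    sm <- apply(x[ord, , drop = FALSE], 2, rolling_mean, w = w)
    idx <- unique(round(seq(1, n, length.out = min(n_nodes, n))))
    nodes <- sm[idx, , drop = FALSE]
    pr <- project_polyline(x, nodes)
    newpos <- if (pr$total > 0) pr$arclength / pr$total else
      (rank(pr$arclength, ties.method = "first") - 1) / (n - 1)
    delta <- mean(abs(newpos - pos))
    pos <- newpos
    if (delta < tol) {
      converged <- TRUE
      break
    }
  }
  structure(list(pseudotime = stats::setNames(minmax(pos), rownames(x)),
                 nodes = nodes, orientation_flipped = FALSE,
                 iterations = iterations, converged = converged),
            class = "pseudotime_result")
}

#' Orient pseudotime so progenitors sit at t = 0
#'
#' Flips t to 1 - t if and only if mean progenitor-marker expression
#' correlates positively with pseudotime, guaranteeing progenitor-high
#' cells at the origin and differentiation-marker-high cells at t = 1.
#'
#' @param result A `pseudotime_result`.
#' @param normalized Genes x cells normalized expression over the same
#'   cells.
#' @param progenitor_markers,differentiation_markers Marker gene ids; all
#'   must be present in `normalized`.
#' @return The (possibly flipped) `pseudotime_result`.
#' @export
orient_pseudotime <- function(result, normalized, progenitor_markers,
                              differentiation_markers) {
  stopifnot(inherits(result, "pseudotime_result"))
  missing <- setdiff(c(progenitor_markers, differentiation_markers),
                     rownames(normalized))
  if (length(missing)) {
    stop("marker gene(s) absent from the expression matrix: ",
         paste(missing, collapse = ", "))
  }
  cells <- names(result$pseudotime)
  prog <- colMeans(normalized[progenitor_markers, cells, drop = FALSE])
  if (stats::cor(prog, result$pseudotime) > 0) {
    result$pseudotime <- 1 - result$pseudotime
    result$nodes <- result$nodes[rev(seq_len(nrow(result$nodes))), ,
                                 drop = FALSE]
    result$orientation_flipped <- !result$orientation_flipped
  }
  result
}

#' Infer oriented pseudotime from normalized expression
#'
#' Convenience driver chaining feature subsetting, correlation-distance
#' embedding (landmark MDS for large n), principal-curve fitting and
#' marker orientation.
#'
#' @param normalized Genes x cells normalized matrix.
#' @param features Feature subset for the distance computation (default:
#'   all rows).
#' @param progenitor_markers,differentiation_markers Marker ids used to
#'   orient the axis.
#' @param k Embedding dimensions (default 10).
#' @param n_landmarks Landmark budget for large datasets.
#' @param seed Integer seed (landmark draw).
#' @param ... Passed to [fit_principal_curve()].
#' @return A `pseudotime_result`.
#' @export
infer_pseudotime <- function(normalized, features = NULL,
                             progenitor_markers = NULL,
                             differentiation_markers = NULL,
                             k = 10, n_landmarks = 500, seed = 1, ...) {
  x <- if (is.null(features)) normalized else
    normalized[features, , drop = FALSE]
  emb <- embed_cells(x, k = k, n_landmarks = n_landmarks, seed = seed)
  res <- fit_principal_curve(emb, ...)
  if (!is.null(progenitor_markers)) {
    res <- orient_pseudotime(res, normalized, progenitor_markers,
                             differentiation_markers)
  }
  res
}

#' Write pseudotime and embedding TSVs
#' @param result A `pseudotime_result`.
#' @param path Output TSV (`cell_id`, `pseudotime`).
#' @export
write_pseudotime <- function(result, path) {
  utils::write.table(
    data.frame(cell_id = names(result$pseudotime),
               pseudotime = unname(result$pseudotime)),
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a pseudotime TSV (interoperability with external trajectory tools)
#' @param path TSV with columns `cell_id`, `pseudotime`.
#' @return A named pseudotime vector.
#' @export
read_pseudotime <- function(path) {
  df <- utils::read.delim(path)
  stats::setNames(df$pseudotime, df$cell_id)
}
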