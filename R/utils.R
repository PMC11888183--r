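# Internal helpers shared across modules.

#' Evaluate code under a temporary RNG seed
#'
#' Restores the caller's RNG state afterwards so seeded helpers do not
#' perturb the global random stream.
#' @noRd
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (has_old) {
        assign(".Random.seed", old, envir = globalenv())
      } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    }, add = TRUE)
    set.seed(as.integer(seed))
  }
  force(code)
}

#' Derive a stage-specific sub-seed from a global seed
#'
#' Deterministic polynomial hash of the stage name folded into the seed, so
#' adding a stage never perturbs the random stream of earlier stages.
#' All arithmetic stays below 2^31.
#'
#' @param seed Integer global seed.
#' @param stage Character stage label.
#' @return An integer seed in `[0, 2^31 - 2]`.
#' @export
derive_seed <- function(seed, stage) {
  stopifnot(is.numeric(seed), length(seed) == 1, is.character(stage), length(stage) == 1)
  h <- 0
  for (ch in utf8ToInt(stage)) h <- (h * 131 + ch) %% 1000000007
  as.integer((as.numeric(seed) %% 2147483647 + h) %% 2147483647)
}

#' Centered rolling mean with shrinking windows at the edges
#' @noRd
rolling_mean <- function(x, w) {
  n <- length(x)
  h <- max(1L, floor(w / 2))
  cs <- cumsum(c(0, x))
  lo <- pmax(seq_len(n) - h, 1L)
  hi <- pmin(seq_len(n) + h, n)
  (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
}

#' Min-max rescale to [0, 1]; constant input maps to 0
#' @noRd
minmax <- function(x) {
  r <- range(x)
  if (r[2] - r[1] <= 0) return(rep(0, length(x)))
  (x - r[1]) / (r[2] - r[1])
}

#' Truncated (zero-excluded) Poisson sampler
#'
#' Models lentiviral integrations after drug selection: every surviving cell
#' carries at least one integration; multiplicities follow Poisson(moi)
#' conditioned on being positive.
#' @noRd
rpois_positive <- function(n, lambda) {
  u <- runif(n, min = stats::dpois(0, lambda), max = 1)
  stats::qpois(u, lambda)
}
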