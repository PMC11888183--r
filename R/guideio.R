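# Guide library and count-table containers, UMI-aware counting and
# library-representation QC.

GUIDE_CATEGORIES <- c("targeting", "safe_targeting", "non_targeting",
                      "positive_control")

#' Construct and validate a guide library
#'
#' A guide library is a data.frame with one row per sgRNA and the fixed
#' column order `guide_id`, `spacer`, `target_gene`, `category`. Targeting
#' and positive-control guides must name a target gene; control guides
#' (safe-targeting cuts at phenotypically neutral loci, non-targeting
#' spacers) leave it empty.
#'
#' @param df A data.frame with the four columns above.
#' @return The validated library, classed `guide_library`.
#' @export
guide_library <- function(df) {
  required <- c("guide_id", "spacer", "target_gene", "category")
  if (!all(required %in% names(df))) {
    stop("guide library needs columns: ", paste(required, collapse = ", "))
  }
  df <- as.data.frame(df)[required]
  df[] <- lapply(df, as.character)
  if (anyDuplicated(df$guide_id)) stop("guide_id values must be unique")
  if (!all(nchar(df$spacer) == 20L)) stop("spacers must be 20 nt long")
  if (!all(grepl("^[ACGT]{20}$", df$spacer))) {
    stop("spacers must be over the ACGT alphabet")
  }
  if (!all(df$category %in% GUIDE_CATEGORIES)) {
    stop("unknown guide category; allowed: ",
         paste(GUIDE_CATEGORIES, collapse = ", "))
  }
  needs_gene <- df$category %in% c("targeting", "positive_control")
  if (any(needs_gene & !nzchar(df$target_gene))) {
    stop("targeting and positive_control guides must have a target_gene")
  }
  rownames(df) <- NULL
  class(df) <- c("guide_library", "data.frame")
  df
}

#' Read a guide library from TSV
#' @param path Path to a tab-separated file with the documented columns.
#' @return A `guide_library`.
#' @export
read_guide_library <- function(path) {
  df <- utils::read.delim(path, colClasses = "character")
  guide_library(df)
}

#' Write a guide library to TSV
#' @param library A `guide_library`.
#' @param path Output path.
#' @export
write_guide_library <- function(library, path) {
  utils::write.table(as.data.frame(library), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Construct a guide UMI count table
#'
#' Guides x samples matrix of non-negative integer UMI counts plus
#' per-sample metadata (`sample_id`, `replicate_id`, `bin`).
#'
#' @param counts Integer matrix, rownames = guide ids, colnames = sample ids.
#' @param samples data.frame with columns `sample_id`, `replicate_id`, `bin`.
#' @return An object of class `guide_counts`.
#' @export
guide_counts <- function(counts, samples) {
  counts <- as.matrix(counts)
  storage.mode(counts) <- "double"
  if (is.null(rownames(counts))) stop("counts must have guide_id rownames")
  if (any(counts < 0) || any(counts != round(counts))) {
    stop("counts must be non-negative integers")
  }
  required <- c("sample_id", "replicate_id", "bin")
  if (!all(required %in% names(samples))) {
    stop("samples needs columns: ", paste(required, collapse = ", "))
  }
  samples <- as.data.frame(samples)[required]
  samples[] <- lapply(samples, as.character)
  if (!identical(colnames(counts), samples$sample_id)) {
    stop("counts columns must match samples$sample_id in order")
  }
  allowed_bins <- c("unsorted", "low", "medium", "high", "plasmid")
  if (!all(samples$bin %in% allowed_bins)) {
    stop("bins must be one of: ", paste(allowed_bins, collapse = ", "))
  }
  structure(list(counts = counts, samples = samples), class = "guide_counts")
}

#' Read/write a guide count table as paired TSV files
#'
#' The counts file has a `guide_id` column followed by one column per
#' sample; the samples file carries the per-sample metadata. The pair
#' round-trips losslessly.
#'
#' @param counts_path,samples_path Paths for the two TSV files.
#' @return `read_guide_counts` returns a `guide_counts`.
#' @export
read_guide_counts <- function(counts_path, samples_path) {
  cts <- utils::read.delim(counts_path, check.names = FALSE,
                           colClasses = NA)
  samples <- utils::read.delim(samples_path, colClasses = "character")
  m <- as.matrix(cts[, -1, drop = FALSE])
  rownames(m) <- cts$guide_id
  guide_counts(m, samples)
}

#' @rdname read_guide_counts
#' @param x A `guide_counts` object.
#' @export
write_guide_counts <- function(x, counts_path, samples_path) {
  stopifnot(inherits(x, "guide_counts"))
  out <- data.frame(guide_id = rownames(x$counts), x$counts,
                    check.names = FALSE)
  utils::write.table(out, counts_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(x$samples, samples_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(counts_path)
}

#' Count distinct UMIs per guide for one sample
#'
#' Screen libraries carry a 9-bp degenerate UMI so molecules, not PCR
#' duplicates, are counted: a guide's count is the number of distinct
#' 9-nt UMI strings observed for it (exact-match deduplication; no
#' mismatch collapsing). Observations with an unknown guide id or a
#' malformed UMI are diverted to a rejected-observations log rather than
#' aborting the run, since real screens contain recombined reads.
#'
#' @param observations data.frame with columns `guide_id`, `umi`.
#' @param library A `guide_library` defining the counting universe.
#' @param sample_id Label for the resulting column.
#' @return A list with `counts` (named integer vector over all library
#'   guides, zeros for unobserved guides), `sample_id`, and `rejected`
#'   (data.frame of discarded observations with a `reason` column).
#' @export
count_guide_umis <- function(observations, library, sample_id = "sample") {
  stopifnot(inherits(library, "guide_library"))
  obs <- as.data.frame(observations)
  if (nrow(obs) > 0 && !all(c("guide_id", "umi") %in% names(obs))) {
    stop("observations needs columns guide_id and umi")
  }
  counts <- stats::setNames(integer(nrow(library)), library$guide_id)
  rejected <- data.frame(guide_id = character(), umi = character(),
                         reason = character())
  if (nrow(obs) > 0) {
    bad_umi <- !grepl("^[ACGT]{9}$", obs$umi)
    unknown <- !(obs$guide_id %in% library$guide_id)
    reason <- ifelse(bad_umi, "malformed_umi",
                     ifelse(unknown, "unknown_guide", NA))
    keep <- is.na(reason)
    rejected <- data.frame(guide_id = obs$guide_id[!keep],
                           umi = obs$umi[!keep],
                           reason = reason[!keep])
    ok <- obs[keep, , drop = FALSE]
    if (nrow(ok) > 0) {
      dedup <- unique(ok[c("guide_id", "umi")])
      tab <- table(dedup$guide_id)
      counts[names(tab)] <- as.integer(tab)
    }
  }
  list(counts = counts, sample_id = sample_id, rejected = rejected)
}

#' Gini coefficient by the sorted-rank formula
#'
#' Equivalent to the mean-absolute-difference definition
#' sum|xi - xj| / (2 n^2 mean).
#' @noRd
gini_coefficient <- function(x) {
  n <- length(x)
  mu <- mean(x)
  if (mu == 0) return(0)
  xs <- sort(x)
  sum((2 * seq_len(n) - n - 1) * xs) / (n^2 * mu)
}

#' Library representation QC: coverage, skew and tail ratio
#'
#' Plasmid-pool quality control checks that the designed library is fully
#' represented with minimal skew before screening.
#'
#' @param counts Named count vector (one sample column), aligned to the
#'   library by guide id; guides absent from `counts` score 0.
#' @param library A `guide_library`.
#' @return A list with `coverage` (fraction of designed guides observed at
#'   least once), `gini` (0 = perfectly even representation), and
#'   `ratio_90_10` (90th/10th percentile count; `Inf` when the 10th
#'   percentile is 0).
#' @export
library_skew <- function(counts, library) {
  stopifnot(inherits(library, "guide_library"))
  if (nrow(library) == 0) stop("library is empty")
  x <- stats::setNames(numeric(nrow(library)), library$guide_id)
  shared <- intersect(names(counts), names(x))
  x[shared] <- counts[shared]
  if (is.null(names(counts))) {
    if (length(counts) != nrow(library)) {
      stop("unnamed counts must have one entry per library guide")
    }
    x[] <- counts
  }
  q <- stats::quantile(x, c(0.1, 0.9), names = FALSE, type = 7)
  list(coverage = mean(x >= 1),
       gini = gini_coefficient(x),
       ratio_90_10 = if (q[1] == 0) Inf else q[2] / q[1])
}
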