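#' Rarefy a feature table to a common depth
#'
#' Subsamples each sample's reads without replacement (a multivariate
#' hypergeometric draw) down to exactly `depth` reads. Samples whose total is
#' below `depth` are dropped and reported; samples already at `depth` are
#' returned unchanged. Draws are taken per sample from a single seeded
#' generator in sample-id sort order, so the result does not depend on input
#' row order.
#'
#' @param features a feature-table tibble (`sample_id` plus integer SV
#'   columns).
#' @param depth target reads per sample (default 1250).
#' @param seed integer seed.
#' @param quiet suppress the dropped-sample message.
#' @return the rarefied feature table (rows in sample-id order); dropped
#'   samples are recorded in the `"dropped"` attribute as a tibble of
#'   `sample_id` and `total`.
#' @examples
#' ft <- tibble::tibble(sample_id = c("a", "b"), sv1 = c(900L, 700L),
#'                      sv2 = c(600L, 100L))
#' rarefy(ft, depth = 1000, seed = 1)
#' @export
rarefy <- function(features, depth = 1250, seed = 1, quiet = FALSE) {
  if (depth < 1) abort("depth must be a positive integer")
  m <- ft_matrix(features)
  m <- m[order(rownames(m)), , drop = FALSE]
  totals <- rowSums(m)
  keep <- totals >= depth
  dropped <- tibble::tibble(sample_id = rownames(m)[!keep],
                            total = unname(totals[!keep]))
  if (!quiet && nrow(dropped) > 0) {
    inform(sprintf("rarefy: dropped %d sample(s) with fewer than %d reads",
                   nrow(dropped), depth))
  }
  m <- m[keep, , drop = FALSE]
  if (nrow(m) == 0) {
    abort(sprintf("all samples fall below depth %d; depth too high", depth))
  }
  set.seed(seed)
  out <- m
  for (i in seq_len(nrow(m))) {
    if (totals[rownames(m)[i]] == depth) next
    reads <- rep.int(seq_len(ncol(m)), m[i, ])
    kept <- sample(reads, depth)
    out[i, ] <- tabulate(kept, nbins = ncol(m))
  }
  res <- ft_tibble(out)
  attr(res, "dropped") <- dropped
  attr(res, "depth") <- as.integer(depth)
  res
}

#' Per-sample alpha diversity: SV richness and Shannon index
#'
#' Richness is the number of SVs observed (count > 0) in a sample; the
#' Shannon index is the entropy of the sample's relative abundances,
#' `H = -sum(p_i * log2(p_i))`, reported in bits (base 2, the QIIME 2
#' convention; set `shannon_base` for another base). Samples with zero total
#' reads get richness 0 and Shannon 0. The table should normally be rarefied
#' to a common depth first so values are comparable across samples.
#'
#' @param features a feature-table tibble.
#' @param shannon_base logarithm base for the Shannon index (default 2).
#' @return a tibble with columns `sample_id`, `richness`, `shannon`.
#' @examples
#' ft <- tibble::tibble(sample_id = "a", x = 1L, y = 1L, z = 1L, w = 1L)
#' alpha_diversity(ft) # richness 4, shannon 2 bits
#' @export
alpha_diversity <- function(features, shannon_base = 2) {
  m <- ft_matrix(features)
  richness <- as.integer(rowSums(m > 0))
  shannon <- as.numeric(vegan::diversity(m, index = "shannon",
                                         base = shannon_base))
  shannon[rowSums(m) == 0] <- 0
  tibble::tibble(sample_id = rownames(m), richness = richness,
                 shannon = shannon)
}
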