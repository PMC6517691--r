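# Independent oracle implementations used to cross-check the package's
# computational paths. These deliberately use naive O(n^2) / enumeration
# formulations rather than anything the implementation calls.

# Shannon entropy in bits by direct summation over positive counts.
shannon_hand <- function(x) {
  tot <- sum(x)
  if (tot == 0) return(0)
  p <- x[x > 0] / tot
  -sum(p * log2(p))
}

# Benjamini-Hochberg step-up by the textbook definition: for each p_i,
# the adjusted value is min over all j with p_(j) >= p_i of m * p_(j) / j,
# capped at 1.
bh_hand <- function(p) {
  m <- length(p)
  ord <- order(p)
  ranked <- p[ord]
  adj <- numeric(m)
  for (i in seq_len(m)) {
    candidates <- vapply(i:m, function(j) m * ranked[j] / j, numeric(1))
    adj[i] <- min(1, min(candidates))
  }
  out <- numeric(m)
  out[ord] <- adj
  out
}

# Exact two-sided Wilcoxon rank-sum p by full enumeration of all
# choose(nx+ny, nx) assignments of the ranks to group x. Assumes no ties.
# Returns the Mann-Whitney U-style p matching wilcox.test's convention
# p = min(1, 2 * min(P(W <= w), P(W >= w))).
wilcox_enum_null <- function(nx, ny) {
  combos <- utils::combn(nx + ny, nx)
  colSums(matrix(seq_len(nx + ny)[combos], nrow = nx)) - nx * (nx + 1) / 2
}

wilcox_enum_p <- function(x, y, null_w = NULL) {
  nx <- length(x); ny <- length(y)
  if (is.null(null_w)) null_w <- wilcox_enum_null(nx, ny)
  r <- rank(c(x, y))
  w <- sum(r[seq_len(nx)]) - nx * (nx + 1) / 2
  lower <- mean(null_w <= w)
  upper <- mean(null_w >= w)
  min(1, 2 * min(lower, upper))
}

# Small handmade feature table used across IO/diversity tests.
toy_features <- function() {
  tibble::tibble(
    sample_id = c("s1", "s2", "s3"),
    SV_a = c(500L, 400L, 5L),
    SV_b = c(500L, 300L, 0L),
    SV_c = c(250L, 300L, 2L)
  )
}

# A quick small simulated cohort already rarefied, shared by several tests.
quick_cohort <- function(n = 300, seed = 42, depth = 1250, ...) {
  sim <- simulate_cohort(cohort_scenario(n_subjects = n, seed = seed, ...))
  rare <- rarefy(sim$features, depth = depth, seed = seed + 1, quiet = TRUE)
  div <- alpha_diversity(rare)
  list(sim = sim, rare = rare, div = div,
       data = dplyr::inner_join(div, sim$metadata, by = "sample_id"))
}

# Handmade two-sex table in which one SV's relative abundance is an exact
# monotone function of age: age-informative by construction.
monotone_table <- function(n = 300, seed = 1, age_range = c(20, 69)) {
  set.seed(seed)
  age <- sample(seq(age_range[1], age_range[2]), n, replace = TRUE)
  sex <- rep_len(c("female", "male"), n)
  depth <- 5000L
  signal <- as.integer(round(depth * (0.1 + 0.6 * (age - age_range[1]) /
                                        diff(age_range))))
  features <- tibble::tibble(
    sample_id = sprintf("m%04d", seq_len(n)),
    SV_signal = signal,
    SV_filler = depth - signal
  )
  metadata <- tibble::tibble(sample_id = features$sample_id,
                             age = age, sex = sex,
                             age_group = derive_age_group(age))
  list(features = features, metadata = metadata)
}
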