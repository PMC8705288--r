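# Independent oracles and small fixture builders. These deliberately use
# naive loop-based computation so they share no code path with the package.

# between-class-variance maximizer by exhaustive search over thresholds;
# foreground = value strictly greater than threshold, smallest tie wins
brute_otsu <- function(values, counts) {
  keep <- counts > 0
  values <- values[keep]; counts <- counts[keep]
  o <- order(values)
  values <- values[o]; counts <- counts[o]
  n <- sum(counts)
  vars <- numeric(length(values) - 1L)
  for (t in seq_len(length(values) - 1L)) {
    lo <- seq_len(t)
    hi <- seq.int(t + 1L, length(values))
    w0 <- sum(counts[lo]) / n
    w1 <- 1 - w0
    m0 <- sum(counts[lo] * values[lo]) / sum(counts[lo])
    m1 <- sum(counts[hi] * values[hi]) / sum(counts[hi])
    vars[t] <- w0 * w1 * (m0 - m1)^2
  }
  # smallest threshold among numerically tied maxima
  values[min(which(vars >= max(vars) * (1 - 1e-9)))]
}

# AUC as the pairwise-ranking probability, ties counted one half
pairwise_auc <- function(pos_scores, neg_scores) {
  total <- 0
  for (p in pos_scores) {
    for (q in neg_scores) {
      total <- total + (p > q) + 0.5 * (p == q)
    }
  }
  total / (length(pos_scores) * length(neg_scores))
}

# voxel counting by explicit iteration over an index subset of one axis
brute_counts <- function(labels, mask, axis = NULL, range = NULL) {
  d <- dim(labels)
  counts <- c(Vb = 0L, Vwt = 0L, Vet = 0L, Vncr = 0L, Ved = 0L)
  for (i in seq_len(d[1])) for (j in seq_len(d[2])) for (k in seq_len(d[3])) {
    if (!is.null(axis)) {
      pos <- c(i, j, k)[axis]
      if (!(pos %in% range)) next
    }
    l <- labels[i, j, k]
    if (mask[i, j, k]) counts["Vb"] <- counts["Vb"] + 1L
    if (l == 1L) counts["Vncr"] <- counts["Vncr"] + 1L
    if (l == 2L) counts["Ved"] <- counts["Ved"] + 1L
    if (l == 4L) counts["Vet"] <- counts["Vet"] + 1L
  }
  counts["Vwt"] <- counts["Vet"] + counts["Vncr"] + counts["Ved"]
  counts
}

# small random labeled volume with intensity, valid labels only
random_tiny_volume <- function(seed, shape = c(7L, 6L, 5L)) {
  set.seed(seed)
  labels <- array(sample(c(0L, 0L, 0L, 1L, 2L, 4L), prod(shape), replace = TRUE),
                  shape)
  intensity <- array(ifelse(labels == 0L,
                            sample(c(0, 100), prod(shape), replace = TRUE),
                            100 + rnorm(prod(shape))),
                     shape)
  labeled_volume(labels, intensity, sprintf("tiny_%d", seed))
}

tiny_cohort <- function(seed = 11L, n = c(4L, 4L, 4L)) {
  generate_cohort(cohort_config(n_short = n[1], n_mid = n[2], n_long = n[3],
                                preset = "tiny", seed = seed))
}
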