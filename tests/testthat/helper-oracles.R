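# Independent brute-force oracles, kept deliberately naive and separate from
# the implementation paths they check.

oracle_entropy <- function(labels) {
  n <- length(labels)
  cls <- unique(labels)
  h <- 0
  for (c in cls) {
    p <- sum(labels == c) / n
    if (p > 0) h <- h - p * log2(p)
  }
  h
}

# chi-square by an explicit double loop over cells
oracle_chi2 <- function(counts) {
  counts <- as.matrix(counts)
  keep <- colSums(counts) > 0
  counts <- counts[, keep, drop = FALSE]
  m <- sum(counts)
  stat <- 0
  for (k in seq_len(nrow(counts))) {
    for (j in seq_len(ncol(counts))) {
      e <- sum(counts[k, ]) * sum(counts[, j]) / m
      if (e > 0) stat <- stat + (counts[k, j] - e)^2 / e
    }
  }
  unname(stat)
}

# information gain as an explicit entropy difference
oracle_ig <- function(counts) {
  counts <- as.matrix(counts)
  counts <- counts[, colSums(counts) > 0, drop = FALSE]
  m <- sum(counts)
  h_t <- oracle_entropy(rep(seq_len(nrow(counts)), rowSums(counts)))
  h_cond <- 0
  for (j in seq_len(ncol(counts))) {
    mj <- sum(counts[, j])
    h_cond <- h_cond + (mj / m) * oracle_entropy(rep(seq_len(nrow(counts)), counts[, j]))
  }
  unname(h_t - h_cond)
}

# KL composition: column-weighted KL(P(T|b_j) || P(T)) over split information
oracle_kl <- function(counts) {
  counts <- as.matrix(counts)
  counts <- counts[, colSums(counts) > 0, drop = FALSE]
  m <- sum(counts)
  p_t <- rowSums(counts) / m
  num <- 0
  split_info <- 0
  for (j in seq_len(ncol(counts))) {
    mj <- sum(counts[, j])
    pj <- mj / m
    split_info <- split_info - pj * log2(pj)
    kl <- 0
    for (k in seq_len(nrow(counts))) {
      pc <- counts[k, j] / mj
      if (pc > 0) kl <- kl + pc * log2(pc / p_t[k])
    }
    num <- num + pj * kl
  }
  if (split_info <= 0) return(0)
  unname(num / split_info)
}

# exhaustive minimum-entropy cut over ALL successive distinct-value midpoints
oracle_best_cut <- function(values, labels) {
  ord <- order(values)
  values <- values[ord]
  labels <- labels[ord]
  uv <- unique(values)
  if (length(uv) < 2) return(NULL)
  mids <- (uv[-length(uv)] + uv[-1]) / 2
  best <- NULL
  for (cut in mids) {
    left <- labels[values < cut]
    right <- labels[values >= cut]
    e <- length(left) / length(labels) * oracle_entropy(left) +
      length(right) / length(labels) * oracle_entropy(right)
    if (is.null(best) || e < best$entropy - 1e-12) {
      best <- list(cut = cut, entropy = e)
    }
  }
  best
}

random_contingency <- function(nrow = 2, ncol = sample(2:6, 1), lambda = 20) {
  m <- matrix(stats::rpois(nrow * ncol, lambda), nrow = nrow)
  # guarantee a usable table: nonzero total and at least one nonzero column
  m[1, 1] <- m[1, 1] + 1L
  rownames(m) <- c("non-severe", "severe")[seq_len(nrow)]
  colnames(m) <- paste0("v", seq_len(ncol))
  m
}

# small synthetic modelling frame used across tests
toy_ade <- function(n = 300, seed = 7, assoc = 0.6) {
  spec <- ade_sim_spec(
    n = n, prevalence = 0.5,
    categorical = list(
      drug = sim_categorical(c("A", "B", "C"), assoc = assoc),
      site = sim_categorical(c("north", "south"), assoc = 0)
    ),
    continuous = list(
      age = sim_continuous("norm", mean = 60, sd = 10, lower = 0, upper = 105,
                           class_shift = 5)
    )
  )
  simulate_ade(spec, seed = seed)
}
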