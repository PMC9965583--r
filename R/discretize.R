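#' Class information entropy
#'
#' Shannon entropy (base 2) of a class-label vector, with 0 log2 0 := 0.
#'
#' @param labels Vector (factor/character/logical) of class labels.
#' @return Entropy in bits.
#' @export
class_entropy <- function(labels) {
  if (length(labels) == 0) stop("cannot take the entropy of an empty label vector")
  p <- table(labels)
  p <- p[p > 0] / length(labels)
  -sum(p * log2(p))
}

# entropy from a count vector, 0 log 0 := 0
entropy_counts <- function(counts) {
  counts <- counts[counts > 0]
  n <- sum(counts)
  if (n == 0) return(0)
  p <- counts / n
  -sum(p * log2(p))
}

#' Candidate cut points for supervised discretization
#'
#' Midpoints between successive distinct sorted values. By default the
#' candidates are restricted to class-boundary points — midpoints between two
#' adjacent value blocks that are not both pure in the same class — which is
#' an exact optimization for entropy minimization: the minimum-entropy cut
#' always lies on a class boundary.
#'
#' @param values Numeric vector, sorted ascending.
#' @param labels Class labels aligned with `values`.
#' @param boundary_only Restrict to class-boundary midpoints (default TRUE).
#' @return Numeric vector of candidate cuts (possibly empty).
#' @export
candidate_cuts <- function(values, labels, boundary_only = TRUE) {
  stopifnot(length(values) == length(labels))
  if (is.unsorted(values)) stop("values must be sorted ascending")
  uv <- unique(values)
  if (length(uv) < 2) return(numeric(0))
  mids <- (uv[-length(uv)] + uv[-1]) / 2
  if (!boundary_only) return(mids)
  # per distinct-value block: which classes occur
  lab <- as.integer(factor(labels))
  block <- match(values, uv)
  has1 <- tapply(lab == 1, block, any)
  has2 <- tapply(lab == 2, block, any)
  if (max(lab) > 2) {
    # generic multi-label guard; binary in this package
    pure_class <- tapply(lab, block, function(z) if (length(unique(z)) == 1) z[1] else NA_integer_)
    keep <- !(
      !is.na(pure_class[-length(pure_class)]) &
        !is.na(pure_class[-1]) &
        pure_class[-length(pure_class)] == pure_class[-1]
    )
  } else {
    pure1 <- has1 & !has2
    pure2 <- has2 & !has1
    same_pure <- (pure1[-length(pure1)] & pure1[-1]) | (pure2[-length(pure2)] & pure2[-1])
    keep <- !same_pure
  }
  mids[keep]
}

#' Minimum-entropy binary cut
#'
#' Evaluates every candidate cut by the class-information entropy of the
#' induced two-partition, weighted by partition size, and returns the cut
#' with minimum weighted entropy. Ties are broken by the smallest cut value.
#'
#' @param values Numeric vector (any order; sorted internally).
#' @param labels Class labels aligned with `values`.
#' @param boundary_only Passed to [candidate_cuts()].
#' @return `list(cut =, entropy =)` or `NULL` when no candidate cut exists.
#' @export
best_cut <- function(values, labels, boundary_only = TRUE) {
  ord <- order(values)
  values <- values[ord]
  labels <- labels[ord]
  cuts <- candidate_cuts(values, labels, boundary_only = boundary_only)
  if (length(cuts) == 0) return(NULL)
  n <- length(values)
  lab <- as.integer(factor(labels)) == 1L
  # cumulative class counts along the sorted order make each cut O(1);
  # cuts are strict midpoints, so findInterval gives the left-partition size
  cum1 <- cumsum(lab)
  nl <- findInterval(cuts, values)
  c1l <- cum1[nl]
  c1r <- cum1[n] - c1l
  plogp <- function(p) ifelse(p > 0, p * log2(p), 0)
  h2 <- function(a, m) {
    p <- ifelse(m > 0, a / m, 0)
    -(plogp(p) + plogp(1 - p))
  }
  e <- (nl / n) * h2(c1l, nl) + ((n - nl) / n) * h2(c1r, n - nl)
  best <- which(e < min(e) + 1e-12)[1] # tie -> smallest cut (cuts ascending)
  list(cut = cuts[best], entropy = e[best])
}

#' Minimum description length acceptance test for a cut
#'
#' The information-theoretic stopping rule of recursive entropy
#' discretization: a binary cut of N examples is accepted only when its
#' information gain exceeds `(log2(N - 1) + delta) / N`, where
#' `delta = log2(3^k - 2) - (k*H - k1*H1 - k2*H2)`, `k`, `k1`, `k2` being
#' the numbers of classes present in the parent and the two partitions and
#' `H`, `H1`, `H2` their entropies.
#'
#' @param n Number of examples in the partition being cut (>= 2).
#' @param gain Information gain of the cut:
#'   `H - (n1/n) H1 - (n2/n) H2`.
#' @param h_parent,h_left,h_right Entropies (bits) of parent and partitions.
#' @param k,k_left,k_right Class counts present in parent and partitions.
#' @return Logical: accept the cut?
#' @export
mdlp_accept <- function(n, gain, h_parent, h_left, h_right,
                        k = 2, k_left = k, k_right = k) {
  stopifnot(n >= 2)
  delta <- log2(3^k - 2) - (k * h_parent - k_left * h_left - k_right * h_right)
  gain > (log2(n - 1) + delta) / n
}

# one recursion step: returns accepted cuts within values[lo..hi] (sorted)
mdlp_recurse <- function(values, lab1, lo, hi, boundary_only) {
  n <- hi - lo + 1
  if (n < 2) return(numeric(0))
  v <- values[lo:hi]
  l <- lab1[lo:hi]
  bc <- best_cut(v, l, boundary_only = boundary_only)
  if (is.null(bc)) return(numeric(0))
  nl <- sum(v < bc$cut)
  h_parent <- class_entropy(l)
  left <- l[seq_len(nl)]
  right <- l[(nl + 1):n]
  h_l <- class_entropy(left)
  h_r <- class_entropy(right)
  gain <- h_parent - (nl / n) * h_l - ((n - nl) / n) * h_r
  k <- length(unique(l))
  if (!mdlp_accept(n, gain, h_parent, h_l, h_r,
                   k = k, k_left = length(unique(left)),
                   k_right = length(unique(right)))) {
    return(numeric(0))
  }
  c(
    mdlp_recurse(values, lab1, lo, lo + nl - 1, boundary_only),
    bc$cut,
    mdlp_recurse(values, lab1, lo + nl, hi, boundary_only)
  )
}

#' Supervised MDL discretization of a continuous attribute
#'
#' Recursively applies the minimum-entropy binary cut with the minimum
#' description length acceptance test until no further cut is accepted.
#' An attribute whose class distribution supports no cut yields a
#' single-interval scheme, flagged non-discretizable — such attributes carry
#' no class information at this granularity (for weighting they receive a
#' zero statistic).
#'
#' @param values Numeric vector.
#' @param labels Binary class labels aligned with `values`.
#' @param name Attribute name carried in the scheme.
#' @param boundary_only Restrict candidates to class-boundary midpoints.
#' @return Object of class `mdlp_scheme`: list with `attribute`, `cuts`
#'   (sorted, possibly empty), `labels` (interval labels, left-closed /
#'   right-open, outer intervals unbounded) and `discretizable`.
#' @examples
#' s <- discretize_mdlp(c(1, 2, 3, 10, 11, 12),
#'                      rep(c("severe", "non-severe"), each = 3))
#' cut_points(s)
#' @export
discretize_mdlp <- function(values, labels, name = "attribute",
                            boundary_only = TRUE) {
  stopifnot(length(values) == length(labels))
  keep <- !is.na(values) & !is.na(labels)
  values <- values[keep]
  labels <- labels[keep]
  ord <- order(values)
  cuts <- sort(mdlp_recurse(values[ord], labels[ord], 1, length(values),
                            boundary_only))
  mdlp_scheme(name, cuts)
}

mdlp_scheme <- function(name, cuts) {
  cuts <- as.numeric(cuts)
  if (is.unsorted(cuts, strictly = TRUE)) stop("cut points must be strictly increasing")
  bounds <- c(-Inf, cuts, Inf)
  labels <- sprintf("[%s, %s)", format(bounds[-length(bounds)], trim = TRUE),
                    format(bounds[-1], trim = TRUE))
  structure(list(attribute = name, cuts = cuts, labels = labels,
                 discretizable = length(cuts) > 0),
            class = "mdlp_scheme")
}

#' @export
print.mdlp_scheme <- function(x, ...) {
  cat("MDL discretization of '", x$attribute, "': ", sep = "")
  if (!x$discretizable) {
    cat("no accepted cut points (non-discretizable)\n")
  } else {
    cat(length(x$cuts), " cut point(s) at ",
        paste(format(x$cuts), collapse = ", "), "\n", sep = "")
  }
  invisible(x)
}

#' Cut points of a discretization scheme
#' @param scheme An `mdlp_scheme`.
#' @return Numeric vector of cuts (may be empty).
#' @export
cut_points <- function(scheme) scheme$cuts

#' Apply a discretization scheme
#'
#' Maps each value to its interval label; intervals are left-closed /
#' right-open so every real maps to exactly one interval.
#'
#' @param scheme An `mdlp_scheme`.
#' @param values Numeric vector.
#' @return Factor of interval labels (all scheme levels retained).
#' @export
apply_scheme <- function(scheme, values) {
  idx <- findInterval(values, scheme$cuts) + 1L
  factor(scheme$labels[idx], levels = scheme$labels)
}
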