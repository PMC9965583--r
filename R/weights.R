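#' Contingency table of an attribute against the target
#'
#' Cross-tabulates a categorical attribute value vector against the binary
#' severity target: observed counts O_kj (classes in rows, attribute values
#' in columns) with row marginals, column marginals and grand total. Value
#' and class order is deterministic (factor level order, lexicographic for
#' character input).
#'
#' @param x Categorical attribute vector.
#' @param target Class label vector, same length.
#' @return Object of class `ade_contingency`: list with `counts` (z x s
#'   integer matrix), `row_marginals`, `col_marginals`, `total`.
#' @export
contingency_table <- function(x, target) {
  if (length(x) != length(target)) {
    stop("attribute and target vectors must have the same length")
  }
  if (length(x) == 0) stop("cannot tabulate empty vectors")
  counts <- table(target, x)
  counts <- matrix(as.integer(counts), nrow = nrow(counts),
                   dimnames = dimnames(counts))
  new_contingency(counts)
}

new_contingency <- function(counts) {
  counts <- as.matrix(counts)
  storage.mode(counts) <- "integer"
  if (any(counts < 0)) stop("contingency counts must be nonnegative")
  structure(list(counts = counts,
                 row_marginals = rowSums(counts),
                 col_marginals = colSums(counts),
                 total = sum(counts)),
            class = "ade_contingency")
}

#' Build a contingency table from a count matrix
#'
#' For tables known only through their printed counts (classes in rows,
#' attribute values in columns).
#'
#' @param counts Nonnegative integer matrix, classes x values.
#' @return An `ade_contingency`.
#' @export
as_contingency <- function(counts) new_contingency(counts)

#' @export
print.ade_contingency <- function(x, ...) {
  m <- cbind(x$counts, total = x$row_marginals)
  m <- rbind(m, total = c(x$col_marginals, x$total))
  print(m)
  invisible(x)
}

# drop attribute values never observed (zero column marginal): their
# expected counts are zero and the chi-square cell term is undefined
drop_empty_columns <- function(tab) {
  keep <- tab$col_marginals > 0
  if (all(keep)) return(tab)
  new_contingency(tab$counts[, keep, drop = FALSE])
}

#' Chi-square statistic of a contingency table
#'
#' Pearson's chi-square sum((O - E)^2 / E) with expected counts
#' E_kj = M_Rk * M_Cj / M, no continuity correction. Attribute values with a
#' zero column marginal are dropped first. Used as the raw attribute-relevance
#' statistic of the chi-square weighting scheme.
#'
#' @param tab An `ade_contingency`.
#' @return Nonnegative chi-square statistic.
#' @export
chi_square <- function(tab) {
  stopifnot(inherits(tab, "ade_contingency"))
  if (tab$total == 0) stop("all-zero contingency table")
  tab <- drop_empty_columns(tab)
  keep_rows <- tab$row_marginals > 0
  expected <- outer(tab$row_marginals, tab$col_marginals) / tab$total
  o <- tab$counts[keep_rows, , drop = FALSE]
  e <- expected[keep_rows, , drop = FALSE]
  sum((o - e)^2 / e)
}

#' Information-gain statistic of a contingency table
#'
#' Mutual information between attribute and target in bits:
#' `H(T) - sum_j P(b_j) H(T | b_j)`. A classical baseline attribute-relevance
#' measure; zero when attribute and target are independent.
#'
#' @param tab An `ade_contingency`.
#' @return Nonnegative information gain (bits).
#' @export
ig_score <- function(tab) {
  stopifnot(inherits(tab, "ade_contingency"))
  if (tab$total == 0) stop("all-zero contingency table")
  tab <- drop_empty_columns(tab)
  h_t <- entropy_counts(tab$row_marginals)
  p_col <- tab$col_marginals / tab$total
  h_cond <- sum(vapply(seq_along(p_col), function(j) {
    p_col[j] * entropy_counts(tab$counts[, j])
  }, numeric(1)))
  max(h_t - h_cond, 0)
}

#' Kullback-Leibler divergence statistic of a contingency table
#'
#' Per attribute value b_j, the divergence KL(P(T | b_j) || P(T)) in bits;
#' the attribute score is the column-probability-weighted average of those
#' divergences, normalized by the attribute's split information
#' `-sum_j P(b_j) log2 P(b_j)`. A single-valued attribute has zero split
#' information and scores 0. A classical baseline relevance measure from
#' value-weighted naive Bayes.
#'
#' @param tab An `ade_contingency`.
#' @return Nonnegative KL-based score.
#' @export
kl_score <- function(tab) {
  stopifnot(inherits(tab, "ade_contingency"))
  if (tab$total == 0) stop("all-zero contingency table")
  tab <- drop_empty_columns(tab)
  p_t <- tab$row_marginals / tab$total
  p_col <- tab$col_marginals / tab$total
  split_info <- -sum(p_col * log2(p_col))
  if (split_info <= 0) return(0)
  kl_j <- vapply(seq_along(p_col), function(j) {
    p_cond <- tab$counts[, j] / tab$col_marginals[j]
    nz <- p_cond > 0
    sum(p_cond[nz] * log2(p_cond[nz] / p_t[nz]))
  }, numeric(1))
  sum(p_col * kl_j) / split_info
}

#' Normalize raw attribute statistics into weights
#'
#' Scales a vector of nonnegative raw relevance statistics so the weights
#' sum to the number of attributes: `w_i = stat_i * n / sum(stat)`. A weight
#' above 1 marks an attribute more relevant than average, below 1 less
#' relevant; weighting schemes sharing this normalization are directly
#' comparable.
#'
#' @param stats Named numeric vector of raw statistics (>= 0).
#' @param method Tag recording how the statistics were computed.
#' @return Object of class `attribute_weights`: data frame with columns
#'   `attribute`, `raw`, `weight`, plus attributes `n` and `method`.
#' @export
normalize_weights <- function(stats, method = "chi2") {
  if (length(stats) == 0) stop("need at least one attribute statistic")
  if (any(stats < 0)) stop("raw statistics must be nonnegative")
  total <- sum(stats)
  if (total <= 0) {
    stop("all attribute statistics are zero: no informative attribute to weight")
  }
  n <- length(stats)
  w <- stats * n / total
  nm <- names(stats)
  if (is.null(nm)) nm <- paste0("x", seq_len(n))
  structure(data.frame(attribute = nm, raw = as.numeric(stats),
                       weight = as.numeric(w), stringsAsFactors = FALSE),
            n = n, method = method, class = c("attribute_weights", "data.frame"))
}

#' @export
print.attribute_weights <- function(x, digits = 3, ...) {
  cat("Attribute weights (", attr(x, "method"), "), n = ", attr(x, "n"),
      ", sum(w) = ", format(sum(x$weight)), "\n", sep = "")
  print(data.frame(attribute = x$attribute,
                   raw = round(x$raw, digits),
                   weight = round(x$weight, digits)), row.names = FALSE)
  invisible(x)
}

raw_stat_fun <- function(method) {
  switch(method,
         chi2 = chi_square,
         ig = ig_score,
         kl = kl_score,
         stop("unknown weighting method: ", method))
}

#' Attribute weights of a dataset
#'
#' Computes one relevance weight per attribute from the training data.
#' Continuous attributes are first discretized with supervised MDL
#' discretization ([discretize_mdlp()]); an attribute that accepts no cut is
#' non-discretizable, carries no detectable class association at this
#' granularity, and receives a raw statistic of 0 (hence weight 0). The raw
#' statistics are normalized by [normalize_weights()] so the weights sum to
#' the number of attributes. Set `normalize = FALSE` to keep the raw
#' statistics as weights.
#'
#' @param data An `ade_data` training set.
#' @param method `"chi2"` (default), `"ig"` or `"kl"`.
#' @param normalize Normalize so weights sum to the attribute count
#'   (default TRUE).
#' @param boundary_only Candidate-cut restriction for discretization.
#' @return An `attribute_weights` object; the discretization schemes used
#'   for continuous attributes are attached as attribute `"schemes"`.
#' @export
attribute_weights <- function(data, method = c("chi2", "ig", "kl"),
                              normalize = TRUE, boundary_only = TRUE) {
  method <- match.arg(method)
  stopifnot(inherits(data, "ade_data"))
  kinds <- attr(data, "kinds")
  y <- data[[attr(data, "target")]]
  stat_fun <- raw_stat_fun(method)
  schemes <- list()
  stats <- vapply(names(kinds), function(a) {
    v <- data[[a]]
    if (kinds[[a]] == "continuous") {
      sch <- discretize_mdlp(v, y, name = a, boundary_only = boundary_only)
      schemes[[a]] <<- sch
      if (!sch$discretizable) return(0)
      v <- apply_scheme(sch, v)
    }
    stat_fun(contingency_table(v, y))
  }, numeric(1))
  if (normalize) {
    w <- normalize_weights(stats, method = method)
  } else {
    w <- structure(data.frame(attribute = names(stats), raw = as.numeric(stats),
                              weight = as.numeric(stats), stringsAsFactors = FALSE),
                   n = length(stats), method = method,
                   class = c("attribute_weights", "data.frame"))
  }
  attr(w, "schemes") <- schemes
  w
}
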