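#' Categorical attribute specification for simulation
#'
#' Defines the class-conditional value distributions of a simulated
#' categorical attribute. Either give `p_severe` / `p_nonsevere` explicitly,
#' or give a marginal `p` plus an association strength `assoc` in [0, 1):
#' the conditionals are then tilted in opposite directions along a linear
#' contrast over the values, `p_severe ~ p * (1 + assoc * t)` and
#' `p_nonsevere ~ p * (1 - assoc * t)` with `t` ranging over [-1, 1], so
#' `assoc = 0` gives an attribute independent of severity and larger values
#' give a stronger attribute-severity association.
#'
#' @param values Character vector of attribute values.
#' @param p Marginal value probabilities (default uniform).
#' @param assoc Association strength in [0, 1) (default 0).
#' @param p_severe,p_nonsevere Explicit class-conditional probabilities
#'   (override `p`/`assoc`).
#' @return List usable in the `categorical` slot of [ade_sim_spec()].
#' @export
sim_categorical <- function(values, p = rep(1 / length(values), length(values)),
                            assoc = 0, p_severe = NULL, p_nonsevere = NULL) {
  k <- length(values)
  stopifnot(k >= 1)
  if (is.null(p_severe) != is.null(p_nonsevere)) {
    stop("give both p_severe and p_nonsevere, or neither")
  }
  if (is.null(p_severe)) {
    stopifnot(length(p) == k, all(p > 0), assoc >= 0, assoc < 1)
    p <- p / sum(p)
    t_contrast <- if (k == 1) 0 else seq(-1, 1, length.out = k)
    p_severe <- p * (1 + assoc * t_contrast)
    p_nonsevere <- p * (1 - assoc * t_contrast)
  }
  check_probs <- function(q, what) {
    if (length(q) != k || any(q < 0) || abs(sum(q) - 1) > 1e-8 * max(1, sum(q))) {
      stop(what, " must be ", k, " nonnegative probabilities summing to 1")
    }
    q / sum(q)
  }
  list(values = values,
       p_severe = check_probs(p_severe, "p_severe"),
       p_nonsevere = check_probs(p_nonsevere, "p_nonsevere"))
}

#' Continuous attribute specification for simulation
#'
#' Normal (optionally truncated, e.g. age in [0, 105]) or lognormal
#' (right-skewed, e.g. therapy duration in days) attribute whose location
#' can shift with severity: `class_shift` is added to the mean (normal) or
#' the log-scale mean (lognormal) for severe records, so 0 gives a
#' severity-independent attribute.
#'
#' @param dist `"norm"` or `"lnorm"`.
#' @param mean,sd Location/scale (log scale for `"lnorm"`).
#' @param lower,upper Truncation bounds (rejection sampling).
#' @param class_shift Location shift for severe records.
#' @return List usable in the `continuous` slot of [ade_sim_spec()].
#' @export
sim_continuous <- function(dist = c("norm", "lnorm"), mean = 0, sd = 1,
                           lower = -Inf, upper = Inf, class_shift = 0) {
  dist <- match.arg(dist)
  stopifnot(sd > 0, lower < upper)
  list(dist = dist, mean = mean, sd = sd, lower = lower, upper = upper,
       class_shift = class_shift)
}

#' Specification of a synthetic adverse-event dataset
#'
#' Describes a FAERS-like severity-classification dataset: record count,
#' baseline severe prevalence, and per-attribute generators with
#' controllable attribute-severity association. The default attribute set
#' emulates an osteoporosis adverse-event cohort: gender, drug name, dose
#' frequency and disease stage drawn from the class-conditional frequencies
#' of the published cohort summary ([osteo_attribute_tables()]), an age in
#' years (truncated normal on [0, 105], severe cases slightly older) and a
#' right-skewed therapy duration in days; the default prevalence 0.581 and
#' n = 20576 match the cohort's 11956 severe / 8620 non-severe records.
#'
#' @param n Number of records.
#' @param prevalence Baseline probability of a severe event.
#' @param categorical Named list of [sim_categorical()] specs (NULL for the
#'   cohort-emulating defaults).
#' @param continuous Named list of [sim_continuous()] specs (NULL for the
#'   default age/duration pair).
#' @return List of class `ade_sim_spec`.
#' @export
ade_sim_spec <- function(n = 20576, prevalence = 11956 / 20576,
                         categorical = NULL, continuous = NULL) {
  stopifnot(n >= 1, prevalence > 0, prevalence < 1)
  if (is.null(categorical)) {
    categorical <- lapply(osteo_attribute_tables(), function(tab) {
      sim_categorical(colnames(tab$counts),
                      p_severe = tab$counts["severe", ] / sum(tab$counts["severe", ]),
                      p_nonsevere = tab$counts["non-severe", ] /
                        sum(tab$counts["non-severe", ]))
    })
  }
  if (is.null(continuous)) {
    continuous <- list(
      age = sim_continuous("norm", mean = 66, sd = 12, lower = 0, upper = 105,
                           class_shift = 4),
      duration = sim_continuous("lnorm", mean = log(365), sd = 1.2,
                                lower = 0, upper = 8677, class_shift = 0.25)
    )
  }
  structure(list(n = n, prevalence = prevalence,
                 categorical = categorical, continuous = continuous),
            class = "ade_sim_spec")
}

rtrunc <- function(n, rfun, lower, upper, ...) {
  out <- rfun(n, ...)
  bad <- which(out < lower | out > upper)
  while (length(bad)) {
    out[bad] <- rfun(length(bad), ...)
    bad <- bad[out[bad] < lower | out[bad] > upper]
  }
  out
}

#' Generate a synthetic adverse-event dataset
#'
#' Draws severity from the baseline prevalence, then every attribute from
#' its class-conditional generator. Fully reproducible: the same spec and
#' seed give an identical dataset.
#'
#' @param spec An [ade_sim_spec()].
#' @param seed Integer seed.
#' @return An `ade_data` with target column `severity`.
#' @examples
#' d <- simulate_ade(ade_sim_spec(n = 200), seed = 42)
#' table(d$severity)
#' @export
simulate_ade <- function(spec, seed = 1) {
  stopifnot(inherits(spec, "ade_sim_spec"))
  set.seed(seed)
  n <- spec$n
  severe <- stats::runif(n) < spec$prevalence
  out <- list()
  for (a in names(spec$categorical)) {
    cs <- spec$categorical[[a]]
    v <- character(n)
    v[severe] <- sample(cs$values, sum(severe), replace = TRUE, prob = cs$p_severe)
    v[!severe] <- sample(cs$values, sum(!severe), replace = TRUE,
                         prob = cs$p_nonsevere)
    out[[a]] <- factor(v, levels = sort(cs$values))
  }
  for (a in names(spec$continuous)) {
    cs <- spec$continuous[[a]]
    v <- numeric(n)
    draw <- function(m, sz) {
      if (cs$dist == "norm") {
        rtrunc(sz, stats::rnorm, cs$lower, cs$upper, mean = m, sd = cs$sd)
      } else {
        rtrunc(sz, stats::rlnorm, cs$lower, cs$upper, meanlog = m, sdlog = cs$sd)
      }
    }
    v[severe] <- draw(cs$mean + cs$class_shift, sum(severe))
    v[!severe] <- draw(cs$mean, sum(!severe))
    out[[a]] <- v
  }
  out$severity <- factor(ifelse(severe, "severe", "non-severe"),
                         levels = c("non-severe", "severe"))
  ade_data(data.frame(out, stringsAsFactors = FALSE), target = "severity")
}
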