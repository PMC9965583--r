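#' Maximum-likelihood logistic regression fit
#'
#' Thin wrapper around the binomial GLM fit (iteratively reweighted least
#' squares): convergence when the relative deviance change falls below 1e-8,
#' at most 100 iterations. Perfect separation triggers a warning and the
#' capped estimate at the iteration limit is returned.
#'
#' @param design Numeric design matrix (no intercept column; one is added).
#' @param target Binary vector/factor; the last factor level (or value 1) is
#'   the positive class.
#' @return List with `alpha` (intercept), `beta` (named coefficient vector)
#'   and `converged`.
#' @export
fit_lr <- function(design, target) {
  design <- as.matrix(design)
  y <- to_binary(target)
  if (length(unique(y)) < 2) stop("target has a single class; cannot fit")
  const <- apply(design, 2, function(col) all(col == col[1]))
  if (any(const)) {
    stop("constant design columns: ", paste(colnames(design)[const], collapse = ", "))
  }
  fit <- suppressWarnings(
    stats::glm.fit(cbind("(Intercept)" = 1, design), y,
                   family = stats::binomial(),
                   control = stats::glm.control(epsilon = 1e-8, maxit = 100))
  )
  if (!fit$converged) {
    warning("logistic regression did not converge (possible perfect separation); ",
            "returning the estimate at the iteration cap")
  }
  cf <- fit$coefficients
  list(alpha = unname(cf[1]), beta = cf[-1], converged = fit$converged)
}

to_binary <- function(target) {
  if (is.factor(target)) as.integer(target) - 1L
  else if (is.logical(target)) as.integer(target)
  else as.integer(as.integer(target) != 0L)
}

#' Incorporate attribute weights into logistic regression coefficients
#'
#' Each raw coefficient beta is shifted by a signed natural-log weight term
#' so that relevant attributes (w > 1) gain influence and irrelevant ones
#' (w < 1) keep their association direction while the magnitude records the
#' weight: beta < 0, w < 1 -> beta + ln(w); beta < 0, w > 1 -> beta - ln(w);
#' beta > 0, w < 1 -> beta - ln(w); beta > 0, w > 1 -> beta + ln(w). The
#' term therefore always carries beta's sign and the adjusted coefficient
#' keeps the raw log-odds-ratio direction. Edge cases: w = 1 or beta = 0
#' leave the coefficient unchanged; w = 0 sets the additive term to the
#' literal constant 1e-10 (`zero_weight = "literal"`, the published rule) or
#' to 0 (`zero_weight = "zero"`). If an adjustment would ever cross zero the
#' coefficient is clipped to 1e-12 on beta's side and the event is counted
#' in the `clipped` column.
#'
#' @param beta Named numeric vector of raw coefficients (no intercept).
#' @param weights An `attribute_weights` object (or a named numeric vector
#'   of weights).
#' @param map Character vector, same length as `beta`, naming the source
#'   attribute of each coefficient (dummy-encoded categoricals share their
#'   attribute's single weight). Defaults to `names(beta)`.
#' @param zero_weight `"literal"` (published rule: additive term 1e-10) or
#'   `"zero"` (leave a zero-weight coefficient unadjusted).
#' @return Data frame of class `awlr_adjustment`: coefficient, attribute,
#'   beta, weight, term, adjusted, clipped.
#' @export
adjust_coefficients <- function(beta, weights, map = names(beta),
                                zero_weight = c("literal", "zero")) {
  zero_weight <- match.arg(zero_weight)
  w_vec <- if (inherits(weights, "attribute_weights")) {
    stats::setNames(weights$weight, weights$attribute)
  } else {
    weights
  }
  if (any(w_vec < 0)) stop("attribute weights must be nonnegative")
  if (is.null(map)) map <- names(beta)
  missing <- setdiff(unique(map), names(w_vec))
  if (length(missing)) {
    stop("no weight for attribute(s): ", paste(missing, collapse = ", "))
  }
  w <- unname(w_vec[map])
  term <- numeric(length(beta))
  zero_w <- w == 0
  plain <- !zero_w & w != 1 & beta != 0
  term[plain] <- sign(beta[plain]) * abs(log(w[plain]))
  if (zero_weight == "literal") term[zero_w & beta != 0] <- 1e-10
  adjusted <- beta + term
  crossed <- beta != 0 & sign(adjusted) != sign(beta)
  adjusted[crossed] <- sign(beta[crossed]) * 1e-12
  structure(data.frame(coefficient = if (is.null(names(beta))) map else names(beta),
                       attribute = map,
                       beta = unname(beta), weight = w, term = term,
                       adjusted = unname(adjusted), clipped = crossed,
                       stringsAsFactors = FALSE),
            class = c("awlr_adjustment", "data.frame"))
}

#' Fit an attribute-weighted logistic regression
#'
#' The full pipeline: standardize continuous attributes (training statistics
#' are stored and reused at prediction time), dummy-encode categorical
#' attributes (first level as reference), fit the unweighted
#' maximum-likelihood logistic regression, compute per-attribute relevance
#' weights on the training data (continuous attributes discretized by
#' supervised MDL discretization for the weight computation only), and shift
#' each coefficient by its attribute's signed log-weight term
#' ([adjust_coefficients()]). With `weight_method = "none"` the model is the
#' standard logistic regression.
#'
#' @param data An `ade_data` training set (or a data frame accepted by
#'   [ade_data()]).
#' @param weight_method `"chi2"` (default), `"ig"`, `"kl"` or `"none"`.
#' @param target Target column name when `data` is a plain data frame.
#' @param zero_weight Handling of zero weights, see [adjust_coefficients()].
#' @param boundary_only Candidate-cut restriction for MDL discretization.
#' @param threshold Classification threshold on the severe-class
#'   probability (default 0.5).
#' @return Object of class `awlr`: list with `alpha`, `adjustment`
#'   (coefficient table), `weights`, `schemes`, `standardization`,
#'   `levels` (factor levels per categorical attribute), `target_levels`,
#'   `threshold`, `weight_method`, `converged`.
#' @examples
#' d <- simulate_ade(ade_sim_spec(n = 400), seed = 1)
#' m <- awlr_fit(d, weight_method = "chi2")
#' head(predict(m, d))
#' @export
awlr_fit <- function(data, weight_method = c("chi2", "ig", "kl", "none"),
                     target = "severity", zero_weight = c("literal", "zero"),
                     boundary_only = TRUE, threshold = 0.5) {
  weight_method <- match.arg(weight_method)
  zero_weight <- match.arg(zero_weight)
  if (!inherits(data, "ade_data")) data <- ade_data(data, target = target)
  kinds <- attr(data, "kinds")
  y <- data[[attr(data, "target")]]
  if (length(unique(y[!is.na(y)])) < 2) stop("training data has a single class")

  std <- list()
  model_tab <- as.data.frame(data)[names(kinds)]
  for (a in names(kinds)[kinds == "continuous"]) {
    z <- standardize(model_tab[[a]])
    std[[a]] <- list(center = attr(z, "center"), scale = attr(z, "scale"))
    model_tab[[a]] <- as.numeric(z)
  }
  levels_map <- lapply(model_tab[names(kinds)[kinds == "categorical"]], levels)

  enc <- encode_design(model_tab, kinds, levels_map)
  # a level unobserved in this training sample yields an all-zero dummy;
  # drop it (its coefficient is indistinguishable from the reference) and
  # record it, so prediction treats the level as baseline
  zero_col <- apply(enc$design, 2, function(col) all(col == 0))
  dropped <- colnames(enc$design)[zero_col]
  if (any(zero_col)) {
    enc$design <- enc$design[, !zero_col, drop = FALSE]
    enc$map <- enc$map[!zero_col]
  }
  fit <- fit_lr(enc$design, y)
  # aliased (collinear) columns come back NA from IRLS; exclude them like
  # unobserved levels
  aliased <- is.na(fit$beta)
  if (any(aliased)) {
    dropped <- c(dropped, names(fit$beta)[aliased])
    fit$beta <- fit$beta[!aliased]
    enc$map <- enc$map[!aliased]
  }

  if (weight_method == "none") {
    w <- structure(data.frame(attribute = names(kinds), raw = NA_real_,
                              weight = rep(1, length(kinds)),
                              stringsAsFactors = FALSE),
                   n = length(kinds), method = "none",
                   class = c("attribute_weights", "data.frame"))
    schemes <- list()
  } else {
    w <- attribute_weights(data, method = weight_method,
                           boundary_only = boundary_only)
    schemes <- attr(w, "schemes")
  }
  adj <- adjust_coefficients(fit$beta, w, map = enc$map,
                             zero_weight = zero_weight)

  structure(list(alpha = fit$alpha,
                 adjustment = adj,
                 weights = w,
                 schemes = schemes,
                 standardization = std,
                 levels = levels_map,
                 kinds = kinds,
                 target = attr(data, "target"),
                 target_levels = levels(y),
                 threshold = threshold,
                 weight_method = weight_method,
                 dropped = dropped,
                 converged = fit$converged),
            class = "awlr")
}

# dummy-encode: first factor level is the reference; continuous pass through
encode_design <- function(tab, kinds, levels_map) {
  cols <- list()
  map <- character(0)
  for (a in names(kinds)) {
    if (kinds[[a]] == "continuous") {
      cols[[a]] <- as.numeric(tab[[a]])
      map <- c(map, a)
    } else {
      lv <- levels_map[[a]]
      v <- factor(as.character(tab[[a]]), levels = lv)
      if (anyNA(v)) stop("unseen or missing level in attribute '", a, "'")
      for (l in lv[-1]) {
        nm <- paste0(a, l)
        cols[[nm]] <- as.numeric(v == l)
        map <- c(map, a)
      }
    }
  }
  design <- do.call(cbind, cols)
  colnames(design) <- names(cols)
  list(design = design, map = map)
}

#' @export
print.awlr <- function(x, digits = 4, ...) {
  cat("Attribute-weighted logistic regression (weights: ",
      x$weight_method, ")\n", sep = "")
  cat("Intercept (never weighted): ", format(x$alpha, digits = digits), "\n\n", sep = "")
  adj <- x$adjustment
  print(data.frame(coefficient = adj$coefficient,
                   attribute = adj$attribute,
                   beta = round(adj$beta, digits),
                   weight = round(adj$weight, digits),
                   adjusted = round(adj$adjusted, digits)),
        row.names = FALSE)
  if (any(adj$clipped)) {
    cat("\n", sum(adj$clipped), " coefficient(s) clipped to preserve sign\n", sep = "")
  }
  if (length(x$dropped)) {
    cat("levels unobserved in training (treated as reference): ",
        paste(x$dropped, collapse = ", "), "\n", sep = "")
  }
  invisible(x)
}

#' @export
coef.awlr <- function(object, adjusted = TRUE, ...) {
  adj <- object$adjustment
  cf <- if (adjusted) adj$adjusted else adj$beta
  c("(Intercept)" = object$alpha, stats::setNames(cf, adj$coefficient))
}

#' Predict severity probabilities from a fitted model
#'
#' Applies the logistic transform to the adjusted linear predictor. New data
#' are standardized with the training statistics and dummy-encoded with the
#' training factor levels.
#'
#' @param object An `awlr` model.
#' @param newdata Data frame (or `ade_data`) of attributes.
#' @param type `"response"` for severe-class probabilities (default),
#'   `"class"` for labels at the model threshold.
#' @param ... Unused.
#' @return Numeric probability vector, or a factor with the training target
#'   levels when `type = "class"`.
#' @export
predict.awlr <- function(object, newdata, type = c("response", "class"), ...) {
  type <- match.arg(type)
  tab <- as.data.frame(newdata)
  missing <- setdiff(names(object$kinds), names(tab))
  if (length(missing)) {
    stop("newdata lacks attribute(s): ", paste(missing, collapse = ", "))
  }
  for (a in names(object$standardization)) {
    s <- object$standardization[[a]]
    tab[[a]] <- (as.numeric(tab[[a]]) - s$center) / s$scale
  }
  enc <- encode_design(tab, object$kinds, object$levels)
  design <- enc$design[, object$adjustment$coefficient, drop = FALSE]
  eta <- object$alpha + as.numeric(design %*% object$adjustment$adjusted)
  p <- stats::plogis(eta)
  if (type == "response") return(p)
  factor(object$target_levels[(p >= object$threshold) + 1L],
         levels = object$target_levels)
}

#' Serialize a fitted model to JSON
#'
#' Writes intercept, raw and adjusted coefficients, attribute weights,
#' adjustment terms, encoding map, standardization statistics and
#' discretization cut points.
#'
#' @param model An `awlr` model.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_awlr <- function(model, path) {
  obj <- list(
    alpha = model$alpha,
    adjustment = model$adjustment,
    weights = as.data.frame(model$weights),
    weight_method = model$weight_method,
    schemes = lapply(model$schemes, function(s) s[c("attribute", "cuts")]),
    standardization = model$standardization,
    levels = model$levels,
    kinds = as.list(model$kinds),
    target = model$target,
    target_levels = model$target_levels,
    threshold = model$threshold,
    dropped = model$dropped,
    converged = model$converged
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Read a serialized model
#'
#' @param path Path written by [write_awlr()].
#' @return An `awlr` model.
#' @export
read_awlr <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  adj <- obj$adjustment
  class(adj) <- c("awlr_adjustment", "data.frame")
  w <- obj$weights
  class(w) <- c("attribute_weights", "data.frame")
  attr(w, "method") <- obj$weight_method
  attr(w, "n") <- nrow(w)
  schemes <- lapply(obj$schemes, function(s) mdlp_scheme(s$attribute, unlist(s$cuts)))
  std <- lapply(obj$standardization, function(s) list(center = s$center, scale = s$scale))
  structure(list(alpha = obj$alpha, adjustment = adj, weights = w,
                 schemes = schemes, standardization = std,
                 levels = lapply(obj$levels, as.character),
                 kinds = unlist(obj$kinds),
                 target = obj$target,
                 target_levels = obj$target_levels,
                 threshold = obj$threshold,
                 weight_method = obj$weight_method,
                 dropped = as.character(unlist(obj$dropped)),
                 converged = obj$converged),
            class = "awlr")
}
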