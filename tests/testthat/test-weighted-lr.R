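test_that("maximum-likelihood fit recovers closed-form and null cases", {
  set.seed(3)
  # attribute independent of a balanced target: alpha ~ 0, beta ~ 0
  n <- 4000
  x <- matrix(rnorm(n), ncol = 1, dimnames = list(NULL, "x"))
  y <- rep(0:1, n / 2)
  fit <- fit_lr(x, y)
  expect_lt(abs(fit$alpha), 0.1)
  expect_lt(abs(fit$beta), 0.1)

  # saturated 2x2 model: beta = log odds ratio ln(ad/bc)
  counts <- c(a = 40, b = 25, c = 15, d = 60) # (x=1,y=1), (x=1,y=0), (x=0,y=1), (x=0,y=0)
  x2 <- matrix(rep(c(1, 1, 0, 0), counts), ncol = 1, dimnames = list(NULL, "x"))
  y2 <- rep(c(1, 0, 1, 0), counts)
  fit2 <- fit_lr(x2, y2)
  expect_equal(unname(fit2$beta), log(40 * 60 / (25 * 15)), tolerance = 1e-6)

  # duplicating every record leaves the MLE unchanged
  fit2d <- fit_lr(rbind(x2, x2), c(y2, y2))
  expect_equal(fit2d$alpha, fit2$alpha, tolerance = 1e-8)
  expect_equal(fit2d$beta, fit2$beta, tolerance = 1e-8)

  expect_error(fit_lr(x2, rep(1, nrow(x2))), "single class")
  expect_error(fit_lr(matrix(1, 10, 1), rep(0:1, 5)), "constant")
})

test_that("coefficient adjustment reproduces the published worked example", {
  adj <- adjust_coefficients(
    c(x1a = -0.751, x1b = -0.751, x2a = 0.262, x2b = 0.262),
    c(x1a = 1.84, x1b = 0.86, x2a = 1.84, x2b = 0.86))
  expect_equal(adj$adjusted, c(-1.36, -0.901, 0.871, 0.412), tolerance = 0.002)
  expect_false(any(adj$clipped))
})

test_that("coefficient adjustment handles the enumerated edge cases", {
  # w = 1: ln(1) = 0, untouched
  expect_equal(adjust_coefficients(c(x = 0.5), c(x = 1))$adjusted, 0.5)
  # beta = 0: left unadjusted
  expect_equal(adjust_coefficients(c(x = 0), c(x = 2.5))$adjusted, 0)
  # w = 0 literal rule: additive term is exactly 1e-10
  lit <- adjust_coefficients(c(x = 0.4), c(x = 0))
  expect_equal(lit$term, 1e-10)
  expect_equal(lit$adjusted, 0.4 + 1e-10)
  # w = 0 alternative: no adjustment
  expect_equal(adjust_coefficients(c(x = 0.4), c(x = 0),
                                   zero_weight = "zero")$adjusted, 0.4)
  expect_error(adjust_coefficients(c(x = 1), c(x = -0.2)), "nonnegative")
  # dummy coefficients share their attribute's weight through the map
  adj <- adjust_coefficients(c(drugA = 0.3, drugB = -0.2, age = 0.1),
                             c(drug = 2, age = 0.5),
                             map = c("drug", "drug", "age"))
  expect_equal(adj$adjusted, c(0.3 + log(2), -0.2 - log(2), 0.1 + abs(log(0.5))),
               tolerance = 1e-12)
})

test_that("adjustment always preserves the raw coefficient's sign", {
  grid <- expand.grid(beta = seq(-3, 3, by = 0.25),
                      w = seq(0.05, 3, by = 0.05))
  adj <- adjust_coefficients(grid$beta, setNames(grid$w, paste0("a", seq_len(nrow(grid)))),
                             map = paste0("a", seq_len(nrow(grid))))
  nz <- grid$beta != 0
  expect_true(all(sign(adj$adjusted[nz]) == sign(grid$beta[nz])))
  # the rule moves coefficients away from zero, never across it
  expect_true(all(abs(adj$adjusted[nz]) >= abs(grid$beta[nz]) - 1e-12))
})

test_that("unit weights leave the weighted model identical to standard LR", {
  d <- toy_ade(n = 500, seed = 9)
  plain <- awlr_fit(d, weight_method = "none")
  forced <- plain
  forced$adjustment <- adjust_coefficients(
    setNames(plain$adjustment$beta, plain$adjustment$coefficient),
    setNames(rep(1, 3), c("drug", "site", "age")),
    map = plain$adjustment$attribute)
  expect_equal(predict(forced, d), predict(plain, d), tolerance = 1e-12)
})

test_that("prediction applies the logistic transform of the adjusted predictor", {
  d <- toy_ade(n = 500, seed = 15)
  m <- awlr_fit(d, weight_method = "chi2")
  p <- predict(m, d)
  expect_true(all(p >= 0 & p <= 1))
  # a record at the continuous mean and categorical reference levels scores
  # logistic(alpha)
  base <- data.frame(drug = factor("A", levels = c("A", "B", "C")),
                     site = factor("north", levels = c("north", "south")),
                     age = m$standardization$age$center)
  expect_equal(predict(m, base), plogis(m$alpha), tolerance = 1e-12)
  # monotonicity in a positively-adjusted continuous attribute
  age_coef <- m$adjustment$adjusted[m$adjustment$coefficient == "age"]
  asc <- transform(base[rep(1, 5), ], age = seq(40, 90, length.out = 5))
  probs <- predict(m, asc)
  if (age_coef > 0) expect_true(all(diff(probs) >= 0))
  else expect_true(all(diff(probs) <= 0))
  # mismatched columns are refused
  expect_error(predict(m, base[, 1:2]), "lacks attribute")
})

test_that("the full weighted fit amplifies informative attributes and shrinks noise", {
  spec <- ade_sim_spec(
    n = 3000, prevalence = 0.5,
    categorical = list(
      strong = sim_categorical(c("a", "b"), assoc = 0.5),
      noise = sim_categorical(c("a", "b"), assoc = 0)
    ),
    continuous = list()
  )
  d <- simulate_ade(spec, seed = 23)
  m <- awlr_fit(d, weight_method = "chi2")
  adj <- m$adjustment
  strong_row <- adj[adj$attribute == "strong", ]
  w <- setNames(m$weights$weight, m$weights$attribute)
  expect_gt(w[["strong"]], 1)
  expect_lt(w[["noise"]], 1)
  # strong attribute's coefficient magnitude grows by |ln w| > 0
  expect_gt(abs(strong_row$adjusted), abs(strong_row$beta))
  # refit on identical data is bit-reproducible
  m2 <- awlr_fit(d, weight_method = "chi2")
  expect_identical(coef(m), coef(m2))
})

test_that("levels unobserved in training are treated as the reference", {
  d <- toy_ade(n = 200, seed = 81)
  train <- as.data.frame(d)[d$drug != "C", ]
  train$drug <- factor(train$drug, levels = c("A", "B", "C")) # level kept, empty
  m <- awlr_fit(ade_data(train, target = "severity"), weight_method = "none")
  expect_true("drugC" %in% m$dropped)
  expect_false("drugC" %in% m$adjustment$coefficient)
  # records with the unseen level predict as if at the reference level
  p <- predict(m, as.data.frame(d))
  ref <- as.data.frame(d)
  ref$drug[ref$drug == "C"] <- "A"
  expect_equal(p[d$drug == "C"], predict(m, ref)[d$drug == "C"], tolerance = 1e-12)
})

test_that("models serialize to JSON and round-trip predictions", {
  d <- toy_ade(n = 400, seed = 33)
  m <- awlr_fit(d, weight_method = "chi2")
  path <- withr::local_tempfile(fileext = ".json")
  write_awlr(m, path)
  m2 <- read_awlr(path)
  expect_equal(predict(m2, d), predict(m, d), tolerance = 1e-12)
  expect_equal(predict(m2, d, type = "class"), predict(m, d, type = "class"))
})
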