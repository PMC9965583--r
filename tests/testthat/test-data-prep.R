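test_that("therapy duration is a whole-day difference with invalid cases flagged", {
  expect_identical(compute_duration("2010-01-01", "2010-01-01"), 0L)
  expect_identical(compute_duration("2010-01-01", "2010-01-31"), 30L)
  # span of the longest observed therapy-to-event interval (8677 days)
  expect_identical(compute_duration("2004-01-01", "2027-10-04"), 8677L)
  expect_identical(compute_duration("2004-01-01", "2027-10-05"), 8678L)
  # event before therapy start or junk dates -> NA for downstream exclusion
  expect_true(is.na(compute_duration("2010-02-01", "2010-01-01")))
  expect_true(is.na(compute_duration("not-a-date", "2010-01-01")))
})

test_that("dose conversion multiplies milligrams by 1000 and is microgram-idempotent", {
  expect_equal(convert_dose(70, "milligram"), 70000)
  expect_equal(convert_dose(20, "microgram"), 20)
  expect_equal(convert_dose(0, "milligram"), 0)
  x <- c(1.5, 2, 0.25)
  once <- convert_dose(x, rep("milligram", 3))
  expect_equal(convert_dose(once, rep("microgram", 3)), once)
  expect_true(is.na(convert_dose(5, "furlong")))
})

test_that("standardization uses reference statistics and round-trips", {
  expect_equal(as.numeric(standardize(c(1, 2, 3), center = 2, scale = 1)),
               c(-1, 0, 1))
  expect_equal(as.numeric(standardize(c(5, 5, 5), center = 5, scale = 1)),
               c(0, 0, 0))
  set.seed(11)
  x <- rnorm(50, 10, 3)
  z <- standardize(x)
  expect_equal(mean(z), 0, tolerance = 1e-9)
  expect_equal(sd(z), 1, tolerance = 1e-9)
  back <- as.numeric(z) * attr(z, "scale") + attr(z, "center")
  expect_equal(back, x, tolerance = 1e-12)
  expect_error(standardize(rep(3, 4)), "constant")
  # held-out data are scaled by training statistics, not their own
  test_z <- standardize(c(100, 200), center = attr(z, "center"),
                        scale = attr(z, "scale"))
  expect_equal(as.numeric(test_z), (c(100, 200) - attr(z, "center")) / attr(z, "scale"))
})

test_that("severity labelling follows the critical-outcome definition and is monotone", {
  expect_equal(as.character(label_severity("hospitalization;other")), "severe")
  expect_equal(as.character(label_severity("other")), "non-severe")
  expect_equal(as.character(label_severity(list(character(0)))), "non-severe")
  expect_equal(as.character(label_severity("mystery-code")), "non-severe")
  # monotone: adding a critical code never demotes severe to non-severe
  set.seed(21)
  pool <- c(SEVERE_OUTCOMES, "other", "congenital anomaly", "required intervention")
  for (i in 1:50) {
    codes <- sample(pool, sample(0:4, 1))
    before <- as.character(label_severity(list(codes)))
    after <- as.character(label_severity(list(c(codes, sample(SEVERE_OUTCOMES, 1)))))
    expect_equal(after, "severe")
    if (before == "severe") expect_equal(after, "severe")
  }
})

make_raw <- function() {
  data.frame(
    pid = sprintf("P%02d", 1:8),
    age = c(70, 65, NA, 80, 55, 62, 71, 68),
    gender = c("F", "F", "M", "F", "M", "F", "", "M"),
    drug = rep(c("Forteo", "Fosamax"), 4),
    amount = c(20, 70, 20, 70, 20, 70, 20, -1),
    unit = c("microgram", "milligram", "microgram", "milligram",
             "stone", "milligram", "microgram", "milligram"),
    start = c("2010-01-01", "2011-05-02", "2010-01-01", "2012-03-01",
              "2010-01-01", "2013-07-09", "2010-01-01", "2010-01-01"),
    event = c("2010-06-01", "2011-05-02", "2010-02-01", "2011-03-01",
              "2010-02-01", "2014-01-01", "2010-02-01", "2010-03-01"),
    outcomes = c("hospitalization", "other", "death", "other;disability",
                 "other", "life-threatening;other", "other", "other"),
    stringsAsFactors = FALSE
  )
}

ade_roles <- c(pid = "id", age = "continuous", gender = "categorical",
               drug = "categorical", amount = "dose_amount",
               unit = "dose_unit", start = "date_start", end = "date_end",
               outcomes = "outcome")
names(ade_roles)[names(ade_roles) == "end"] <- "event"

test_that("record preparation derives attributes and logs every exclusion", {
  out <- prepare_ade(make_raw(), ade_roles)
  excl <- exclusion_log(out)
  # P03: missing age; P04: event before start; P05: unknown unit;
  # P07: empty gender; P08: negative dose
  expect_setequal(excl$record_id, c("P03", "P04", "P05", "P07", "P08"))
  expect_equal(nrow(out), 3)
  expect_true(all(c("duration", "dose_amount", "age", "gender", "drug",
                    "severity") %in% names(out)))
  expect_equal(out$dose_amount, c(20, 70000, 70000))
  expect_equal(out$duration, c(151, 0, 176))
  expect_equal(as.character(out$severity), c("severe", "non-severe", "severe"))
  expect_equal(unname(attribute_kinds(out)[c("age", "gender")]),
               c("continuous", "categorical"))
})

test_that("column roles round-trip through the YAML config", {
  path <- withr::local_tempfile(fileext = ".yml")
  writeLines(paste(names(ade_roles), ade_roles, sep = ": "), path)
  expect_identical(read_roles(path)[names(ade_roles)], ade_roles)
  bad <- withr::local_tempfile(fileext = ".yml")
  writeLines("age: numericish", bad)
  expect_error(read_roles(bad), "unknown column roles")
})

test_that("the shipped synthetic example cleans end-to-end", {
  raw <- read.csv(system.file("extdata", "synthetic_raw_records.csv",
                              package = "awlr"), stringsAsFactors = FALSE)
  roles <- read_roles(system.file("extdata", "roles_example.yml",
                                  package = "awlr"))
  d <- prepare_ade(raw, roles)
  expect_s3_class(d, "ade_data")
  expect_equal(nrow(d) + nrow(exclusion_log(d)), nrow(raw))
  expect_true(all(d$duration >= 0))
  expect_setequal(unique(attribute_kinds(d)), c("categorical", "continuous"))
})

test_that("the dataset container validates target and kinds", {
  df <- data.frame(a = factor(c("x", "y")), b = c(1, 2),
                   severity = factor(c("severe", "non-severe")))
  d <- ade_data(df)
  expect_equal(unname(attribute_kinds(d)), c("categorical", "continuous"))
  expect_equal(target_name(d), "severity")
  expect_error(ade_data(df[, 1:2]), "not found")
  df3 <- df
  df3$severity <- factor(rep("severe", 2))
  expect_error(ade_data(df3), "two classes")
})
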