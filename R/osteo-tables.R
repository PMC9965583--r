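#' Published attribute-by-severity counts of an osteoporosis cohort
#'
#' Contingency tables (severity class x attribute value) for the four
#' categorical attributes of a published osteoporosis adverse-event cohort
#' drawn from the public FDA adverse-event database (2004-2018; 11956 severe
#' and 8620 non-severe reports). They serve as realistic oracle inputs for
#' the weighting functions and as the default marginals of the synthetic
#' generator. The disease table's non-severe column is not printed legibly
#' in the source summary and is reconstructed here by row-sum arithmetic
#' (totals minus severe counts); it is exact given the printed totals.
#'
#' Per-class age and duration distributions are not published, so no
#' continuous-attribute fixture exists; synthetic continuous attributes are
#' used for discretization tests instead.
#'
#' @return Named list of `ade_contingency` tables: `gender`, `drug_name`,
#'   `dose_frequency`, `disease`. Rows are `non-severe` / `severe`.
#' @examples
#' chi_square(osteo_attribute_tables()$gender)
#' @export
osteo_attribute_tables <- function() {
  mk <- function(values, severe, nonsevere) {
    as_contingency(rbind("non-severe" = stats::setNames(nonsevere, values),
                         "severe" = stats::setNames(severe, values)))
  }
  list(
    gender = mk(c("Female", "Male"),
                severe = c(10633, 1323),
                nonsevere = c(7889, 731)),
    drug_name = mk(c("Forteo", "Aclasta", "Zolendronic acid", "Prolia",
                     "Reclast", "Fosamax", "Actonel", "Evista", "Boniva",
                     "Alendronate sodium"),
                   severe = c(7929, 863, 522, 508, 580, 564, 441, 267, 147, 135),
                   nonsevere = c(4051, 770, 748, 713, 599, 577, 383, 277, 372, 130)),
    dose_frequency = mk(c("Once", "Every day", "Every week", "Every month",
                          "Every 3 months", "Every 6 months", "Every year"),
                        severe = c(185, 8364, 886, 192, 28, 443, 1858),
                        nonsevere = c(164, 4424, 915, 419, 46, 600, 2052)),
    # non-severe counts reconstructed as total - severe
    disease = mk(c("Osteoporosis", "Osteopenia", "Osteoporosis prophylaxis"),
                 severe = c(11536, 342, 78),
                 nonsevere = c(8086, 447, 87))
  )
}

#' Published per-fold chi-square attribute weights of the osteoporosis study
#'
#' The chi-square attribute weights reported for each of the 10
#' balanced-sampling folds of the published osteoporosis cohort analysis
#' (six attributes; every column sums to 6 up to the printed rounding).
#' The exact values depend on the study's private training splits and are
#' used here only for structural checks (weight conservation, ranking
#' shape), not as a reproduction target.
#'
#' @return 6 x 10 numeric matrix, attributes in rows, folds in columns.
#' @export
osteo_fold_weights <- function() {
  m <- rbind(
    disease = c(0.19, 0.14, 0.15, 0.16, 0.18, 0.17, 0.17, 0.18, 0.17, 0.18),
    gender = c(0.07, 0.06, 0.07, 0.09, 0.09, 0.08, 0.05, 0.08, 0.07, 0.07),
    drug_name = c(2.07, 2.06, 2.02, 2.08, 2.08, 1.98, 2.07, 1.92, 1.98, 2.07),
    dose_frequency = c(1.87, 1.83, 1.78, 1.84, 1.89, 1.82, 1.82, 1.71, 1.84, 1.81),
    age = c(0.75, 0.78, 0.87, 0.72, 0.68, 0.78, 0.72, 0.87, 0.87, 0.76),
    duration = c(1.05, 1.13, 1.11, 1.11, 1.08, 1.17, 1.17, 1.24, 1.07, 1.11)
  )
  colnames(m) <- paste0("fold", 1:10)
  m
}
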