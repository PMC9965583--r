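#' Outcome codes that define a severe adverse event
#'
#' Following the WHO definition, an adverse drug event is severe when its
#' outcome is death, disability, hospitalization or a life-threatening
#' condition; any other outcome is non-severe.
#'
#' @format Character vector of the four critical outcome codes.
#' @export
SEVERE_OUTCOMES <- c("death", "disability", "hospitalization", "life-threatening")

#' Therapy duration in whole days
#'
#' Number of days between the start of therapy and the occurrence of the
#' adverse event. Unparseable dates or an event date preceding the therapy
#' start yield `NA`; such records are meant to be excluded downstream with a
#' logged reason.
#'
#' @param therapy_start Character or `Date` vector (ISO-8601 when character).
#' @param event_date Character or `Date` vector, same length.
#' @return Integer vector of nonnegative day counts (`NA` where invalid).
#' @examples
#' compute_duration("2010-01-01", "2010-01-31")
#' @export
compute_duration <- function(therapy_start, event_date) {
  parse_iso <- function(x) {
    if (inherits(x, "Date")) x else as.Date(as.character(x), format = "%Y-%m-%d")
  }
  start <- parse_iso(therapy_start)
  end <- parse_iso(event_date)
  d <- as.integer(floor(as.numeric(difftime(end, start, units = "days"))))
  d[!is.na(d) & d < 0] <- NA_integer_
  d
}

#' Convert dose amounts to micrograms
#'
#' Doses reported in milligrams are multiplied by 1000; microgram doses pass
#' through unchanged. Unknown units yield `NA` so the record can be excluded.
#'
#' @param amount Numeric vector of dose amounts.
#' @param unit Character vector of units; `"milligram"`/`"mg"` or
#'   `"microgram"`/`"ug"`/`"mcg"` (case-insensitive).
#' @return Numeric vector of doses in micrograms.
#' @examples
#' convert_dose(70, "milligram")
#' @export
convert_dose <- function(amount, unit) {
  stopifnot(length(amount) == length(unit))
  u <- tolower(trimws(as.character(unit)))
  out <- rep(NA_real_, length(amount))
  mg <- u %in% c("milligram", "milligrams", "mg")
  ug <- u %in% c("microgram", "micrograms", "ug", "mcg", "µg")
  out[mg] <- amount[mg] * 1000
  out[ug] <- amount[ug]
  out[!is.na(out) & out < 0] <- NA_real_
  out
}

#' Standardize a numeric vector against reference statistics
#'
#' Centres and scales to mean 0 / sd 1 using the supplied reference mean and
#' standard deviation. When applied to held-out data the reference statistics
#' must come from the training portion, so that no information leaks from the
#' test set.
#'
#' @param x Numeric vector.
#' @param center Reference mean; defaults to `mean(x, na.rm = TRUE)`.
#' @param scale Reference standard deviation; defaults to
#'   `sd(x, na.rm = TRUE)`. Must be strictly positive.
#' @return Numeric vector `(x - center) / scale` with the reference
#'   statistics attached as attributes `"center"` and `"scale"`.
#' @export
standardize <- function(x, center = mean(x, na.rm = TRUE),
                        scale = stats::sd(x, na.rm = TRUE)) {
  if (is.na(scale) || scale <= 0) {
    stop("cannot standardize a constant attribute (reference sd must be > 0)")
  }
  out <- (x - center) / scale
  attr(out, "center") <- center
  attr(out, "scale") <- scale
  out
}

#' Label event severity from outcome codes
#'
#' An event is severe when any of its outcome codes is one of
#' [SEVERE_OUTCOMES]; events with no critical code — including empty or
#' unrecognized outcome sets — are non-severe.
#'
#' @param outcome_codes A list of character vectors (one set of codes per
#'   record), or a character vector whose elements hold `;`-separated codes.
#' @return Factor with levels `c("non-severe", "severe")`.
#' @examples
#' label_severity(c("hospitalization;other", "other"))
#' @export
label_severity <- function(outcome_codes) {
  if (!is.list(outcome_codes)) {
    outcome_codes <- strsplit(as.character(outcome_codes), ";", fixed = TRUE)
  }
  severe <- vapply(outcome_codes, function(codes) {
    codes <- tolower(trimws(codes))
    any(codes %in% SEVERE_OUTCOMES)
  }, logical(1))
  factor(ifelse(severe, "severe", "non-severe"),
         levels = c("non-severe", "severe"))
}

#' Read a column-role configuration
#'
#' Roles are declared in a YAML file mapping column name to one of:
#' `id`, `categorical`, `continuous`, `date_start`, `date_end`,
#' `dose_amount`, `dose_unit`, `outcome`, `target`, `drop`.
#'
#' @param path Path to the YAML file.
#' @return Named character vector of roles.
#' @export
read_roles <- function(path) {
  roles <- unlist(yaml::read_yaml(path))
  validate_roles(roles)
  roles
}

validate_roles <- function(roles) {
  known <- c("id", "categorical", "continuous", "date_start", "date_end",
             "dose_amount", "dose_unit", "outcome", "target", "drop")
  bad <- setdiff(unique(roles), known)
  if (length(bad)) {
    stop("unknown column roles: ", paste(bad, collapse = ", "))
  }
  if (sum(roles == "target") + sum(roles == "outcome") == 0) {
    stop("roles must declare a 'target' or an 'outcome' column")
  }
  invisible(roles)
}

#' Prepare raw adverse-event records for modelling
#'
#' Applies the standard pharmacovigilance cleaning pipeline: parse dates and
#' derive the therapy `duration` in days, convert dose amounts to micrograms,
#' label severity from outcome codes (or accept an already-binary target),
#' and drop records with missing or invalid required fields. Every exclusion
#' is logged with its reason. Continuous attributes are returned on their raw
#' scale; standardization belongs to model fitting so its statistics can come
#' from the training split only.
#'
#' @param raw Data frame of raw records.
#' @param roles Named character vector of column roles (see [read_roles()]).
#' @param drop_duplicates Drop exact duplicate records after cleaning
#'   (default `FALSE`; duplicate handling in spontaneous-report data is a
#'   policy choice, so it is explicit and logged).
#' @return An object of class `ade_data`: the cleaned modelling table with
#'   attributes `kinds` (per-attribute `"categorical"`/`"continuous"`),
#'   `target` (target column name) and `exclusions` (data frame of record
#'   id / reason).
#' @export
prepare_ade <- function(raw, roles, drop_duplicates = FALSE) {
  stopifnot(is.data.frame(raw))
  validate_roles(roles)
  missing_cols <- setdiff(names(roles)[roles != "drop"], names(raw))
  if (length(missing_cols)) {
    stop("columns declared in roles but absent from data: ",
         paste(missing_cols, collapse = ", "))
  }
  n <- nrow(raw)
  id_col <- names(roles)[roles == "id"][1]
  ids <- if (!is.na(id_col)) as.character(raw[[id_col]]) else as.character(seq_len(n))
  reason <- rep(NA_character_, n)
  flag <- function(bad, why) {
    bad <- bad & is.na(reason)
    reason[bad] <<- why
  }

  out <- list()
  kinds <- character()

  start_col <- names(roles)[roles == "date_start"][1]
  end_col <- names(roles)[roles == "date_end"][1]
  if (!is.na(start_col) && !is.na(end_col)) {
    dur <- compute_duration(raw[[start_col]], raw[[end_col]])
    flag(is.na(dur), "invalid or inconsistent therapy/event dates")
    out$duration <- dur
    kinds["duration"] <- "continuous"
  }

  amt_col <- names(roles)[roles == "dose_amount"][1]
  unit_col <- names(roles)[roles == "dose_unit"][1]
  if (!is.na(amt_col)) {
    dose <- if (!is.na(unit_col)) {
      convert_dose(raw[[amt_col]], raw[[unit_col]])
    } else {
      as.numeric(raw[[amt_col]])
    }
    flag(is.na(dose), "missing dose amount or unknown dose unit")
    out$dose_amount <- dose
    kinds["dose_amount"] <- "continuous"
  }

  for (col in names(roles)[roles == "continuous"]) {
    v <- suppressWarnings(as.numeric(raw[[col]]))
    flag(is.na(v), paste("missing continuous attribute:", col))
    out[[col]] <- v
    kinds[col] <- "continuous"
  }
  for (col in names(roles)[roles == "categorical"]) {
    v <- as.character(raw[[col]])
    v[!is.na(v) & trimws(v) == ""] <- NA_character_
    flag(is.na(v), paste("missing categorical attribute:", col))
    out[[col]] <- v
    kinds[col] <- "categorical"
  }

  target_col <- names(roles)[roles == "target"][1]
  outcome_col <- names(roles)[roles == "outcome"][1]
  if (!is.na(target_col)) {
    tv <- tolower(trimws(as.character(raw[[target_col]])))
    ok <- tv %in% c("severe", "non-severe")
    flag(!ok, "target not one of severe/non-severe")
    sev <- factor(tv, levels = c("non-severe", "severe"))
  } else {
    sev <- label_severity(raw[[outcome_col]])
  }
  out$severity <- sev

  keep <- is.na(reason)
  tab <- data.frame(out, stringsAsFactors = FALSE, check.names = FALSE)[keep, , drop = FALSE]
  exclusions <- data.frame(record_id = ids[!keep], reason = reason[!keep],
                           stringsAsFactors = FALSE)
  if (drop_duplicates) {
    dup <- duplicated(tab)
    if (any(dup)) {
      exclusions <- rbind(exclusions,
                          data.frame(record_id = rownames(tab)[dup],
                                     reason = "duplicate record",
                                     stringsAsFactors = FALSE))
      tab <- tab[!dup, , drop = FALSE]
    }
  }
  for (col in names(kinds)[kinds == "categorical"]) {
    tab[[col]] <- factor(tab[[col]])
  }
  rownames(tab) <- NULL
  ade_data(tab, target = "severity", kinds = kinds, exclusions = exclusions)
}

#' Construct a modelling dataset
#'
#' Light container for a cleaned adverse-event table: a data frame plus the
#' target column name and the kind (categorical or continuous) of every
#' attribute. Validity: the target is a two-level factor present in the
#' table, every declared attribute exists, and kinds match column types.
#'
#' @param data Data frame of attributes plus the target column.
#' @param target Name of the binary target column (factor, positive class =
#'   last level, conventionally `"severe"`).
#' @param kinds Named character vector mapping each attribute column to
#'   `"categorical"` or `"continuous"`. Defaults to factor/character columns
#'   as categorical and numeric columns as continuous.
#' @param exclusions Optional data frame logging dropped records.
#' @return Object of class `ade_data` (a data frame with metadata
#'   attributes).
#' @export
ade_data <- function(data, target = "severity", kinds = NULL, exclusions = NULL) {
  stopifnot(is.data.frame(data))
  if (!target %in% names(data)) stop("target column '", target, "' not found")
  if (!is.factor(data[[target]])) {
    data[[target]] <- factor(data[[target]])
  }
  if (nlevels(data[[target]]) != 2) {
    stop("target must have exactly two classes, got ",
         nlevels(data[[target]]))
  }
  attrs <- setdiff(names(data), target)
  if (is.null(kinds)) {
    kinds <- vapply(data[attrs], function(col) {
      if (is.numeric(col)) "continuous" else "categorical"
    }, character(1))
  }
  kinds <- kinds[attrs]
  names(kinds) <- attrs
  if (anyNA(kinds)) stop("every attribute needs a declared kind")
  bad <- !kinds %in% c("categorical", "continuous")
  if (any(bad)) stop("invalid kinds for: ", paste(attrs[bad], collapse = ", "))
  for (a in attrs[kinds == "categorical"]) {
    if (!is.factor(data[[a]])) data[[a]] <- factor(data[[a]])
  }
  for (a in attrs[kinds == "continuous"]) {
    if (!is.numeric(data[[a]])) stop("continuous attribute '", a, "' is not numeric")
  }
  structure(data,
            target = target,
            kinds = kinds,
            exclusions = exclusions,
            class = c("ade_data", "data.frame"))
}

#' @export
print.ade_data <- function(x, ...) {
  kinds <- attr(x, "kinds")
  tgt <- attr(x, "target")
  cat("Adverse-event modelling dataset: ", nrow(x), " records, ",
      length(kinds), " attributes\n", sep = "")
  cat("  categorical: ",
      paste(names(kinds)[kinds == "categorical"], collapse = ", "), "\n",
      sep = "")
  cat("  continuous:  ",
      paste(names(kinds)[kinds == "continuous"], collapse = ", "), "\n",
      sep = "")
  cat("  target '", tgt, "': ", sep = "")
  print(table(x[[tgt]]))
  excl <- attr(x, "exclusions")
  if (!is.null(excl) && nrow(excl)) {
    cat("  excluded records: ", nrow(excl), "\n", sep = "")
  }
  invisible(x)
}

#' Attribute kinds of a dataset
#' @param data An `ade_data` object.
#' @return Named character vector (`"categorical"`/`"continuous"`).
#' @export
attribute_kinds <- function(data) attr(data, "kinds")

#' Target column name of a dataset
#' @param data An `ade_data` object.
#' @return Character scalar.
#' @export
target_name <- function(data) attr(data, "target")

#' Exclusion log of a prepared dataset
#' @param data An `ade_data` object.
#' @return Data frame of record id / reason, or `NULL`.
#' @export
exclusion_log <- function(data) attr(data, "exclusions")

# Subset rows keeping ade_data metadata.
subset_ade <- function(data, idx) {
  out <- as.data.frame(data)[idx, , drop = FALSE]
  rownames(out) <- NULL
  ade_data(out, target = attr(data, "target"), kinds = attr(data, "kinds"))
}
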