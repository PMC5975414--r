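# Harmonization of raw TCGA-style clinical fields into small categorical
# vocabularies plus an overall-survival (time, event) pair. Unknown,
# missing or "Indeterminate" inputs always land in the literal category
# "UNDEFINED"; the rules are total over arbitrary input strings.

UNDEFINED <- "UNDEFINED"

is_missing_raw <- function(v) {
  is.na(v) | !nzchar(trimws(as.character(v))) |
    tolower(trimws(as.character(v))) %in%
      c("indeterminate", "na", "[not available]", "[unknown]")
}

as_num <- function(v) suppressWarnings(as.numeric(v))

#' Bin packs smoked per year into three categories
#'
#' Cut-offs 10 and 100 give the half-open bins `[0,10)` ("less than 10"),
#' `[10,100)` ("less than 100") and `[100,Inf)` ("greater than 100");
#' missing values map to `"UNDEFINED"`.
#'
#' @param value Numeric vector of pack-years (may contain `NA`).
#' @return Character vector of category labels.
#' @export
bin_pack_years <- function(value) {
  value <- as_num(value)
  if (any(value < 0, na.rm = TRUE)) stop("pack-years must be non-negative")
  out <- rep(UNDEFINED, length(value))
  out[!is.na(value) & value < 10] <- "less than 10"
  out[!is.na(value) & value >= 10 & value < 100] <- "less than 100"
  out[!is.na(value) & value >= 100] <- "greater than 100"
  out
}

#' Derive overall survival (time, event) from raw follow-up fields
#'
#' The event is death (1) iff `day_to_death` is present and non-zero,
#' otherwise censored (0) when any time information exists. The survival
#' time is the larger of the two present values. Both fields missing
#' yields `(NA, NA)`.
#'
#' @param day_to_death Numeric vector (days), `NA` for missing.
#' @param days_to_last_follow_up Numeric vector (days), `NA` for missing.
#' @return Data frame with columns `time` and `event`.
#' @export
derive_survival <- function(day_to_death, days_to_last_follow_up) {
  d <- as_num(day_to_death)
  f <- as_num(days_to_last_follow_up)
  n <- max(length(d), length(f))
  d <- rep_len(d, n); f <- rep_len(f, n)
  if (any(d < 0, na.rm = TRUE) || any(f < 0, na.rm = TRUE)) {
    stop("survival times must be non-negative")
  }
  time <- pmax(d, f, na.rm = TRUE)          # NA only when both missing
  event <- ifelse(is.na(d) & is.na(f), NA_real_,
                  as.numeric(!is.na(d) & d != 0))
  data.frame(time = time, event = event)
}

#' Collapse tumor stage strings to five classes
#'
#' Maps any substage (e.g. `"Stage IIIA"`) to its root numeral, yielding
#' the five classes I, II, III, IV and X. Matching is case-insensitive;
#' the `"Stage "` prefix is optional and only a single trailing substage
#' letter (A/B/C) is stripped. Unmatched strings, `"Indeterminate"` and
#' missing values map to `"UNDEFINED"`. Applies identically to
#' pathology, clinical and Masaoka stage fields.
#'
#' @param raw_stage Character vector of raw stage strings.
#' @return Character vector of `"I"`, `"II"`, `"III"`, `"IV"`, `"X"` or
#'   `"UNDEFINED"`.
#' @export
collapse_stage <- function(raw_stage) {
  raw_stage <- as.character(raw_stage)
  out <- rep(UNDEFINED, length(raw_stage))
  ok <- !is_missing_raw(raw_stage)
  s <- toupper(trimws(raw_stage[ok]))
  s <- sub("^STAGE[ _]+", "", s)
  root <- sub("^(IV|III|II|I)[ABC]$", "\\1", s)
  valid <- root %in% c("I", "II", "III", "IV", "X")
  res <- rep(UNDEFINED, length(s))
  res[valid] <- root[valid]
  out[ok] <- res
  out
}

#' Merge liver-cancer risk-factor categories
#'
#' "Alpha-1 antitrypsin deficiency", "hemochromatosis" and "other" are
#' combined into `"others"`; "Alcohol consumption", "hepatitis b" and
#' "hepatitis c" keep their own class. Matching is case-insensitive;
#' anything else (including missing) maps to `"UNDEFINED"`.
#'
#' @param raw Character vector of raw risk-factor strings.
#' @return Character vector of category labels.
#' @export
merge_lihc_risk <- function(raw) {
  raw <- as.character(raw)
  out <- rep(UNDEFINED, length(raw))
  ok <- !is_missing_raw(raw)
  low <- tolower(trimws(raw[ok]))
  res <- rep(UNDEFINED, length(low))
  res[low %in% c("alpha-1 antitrypsin deficiency", "hemochromatosis",
                 "other")] <- "others"
  res[low == "alcohol consumption"] <- "Alcohol consumption"
  res[low == "hepatitis b"] <- "hepatitis b"
  res[low == "hepatitis c"] <- "hepatitis c"
  out[ok] <- res
  out
}

#' Bin alcohol consumption per day
#'
#' Zero maps to `"0"`, any positive value to `">0"`, missing to
#' `"UNDEFINED"`.
#'
#' @param value Numeric vector.
#' @return Character vector of `"0"`, `">0"` or `"UNDEFINED"`.
#' @export
bin_alcohol <- function(value) {
  value <- as_num(value)
  if (any(value < 0, na.rm = TRUE)) stop("alcohol per day must be non-negative")
  out <- rep(UNDEFINED, length(value))
  out[!is.na(value) & value == 0] <- "0"
  out[!is.na(value) & value > 0] <- ">0"
  out
}

#' Bin number of pregnancies into six classes
#'
#' Counts 1 through 5 map to their numeral strings, anything above 5 to
#' `">5"`. Zero is outside the declared vocabulary and maps to
#' `"UNDEFINED"`, as do missing values.
#'
#' @param value Numeric vector of pregnancy counts.
#' @return Character vector of `"1"` .. `"5"`, `">5"` or `"UNDEFINED"`.
#' @export
bin_pregnancies <- function(value) {
  value <- as_num(value)
  if (any(value < 0, na.rm = TRUE)) stop("pregnancy count must be non-negative")
  out <- rep(UNDEFINED, length(value))
  sel <- !is.na(value) & value >= 1 & value <= 5 & value == floor(value)
  out[sel] <- as.character(value[sel])
  out[!is.na(value) & value > 5] <- ">5"
  out
}

passthrough_category <- function(raw) {
  raw <- as.character(raw)
  out <- trimws(raw)
  out[is_missing_raw(raw)] <- UNDEFINED
  out
}

#' Default harmonization rules
#'
#' The shipped rule set covering the raw TCGA-style fields the package's
#' transformations handle: sample type pass-through, pack-years binning,
#' overall-survival construction, stage collapsing (pathology, clinical,
#' Masaoka), liver-cancer risk-factor merging, alcohol and pregnancy
#' binning. Rules are data: they can also be loaded from a JSON file with
#' [read_rules()] so per-tumor variable lists need no code change.
#'
#' @return A list of variable rules (each a list with `name`, `kind`,
#'   `field`/`fields` and optional `parameters`).
#' @export
default_rules <- function() {
  list(
    list(name = "sample_type", kind = "passthrough", field = "sample_type"),
    list(name = "pack_years", kind = "builtin", builtin = "pack_years",
         field = "number_pack_years_smoked"),
    list(name = "survival", kind = "survival",
         fields = c("day_to_death", "days_to_last_follow-up")),
    list(name = "pathology_stage", kind = "builtin", builtin = "stage",
         field = "pathology_stage"),
    list(name = "clinical_stage", kind = "builtin", builtin = "stage",
         field = "clinical_stage"),
    list(name = "masaoka_stage", kind = "builtin", builtin = "stage",
         field = "masaoka_stage"),
    list(name = "risk_factor", kind = "builtin", builtin = "lihc_risk",
         field = "risk_factor"),
    list(name = "alcohol_per_day", kind = "builtin", builtin = "alcohol",
         field = "alcohol_per_day"),
    list(name = "pregnancies", kind = "builtin", builtin = "pregnancies",
         field = "number_of_pregnancies")
  )
}

#' Read a harmonization rules file (JSON)
#'
#' @param path JSON file: a list of rule objects with fields `name`,
#'   `kind` (`passthrough`, `numeric-binned`, `merge-map`, `survival` or
#'   `builtin`), `field`/`fields` and `parameters`.
#' @return List of rules as consumed by [harmonize()].
#' @export
read_rules <- function(path) {
  rules <- jsonlite::read_json(path, simplifyVector = FALSE)
  for (r in rules) {
    if (is.null(r$name) || is.null(r$kind)) {
      stop("each rule needs 'name' and 'kind'")
    }
  }
  lapply(rules, function(r) {
    if (!is.null(r$fields)) r$fields <- unlist(r$fields)
    if (!is.null(r$parameters$cutoffs)) {
      cuts <- unlist(r$parameters$cutoffs)
      if (is.unsorted(cuts, strictly = TRUE)) {
        stop("numeric-binned cutoffs must be strictly increasing in rule ",
             r$name)
      }
      r$parameters$cutoffs <- cuts
    }
    if (!is.null(r$parameters$labels)) {
      r$parameters$labels <- unlist(r$parameters$labels)
    }
    r
  })
}

apply_builtin <- function(builtin, raw) {
  switch(builtin,
    pack_years = bin_pack_years(ifelse(is_missing_raw(raw), NA, raw)),
    stage = collapse_stage(raw),
    lihc_risk = merge_lihc_risk(raw),
    alcohol = bin_alcohol(ifelse(is_missing_raw(raw), NA, raw)),
    pregnancies = bin_pregnancies(ifelse(is_missing_raw(raw), NA, raw)),
    stop("unknown builtin rule '", builtin, "'")
  )
}

apply_rule_vec <- function(rule, raw) {
  switch(rule$kind,
    passthrough = passthrough_category(raw),
    builtin = {
      # totality: bad numerics (e.g. negative artifacts) become UNDEFINED
      tryCatch(apply_builtin(rule$builtin, raw), error = function(e) {
        vapply(raw, function(v) {
          tryCatch(apply_builtin(rule$builtin, v), error = function(e2) UNDEFINED)
        }, "")
      })
    },
    `numeric-binned` = {
      v <- as_num(raw)
      cuts <- rule$parameters$cutoffs
      labs <- rule$parameters$labels     # length = length(cuts) + 1
      out <- rep(UNDEFINED, length(v))
      ok <- !is.na(v)
      out[ok] <- labs[findInterval(v[ok], cuts) + 1]
      out
    },
    `merge-map` = {
      map <- rule$parameters$map
      dflt <- rule$parameters$default %||% UNDEFINED
      vapply(as.character(raw), function(v) {
        if (is_missing_raw(v)) return(UNDEFINED)
        map[[trimws(v)]] %||% dflt
      }, "", USE.NAMES = FALSE)
    },
    stop("unknown rule kind '", rule$kind, "'")
  )
}

#' Harmonize raw clinical records
#'
#' Applies each rule to each record, producing one categorical column per
#' non-survival rule plus `survival_time`/`survival_event` for the
#' survival rule. A rule referencing an absent raw field yields
#' `"UNDEFINED"` for all records with a warning. A harmonization report
#' (per-variable category counts and UNDEFINED counts) is attached as the
#' `report` attribute.
#'
#' @param records Data frame with a `sample_id` column plus raw fields
#'   (one row per sample; empty string or `NA` = missing).
#' @param rules List of rules, see [default_rules()].
#' @return Data frame of harmonized records, input order preserved, with
#'   attribute `report`.
#' @export
harmonize <- function(records, rules = default_rules()) {
  stopifnot(is.data.frame(records), "sample_id" %in% names(records))
  if (anyDuplicated(records$sample_id)) stop("sample_id must be unique")
  nm <- vapply(rules, `[[`, "", "name")
  if (anyDuplicated(nm)) stop("rule names must be unique")
  out <- data.frame(sample_id = as.character(records$sample_id),
                    stringsAsFactors = FALSE)
  report <- list()
  for (rule in rules) {
    if (identical(rule$kind, "survival")) {
      flds <- rule$fields
      getf <- function(f) {
        if (f %in% names(records)) {
          v <- records[[f]]
          ifelse(is_missing_raw(v), NA, as_num(v))
        } else {
          warning("survival field '", f, "' absent; treated as missing")
          rep(NA_real_, nrow(records))
        }
      }
      surv <- derive_survival(getf(flds[1]), getf(flds[2]))
      out$survival_time <- surv$time
      out$survival_event <- surv$event
      report[[rule$name]] <- list(
        n_event = sum(surv$event == 1, na.rm = TRUE),
        n_censored = sum(surv$event == 0, na.rm = TRUE),
        n_missing = sum(is.na(surv$event)))
    } else {
      if (!rule$field %in% names(records)) {
        warning("raw field '", rule$field, "' absent; variable '",
                rule$name, "' set to UNDEFINED")
        cats <- rep(UNDEFINED, nrow(records))
      } else {
        cats <- apply_rule_vec(rule, records[[rule$field]])
      }
      out[[rule$name]] <- cats
      tb <- table(cats)
      report[[rule$name]] <- list(
        counts = as.list(stats::setNames(as.integer(tb), names(tb))),
        n_undefined = sum(cats == UNDEFINED))
    }
  }
  attr(out, "report") <- report
  out
}

#' Read a clinical TSV
#'
#' One row per sample, header of raw field names (names are taken
#' verbatim, so hyphenated TCGA fields survive), empty cell = missing.
#'
#' @param path TSV path.
#' @return Data frame of raw clinical records.
#' @export
read_clinical_tsv <- function(path) {
  utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE,
                    colClasses = "character", na.strings = NULL)
}

#' Write a harmonization report as JSON
#'
#' @param harmonized Output of [harmonize()].
#' @param path Output JSON path.
#' @return `path`, invisibly.
#' @export
write_harmonization_report <- function(harmonized, path) {
  jsonlite::write_json(attr(harmonized, "report"), path,
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}
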