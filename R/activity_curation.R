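## Curation of Ki activity records into spKi labels.
##
## Raw ChEMBL-style rows (molecule, target, relation, value, units,
## comment, year) are standardized to nM, resolved per (molecule, target)
## pair under the relation rules, deduplicated, and transformed to the
## scaled potency score spKi in [0, 1]:
##
##   spKi = 0                 if Ki >= 10,000 nM or inactive
##        = 1                 if Ki <= 1.0 nM
##        = (4 - log10 Ki)/4  otherwise
##
## Every input record receives exactly one disposition (used or excluded
## with a reason), so kept + excluded always equals the input count.

# micro sign (U+00B5) and Greek mu (U+03BC) both normalize to "u"
unit_to_nM <- c("M" = 1e9, "mM" = 1e6, "uM" = 1e3,
                "um" = 1e3, "nM" = 1, "pM" = 1e-3)

normalize_unit_string <- function(u) {
  u <- trimws(as.character(u))
  gsub(paste0("[", intToUtf8(181), intToUtf8(956), "]"), "u", u)
}

normalize_relation <- function(rel) {
  rel <- trimws(ifelse(is.na(rel), "", as.character(rel)))
  map <- c("=" = "eq", "eq" = "eq", "==" = "eq",
           "<" = "lt", "lt" = "lt",
           "<=" = "le", "le" = "le",
           ">" = "gt", "gt" = "gt",
           ">=" = "ge", "ge" = "ge", "none" = "none")
  rel[rel == ""] <- "none"
  # single-character Unicode comparison signs (U+2264, U+2265)
  rel[rel == intToUtf8(8804)] <- "<="
  rel[rel == intToUtf8(8805)] <- ">="
  out <- unname(map[rel])
  if (any(is.na(out)))
    stop("unrecognized activity relation: ",
         paste(unique(rel[is.na(out)]), collapse = ", "))
  out
}

#' Convert activity records to nanomolar
#'
#' Recognized molar-concentration units (M, mM, uM, nM, pM) are converted
#' to nM; records with any other units are excluded with a logged reason.
#'
#' @param records data.frame with at least `value` and `units` columns.
#' @return List with `records` (converted, `units` = "nM") and `excluded`
#'   (the rejected rows plus a `reason` column).
#' @export
standardize_units <- function(records) {
  stopifnot(is.data.frame(records), all(c("value", "units") %in% names(records)))
  u <- normalize_unit_string(records$units)
  known <- u %in% names(unit_to_nM)
  # records with no value carry no unit information to convert; keep them
  # for the relation rules to judge
  novalue <- is.na(records$value)
  ok <- known | novalue
  kept <- records[ok, , drop = FALSE]
  conv <- ifelse(is.na(kept$value), NA_real_,
                 kept$value * unname(unit_to_nM[normalize_unit_string(kept$units)]))
  kept$value <- conv
  kept$units <- ifelse(is.na(kept$value), kept$units, "nM")
  excluded <- records[!ok, , drop = FALSE]
  if (nrow(excluded)) excluded$reason <- "unrecognized_units"
  list(records = kept, excluded = excluded)
}

#' Resolve duplicate measurements for one (molecule, target) pair
#'
#' If the measurements span more than one order of magnitude
#' (max/min > 10), the most recent one is taken; ties in recency fall back
#' to the geometric mean of the tied most-recent values. Otherwise the
#' geometric mean (the back-transformed average of log10 values) of all
#' measurements is used.
#'
#' @param values Measured Ki values in nM (> 0).
#' @param years Measurement years (recency proxy), same length.
#' @return Single Ki in nM.
#' @export
resolve_duplicates <- function(values, years = rep(NA_integer_, length(values))) {
  stopifnot(length(values) >= 1, length(years) == length(values),
            all(values > 0))
  if (length(values) == 1) return(values)
  if (max(values) / min(values) > 10) {
    yr <- ifelse(is.na(years), -Inf, years)
    recent <- values[yr == max(yr)]
    return(geometric_mean(recent))
  }
  geometric_mean(values)
}

#' Scaled pKi potency score
#'
#' Maps Ki in nM to spKi in \[0, 1\]: 0 at or above 10,000 nM (or
#' inactive), 1 at or below 1.0 nM, linear in log10(Ki) between. Monotone
#' non-increasing in Ki and continuous at both boundaries.
#'
#' @param ki_nM Ki values in nM (> 0). `NA` allowed where `inactive`.
#' @param inactive Logical, recycled: score 0 regardless of value.
#' @return spKi scores in \[0, 1\].
#' @export
spki <- function(ki_nM, inactive = FALSE) {
  inactive <- rep_len(inactive, length(ki_nM))
  if (any(!inactive & (is.na(ki_nM) | ki_nM <= 0)))
    stop("Ki must be positive (and present) for non-inactive records")
  out <- numeric(length(ki_nM))
  active <- !inactive
  k <- ki_nM[active]
  out[active] <- ifelse(k >= 10000, 0,
                        ifelse(k <= 1, 1, (4 - log10(k)) / 4))
  out
}

#' Inverse of the spKi transform on its linear branch
#'
#' @param s spKi scores strictly inside (0, 1).
#' @return Ki in nM: `10^(4 - 4 s)`.
#' @export
spki_to_ki <- function(s) {
  stopifnot(all(s > 0 & s < 1))
  10^(4 - 4 * s)
}

# Relation rules for all records of one (molecule, target) pair.
# Returns list(outcome = NULL or list(ki_nM, inactive, provenance),
#              disposition = character per record, note = character per record)
apply_relation_rules_group <- function(rel, value, year, comment) {
  n <- length(rel)
  disp <- character(n)
  note <- rep("", n)
  has_val <- !is.na(value)
  comment <- ifelse(is.na(comment), "", trimws(tolower(comment)))
  active_comment <- grepl("active", comment) & !grepl("not active|inactive", comment)

  eqm <- rel == "eq" & has_val
  disp[rel == "eq" & !has_val] <- "excluded:eq_without_value"
  disp[rel == "none" & comment == ""] <- "excluded:no_relation_no_comment"
  disp[rel == "none" & comment != "" & active_comment & !has_val] <-
    "excluded:active_comment_without_value"
  disp[rel == "none" & comment != "" & disp == ""] <- "excluded:no_relation"
  disp[rel %in% c("lt", "le") & !has_val] <- "excluded:censored_without_value"

  ub <- rel %in% c("lt", "le") & has_val
  inb <- rel %in% c("gt", "ge")

  if (any(eqm)) {
    ki <- resolve_duplicates(value[eqm], year[eqm])
    disp[eqm] <- "used:measured"
    disp[ub] <- "used:observation_superseded_by_measured"
    disp[inb] <- "used:superseded_by_measured"
    note[ub | inb] <- "measured values take precedence"
    outcome <- list(ki_nM = ki, inactive = FALSE, provenance = "measured")
  } else if (any(ub)) {
    ki <- max(value[ub])
    disp[ub] <- "used:upper_bound"
    disp[inb] <- "used:conflict_with_upper_bound"
    note[inb] <- "inactive relation conflicts with censored-active record"
    outcome <- list(ki_nM = ki, inactive = FALSE, provenance = "upper_bound")
  } else if (any(inb)) {
    disp[inb] <- "used:inactive"
    outcome <- list(ki_nM = NA_real_, inactive = TRUE,
                    provenance = "inactive_by_relation")
  } else {
    outcome <- NULL
  }
  disp[disp == ""] <- "excluded:unusable"
  list(outcome = outcome, disposition = disp, note = note)
}

#' Apply the relation rules to the records of one (molecule, target) pair
#'
#' Measured values (relation `=` with a value) take precedence; without
#' them, `<`/`<=` records yield a single upper-bound measurement at the
#' highest reported value; `>`/`>=` records mark the molecule as not
#' active. Records with `=` and no value, no relation and no comment, or
#' an "active" comment without a value are excluded.
#'
#' @param records data.frame for one pair with columns `relation`, `value`
#'   (nM), `year`, `comment`.
#' @return List with `outcome` (`NULL`, or list with `ki_nM`, `inactive`,
#'   `provenance`) and per-record `disposition` and `note` vectors.
#' @export
apply_relation_rules <- function(records) {
  stopifnot(is.data.frame(records), "relation" %in% names(records))
  apply_relation_rules_group(
    normalize_relation(records$relation), records$value,
    if (is.null(records$year)) rep(NA_integer_, nrow(records)) else records$year,
    if (is.null(records$comment)) rep(NA_character_, nrow(records)) else records$comment)
}

#' Curate a raw Ki activity table into spKi labels
#'
#' Runs the full curation pipeline: activity-type check, unit
#' standardization to nM, per-pair relation rules, duplicate resolution,
#' and the spKi transform. Optionally filters targets with too few
#' activities or too little label spread.
#'
#' @param raw data.frame with columns `molecule_id`, `target_id`,
#'   `activity_type`, `relation`, `value`, `units`, and optionally
#'   `comment`, `year`.
#' @param min_activities Targets with fewer curated activities are dropped
#'   (default 40). `NULL` disables target filtering.
#' @param min_label_spread Targets whose spKi standard deviation falls
#'   below this are dropped (default 0.01).
#' @return List with `curated` (data.frame: `molecule_id`, `target_id`,
#'   `ki_nM`, `spki`, `provenance`), `record_report` (one row per input
#'   record with its `disposition`), `excluded` (the excluded subset), and
#'   `dropped_targets`.
#' @export
curate_activities <- function(raw, min_activities = 40, min_label_spread = 0.01) {
  stopifnot(is.data.frame(raw))
  needed <- c("molecule_id", "target_id", "activity_type", "relation",
              "value", "units")
  miss <- setdiff(needed, names(raw))
  if (length(miss)) stop("raw table missing columns: ", paste(miss, collapse = ", "))
  if (is.null(raw$comment)) raw$comment <- NA_character_
  if (is.null(raw$year)) raw$year <- NA_integer_
  raw$.rec <- seq_len(nrow(raw))
  if (any(!is.na(raw$value) & raw$value < 0)) stop("negative activity values")

  disposition <- rep(NA_character_, nrow(raw))
  note <- rep("", nrow(raw))

  wrong_type <- is.na(raw$activity_type) | raw$activity_type != "Ki"
  disposition[wrong_type] <- "excluded:wrong_activity_type"

  su <- standardize_units(raw[!wrong_type, , drop = FALSE])
  if (nrow(su$excluded))
    disposition[su$excluded$.rec] <- "excluded:unrecognized_units"
  rec <- su$records

  curated <- list()
  if (nrow(rec)) {
    grp <- split(rec, paste(rec$molecule_id, rec$target_id, sep = "\r"),
                 drop = TRUE)
    for (g in grp) {
      res <- apply_relation_rules(g)
      disposition[g$.rec] <- res$disposition
      note[g$.rec] <- res$note
      if (!is.null(res$outcome)) {
        o <- res$outcome
        curated[[length(curated) + 1L]] <- data.frame(
          molecule_id = g$molecule_id[1], target_id = g$target_id[1],
          ki_nM = o$ki_nM, spki = spki(o$ki_nM, o$inactive),
          provenance = o$provenance, stringsAsFactors = FALSE)
      }
    }
  }
  curated <- if (length(curated)) do.call(rbind, curated) else
    data.frame(molecule_id = character(), target_id = character(),
               ki_nM = numeric(), spki = numeric(),
               provenance = character(), stringsAsFactors = FALSE)
  curated <- curated[order(curated$target_id, curated$molecule_id), , drop = FALSE]
  rownames(curated) <- NULL

  record_report <- data.frame(
    record = raw$.rec, molecule_id = raw$molecule_id,
    target_id = raw$target_id, disposition = disposition, note = note,
    stringsAsFactors = FALSE)
  stopifnot(!anyNA(record_report$disposition))

  dropped <- data.frame(target_id = character(), n_activities = integer(),
                        spki_sd = numeric(), reason = character(),
                        stringsAsFactors = FALSE)
  if (!is.null(min_activities) && nrow(curated)) {
    ft <- filter_targets(curated, min_activities = min_activities,
                         min_label_spread = min_label_spread)
    curated <- ft$curated
    dropped <- ft$dropped_targets
  }
  list(curated = curated, record_report = record_report,
       excluded = record_report[startsWith(record_report$disposition,
                                           "excluded:"), , drop = FALSE],
       dropped_targets = dropped)
}

#' Drop targets with too few activities or too little label variability
#'
#' @param curated Curated activity data.frame (see [curate_activities()]).
#' @param min_activities Minimum number of curated activities per target
#'   (targets with fewer are dropped; default 40).
#' @param min_label_spread Minimum spKi standard deviation per target.
#' @return List with `curated` (surviving rows) and `dropped_targets`
#'   report.
#' @export
filter_targets <- function(curated, min_activities = 40,
                           min_label_spread = 0.01) {
  stopifnot(is.data.frame(curated), all(c("target_id", "spki") %in% names(curated)))
  n <- table(curated$target_id)
  sds <- tapply(curated$spki, curated$target_id, stats::sd)
  sds[is.na(sds)] <- 0
  ids <- names(n)
  too_few <- as.integer(n) < min_activities
  too_flat <- !too_few & sds[ids] < min_label_spread
  dropped <- data.frame(
    target_id = ids[too_few | too_flat],
    n_activities = as.integer(n)[too_few | too_flat],
    spki_sd = as.numeric(sds[ids])[too_few | too_flat],
    reason = ifelse(too_few[too_few | too_flat], "too_few_activities",
                    "insufficient_variability"),
    stringsAsFactors = FALSE)
  keep <- !(curated$target_id %in% dropped$target_id)
  out <- curated[keep, , drop = FALSE]
  if (nrow(out) == 0) stop("no targets survive filtering")
  rownames(out) <- NULL
  list(curated = out, dropped_targets = dropped)
}

#' Read a raw activity table (CSV/TSV)
#' @param path File path; comma-separated for `.csv`, else tab.
#' @return data.frame of raw activity records.
#' @export
read_activity_table <- function(path) {
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  utils::read.table(path, header = TRUE, sep = sep, stringsAsFactors = FALSE,
                    quote = "\"", comment.char = "")
}
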