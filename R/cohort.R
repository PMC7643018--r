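#' Construct a table of subject records
#'
#' One row per scan (subject, visit) with diagnosis and the covariates used
#' by the normative model. A subject may own several visits but must keep a
#' single diagnosis across all of them; converters are excluded upstream.
#'
#' @param subject_id,visit_id character vectors.
#' @param diagnosis factor/character in `c("NC","AD","FTD")`.
#' @param age years, positive.
#' @param sex `"M"` or `"F"`.
#' @param icv intracranial vault volume in mm^3, positive.
#' @param field_strength `"1.5T"` or `"3T"`.
#' @param site,scanner opaque identifiers.
#' @return data.frame of class `subject_records`.
#' @export
subject_records <- function(subject_id, visit_id, diagnosis, age, sex, icv,
                            field_strength, site = "siteA", scanner = "scanner1") {
  n <- length(subject_id)
  df <- data.frame(
    subject_id = as.character(subject_id),
    visit_id = as.character(visit_id),
    diagnosis = as.character(diagnosis),
    age = as.numeric(age),
    sex = as.character(sex),
    icv = as.numeric(icv),
    field_strength = as.character(field_strength),
    site = rep_len(as.character(site), n),
    scanner = rep_len(as.character(scanner), n),
    stringsAsFactors = FALSE
  )
  if (any(!nzchar(df$subject_id))) stop("empty subject_id")
  if (!all(df$diagnosis %in% c("NC", "AD", "FTD")))
    stop("diagnosis must be one of NC, AD, FTD")
  if (!all(df$sex %in% c("M", "F"))) stop("sex must be M or F")
  if (!all(df$field_strength %in% c("1.5T", "3T")))
    stop("field_strength must be 1.5T or 3T")
  if (any(!is.finite(df$age)) || any(df$age <= 0)) stop("age must be positive")
  if (any(!is.finite(df$icv)) || any(df$icv <= 0)) stop("icv must be positive")
  class(df) <- c("subject_records", "data.frame")
  df
}

#' Validate consistency of metadata and feature rows
#'
#' Report-only check: flags subjects whose diagnosis changes between visits
#' (to be excluded, as converters are), feature rows without metadata
#' (orphans) and metadata rows without features.
#'
#' @param records a [subject_records()] data.frame.
#' @param table a [feature_table()].
#' @return list with `converters` (subject ids), `orphan_rows`
#'   (subject/visit keys present only in the table), `missing_rows` (keys
#'   present only in the metadata), and logical `ok`.
#' @export
validate_cohort <- function(records, table) {
  dx_per_subj <- tapply(records$diagnosis, records$subject_id,
                        function(d) length(unique(d)))
  converters <- names(dx_per_subj)[dx_per_subj > 1]
  key <- function(s, v) paste(s, v, sep = "\r")
  meta_keys <- key(records$subject_id, records$visit_id)
  row_keys <- key(table$ids$subject_id, table$ids$visit_id)
  orphan_rows <- setdiff(row_keys, meta_keys)
  missing_rows <- setdiff(meta_keys, row_keys)
  unkey <- function(k) {
    if (!length(k)) return(data.frame(subject_id = character(0),
                                      visit_id = character(0)))
    parts <- strsplit(k, "\r", fixed = TRUE)
    data.frame(subject_id = vapply(parts, `[`, "", 1),
               visit_id = vapply(parts, `[`, "", 2),
               stringsAsFactors = FALSE)
  }
  out <- list(converters = converters,
              orphan_rows = unkey(orphan_rows),
              missing_rows = unkey(missing_rows))
  out$ok <- length(converters) == 0 && length(orphan_rows) == 0 &&
    length(missing_rows) == 0
  out
}

# align records to the rows of a feature table; errors on missing metadata
align_records <- function(records, table) {
  key <- function(s, v) paste(s, v, sep = "\r")
  idx <- match(key(table$ids$subject_id, table$ids$visit_id),
               key(records$subject_id, records$visit_id))
  if (anyNA(idx)) stop("feature rows without matching subject records")
  records[idx, , drop = FALSE]
}
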