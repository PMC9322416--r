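#' Annual reproduction records
#'
#' The package works on a long-format table of per-male annual reproduction:
#' one row per male and age class, holding the number of extra-group young
#' sired at that age (`egp`), within-group young sired (`wgp`), and social
#' ("apparent") offspring raised on the male's territory (`rs_ap`), together
#' with the male's dominance status at that age. Age classes are integers
#' `1..max_class`, with the top class pooling all older ages.
#'
#' @name annual-records
#' @keywords internal
NULL

.record_cols <- c("male_id", "cohort_year", "age_class", "is_dominant",
                  "egp", "wgp", "rs_ap")

#' Assign an age in years to an integer age class
#'
#' Ages are rounded to the nearest integer (half-years round up), with two
#' conventions: males at least 8 months but younger than 1.5 years are class
#' 1 (reproductive maturity starts around 8 months), and all ages of
#' `max_class` years or more are pooled into the top class.
#'
#' @param age_years numeric vector of ages in years; must be >= 8/12.
#' @param max_class integer, the pooled top class (default 12).
#' @return integer vector of age classes in `1..max_class`.
#' @examples
#' bin_age_class(c(0.9, 2.7, 12.4))
#' @export
bin_age_class <- function(age_years, max_class = 12L) {
  if (!is.numeric(age_years)) stop("`age_years` must be numeric")
  if (any(is.na(age_years))) stop("`age_years` contains missing values")
  if (any(age_years < 8 / 12)) {
    stop("age below reproductive maturity (< 8 months): ",
         paste(signif(age_years[age_years < 8 / 12], 3), collapse = ", "))
  }
  cls <- floor(age_years + 0.5)         # nearest integer, halves up
  cls[age_years < 1.5] <- 1L
  cls[cls >= max_class] <- as.integer(max_class)
  as.integer(cls)
}

#' Validate a table of annual records
#'
#' Checks the structural invariants of the long-format annual table: required
#' columns, non-negative integer counts, at most one row per male and age
#' class, and zero apparent reproduction for non-dominant males (a male with
#' no breeding position has no social female, so his social offspring count
#' is zero by definition).
#'
#' @param records data.frame of annual records.
#' @param strict logical; if `TRUE` unknown columns are an error, otherwise
#'   they are carried along untouched.
#' @return `records`, invisibly, with canonical column types.
#' @export
validate_records <- function(records, strict = TRUE) {
  if (!is.data.frame(records)) stop("`records` must be a data.frame")
  missing_cols <- setdiff(.record_cols, names(records))
  if (length(missing_cols)) {
    stop("missing required columns: ", paste(missing_cols, collapse = ", "))
  }
  extra <- setdiff(names(records), .record_cols)
  if (strict && length(extra)) {
    stop("unknown columns under strict validation: ",
         paste(extra, collapse = ", "))
  }
  records$male_id <- as.character(records$male_id)
  records$is_dominant <- as.logical(records$is_dominant)
  for (col in c("cohort_year", "age_class", "egp", "wgp", "rs_ap")) {
    v <- records[[col]]
    if (!is.numeric(v) || any(is.na(v))) {
      stop("column `", col, "` must be numeric with no missing values")
    }
    if (any(v != round(v))) stop("column `", col, "` must be integer-valued")
    records[[col]] <- as.integer(round(v))
  }
  if (any(is.na(records$is_dominant))) stop("`is_dominant` has missing values")
  for (col in c("egp", "wgp", "rs_ap")) {
    if (any(records[[col]] < 0)) stop("negative counts in `", col, "`")
  }
  if (any(records$age_class < 1)) stop("age_class must be >= 1")
  key <- paste(records$male_id, records$age_class)
  if (anyDuplicated(key)) {
    stop("duplicate (male_id, age_class) rows: ",
         paste(unique(key[duplicated(key)]), collapse = "; "))
  }
  bad <- !records$is_dominant & records$rs_ap > 0
  if (any(bad)) {
    stop("non-dominant males must have rs_ap = 0 (violated for ",
         paste(unique(records$male_id[bad]), collapse = ", "), ")")
  }
  invisible(records)
}

#' Read annual records from a delimited text file
#'
#' Reads a comma- or tab-delimited long-format table (delimiter detected
#' from the header line), applies optional column renaming, converts an
#' `age_years` column to age classes when `age_class` is absent, fills
#' missing counts for otherwise-present rows with zero (with a warning), and
#' validates the result.
#'
#' @param path path to a delimited text file with a header row.
#' @param col_map optional named character vector mapping file column names
#'   to the canonical names, e.g. `c(id = "male_id")`.
#' @param strict logical, passed to [validate_records()].
#' @param max_class pooled top age class used when binning `age_years`.
#' @return data.frame of validated annual records.
#' @export
read_records <- function(path, col_map = NULL, strict = TRUE, max_class = 12L) {
  if (!file.exists(path)) stop("file not found: ", path)
  header <- readLines(path, n = 1L)
  sep <- if (grepl("\t", header, fixed = TRUE)) "\t" else ","
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE)
  if (!is.null(col_map)) {
    idx <- match(names(col_map), names(df))
    if (anyNA(idx)) {
      stop("col_map names not in file: ",
           paste(names(col_map)[is.na(idx)], collapse = ", "))
    }
    names(df)[idx] <- unname(col_map)
  }
  if (!"age_class" %in% names(df) && "age_years" %in% names(df)) {
    df$age_class <- bin_age_class(df$age_years, max_class = max_class)
    df$age_years <- NULL
  }
  for (col in c("egp", "wgp", "rs_ap")) {
    if (col %in% names(df) && anyNA(df[[col]])) {
      n_na <- sum(is.na(df[[col]]))
      warning(n_na, " missing `", col, "` count(s) set to 0")
      df[[col]][is.na(df[[col]])] <- 0L
    }
  }
  validate_records(df, strict = strict)
}

#' Write annual records to a delimited text file
#'
#' @param records validated annual records.
#' @param path output path.
#' @param sep field delimiter, tab by default.
#' @return `path`, invisibly.
#' @export
write_records <- function(records, path, sep = "\t") {
  records <- validate_records(records, strict = FALSE)
  utils::write.table(records[, .record_cols], path, sep = sep,
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Restrict records to a cohort window and drop excluded males
#'
#' Keeps males whose cohort (birth) year lies in `[first_cohort,
#' last_cohort]` and who are not listed in `exclude_ids`; reports how many
#' males were removed for each reason.
#'
#' @param records annual records.
#' @param first_cohort,last_cohort inclusive cohort-year bounds.
#' @param exclude_ids character vector of male ids to drop (e.g. translocated
#'   males or males still alive at the end of the study).
#' @return filtered records.
#' @export
filter_cohort <- function(records, first_cohort, last_cohort,
                          exclude_ids = character()) {
  if (first_cohort > last_cohort) stop("cohort bounds out of order")
  if (nrow(records) == 0L) return(records)
  cohort_by_male <- tapply(records$cohort_year, records$male_id, `[`, 1L)
  out_of_window <- names(cohort_by_male)[cohort_by_male < first_cohort |
                                           cohort_by_male > last_cohort]
  excluded <- setdiff(intersect(unique(records$male_id), exclude_ids),
                      out_of_window)
  message(length(out_of_window), " male(s) removed: cohort outside ",
          first_cohort, "-", last_cohort, "; ",
          length(excluded), " male(s) removed: explicitly excluded")
  keep <- !(records$male_id %in% c(out_of_window, exclude_ids))
  records[keep, , drop = FALSE]
}

#' Aggregate annual records to per-male lifetime summaries
#'
#' @param records validated annual records.
#' @return data.frame with one row per male: `male_id`, `cohort_year`,
#'   `lifespan_class` (last age class with a record), `age_first_dominance`
#'   (`NA` for males that never gained a breeding position), and lifetime
#'   totals `lifetime_egp`, `lifetime_wgp`, `lifetime_rs`
#'   (= egp + wgp), `lifetime_rs_ap`.
#' @export
aggregate_lifetime <- function(records) {
  records <- validate_records(records, strict = FALSE)
  split_by <- split(records, records$male_id)
  out <- do.call(rbind, lapply(split_by, function(d) {
    dom_ages <- d$age_class[d$is_dominant]
    data.frame(
      male_id = d$male_id[1L],
      cohort_year = d$cohort_year[1L],
      lifespan_class = max(d$age_class),
      age_first_dominance = if (length(dom_ages)) min(dom_ages) else NA_integer_,
      lifetime_egp = sum(d$egp),
      lifetime_wgp = sum(d$wgp),
      lifetime_rs = sum(d$egp) + sum(d$wgp),
      lifetime_rs_ap = sum(d$rs_ap),
      stringsAsFactors = FALSE
    )
  }))
  rownames(out) <- NULL
  out[order(out$male_id), , drop = FALSE]
}

#' Build a males-by-age component matrix
#'
#' Lays the annual records out as aligned males x age-class matrices for the
#' four measures (EGP, WGP, RS = EGP + WGP, RS_ap). Ages a male lived but
#' has no row for are zero-filled (the alive interval is derived from his
#' last recorded age). Two padding conventions are supported for ages beyond
#' a male's death:
#' \describe{
#'   \item{additive}{dead males contribute zeros, so summing a male's row
#'     recovers his lifetime total and all age-specific (co)variance terms
#'     add up to the lifetime variance;}
#'   \item{independent}{dead males contribute missing values, so per-age
#'     statistics are computed among survivors only, free of longevity.}
#' }
#'
#' @param records validated annual records.
#' @param mode `"additive"` or `"independent"`.
#' @param n_classes number of age classes (>= the maximum observed class).
#' @return an object of class `age_matrix`: a list with `male_ids`,
#'   `age_classes`, `mode`, and numeric matrices `EGP`, `WGP`, `RS`, `RS_ap`.
#' @export
build_age_matrix <- function(records, mode = c("additive", "independent"),
                             n_classes = 12L) {
  mode <- match.arg(mode)
  records <- validate_records(records, strict = FALSE)
  if (nrow(records) && max(records$age_class) > n_classes) {
    stop("record with age_class > n_classes (", n_classes, ")")
  }
  ids <- sort(unique(records$male_id))
  n <- length(ids)
  empty <- matrix(0, n, n_classes, dimnames = list(ids, seq_len(n_classes)))
  m <- list(EGP = empty, WGP = empty, RS_ap = empty)
  row <- match(records$male_id, ids)
  idx <- cbind(row, records$age_class)
  m$EGP[idx] <- records$egp
  m$WGP[idx] <- records$wgp
  m$RS_ap[idx] <- records$rs_ap
  if (mode == "independent") {
    lifespan <- tapply(records$age_class, records$male_id, max)[ids]
    dead <- outer(as.integer(lifespan), seq_len(n_classes), `<`)
    m$EGP[dead] <- NA_real_
    m$WGP[dead] <- NA_real_
    m$RS_ap[dead] <- NA_real_
  }
  structure(
    list(male_ids = ids, age_classes = seq_len(n_classes), mode = mode,
         EGP = m$EGP, WGP = m$WGP, RS = m$EGP + m$WGP, RS_ap = m$RS_ap),
    class = "age_matrix"
  )
}

#' @export
print.age_matrix <- function(x, ...) {
  cat("age_matrix:", length(x$male_ids), "males x",
      length(x$age_classes), "age classes, mode =", x$mode, "\n")
  invisible(x)
}

# subset an age_matrix by male index (used by the bootstrap)
subset_age_matrix <- function(mat, idx) {
  for (comp in c("EGP", "WGP", "RS", "RS_ap")) {
    mat[[comp]] <- mat[[comp]][idx, , drop = FALSE]
  }
  mat$male_ids <- mat$male_ids[idx]
  mat
}
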