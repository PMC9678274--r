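#' Column dialect for task-data files
#'
#' Deposited task-data files may name their columns differently from the
#' canonical schema. A dialect maps each canonical field to the header name
#' used in the file; unspecified fields keep their canonical names.
#'
#' @param ... named character overrides, e.g.
#'   `panel_dialect(reviewer_id = "subject", rating = "response")`.
#' @param sep field separator (default comma).
#' @return a named list of class `panel_dialect`.
#' @export
#' @examples
#' panel_dialect(reviewer_id = "subject")
panel_dialect <- function(..., sep = ",") {
  d <- as.list(stats::setNames(panel_record_cols, panel_record_cols))
  over <- list(...)
  unknown <- setdiff(names(over), panel_record_cols)
  if (length(unknown))
    fb_stop("dialect names unknown field(s): %s",
            paste(unknown, collapse = ", "), class = "facebias_format")
  d[names(over)] <- over
  structure(c(d, list(.sep = sep)), class = "panel_dialect")
}

#' Read a reviewer panel from delimited text
#'
#' Reads one-row-per-trial task data (the layout of the studies' deposited
#' CSV files) and returns a validated [reviewer_panel()]. Row order never
#' affects downstream statistics.
#'
#' @param path path to a delimited text file with a header row.
#' @param dialect a [panel_dialect()] mapping canonical fields to file
#'   column names.
#' @return a [reviewer_panel()].
#' @export
read_panel <- function(path, dialect = panel_dialect()) {
  if (!file.exists(path))
    fb_stop("file not found: %s", path, class = "facebias_io")
  raw <- utils::read.csv(path, sep = dialect$.sep, stringsAsFactors = FALSE,
                         check.names = FALSE, fileEncoding = "UTF-8")
  want <- unlist(dialect[panel_record_cols])
  missing <- setdiff(want, names(raw))
  if (length(missing))
    fb_stop("input is missing required column(s): %s",
            paste(missing, collapse = ", "), class = "facebias_format")
  rec <- raw[, want, drop = FALSE]
  names(rec) <- panel_record_cols
  if (nrow(rec)) {
    rec$study <- as.integer(rec$study)
    rec$rating <- as.integer(rec$rating)
    rec$mated <- as_flag(rec$mated, "mated")
    rec$is_attention <- as_flag(rec$is_attention, "is_attention")
    for (col in c("condition", "variant", "reviewer_id", "pair_id",
                  "source", "algorithm_decision"))
      rec[[col]] <- as.character(rec[[col]])
  }
  reviewer_panel(rec)
}

as_flag <- function(x, what) {
  if (is.logical(x)) return(x)
  v <- tolower(as.character(x))
  out <- ifelse(v %in% c("true", "t", "1", "yes"), TRUE,
                ifelse(v %in% c("false", "f", "0", "no"), FALSE, NA))
  if (anyNA(out))
    fb_stop("column '%s' contains non-boolean values", what,
            class = "facebias_format")
  out
}

#' Write a reviewer panel to delimited text
#'
#' Produces a file that [read_panel()] inverts exactly: every field value
#' round-trips, including non-ASCII identifiers. An empty panel yields a
#' header-only file.
#'
#' @param panel a valid [reviewer_panel()].
#' @param path output file path.
#' @param dialect a [panel_dialect()]; column names in the file follow it.
#' @return `path`, invisibly.
#' @export
write_panel <- function(panel, path, dialect = panel_dialect()) {
  validate_panel(panel)
  out <- panel$records[, panel_record_cols, drop = FALSE]
  names(out) <- unlist(dialect[panel_record_cols])
  ok <- tryCatch({
    utils::write.csv(out, path, row.names = FALSE, quote = TRUE,
                     fileEncoding = "UTF-8")
    TRUE
  }, error = function(e) FALSE, warning = function(w) FALSE)
  if (!ok) fb_stop("cannot write to '%s'", path, class = "facebias_io")
  invisible(path)
}

#' Read or write trust-question records
#'
#' Trust data hold one row per reviewer x phase: whether the reviewer said
#' they would trust the algorithm (or, in the control condition, another
#' person) to make identity decisions. Study 1 asked the question only
#' before the task (`phase = "pre"`); study 2 asked it before and after.
#'
#' @param path CSV path with columns `reviewer_id`, `condition`, `phase`,
#'   `agrees`.
#' @return a data.frame of trust records.
#' @export
read_trust <- function(path) {
  if (!file.exists(path))
    fb_stop("file not found: %s", path, class = "facebias_io")
  x <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("reviewer_id", "condition", "phase", "agrees")
  missing <- setdiff(need, names(x))
  if (length(missing))
    fb_stop("trust data missing column(s): %s",
            paste(missing, collapse = ", "), class = "facebias_format")
  if (!all(x$phase %in% c("pre", "post")))
    fb_stop("trust phase must be 'pre' or 'post'", class = "facebias_validation")
  x$agrees <- as_flag(x$agrees, "agrees")
  x
}

#' @rdname read_trust
#' @param trust data.frame of trust records.
#' @export
write_trust <- function(trust, path) {
  utils::write.csv(trust, path, row.names = FALSE, quote = TRUE,
                   fileEncoding = "UTF-8")
  invisible(path)
}
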