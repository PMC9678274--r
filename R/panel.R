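#' Reviewer panel objects
#'
#' A `reviewer_panel` bundles per-trial rating records with the face-pair
#' roster of the task. Each record is one reviewer x face-pair trial: the
#' reviewer's rating on the 7-point similarity-confidence scale (coded
#' -3..+3, 0 = "I am not sure"), the algorithm decision shown with the pair
#' (`SAME`, `DIFFERENT`, or `NONE` in the control condition), and design
#' labels (study, condition, survey variant). The roster describes the face
#' pairs: stimulus source, mated status (same identity or not), and whether
#' the pair is one of the two celebrity attention checks.
#'
#' @param records data.frame with columns `study`, `condition`, `variant`,
#'   `reviewer_id`, `pair_id`, `source`, `mated`, `algorithm_decision`,
#'   `rating`, `is_attention`.
#' @param roster data.frame with columns `pair_id`, `source`, `mated`,
#'   `is_attention`; if `NULL`, reconstructed from `records`.
#' @param filtered logical; `TRUE` once the attention-check exclusion has
#'   been applied (set by [attention_filter()]).
#' @return an object of class `reviewer_panel`: a list with elements
#'   `records` and `roster`.
#' @seealso [read_panel()], [simulate_panel()], [attention_filter()]
#' @export
#' @examples
#' pan <- simulate_panel(simulation_config(n_per_condition = 4, seed = 1))
#' pan
#' n_reviewers(pan)
reviewer_panel <- function(records, roster = NULL, filtered = FALSE) {
  records <- as.data.frame(records, stringsAsFactors = FALSE)
  if (is.null(roster)) {
    roster <- unique(records[, c("pair_id", "source", "mated", "is_attention")])
    rownames(roster) <- NULL
  }
  roster <- as.data.frame(roster, stringsAsFactors = FALSE)
  pan <- structure(list(records = records, roster = roster),
                   class = "reviewer_panel", filtered = filtered)
  validate_panel(pan)
  pan
}

panel_record_cols <- c("study", "condition", "variant", "reviewer_id",
                       "pair_id", "source", "mated", "algorithm_decision",
                       "rating", "is_attention")

#' Validate a reviewer panel
#'
#' Checks the structural invariants of the data model: required columns,
#' enum membership, ratings within -3..3, the control condition carrying no
#' algorithm decision, attention status matching the CELEBRITY source, each
#' reviewer sitting in exactly one condition and one variant, and roster
#' consistency with the records.
#'
#' @param panel a [reviewer_panel()].
#' @return the panel, invisibly; errors describe the first violation found.
#' @export
validate_panel <- function(panel) {
  if (!inherits(panel, "reviewer_panel"))
    fb_stop("not a reviewer_panel object", class = "facebias_validation")
  rec <- panel$records
  missing <- setdiff(panel_record_cols, names(rec))
  if (length(missing))
    fb_stop("panel records missing column(s): %s",
            paste(missing, collapse = ", "), class = "facebias_format")
  if (nrow(rec) == 0) return(invisible(panel))

  bad <- which(!rec$rating %in% (-3:3))
  if (length(bad))
    fb_stop("rating outside [-3, 3] at record row %d (value %s)",
            bad[1], as.character(rec$rating[bad[1]]),
            class = "facebias_validation")
  if (!all(rec$condition %in% fb_conditions))
    fb_stop("unknown condition: %s",
            paste(setdiff(unique(rec$condition), fb_conditions), collapse = ", "),
            class = "facebias_validation")
  if (!all(rec$algorithm_decision %in% fb_labels))
    fb_stop("unknown algorithm_decision value", class = "facebias_validation")
  if (!all(rec$source %in% fb_sources))
    fb_stop("unknown stimulus source", class = "facebias_validation")
  if (!is.logical(rec$mated) || anyNA(rec$mated))
    fb_stop("mated must be logical without NA", class = "facebias_validation")

  ctrl <- rec$condition == "control"
  if (any(rec$algorithm_decision[ctrl] != "NONE"))
    fb_stop("control-condition records must have algorithm_decision NONE",
            class = "facebias_validation")
  if (any(rec$algorithm_decision[!ctrl] == "NONE"))
    fb_stop("non-control records must carry a SAME or DIFFERENT label",
            class = "facebias_validation")
  if (!identical(rec$is_attention, rec$source == "CELEBRITY"))
    fb_stop("is_attention must hold exactly for CELEBRITY pairs",
            class = "facebias_validation")

  per_rev <- unique(rec[, c("reviewer_id", "condition", "variant")])
  if (anyDuplicated(per_rev$reviewer_id))
    fb_stop("reviewer %s appears in more than one condition or variant",
            per_rev$reviewer_id[duplicated(per_rev$reviewer_id)][1],
            class = "facebias_validation")

  ros <- panel$roster
  key <- unique(rec[, c("pair_id", "source", "mated", "is_attention")])
  m <- merge(key, ros, by = "pair_id", suffixes = c("", ".roster"))
  if (nrow(m) < nrow(key) ||
      !all(m$source == m$source.roster & m$mated == m$mated.roster))
    fb_stop("records disagree with the roster on pair metadata",
            class = "facebias_validation")
  invisible(panel)
}

#' @export
print.reviewer_panel <- function(x, ...) {
  rec <- x$records
  cat(sprintf("<reviewer_panel> %d records, %d reviewers, %d roster pairs%s\n",
              nrow(rec), length(unique(rec$reviewer_id)), nrow(x$roster),
              if (isTRUE(attr(x, "filtered"))) " (attention-filtered)" else ""))
  if (nrow(rec)) {
    tab <- table(condition = unique(rec[, c("reviewer_id", "condition")])$condition)
    cat("  reviewers per condition:",
        paste(sprintf("%s=%d", names(tab), tab), collapse = ", "), "\n")
  }
  invisible(x)
}

#' Count reviewers in a panel
#'
#' @param panel a [reviewer_panel()].
#' @param condition optional condition code to restrict to.
#' @return integer count of distinct reviewers.
#' @export
n_reviewers <- function(panel, condition = NULL) {
  rec <- panel$records
  if (!is.null(condition)) rec <- rec[rec$condition == condition, ]
  length(unique(rec$reviewer_id))
}

#' Conditions present in a panel
#' @param panel a [reviewer_panel()].
#' @return character vector of condition codes, in canonical order.
#' @export
panel_conditions <- function(panel) {
  intersect(fb_conditions, unique(panel$records$condition))
}

# records of one condition (and optionally one decision label), scored
# trials only
select_records <- function(panel, condition, decision_label = NULL) {
  rec <- panel$records
  rec <- rec[rec$condition == condition & !rec$is_attention, , drop = FALSE]
  if (nrow(rec) == 0)
    fb_stop("no records for condition '%s'", condition,
            class = "facebias_empty")
  if (!is.null(decision_label)) {
    decision_label <- match.arg(decision_label, fb_labels)
    rec <- rec[rec$algorithm_decision == decision_label, , drop = FALSE]
    if (nrow(rec) == 0)
      fb_stop("no records for condition '%s' with label '%s'",
              condition, decision_label, class = "facebias_empty")
  }
  rec
}
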