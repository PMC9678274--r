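#' Apply the attention-check exclusion
#'
#' Each task roster contains two celebrity face pairs (one mated, one
#' non-mated) that serve as attention checks. Reviewers who do not respond
#' correctly to both are excluded from analysis. Correctness uses the same
#' decision threshold as scoring (theta = 0.5): a mated pair is answered
#' correctly iff the rating is >= 1, a non-mated pair iff the rating is
#' <= 0. Attention trials are removed from the surviving records, so
#' downstream stages see exactly the 12 scored pairs per reviewer.
#'
#' The operation is idempotent: reviewers with no remaining attention
#' records (an already-filtered panel) are retained.
#'
#' @param panel a [reviewer_panel()] whose roster contains exactly two
#'   attention pairs.
#' @param theta decision threshold used for attention correctness.
#' @return a list with elements `panel` (the filtered [reviewer_panel()])
#'   and `excluded` (character vector of excluded reviewer ids).
#' @export
#' @examples
#' cfg <- simulation_config(n_per_condition = 20, attention_error_rate = 0.2,
#'                          seed = 7)
#' out <- attention_filter(simulate_panel(cfg))
#' length(out$excluded)
attention_filter <- function(panel, theta = 0.5) {
  validate_panel(panel)
  att_pairs <- panel$roster$pair_id[panel$roster$is_attention]
  if (length(att_pairs) != 2L)
    fb_stop("roster must contain exactly 2 attention pairs (found %d)",
            length(att_pairs), class = "facebias_config")
  rec <- panel$records
  att <- rec[rec$is_attention, , drop = FALSE]
  correct <- ifelse(att$mated, att$rating > theta, att$rating <= theta)
  excluded <- sort(unique(att$reviewer_id[!correct]))
  keep <- !(rec$reviewer_id %in% excluded) & !rec$is_attention
  out <- panel
  out$records <- rec[keep, , drop = FALSE]
  rownames(out$records) <- NULL
  attr(out, "filtered") <- TRUE
  validate_panel(out)
  list(panel = out, excluded = excluded)
}
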