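#' Published summary statistics of the two emulated studies
#'
#' Point values of the published per-condition performance tables of the
#' two face-matching studies this package's generator emulates: percent
#' correct, FPR, TPR, sensitivity d' and criterion c at the standard
#' decision threshold (theta = 0.5), one row per condition x algorithm
#' decision label. These are reference inputs (as printed, 2 decimal
#' places), used to cross-check the closed-form SDT operations and to
#' parameterize realistic simulations.
#'
#' @param study 1 or 2.
#' @return data.frame with columns `condition`, `mask`,
#'   `algorithm_decision`, `n`, `pct_correct`, `fpr`, `tpr`, `d_prime`,
#'   `c`.
#' @export
#' @examples
#' reference_summary(1)
reference_summary <- function(study = 1) {
  if (!study %in% c(1, 2))
    fb_stop("study must be 1 or 2", class = "facebias_config")
  path <- system.file("extdata",
                      sprintf("study%d_printed_summary.csv", study),
                      package = "facebias", mustWork = TRUE)
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' Headline criterion shifts implied by a reference table
#'
#' `delta_c = c_different - c_same` per labelled condition, computed from
#' the criterion column of [reference_summary()].
#'
#' @param study 1 or 2.
#' @return named numeric vector over labelled conditions.
#' @export
#' @examples
#' reference_delta_c(1)
reference_delta_c <- function(study = 1) {
  tab <- reference_summary(study)
  tab <- tab[tab$algorithm_decision != "NONE", ]
  conds <- unique(tab$condition)
  vapply(conds, function(cc)
    tab$c[tab$condition == cc & tab$algorithm_decision == "DIFFERENT"] -
      tab$c[tab$condition == cc & tab$algorithm_decision == "SAME"],
    numeric(1))
}
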