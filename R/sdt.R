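#' Binarize a similarity-confidence rating
#'
#' Converts a 7-point rating into a same/different review outcome at a
#' threshold theta. At the default decision threshold theta = 0.5, ratings
#' of 1 and above ("I am somewhat certain this is the same person" and
#' stronger) confirm the pair as the same person; 0 and below call it
#' different people.
#'
#' @param rating integer rating(s) in -3..3.
#' @param theta half-integer threshold from the grid
#'   `c(-2.5, -1.5, -0.5, 0.5, 1.5, 2.5)`.
#' @return character vector, `"same"` or `"different"`.
#' @export
#' @examples
#' binarize(c(-3, 0, 1, 3), theta = 0.5)
binarize <- function(rating, theta = 0.5) {
  check_theta(theta)
  if (any(!rating %in% (-3:3)))
    fb_stop("rating outside [-3, 3]", class = "facebias_validation")
  ifelse(rating > theta, "same", "different")
}

check_theta <- function(theta) {
  if (length(theta) != 1 || !theta %in% fb_theta_grid)
    fb_stop("theta must be one of {%s}",
            paste(fb_theta_grid, collapse = ", "), class = "facebias_config")
  invisible(theta)
}

#' Adjust an extreme hit or false-alarm rate
#'
#' Proportions of exactly 0 or 1 have no probit; they are replaced by
#' `(hits + 0.5) / (n + 1)`. Interior rates are returned unchanged as
#' `hits / n`.
#'
#' @param hits count of positive responses, `0 <= hits <= n`.
#' @param n trial count, `n >= 1`.
#' @return adjusted proportion in (0, 1).
#' @export
#' @examples
#' adjust_extreme(0, 6)   # 0.5/7
#' adjust_extreme(3, 6)   # untouched
adjust_extreme <- function(hits, n) {
  if (any(n < 1)) fb_stop("n must be >= 1", class = "facebias_degenerate")
  if (any(hits < 0 | hits > n))
    fb_stop("hits must lie in [0, n]", class = "facebias_validation")
  ifelse(hits == 0 | hits == n, (hits + 0.5) / (n + 1), hits / n)
}

# vectorized adjustment of an already-averaged rate given the underlying
# total trial count
adjust_rate <- function(p, n_total) {
  ifelse(p <= 0, 0.5 / (n_total + 1),
         ifelse(p >= 1, (n_total + 0.5) / (n_total + 1), p))
}

#' Sensitivity d' from hit and false-alarm rates
#'
#' Equal-variance Gaussian sensitivity, `qnorm(tpr) - qnorm(fpr)`: the
#' separation (in latent-axis standard deviations) between the mated and
#' non-mated evidence distributions.
#'
#' @param tpr true positive rate(s), strictly inside (0, 1).
#' @param fpr false positive rate(s), strictly inside (0, 1).
#' @return numeric d'.
#' @export
#' @examples
#' dprime(0.61, 0.21)
dprime <- function(tpr, fpr) {
  check_rates(tpr, fpr)
  stats::qnorm(tpr) - stats::qnorm(fpr)
}

#' Criterion c from hit and false-alarm rates
#'
#' The response criterion relative to the midpoint of the two evidence
#' distributions, `-(qnorm(tpr) + qnorm(fpr)) / 2`. Higher c means the
#' reviewer demands more evidence before responding "same person".
#'
#' @inheritParams dprime
#' @return numeric c.
#' @export
#' @examples
#' criterion(0.69, 0.14)
criterion <- function(tpr, fpr) {
  check_rates(tpr, fpr)
  -(stats::qnorm(tpr) + stats::qnorm(fpr)) / 2
}

check_rates <- function(tpr, fpr) {
  if (any(tpr <= 0 | tpr >= 1) || any(fpr <= 0 | fpr >= 1))
    fb_stop("rates must lie strictly in (0, 1); apply adjust_extreme() first",
            class = "facebias_domain")
  invisible(NULL)
}

# Per-reviewer confusion cells for one condition x decision label: raw
# per-reviewer rates and counts, one row per reviewer. The workhorse behind
# condition_rates(), accuracy() and the bootstrap.
reviewer_cells <- function(panel, condition, decision_label = NULL,
                           theta = 0.5) {
  check_theta(theta)
  rec <- select_records(panel, condition, decision_label)
  same <- rec$rating > theta
  f <- factor(rec$reviewer_id, levels = unique(rec$reviewer_id))
  n_mated    <- tapply(rec$mated, f, sum)
  n_nonmated <- tapply(!rec$mated, f, sum)
  hits <- tapply(same & rec$mated, f, sum)
  fas  <- tapply(same & !rec$mated, f, sum)
  corr <- tapply(same == rec$mated, f, sum)
  bad <- which(n_mated == 0 | n_nonmated == 0)
  if (length(bad))
    fb_stop("reviewer %s has no %s trials under label %s",
            levels(f)[bad[1]],
            if (n_mated[bad[1]] == 0) "mated" else "non-mated",
            decision_label %||% "<any>", class = "facebias_degenerate")
  data.frame(reviewer_id = levels(f),
             n_mated = as.integer(n_mated),
             n_nonmated = as.integer(n_nonmated),
             hits = as.integer(hits), fas = as.integer(fas),
             tpr = as.numeric(hits / n_mated),
             fpr = as.numeric(fas / n_nonmated),
             accuracy = as.numeric(corr / (n_mated + n_nonmated)),
             stringsAsFactors = FALSE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Condition-level confusion rates
#'
#' Computes the true positive rate (TPR; fraction of mated pairs confirmed
#' as the same person) and false positive rate (FPR; fraction of non-mated
#' pairs confirmed) for one condition and algorithm decision label at a
#' threshold. Per-reviewer rates are counted over that reviewer's trials and
#' then averaged with equal weight across reviewers; with the balanced
#' rosters used here this coincides with pooled counting.
#'
#' Extreme aggregated rates (0 or 1) are adjusted before any probit is
#' taken; `adjust = "reviewer"` instead applies [adjust_extreme()] to each
#' reviewer's rate before averaging (per-reviewer cells here have only a few
#' trials, so this mode visibly biases the aggregate and is not the
#' default), and `adjust = "none"` disables adjustment.
#'
#' @inheritParams reviewer_cells
#' @param condition condition code.
#' @param decision_label `"SAME"`, `"DIFFERENT"`, or `"NONE"` (control);
#'   `NULL` pools all labels.
#' @param adjust extreme-rate handling, see Details.
#' @return an object of class `confusion_rates`: list with `tpr`, `fpr`,
#'   `n_mated`, `n_nonmated` (total trial counts), `n_reviewers`, and the
#'   `per_reviewer` data.frame.
#' @export
#' @examples
#' pan <- simulate_panel(simulation_config(n_per_condition = 30, seed = 2))
#' pan <- attention_filter(pan)$panel
#' condition_rates(pan, "mask", "DIFFERENT")
condition_rates <- function(panel, condition, decision_label = NULL,
                            theta = 0.5,
                            adjust = c("aggregate", "reviewer", "none")) {
  adjust <- match.arg(adjust)
  cells <- reviewer_cells(panel, condition, decision_label, theta)
  Nm <- sum(cells$n_mated); Nn <- sum(cells$n_nonmated)
  if (adjust == "reviewer") {
    tpr <- mean(adjust_extreme(cells$hits, cells$n_mated))
    fpr <- mean(adjust_extreme(cells$fas, cells$n_nonmated))
  } else {
    tpr <- mean(cells$tpr); fpr <- mean(cells$fpr)
    if (adjust == "aggregate") {
      tpr <- adjust_rate(tpr, Nm)
      fpr <- adjust_rate(fpr, Nn)
    }
  }
  structure(list(tpr = tpr, fpr = fpr, n_mated = Nm, n_nonmated = Nn,
                 n_reviewers = nrow(cells), condition = condition,
                 decision_label = decision_label %||% "<pooled>",
                 theta = theta, per_reviewer = cells),
            class = "confusion_rates")
}

#' @export
print.confusion_rates <- function(x, ...) {
  cat(sprintf(paste0("<confusion_rates> %s / %s @ theta=%.1f: ",
                     "TPR=%.3f FPR=%.3f (%d reviewers)\n"),
              x$condition, x$decision_label, x$theta, x$tpr, x$fpr,
              x$n_reviewers))
  invisible(x)
}

#' Criterion shift between algorithm decision labels
#'
#' The cognitive-bias statistic: how far the reviewers' criterion moves when
#' the algorithm labels a pair "DIFFERENT PEOPLE" versus "SAME PERSON",
#' `delta_c = c_different - c_same`. Rate shifts are reported as
#' same-minus-different, so positive values mean the SAME label pulls
#' responses toward "same person".
#'
#' @param rates_same [condition_rates()] result for the SAME label.
#' @param rates_diff [condition_rates()] result for the DIFFERENT label.
#' @return list of class `bias_shift` with `delta_c`, `delta_tpr`,
#'   `delta_fpr`.
#' @export
#' @examples
#' s <- structure(list(tpr = 0.82, fpr = 0.21), class = "confusion_rates")
#' d <- structure(list(tpr = 0.75, fpr = 0.16), class = "confusion_rates")
#' bias_shift(s, d)$delta_c
bias_shift <- function(rates_same, rates_diff) {
  structure(list(
    delta_c = criterion(rates_diff$tpr, rates_diff$fpr) -
      criterion(rates_same$tpr, rates_same$fpr),
    delta_tpr = rates_same$tpr - rates_diff$tpr,
    delta_fpr = rates_same$fpr - rates_diff$fpr), class = "bias_shift")
}

#' Percent correct for a condition
#'
#' Fraction of trials whose binarized decision matches the pair's mated
#' status, computed per reviewer and averaged with equal weight.
#'
#' @inheritParams condition_rates
#' @return proportion in `[0, 1]`.
#' @export
accuracy <- function(panel, condition, decision_label = NULL, theta = 0.5) {
  mean(reviewer_cells(panel, condition, decision_label, theta)$accuracy)
}

#' Similarity-confidence summary for a condition
#'
#' `mu_abs` is the mean absolute rating over all scored records of the
#' condition (how confident reviewers were, regardless of direction);
#' `mu_same` / `mu_different` average the raw ratings by algorithm decision
#' label, and `delta_mu = mu_different - mu_same` is the confidence twin of
#' the criterion shift. For the control condition (no labels) `delta_mu` is
#' `NA` with `has_labels = FALSE`.
#'
#' @inheritParams condition_rates
#' @return list of class `confidence_summary` with `mu_abs`, `mu_same`,
#'   `mu_different`, `delta_mu`, `has_labels`.
#' @export
confidence_summary <- function(panel, condition) {
  rec <- select_records(panel, condition)
  labelled <- all(rec$algorithm_decision != "NONE")
  mu_same <- if (labelled)
    mean(rec$rating[rec$algorithm_decision == "SAME"]) else NA_real_
  mu_diff <- if (labelled)
    mean(rec$rating[rec$algorithm_decision == "DIFFERENT"]) else NA_real_
  structure(list(mu_abs = mean(abs(rec$rating)),
                 mu_same = mu_same, mu_different = mu_diff,
                 delta_mu = mu_diff - mu_same,
                 has_labels = labelled, condition = condition),
            class = "confidence_summary")
}
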