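#' @name inference
#' @title Bootstrap and classical inference for reviewer panels
#' @description Reviewers are the exchangeable unit in these studies: all
#'   confidence intervals resample reviewers with replacement (percentile
#'   intervals), shift tests resample reviewers jointly across the two
#'   decision labels (the labels are within-subject), and cross-condition
#'   comparisons resample each condition independently. Classical ANOVAs and
#'   t-tests mirror the panel-level analyses of the studies.
NULL

new_boot_result <- function(estimate, reps, B, seed, metric, n) {
  qs <- stats::quantile(reps, c(0.025, 0.975), names = FALSE, type = 7)
  p <- min(1, 2 * min(mean(reps <= 0), mean(reps >= 0)))
  structure(list(estimate = estimate, ci_low = qs[1], ci_high = qs[2],
                 p_two_sided = p, significant = p < 0.05,
                 B = B, seed = seed, metric = metric, n = n),
            class = "fb_boot")
}

#' @export
print.fb_boot <- function(x, ...) {
  cat(sprintf("<bootstrap> %s = %.4f  95%% CI [%.4f, %.4f]  p = %.4g  (B = %d, n = %d)\n",
              x$metric, x$estimate, x$ci_low, x$ci_high, x$p_two_sided,
              x$B, x$n))
  invisible(x)
}

# B x n resampling index matrix
boot_index <- function(n, B) matrix(sample.int(n, n * B, replace = TRUE), B, n)

resampled_means <- function(v, idx) rowMeans(matrix(v[idx], nrow(idx)))

metric_fun <- function(metric) {
  if (is.function(metric)) return(metric)
  switch(metric,
         dprime = function(tpr, fpr) dprime(tpr, fpr),
         criterion = , c = function(tpr, fpr) criterion(tpr, fpr),
         tpr = function(tpr, fpr) tpr,
         fpr = function(tpr, fpr) fpr,
         fb_stop("unknown metric '%s'", metric, class = "facebias_config"))
}

#' Bootstrap confidence interval for a condition-level metric
#'
#' Resamples reviewers with replacement within one condition x decision
#' label cell and recomputes the metric on each replicate's averaged
#' (extreme-adjusted) rates. Deterministic given `seed`; invariant to
#' reviewer ordering.
#'
#' @inheritParams condition_rates
#' @param metric `"dprime"`, `"criterion"` (alias `"c"`), `"tpr"`, `"fpr"`,
#'   `"accuracy"`, or a vectorized `function(tpr, fpr)` of adjusted mean
#'   rates.
#' @param B bootstrap replicates (>= 1000 recommended; default 10000).
#' @param seed integer seed for the resampling stream.
#' @return an `fb_boot` object: `estimate`, percentile `ci_low` /
#'   `ci_high`, doubled-tail `p_two_sided` against zero, `B`, `seed`, `n`.
#' @export
#' @examples
#' pan <- attention_filter(simulate_panel(
#'   simulation_config(n_per_condition = 30, seed = 5)))$panel
#' bootstrap_metric(pan, "mask", "SAME", "dprime", B = 1000, seed = 11)
bootstrap_metric <- function(panel, condition, decision_label = NULL,
                             metric = "dprime", theta = 0.5, B = 10000,
                             seed = 1L) {
  cells <- reviewer_cells(panel, condition, decision_label, theta)
  n <- nrow(cells)
  if (n < 2)
    fb_stop("need at least 2 reviewers to bootstrap (have %d)", n,
            class = "facebias_degenerate")
  cells <- cells[order(cells$reviewer_id), ]  # ordering invariance
  Nm <- sum(cells$n_mated); Nn <- sum(cells$n_nonmated)
  is_acc <- identical(metric, "accuracy")
  f <- if (is_acc) NULL else metric_fun(metric)
  point <- if (is_acc) mean(cells$accuracy) else
    f(adjust_rate(mean(cells$tpr), Nm), adjust_rate(mean(cells$fpr), Nn))
  reps <- with_seed(seed, {
    idx <- boot_index(n, B)
    if (is_acc) resampled_means(cells$accuracy, idx) else {
      mt <- adjust_rate(resampled_means(cells$tpr, idx), Nm)
      mf <- adjust_rate(resampled_means(cells$fpr, idx), Nn)
      f(mt, mf)
    }
  })
  new_boot_result(point, reps, B, seed,
                  if (is.function(metric)) "custom" else metric, n)
}

# per-reviewer cells under both labels, aligned by reviewer
shift_cells <- function(panel, condition, theta) {
  s <- reviewer_cells(panel, condition, "SAME", theta)
  d <- reviewer_cells(panel, condition, "DIFFERENT", theta)
  m <- merge(s, d, by = "reviewer_id", suffixes = c("_s", "_d"))
  if (nrow(m) < 2)
    fb_stop("need at least 2 reviewers with both labels",
            class = "facebias_degenerate")
  m[order(m$reviewer_id), ]
}

shift_stat <- function(metric, mt_s, mf_s, mt_d, mf_d, Nm, Nn) {
  switch(metric,
         c = criterion(adjust_rate(mt_d, Nm), adjust_rate(mf_d, Nn)) -
           criterion(adjust_rate(mt_s, Nm), adjust_rate(mf_s, Nn)),
         tpr = mt_s - mt_d,
         fpr = mf_s - mf_d)
}

#' Bootstrap test of a label-induced shift within a condition
#'
#' The statistic is the shift between decision labels: `delta_c =
#' c_different - c_same` for `metric = "c"`, or the same-minus-different
#' rate difference for `"tpr"` / `"fpr"` (positive = the SAME label pulls
#' responses toward "same person"). Reviewers are resampled jointly across
#' labels (each reviewer rated trials under both), giving within-subject
#' inference; the two-sided p is the doubled tail fraction of replicates
#' crossing zero.
#'
#' @inheritParams bootstrap_metric
#' @param metric `"c"`, `"tpr"`, or `"fpr"`.
#' @return an `fb_boot` object.
#' @export
shift_test <- function(panel, condition, metric = c("c", "tpr", "fpr"),
                       theta = 0.5, B = 10000, seed = 1L) {
  metric <- match.arg(metric)
  m <- shift_cells(panel, condition, theta)
  n <- nrow(m)
  Nm <- sum(m$n_mated_s); Nn <- sum(m$n_nonmated_s)
  point <- shift_stat(metric, mean(m$tpr_s), mean(m$fpr_s),
                      mean(m$tpr_d), mean(m$fpr_d), Nm, Nn)
  reps <- with_seed(seed, {
    idx <- boot_index(n, B)
    shift_stat(metric,
               resampled_means(m$tpr_s, idx), resampled_means(m$fpr_s, idx),
               resampled_means(m$tpr_d, idx), resampled_means(m$fpr_d, idx),
               Nm, Nn)
  })
  new_boot_result(point, reps, B, seed, paste0("shift_", metric), n)
}

#' Bootstrap comparison of shifts across two conditions or studies
#'
#' The statistic is `shift(panel_a, condition_a) - shift(panel_b,
#' condition_b)`; reviewers are resampled independently within each
#' condition. Antisymmetric in its arguments.
#'
#' @inheritParams shift_test
#' @param panel_a,panel_b filtered panels (may be the same object).
#' @param condition_a,condition_b condition codes within each panel.
#' @return an `fb_boot` object.
#' @export
cross_condition_shift_test <- function(panel_a, condition_a,
                                       panel_b = panel_a, condition_b,
                                       metric = c("c", "tpr", "fpr"),
                                       theta = 0.5, B = 10000, seed = 1L) {
  metric <- match.arg(metric)
  ma <- shift_cells(panel_a, condition_a, theta)
  mb <- shift_cells(panel_b, condition_b, theta)
  one <- function(m) shift_stat(metric, mean(m$tpr_s), mean(m$fpr_s),
                                mean(m$tpr_d), mean(m$fpr_d),
                                sum(m$n_mated_s), sum(m$n_nonmated_s))
  point <- one(ma) - one(mb)
  reps <- with_seed(seed, {
    ia <- boot_index(nrow(ma), B); ib <- boot_index(nrow(mb), B)
    sa <- shift_stat(metric,
                     resampled_means(ma$tpr_s, ia), resampled_means(ma$fpr_s, ia),
                     resampled_means(ma$tpr_d, ia), resampled_means(ma$fpr_d, ia),
                     sum(ma$n_mated_s), sum(ma$n_nonmated_s))
    sb <- shift_stat(metric,
                     resampled_means(mb$tpr_s, ib), resampled_means(mb$fpr_s, ib),
                     resampled_means(mb$tpr_d, ib), resampled_means(mb$fpr_d, ib),
                     sum(mb$n_mated_s), sum(mb$n_nonmated_s))
    sa - sb
  })
  new_boot_result(point, reps, B, seed,
                  sprintf("shift_%s(%s - %s)", metric, condition_a,
                          condition_b),
                  nrow(ma) + nrow(mb))
}

new_anova_result <- function(tab) structure(tab, class = c("fb_anova",
                                                           "data.frame"))

#' Mixed two-way ANOVA on panel accuracy
#'
#' Split-plot design: the between-subjects factor is the experimental
#' condition (e.g. mask vs no-mask, or 65% vs 95% claimed accuracy), the
#' within-subjects factor is the algorithm decision label; each reviewer
#' contributes one accuracy value per label. The between effect is tested
#' against subjects-within-groups, the within and interaction effects
#' against the label x subject residual, via [stats::aov()] with an
#' `Error(reviewer)` stratum. With g groups and N reviewers total, the
#' between denominator df is N - g.
#'
#' @inheritParams condition_rates
#' @param conditions the two (or more) labelled conditions to compare;
#'   default: every non-control condition in the panel.
#' @return an `fb_anova` data.frame with one row per effect (`between`,
#'   `within`, `interaction`): `F`, `df_num`, `df_den`, `p`.
#' @export
mixed_anova_accuracy <- function(panel, conditions = NULL, theta = 0.5) {
  conditions <- conditions %||% setdiff(panel_conditions(panel), "control")
  if (length(conditions) < 2)
    fb_stop("need at least two labelled conditions", class = "facebias_config")
  long <- do.call(rbind, lapply(conditions, function(cond) {
    do.call(rbind, lapply(c("SAME", "DIFFERENT"), function(lab) {
      cells <- reviewer_cells(panel, cond, lab, theta)
      data.frame(group = cond, label = lab,
                 reviewer_id = cells$reviewer_id, acc = cells$accuracy,
                 stringsAsFactors = FALSE)
    }))
  }))
  counts <- table(long$reviewer_id)
  if (any(counts != 2))
    fb_stop("each reviewer must contribute exactly one accuracy per label",
            class = "facebias_design")
  long$group <- factor(long$group); long$label <- factor(long$label)
  long$reviewer_id <- factor(long$reviewer_id)
  fit <- stats::aov(acc ~ group * label + Error(reviewer_id), data = long)
  s <- summary(fit)
  btw <- s[["Error: reviewer_id"]][[1]]
  wth <- s[["Error: Within"]][[1]]
  row_of <- function(tab, name) {
    i <- match(name, trimws(rownames(tab)))
    c(F = tab[i, "F value"], df_num = tab[i, "Df"],
      df_den = tab[trimws(rownames(tab)) == "Residuals", "Df"],
      p = tab[i, "Pr(>F)"])
  }
  out <- rbind(between = row_of(btw, "group"),
               within = row_of(wth, "label"),
               interaction = row_of(wth, "group:label"))
  new_anova_result(data.frame(effect = rownames(out), out,
                              row.names = NULL))
}

#' One-way ANOVA on mean absolute confidence
#'
#' One mean-|rating| value per reviewer, compared across assigned
#' conditions (between-subjects). Mirrors the panel analysis asking whether
#' masks or accuracy framing systematically reduce similarity-confidence.
#'
#' @inheritParams mixed_anova_accuracy
#' @param conditions conditions to include; default: all present.
#' @return an `fb_anova` data.frame with a single `between` row.
#' @export
oneway_anova_abs_confidence <- function(panel, conditions = NULL) {
  conditions <- conditions %||% panel_conditions(panel)
  if (length(conditions) < 2)
    fb_stop("need at least two conditions", class = "facebias_config")
  df <- do.call(rbind, lapply(conditions, function(cond) {
    rec <- select_records(panel, cond)
    agg <- tapply(abs(rec$rating), rec$reviewer_id, mean)
    if (length(agg) < 2)
      fb_stop("condition '%s' has fewer than 2 reviewers", cond,
              class = "facebias_degenerate")
    data.frame(condition = cond, mu_abs = as.numeric(agg))
  }))
  tab <- stats::anova(stats::lm(mu_abs ~ condition, data = df))
  new_anova_result(data.frame(effect = "between",
                              F = tab["condition", "F value"],
                              df_num = tab["condition", "Df"],
                              df_den = tab["Residuals", "Df"],
                              p = tab["condition", "Pr(>F)"]))
}

new_ttest <- function(t, df, p, kind, degenerate = FALSE)
  structure(list(t = t, df = df, p = p, kind = kind,
                 degenerate = degenerate), class = "fb_ttest")

#' @export
print.fb_ttest <- function(x, ...) {
  cat(sprintf("<t-test (%s)> t(%.4g) = %.3f, p = %.4g%s\n", x$kind, x$df,
              x$t, x$p, if (x$degenerate) "  [degenerate]" else ""))
  invisible(x)
}

#' Post-hoc comparison of mean absolute confidence between two conditions
#'
#' Welch two-sample t-test on per-reviewer mean |rating|, without
#' multiplicity correction (the study reports bare pairwise p values).
#'
#' @inheritParams mixed_anova_accuracy
#' @param condition_pair character vector of the two condition codes.
#' @return an `fb_ttest`.
#' @export
pairwise_posthoc <- function(panel, condition_pair) {
  stopifnot(length(condition_pair) == 2)
  mu <- lapply(condition_pair, function(cond) {
    rec <- select_records(panel, cond)
    as.numeric(tapply(abs(rec$rating), rec$reviewer_id, mean))
  })
  tt <- stats::t.test(mu[[1]], mu[[2]], var.equal = FALSE)
  new_ttest(unname(tt$statistic), unname(tt$parameter), tt$p.value,
            "two_sample")
}

#' Per-pair confidence-shift test
#'
#' For one face pair within a condition, compares raw ratings given under
#' the SAME versus DIFFERENT algorithm decision (two-sample t across
#' reviewers; each reviewer saw the pair under exactly one label).
#'
#' @inheritParams condition_rates
#' @param pair_id face-pair identifier.
#' @return an `fb_ttest`.
#' @export
per_pair_shift_test <- function(panel, condition, pair_id) {
  rec <- select_records(panel, condition)
  rec <- rec[rec$pair_id == pair_id, , drop = FALSE]
  a <- rec$rating[rec$algorithm_decision == "SAME"]
  b <- rec$rating[rec$algorithm_decision == "DIFFERENT"]
  if (length(a) < 2 || length(b) < 2)
    fb_stop("pair '%s' lacks ratings under both labels", pair_id,
            class = "facebias_degenerate")
  if (stats::sd(a) == 0 && stats::sd(b) == 0)
    return(new_ttest(if (mean(a) == mean(b)) 0 else Inf,
                     length(a) + length(b) - 2,
                     if (mean(a) == mean(b)) 1 else 0, "two_sample",
                     degenerate = TRUE))
  tt <- stats::t.test(a, b, var.equal = FALSE)
  new_ttest(unname(tt$statistic), unname(tt$parameter), tt$p.value,
            "two_sample")
}

#' Count face pairs with a significant confidence shift
#'
#' Applies [per_pair_shift_test()] to every scored pair of a condition and
#' counts p-values below `alpha`. Pairs never rated under both labels
#' (possible in small or single-variant panels) are not testable and are
#' skipped.
#'
#' @inheritParams per_pair_shift_test
#' @param alpha significance level (default 0.05).
#' @return integer count (out of the testable scored pairs).
#' @export
count_significant_pairs <- function(panel, condition, alpha = 0.05) {
  pairs <- unique(select_records(panel, condition)$pair_id)
  sum(vapply(pairs, function(p) {
    tt <- tryCatch(per_pair_shift_test(panel, condition, p),
                   facebias_degenerate = function(e) NULL)
    !is.null(tt) && tt$p < alpha
  }, logical(1)))
}

#' Per-pair confidence shifts for a condition
#'
#' `delta_mu = mu_different - mu_same` per scored face pair: the raw-rating
#' counterpart of the criterion shift, used by [pairlevel_paired_test()] to
#' compare bias between conditions across the common 12 pairs.
#'
#' @inheritParams condition_rates
#' @return named numeric vector over pair ids.
#' @export
pair_shifts <- function(panel, condition) {
  rec <- select_records(panel, condition)
  pairs <- sort(unique(rec$pair_id))
  vapply(pairs, function(p) {
    r <- rec[rec$pair_id == p, ]
    mean(r$rating[r$algorithm_decision == "DIFFERENT"]) -
      mean(r$rating[r$algorithm_decision == "SAME"])
  }, numeric(1))
}

#' Paired t-test on pair-level confidence shifts
#'
#' Compares two conditions' per-pair shift vectors (aligned by pair id)
#' with a paired t-test over the 12 common face pairs (df = 11). A
#' zero-variance difference vector is flagged as degenerate rather than
#' raising an error.
#'
#' @param delta_mu_a,delta_mu_b numeric vectors of per-pair shifts, equal
#'   length, aligned by pair.
#' @return an `fb_ttest` with `kind = "paired"`.
#' @export
pairlevel_paired_test <- function(delta_mu_a, delta_mu_b) {
  if (length(delta_mu_a) != length(delta_mu_b))
    fb_stop("shift vectors differ in length (%d vs %d)",
            length(delta_mu_a), length(delta_mu_b),
            class = "facebias_validation")
  d <- delta_mu_a - delta_mu_b
  n <- length(d)
  if (stats::sd(d) <= 1e-12 * (abs(mean(d)) + 1))
    return(new_ttest(if (mean(d) == 0) 0 else Inf * sign(mean(d)), n - 1,
                     if (mean(d) == 0) 1 else 0, "paired",
                     degenerate = TRUE))
  t <- mean(d) / (stats::sd(d) / sqrt(n))
  new_ttest(t, n - 1, 2 * stats::pt(-abs(t), n - 1), "paired")
}

#' Trust proportion for a condition and phase
#'
#' @param trust data.frame of trust records (see [read_trust()]).
#' @param condition condition code.
#' @param phase `"pre"` or `"post"`.
#' @return fraction of reviewers agreeing to trust.
#' @export
trust_proportion <- function(trust, condition, phase = "pre") {
  sel <- trust$condition == condition & trust$phase == phase
  if (!any(sel))
    fb_stop("no trust records for condition '%s', phase '%s'", condition,
            phase, class = "facebias_empty")
  mean(trust$agrees[sel])
}
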