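#' Rating-scale ROC curve
#'
#' Sweeps the binarization threshold over the full grid of the 7-point
#' scale, from very permissive (theta = -2.5) to very strict (theta = 2.5),
#' computing one (FPR, TPR) point per threshold for the given condition and
#' decision label, and anchors the curve at (0, 0) and (1, 1).
#'
#' @inheritParams condition_rates
#' @param thetas threshold grid; defaults to the full 6-value grid.
#' @return object of class `fb_roc`: data.frame with columns `theta`
#'   (`NA` for anchors), `fpr`, `tpr`, sorted by `fpr`; attributes carry
#'   the condition and label tags.
#' @export
#' @examples
#' pan <- simulate_panel(simulation_config(n_per_condition = 40, seed = 3))
#' pan <- attention_filter(pan)$panel
#' auc(roc_curve(pan, "no_mask", "SAME"))
roc_curve <- function(panel, condition, decision_label = NULL,
                      thetas = fb_theta_grid,
                      adjust = c("aggregate", "reviewer", "none")) {
  adjust <- match.arg(adjust)
  pts <- lapply(thetas, function(th) {
    r <- condition_rates(panel, condition, decision_label, th, adjust)
    data.frame(theta = th, fpr = r$fpr, tpr = r$tpr)
  })
  pts <- do.call(rbind, pts)
  pts <- rbind(data.frame(theta = NA_real_, fpr = 0, tpr = 0),
               pts,
               data.frame(theta = NA_real_, fpr = 1, tpr = 1))
  pts <- pts[order(pts$fpr, pts$tpr), ]
  rownames(pts) <- NULL
  structure(pts, class = c("fb_roc", "data.frame"),
            condition = condition,
            decision_label = decision_label %||% "<pooled>")
}

#' Trapezoidal area under an ROC curve
#'
#' @param curve an [roc_curve()] result, or any data.frame with `fpr` and
#'   `tpr` columns sorted by `fpr` and anchored at (0,0) and (1,1).
#' @return AUC in `[0, 1]`.
#' @export
auc <- function(curve) {
  f <- curve$fpr; t <- curve$tpr
  if (is.null(f) || is.null(t) || length(f) < 2)
    fb_stop("curve must supply fpr/tpr columns", class = "facebias_validation")
  if (is.unsorted(f))
    fb_stop("curve points must be sorted by fpr", class = "facebias_validation")
  if (sum(f == 0 & t == 0) != 1 || sum(f == 1 & t == 1) != 1)
    fb_stop("curve must contain each anchor (0,0) and (1,1) exactly once",
            class = "facebias_validation")
  sum(diff(f) * (utils::head(t, -1) + utils::tail(t, -1)) / 2)
}

#' Constant-criterion (isobias) curve in ROC space
#'
#' The locus of `(FPR, TPR) = (pnorm(-d/2 - c), pnorm(d/2 - c))` as
#' sensitivity d varies with the criterion held fixed. At d = 0 the curve
#' meets the anti-diagonal `tpr = 1 - fpr`; as d grows, TPR rises and FPR
#' falls. Curves for distinct criteria never intersect, which is what lets
#' band overlap be decided exactly in criterion space.
#'
#' @param c criterion value.
#' @param d_max largest sensitivity sampled (default 4, beyond any d'
#'   measured in these tasks).
#' @param n_samples number of polyline samples (>= 2).
#' @return object of class `fb_isobias_curve`: data.frame with columns `d`,
#'   `fpr`, `tpr`; attribute `c` holds the criterion.
#' @export
#' @examples
#' head(isobias_curve(0.29))
isobias_curve <- function(c, d_max = 4, n_samples = 201) {
  if (d_max <= 0) fb_stop("d_max must be > 0", class = "facebias_config")
  if (n_samples < 2) fb_stop("n_samples must be >= 2", class = "facebias_config")
  d <- seq(0, d_max, length.out = n_samples)
  structure(data.frame(d = d,
                       fpr = stats::pnorm(-d / 2 - c),
                       tpr = stats::pnorm(d / 2 - c)),
            class = c("fb_isobias_curve", "data.frame"), c = c)
}

#' Isobias band between the two decision-label criteria
#'
#' At one decision threshold, the criteria measured under SAME and
#' DIFFERENT algorithm decisions bound a region of ROC space (the band
#' between their isobias curves). The band is stored as the ordered
#' criterion interval; geometry for plotting comes from [isobias_curve()].
#'
#' @param theta the decision threshold the band belongs to.
#' @param c_same criterion measured under the SAME label.
#' @param c_different criterion measured under the DIFFERENT label.
#' @return object of class `fb_isobias_band`: list with `theta`, `c_same`,
#'   `c_different`, `c_low`, `c_high`.
#' @export
#' @examples
#' isobias_band(0.5, 0.10, 0.55)
isobias_band <- function(theta, c_same, c_different) {
  structure(list(theta = theta, c_same = c_same, c_different = c_different,
                 c_low = min(c_same, c_different),
                 c_high = max(c_same, c_different)),
            class = "fb_isobias_band")
}

#' @export
print.fb_isobias_band <- function(x, ...) {
  cat(sprintf("<isobias_band> theta=%.1f  c in [%.3f, %.3f]\n",
              x$theta, x$c_low, x$c_high))
  invisible(x)
}

#' Do two isobias bands overlap?
#'
#' Because isobias curves for distinct criteria never cross, two bands
#' overlap in ROC space exactly when their criterion intervals intersect
#' (closed intervals). Overlap of adjacent-threshold bands signals that the
#' label-induced criterion shift is comparable to a full step of the
#' confidence scale.
#'
#' @param a,b [isobias_band()] objects.
#' @return logical; symmetric in its arguments.
#' @export
bands_overlap <- function(a, b) {
  a$c_low <= b$c_high && b$c_low <= a$c_high
}

#' Band geometry for all thresholds of a condition
#'
#' Convenience builder: one [isobias_band()] per threshold, from the
#' criteria measured under each label.
#'
#' @inheritParams roc_curve
#' @return list of `fb_isobias_band`, named by theta.
#' @export
condition_bands <- function(panel, condition, thetas = fb_theta_grid,
                            adjust = c("aggregate", "reviewer", "none")) {
  adjust <- match.arg(adjust)
  out <- lapply(thetas, function(th) {
    rs <- condition_rates(panel, condition, "SAME", th, adjust)
    rd <- condition_rates(panel, condition, "DIFFERENT", th, adjust)
    isobias_band(th, criterion(rs$tpr, rs$fpr), criterion(rd$tpr, rd$fpr))
  })
  names(out) <- as.character(thetas)
  out
}

#' Export curve and band geometry as a tidy table
#'
#' Flattens ROC points and isobias band polylines for a condition into one
#' long data.frame (`series`, `theta`, `d`, `fpr`, `tpr`, `c_same`,
#' `c_different`) suitable for any plotting front end.
#'
#' @inheritParams condition_bands
#' @param d_max,n_samples passed to [isobias_curve()].
#' @return data.frame.
#' @export
band_geometry <- function(panel, condition, thetas = fb_theta_grid,
                          d_max = 4, n_samples = 201) {
  bands <- condition_bands(panel, condition, thetas)
  rows <- lapply(bands, function(b) {
    lo <- isobias_curve(b$c_low, d_max, n_samples)
    hi <- isobias_curve(b$c_high, d_max, n_samples)
    rbind(
      data.frame(series = "band_low", theta = b$theta, d = lo$d,
                 fpr = lo$fpr, tpr = lo$tpr,
                 c_same = b$c_same, c_different = b$c_different),
      data.frame(series = "band_high", theta = b$theta, d = hi$d,
                 fpr = hi$fpr, tpr = hi$tpr,
                 c_same = b$c_same, c_different = b$c_different))
  })
  geom <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  geom$condition <- condition
  geom
}
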