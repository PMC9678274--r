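test_that("ROC curves are anchored, sorted and complete", {
  pan <- sim_filtered(n_per_condition = 20, conditions = "no_mask", seed = 41)
  cu <- roc_curve(pan, "no_mask", "SAME")
  expect_equal(nrow(cu), 8L)
  expect_equal(sum(is.na(cu$theta)), 2L)
  expect_false(is.unsorted(cu$fpr))
  expect_equal(cu$fpr[1], 0); expect_equal(cu$tpr[1], 0)
  expect_equal(cu$fpr[8], 1); expect_equal(cu$tpr[8], 1)
})

test_that("trapezoidal AUC handles reference shapes and rejects bad input", {
  diag <- data.frame(fpr = c(0, 0.5, 1), tpr = c(0, 0.5, 1))
  expect_equal(auc(diag), 0.5)
  perfect <- data.frame(fpr = c(0, 0, 1), tpr = c(0, 1, 1))
  expect_equal(auc(perfect), 1)
  # adding collinear points changes nothing
  diag_dense <- data.frame(fpr = seq(0, 1, 0.1), tpr = seq(0, 1, 0.1))
  expect_equal(auc(diag_dense), 0.5)
  expect_error(auc(data.frame(fpr = c(0, 1, 0.5), tpr = c(0, 1, 0.5))),
               class = "facebias_validation")
  expect_error(auc(data.frame(fpr = c(0, 0.5), tpr = c(0, 0.5))),
               class = "facebias_validation")
})

test_that("simulated ROC matches the closed-form observer prediction", {
  # d' = 1.5, no label coupling: interior points and AUC follow the
  # generator's own closed form (criteria at d/2 + offsets, reviewer
  # heterogeneity shrinking the expected rates by 1/sqrt(1 + sd_d^2/4 +
  # sd_o^2))
  d <- 1.5
  pan <- sim_filtered(n_per_condition = 2000, conditions = "no_mask",
                      d_prime = c(no_mask = d), delta_c = c(no_mask = 0),
                      seed = 4)
  cu <- roc_curve(pan, "no_mask", "SAME")
  shrink <- 1 / sqrt(1 + 0.3^2 / 4 + 0.2^2)
  offs <- c(-1.0, -0.6, -0.2, 0.2, 0.6, 1.0)
  pred <- data.frame(fpr = pnorm((-d / 2 - offs) * shrink),
                     tpr = pnorm((d / 2 - offs) * shrink))
  obs <- cu[!is.na(cu$theta), ]
  pred <- pred[order(pred$fpr), ]
  expect_lt(max(abs(obs$fpr - pred$fpr)), 0.02)
  expect_lt(max(abs(obs$tpr - pred$tpr)), 0.02)
  pred_poly <- rbind(c(0, 0), as.matrix(pred), c(1, 1))
  pred_auc <- sum(diff(pred_poly[, 1]) *
                    (head(pred_poly[, 2], -1) + tail(pred_poly[, 2], -1)) / 2)
  expect_equal(auc(cu), pred_auc, tolerance = 0.02)
  # and the smooth equal-variance value pnorm(d/sqrt(2)) is close above
  expect_equal(auc(cu), pnorm(d / sqrt(2)), tolerance = 0.025)
})

test_that("a flat observer's ROC hugs the diagonal", {
  # sd_dprime = 0: with heterogeneity the truncation at d >= 0 gives the
  # average reviewer a small positive sensitivity even when d' = 0
  pan <- sim_filtered(n_per_condition = 500, conditions = "mask",
                      d_prime = c(mask = 0), delta_c = c(mask = 0),
                      sd_dprime = 0, seed = 6)
  cu <- roc_curve(pan, "mask", "SAME")
  obs <- cu[!is.na(cu$theta), ]
  expect_lt(max(abs(obs$tpr - obs$fpr)), 0.08)
  expect_lt(abs(auc(cu) - 0.5), 0.04)
})

test_that("isobias curves pass through their defining criterion points", {
  ic0 <- isobias_curve(0, d_max = 2, n_samples = 3)
  expect_equal(ic0$fpr[1], 0.5); expect_equal(ic0$tpr[1], 0.5)
  ic <- isobias_curve(0.29, d_max = 4, n_samples = 401)
  at <- which.min(abs(ic$d - 1.56))
  expect_lt(abs(ic$fpr[at] - 0.14), 0.01)
  expect_lt(abs(ic$tpr[at] - 0.69), 0.01)
  # monotone in d along a curve, and nested across criteria
  expect_true(all(diff(ic$tpr) > 0))
  expect_true(all(diff(ic$fpr) < 0))
  ic2 <- isobias_curve(0.6, d_max = 4, n_samples = 401)
  expect_true(all(ic$fpr > ic2$fpr) && all(ic$tpr > ic2$tpr))
  expect_error(isobias_curve(0, d_max = -1), class = "facebias_config")
})

test_that("bands are order-invariant intervals with symmetric overlap", {
  b <- isobias_band(0.5, 0.10, 0.55)
  expect_equal(c(b$c_low, b$c_high), c(0.10, 0.55))
  b2 <- isobias_band(0.5, 0.55, 0.10)
  expect_equal(c(b2$c_low, b2$c_high), c(0.10, 0.55))
  expect_equal(isobias_band(0.5, 0.3, 0.3)$c_high -
                 isobias_band(0.5, 0.3, 0.3)$c_low, 0)
  expect_true(bands_overlap(isobias_band(1, 0.1, 0.5),
                            isobias_band(2, 0.4, 0.9)))
  expect_false(bands_overlap(isobias_band(1, 0.1, 0.2),
                             isobias_band(2, 0.3, 0.4)))
  set.seed(7)
  for (i in 1:25) {
    a <- isobias_band(1, runif(1, -1, 1), runif(1, -1, 1))
    b <- isobias_band(2, runif(1, -1, 1), runif(1, -1, 1))
    expect_identical(bands_overlap(a, b), bands_overlap(b, a))
  }
})

test_that("interval overlap equals geometric band intersection in ROC space", {
  # oracle: at a shared FPR the band spans a TPR interval; two regions
  # intersect iff the TPR intervals intersect somewhere on a dense grid
  geometric_overlap <- function(a, b) {
    f <- seq(0.001, 0.999, length.out = 801)
    qf <- qnorm(f)
    # at fpr f a criterion cc sits at tpr = pnorm(-2*cc - qnorm(f)); the
    # band region keeps d = qnorm(tpr) - qnorm(f) >= 0
    tpr_span <- function(bd) {
      hi <- pnorm(-2 * bd$c_low - qf)   # smaller c -> higher tpr
      lo <- pmax(f, pnorm(-2 * bd$c_high - qf))
      cbind(lo = lo, hi = hi, valid = hi >= f)
    }
    sa <- tpr_span(a); sb <- tpr_span(b)
    any(sa[, "valid"] > 0 & sb[, "valid"] > 0 &
          sa[, "lo"] <= sb[, "hi"] & sb[, "lo"] <= sa[, "hi"])
  }
  set.seed(12)
  for (i in 1:20) {
    a <- isobias_band(1, runif(1, 0, 0.8), runif(1, 0, 0.8))
    b <- isobias_band(2, runif(1, 0, 0.8), runif(1, 0, 0.8))
    expect_identical(bands_overlap(a, b), geometric_overlap(a, b),
                     label = sprintf("case %d", i))
  }
})

test_that("band geometry export is tidy and plot-ready", {
  pan <- sim_filtered(n_per_condition = 25, conditions = "mask", seed = 3)
  geom <- band_geometry(pan, "mask", n_samples = 21)
  expect_setequal(unique(geom$series), c("band_low", "band_high"))
  expect_equal(nrow(geom), 6 * 2 * 21)
  expect_true(all(c("theta", "d", "fpr", "tpr", "c_same", "c_different",
                    "condition") %in% names(geom)))
})
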