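test_that("bootstrap is deterministic under a seed and ordering-invariant", {
  pan <- sim_filtered(n_per_condition = 25, conditions = "mask", seed = 51)
  b1 <- bootstrap_metric(pan, "mask", "SAME", "dprime", B = 1000, seed = 9)
  b2 <- bootstrap_metric(pan, "mask", "SAME", "dprime", B = 1000, seed = 9)
  expect_identical(b1[c("estimate", "ci_low", "ci_high", "p_two_sided")],
                   b2[c("estimate", "ci_low", "ci_high", "p_two_sided")])
  b3 <- bootstrap_metric(pan, "mask", "SAME", "dprime", B = 1000, seed = 10)
  expect_false(identical(b1$ci_low, b3$ci_low))
  shuf <- pan
  set.seed(1)
  shuf$records <- shuf$records[sample(nrow(shuf$records)), ]
  b4 <- bootstrap_metric(shuf, "mask", "SAME", "dprime", B = 1000, seed = 9)
  expect_identical(b1$ci_low, b4$ci_low)
})

test_that("a metric with no across-reviewer variance has a zero-width CI", {
  pan <- tiny_panel(list(a = rep(3, 12), b = rep(3, 12), c = rep(3, 12)))
  b <- bootstrap_metric(pan, "no_mask", "SAME", "accuracy", B = 1000,
                        seed = 2)
  expect_equal(b$ci_low, b$ci_high)
  expect_equal(b$estimate, 0.5)  # all-"same" responses: mated half correct
  solo <- tiny_panel(list(only = rep(1, 12)))
  expect_error(bootstrap_metric(solo, "no_mask", "SAME", "tpr"),
               class = "facebias_degenerate")
})

test_that("shift tests point where the generator put the bias", {
  pan <- sim_filtered(n_per_condition = 200, conditions = "mask",
                      d_prime = c(mask = 0.9), delta_c = c(mask = 0.6),
                      seed = 23)
  st <- shift_test(pan, "mask", "c", B = 2000, seed = 31)
  expect_gt(st$estimate, 0.3)
  expect_true(st$significant)
  expect_true(st$ci_low <= st$estimate && st$estimate <= st$ci_high)
})

test_that("cross-condition shifts are antisymmetric and null on identity", {
  pan <- sim_filtered(n_per_condition = 40,
                      conditions = c("no_mask", "mask"), seed = 29)
  ab <- cross_condition_shift_test(pan, "mask", pan, "no_mask", "c",
                                   B = 1500, seed = 5)
  ba <- cross_condition_shift_test(pan, "no_mask", pan, "mask", "c",
                                   B = 1500, seed = 5)
  expect_equal(ab$estimate, -ba$estimate)
  self <- cross_condition_shift_test(pan, "mask", pan, "mask", "c",
                                     B = 1500, seed = 5)
  expect_equal(self$estimate, 0)
  expect_gt(self$p_two_sided, 0.5)
})

test_that("a strong bias gap across conditions is detected", {
  pan <- sim_filtered(n_per_condition = 500,
                      conditions = c("no_mask", "mask"),
                      d_prime = c(no_mask = 1.7, mask = 0.9),
                      delta_c = c(no_mask = 0.21, mask = 0.45), seed = 77)
  gap <- cross_condition_shift_test(pan, "mask", pan, "no_mask", "c",
                                    B = 2000, seed = 3)
  expect_true(gap$significant)
  expect_gt(gap$estimate, 0)
})

test_that("the mixed ANOVA matches a hand sums-of-squares oracle", {
  # hand-computable toy: group A flat at 0.5, group B flat at 1.0 except
  # one label cell
  long <- data.frame(
    group = rep(c("A", "B"), each = 4),
    label = rep(c("SAME", "DIFFERENT"), 4),
    reviewer_id = rep(c("a1", "a2", "b1", "b2"), each = 2),
    acc = c(0.5, 0.5, 0.5, 0.5, 1.0, 1.0, 1.0, 0.5))
  fit <- stats::aov(acc ~ group * label + Error(reviewer_id), data = long)
  want <- oracle_mixed_anova(long)
  s <- summary(fit)
  btw <- s[["Error: reviewer_id"]][[1]]
  expect_equal(btw["group", "F value"], want$F[want$effect == "between"])

  # random balanced panels: full agreement, implementation vs oracle
  for (seed in c(101, 102, 103)) {
    pan <- random_balanced_panel(12, seed)
    got <- mixed_anova_accuracy(pan)
    long <- do.call(rbind, lapply(c("no_mask", "mask"), function(cond)
      do.call(rbind, lapply(c("SAME", "DIFFERENT"), function(lab) {
        cells <- facebias:::reviewer_cells(pan, cond, lab)
        data.frame(group = cond, label = lab,
                   reviewer_id = cells$reviewer_id, acc = cells$accuracy)
      }))))
    want <- oracle_mixed_anova(long)
    expect_equal(got$F, want$F, tolerance = 1e-10)
    expect_equal(got$df_den, want$df_den)
    expect_equal(got$df_den[1], n_reviewers(pan, "no_mask") +
                   n_reviewers(pan, "mask") - 2)
  }
})

test_that("label-invariant identical groups give vanishing F", {
  ratings <- rep(c(2, -2), 6)
  pan <- reviewer_panel(rbind(
    tiny_panel(list(a1 = ratings, a2 = ratings * c(-1, rep(1, 11))),
               condition = "no_mask")$records,
    tiny_panel(list(b1 = ratings, b2 = ratings * c(-1, rep(1, 11))),
               condition = "mask")$records))
  out <- mixed_anova_accuracy(pan)
  expect_equal(out$F[out$effect == "between"], 0, tolerance = 1e-12)
})

test_that("one-way confidence ANOVA reduces to t^2 with two groups", {
  pan <- sim_filtered(n_per_condition = 30,
                      conditions = c("no_mask", "mask"), seed = 61)
  a <- oneway_anova_abs_confidence(pan)
  mu <- lapply(c("no_mask", "mask"), function(cond) {
    rec <- pan$records[pan$records$condition == cond, ]
    as.numeric(tapply(abs(rec$rating), rec$reviewer_id, mean))
  })
  tt <- stats::t.test(mu[[1]], mu[[2]], var.equal = TRUE)
  expect_equal(a$F, unname(tt$statistic)^2, tolerance = 1e-10)
  expect_equal(a$p, tt$p.value, tolerance = 1e-10)
  expect_equal(a$df_den, length(mu[[1]]) + length(mu[[2]]) - 2)
})

test_that("post-hoc confidence comparisons behave sanely", {
  pan <- sim_filtered(n_per_condition = 120,
                      conditions = c("control", "mask"),
                      d_prime = c(control = 2.6, mask = 0.2),
                      delta_c = c(control = 0, mask = 0), seed = 71)
  ph <- pairwise_posthoc(pan, c("control", "mask"))
  expect_lt(ph$p, 0.001)  # extreme separation in confidence usage
  expect_equal(ph$kind, "two_sample")
})

test_that("per-pair tests flag planted shifts and respect degeneracy", {
  pan <- sim_filtered(n_per_condition = 400, conditions = "mask",
                      d_prime = c(mask = 0.9), delta_c = c(mask = 1.2),
                      seed = 83)
  n_sig <- count_significant_pairs(pan, "mask")
  expect_gte(n_sig, 8)  # large coupling: most of the 12 pairs shift
  tt <- per_pair_shift_test(pan, "mask",
                            unique(pan$records$pair_id)[1])
  expect_s3_class(tt, "fb_ttest")
  # identical label groups -> t = 0, degenerate
  flat <- sim_filtered(n_per_condition = 20, conditions = "mask", seed = 2)
  flat$records$rating[flat$records$pair_id == "gfmt_01"] <- 2L
  t0 <- per_pair_shift_test(flat, "mask", "gfmt_01")
  expect_equal(t0$t, 0)
  expect_true(t0$degenerate)
  # a pair never shown under both labels is not testable
  solo <- tiny_panel(list(a = rep(2, 12), b = rep(1, 12)))
  expect_error(per_pair_shift_test(solo, "no_mask", "gfmt_01"),
               class = "facebias_degenerate")
  expect_equal(count_significant_pairs(solo, "no_mask"), 0L)
})

test_that("pair-level paired test equals a one-sample t on differences", {
  set.seed(3)
  a <- rnorm(12, 0.5, 0.4); b <- rnorm(12, 0.2, 0.4)
  got <- pairlevel_paired_test(a, b)
  ref <- stats::t.test(a - b)
  expect_equal(got$t, unname(ref$statistic))
  expect_equal(got$p, ref$p.value)
  expect_equal(got$df, 11)
  same <- pairlevel_paired_test(a, a)
  expect_equal(same$t, 0)
  const <- pairlevel_paired_test(a, a - 0.3)
  expect_true(const$degenerate)
  expect_true(is.infinite(const$t))
  expect_error(pairlevel_paired_test(a, a[1:5]),
               class = "facebias_validation")
})

test_that("trust proportions count agreement and recover simulated rates", {
  trust <- data.frame(reviewer_id = sprintf("r%d", 1:4),
                      condition = "control", phase = "pre",
                      agrees = c(TRUE, TRUE, TRUE, FALSE))
  expect_equal(trust_proportion(trust, "control", "pre"), 0.75)
  expect_error(trust_proportion(trust, "mask", "pre"),
               class = "facebias_empty")
  cfg <- simulation_config(n_per_condition = 600, conditions = "alg95",
                           seed = 19)
  tr <- simulate_trust(cfg, p_pre = c(alg95 = 0.69),
                       p_post = c(alg95 = 0.53))
  # binomial sd at n = 600 is about 0.02; allow 3 sd
  expect_lt(abs(trust_proportion(tr, "alg95", "pre") - 0.69), 0.06)
  expect_lt(abs(trust_proportion(tr, "alg95", "post") - 0.53), 0.06)
  expect_lt(abs(trust_proportion(tr, "alg95", "pre") -
                  trust_proportion(tr, "alg95", "post") - 0.16), 0.09)
})
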