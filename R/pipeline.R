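#' Configuration for an end-to-end pipeline run
#'
#' @param input either a [simulation_config()] (simulate a panel) or a file
#'   path to task data readable by [read_panel()].
#' @param trust optional trust data: a data.frame, or a file path for
#'   [read_trust()].
#' @param dialect [panel_dialect()] used when `input` is a path.
#' @param theta decision threshold for the summary tables (must belong to
#'   `theta_grid`).
#' @param theta_grid threshold sweep for ROC and band geometry.
#' @param B bootstrap replicates for all intervals and shift tests.
#' @param seed master seed; every stochastic stage derives its own stream
#'   from it via [derive_seed()].
#' @param out_dir optional directory; when given, all tables and a JSON
#'   report are written there.
#' @param verbose emit progress messages.
#' @return list of class `run_config`.
#' @export
run_config <- function(input, trust = NULL, dialect = panel_dialect(),
                       theta = 0.5, theta_grid = fb_theta_grid, B = 10000,
                       seed = 1L, out_dir = NULL, verbose = FALSE) {
  if (!theta %in% theta_grid)
    fb_stop("theta must belong to theta_grid", class = "facebias_config")
  structure(list(input = input, trust = trust, dialect = dialect,
                 theta = theta, theta_grid = theta_grid, B = as.integer(B),
                 seed = as.integer(seed), out_dir = out_dir,
                 verbose = isTRUE(verbose)),
            class = "run_config")
}

boot_ci_cols <- function(b) c(b$estimate, b$ci_low, b$ci_high)

#' Condition x label summary table
#'
#' The machine twin of the studies' performance tables: one row per
#' condition x decision label with reviewer count, percent correct, FPR,
#' TPR, d' and c, each with a percentile bootstrap 95% CI over reviewers.
#'
#' @inheritParams condition_rates
#' @param B,seed bootstrap replicates and master seed (per-cell streams are
#'   derived from the seed, condition, label and metric).
#' @return data.frame, one row per condition x label.
#' @export
summary_table <- function(panel, theta = 0.5, B = 10000, seed = 1L) {
  rows <- list()
  for (cond in panel_conditions(panel)) {
    labels <- if (cond == "control") "NONE" else c("DIFFERENT", "SAME")
    for (lab in labels) {
      r <- condition_rates(panel, cond, lab, theta)
      cell <- function(metric) boot_ci_cols(bootstrap_metric(
        panel, cond, lab, metric, theta, B,
        derive_seed(seed, cond, lab, if (is.character(metric)) metric else "f")))
      pc <- cell("accuracy"); fp <- cell("fpr"); tp <- cell("tpr")
      dp <- cell("dprime");   cr <- cell("criterion")
      rows[[length(rows) + 1L]] <- data.frame(
        condition = cond, algorithm_decision = lab, n = r$n_reviewers,
        pct_correct = pc[1], pct_correct_lo = pc[2], pct_correct_hi = pc[3],
        fpr = fp[1], fpr_lo = fp[2], fpr_hi = fp[3],
        tpr = tp[1], tpr_lo = tp[2], tpr_hi = tp[3],
        d_prime = dp[1], d_prime_lo = dp[2], d_prime_hi = dp[3],
        c = cr[1], c_lo = cr[2], c_hi = cr[3], stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

#' Label-shift table across conditions
#'
#' One row per labelled condition x metric (`c`, `tpr`, `fpr`): the
#' label-induced shift with bootstrap CI, doubled-tail p and a
#' significance flag — the machine twin of the cross-condition shift
#' figure.
#'
#' @inheritParams summary_table
#' @return data.frame.
#' @export
shift_table <- function(panel, theta = 0.5, B = 10000, seed = 1L) {
  conds <- setdiff(panel_conditions(panel), "control")
  rows <- lapply(conds, function(cond) {
    do.call(rbind, lapply(c("c", "tpr", "fpr"), function(met) {
      b <- shift_test(panel, cond, met, theta, B,
                      derive_seed(seed, cond, "shift", met))
      data.frame(condition = cond, metric = met, estimate = b$estimate,
                 ci_low = b$ci_low, ci_high = b$ci_high, p = b$p_two_sided,
                 significant = b$significant, n = b$n,
                 stringsAsFactors = FALSE)
    }))
  })
  do.call(rbind, rows)
}

#' Run the full analysis pipeline
#'
#' Executes the whole chain: obtain a panel (simulate from a
#' [simulation_config()] or ingest a task-data file), apply the
#' attention-check exclusion, build the summary and shift tables, ROC and
#' isobias band geometry for every labelled condition, ANOVAs (mixed on
#' accuracy when at least two labelled conditions are present; one-way on
#' absolute confidence when at least two conditions are present), per-pair
#' significance counts, and trust proportions when trust data are
#' supplied. All artifacts are reproducible from `(input, config)` alone;
#' with a fixed master seed two runs are identical.
#'
#' @param config a [run_config()].
#' @return object of class `study_report`: list with `summary`, `shifts`,
#'   `roc`, `bands`, `anova_accuracy`, `anova_confidence`,
#'   `significant_pairs`, `pairlevel`, `trust`, `excluded`, `provenance`.
#' @export
#' @examples
#' cfg <- run_config(simulation_config(n_per_condition = 15, seed = 2),
#'                   B = 1000, seed = 7)
#' rep <- run_pipeline(cfg)
#' rep$shifts
run_pipeline <- function(config) {
  if (!inherits(config, "run_config"))
    fb_stop("config must be a run_config", class = "facebias_config")
  say <- function(...) if (config$verbose) message(sprintf(...))
  log <- character()
  note <- function(...) {
    log <<- c(log, sprintf(...)); say("%s", utils::tail(log, 1))
  }

  panel <- if (inherits(config$input, "simulation_config")) {
    note("stage simulate: seed %d", config$input$seed)
    simulate_panel(config$input)
  } else {
    note("stage ingest: %s", config$input)
    read_panel(config$input, config$dialect)
  }
  fl <- attention_filter(panel, theta = config$theta)
  note("stage filter: excluded %d of %d reviewers", length(fl$excluded),
       n_reviewers(panel))
  panel <- fl$panel

  note("stage summary: B=%d master seed %d", config$B, config$seed)
  summ <- summary_table(panel, config$theta, config$B, config$seed)
  shifts <- shift_table(panel, config$theta, config$B, config$seed)

  labelled <- setdiff(panel_conditions(panel), "control")
  roc <- do.call(rbind, unlist(lapply(panel_conditions(panel), function(cond) {
    labs <- if (cond == "control") "NONE" else c("SAME", "DIFFERENT")
    lapply(labs, function(lab) {
      cu <- roc_curve(panel, cond, lab, config$theta_grid)
      data.frame(condition = cond, algorithm_decision = lab,
                 theta = cu$theta, fpr = cu$fpr, tpr = cu$tpr)
    })
  }), recursive = FALSE))
  bands <- do.call(rbind, lapply(labelled, function(cond)
    band_geometry(panel, cond, config$theta_grid)))

  anova_acc <- if (length(labelled) >= 2)
    mixed_anova_accuracy(panel, labelled, config$theta) else NULL
  anova_conf <- if (length(panel_conditions(panel)) >= 2)
    oneway_anova_abs_confidence(panel) else NULL
  sig_pairs <- vapply(labelled, function(cond)
    count_significant_pairs(panel, cond), integer(1))
  pairlevel <- if (length(labelled) == 2) {
    sa <- pair_shifts(panel, labelled[1]); sb <- pair_shifts(panel, labelled[2])
    common <- intersect(names(sa), names(sb))
    pairlevel_paired_test(sa[common], sb[common])
  } else NULL

  trust <- NULL
  if (!is.null(config$trust)) {
    td <- if (is.character(config$trust)) read_trust(config$trust) else
      config$trust
    combos <- unique(td[, c("condition", "phase")])
    trust <- data.frame(
      condition = combos$condition, phase = combos$phase,
      proportion = mapply(function(cc, ph) trust_proportion(td, cc, ph),
                          combos$condition, combos$phase),
      stringsAsFactors = FALSE)
    rownames(trust) <- NULL
  }

  report <- structure(list(
    summary = summ, shifts = shifts, roc = roc, bands = bands,
    anova_accuracy = anova_acc, anova_confidence = anova_conf,
    significant_pairs = sig_pairs, pairlevel = pairlevel, trust = trust,
    excluded = fl$excluded,
    provenance = list(seed = config$seed, B = config$B,
                      theta = config$theta,
                      theta_grid = config$theta_grid,
                      input = if (inherits(config$input, "simulation_config"))
                        unclass(config$input[setdiff(names(config$input),
                                                     "roster")])
                      else config$input,
                      n_excluded = length(fl$excluded),
                      package_version = as.character(
                        utils::packageVersion("facebias"))),
    log = log), class = "study_report")

  if (!is.null(config$out_dir)) write_report(report, config$out_dir)
  report
}

write_report <- function(report, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  w <- function(df, name) if (!is.null(df))
    utils::write.csv(df, file.path(out_dir, name), row.names = FALSE)
  w(report$summary, "summary.csv")
  w(report$shifts, "shifts.csv")
  w(report$roc, "roc.csv")
  w(report$bands, "bands.csv")
  writeLines(report$log, file.path(out_dir, "run.log"))
  json <- report[setdiff(names(report), c("roc", "bands", "log"))]
  jsonlite::write_json(json, file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, digits = 10, pretty = TRUE,
                       force = TRUE)
  invisible(out_dir)
}

#' @export
print.study_report <- function(x, ...) {
  cat("<study_report>\n")
  cat(sprintf("  %d summary rows, %d shift rows, %d reviewers excluded\n",
              nrow(x$summary), nrow(x$shifts), x$provenance$n_excluded))
  inv <- x$shifts[x$shifts$metric == "c", c("condition", "estimate", "p")]
  if (nrow(inv)) {
    cat("  criterion shifts (delta_c):\n")
    for (i in seq_len(nrow(inv)))
      cat(sprintf("    %-8s %.3f (p = %.4g)\n", inv$condition[i],
                  inv$estimate[i], inv$p[i]))
  }
  invisible(x)
}

fmt_ci <- function(est, lo, hi)
  sprintf("%.2f (%.2f-%.2f)", round2(est), round2(lo), round2(hi))

#' Format a report as a publication-style study table
#'
#' Renders the summary table of a [run_pipeline()] report in the layout of
#' the studies' printed tables (values at 2 decimal places with 95% CIs),
#' selecting the conditions of the requested study. A requested condition
#' absent from the report yields an explicit gap row rather than a silent
#' omission.
#'
#' @param report a `study_report`.
#' @param which `"study1"` (control / no-mask / mask) or `"study2"`
#'   (65-algorithm / 95-algorithm / control).
#' @return data.frame of formatted strings.
#' @export
make_table <- function(report, which = c("study1", "study2")) {
  which <- match.arg(which)
  conds <- if (which == "study1") c("control", "no_mask", "mask") else
    c("alg65", "alg95", "control")
  mask_of <- c(control = "No Mask", no_mask = "No Mask", mask = "Mask",
               alg65 = "Mask", alg95 = "Mask")
  s <- report$summary
  rows <- lapply(conds, function(cond) {
    sub <- s[s$condition == cond, , drop = FALSE]
    if (nrow(sub) == 0)
      return(data.frame(Condition = cond, Mask = mask_of[[cond]],
                        `Algorithm Decision` = "<missing>", n = NA_integer_,
                        `% Correct (95% CI)` = NA, `FPR (95% CI)` = NA,
                        `TPR (95% CI)` = NA, `d' (95% CI)` = NA,
                        `c (95% CI)` = NA, check.names = FALSE))
    data.frame(
      Condition = cond, Mask = mask_of[[cond]],
      `Algorithm Decision` = sub$algorithm_decision, n = sub$n,
      `% Correct (95% CI)` = fmt_ci(sub$pct_correct, sub$pct_correct_lo,
                                    sub$pct_correct_hi),
      `FPR (95% CI)` = fmt_ci(sub$fpr, sub$fpr_lo, sub$fpr_hi),
      `TPR (95% CI)` = fmt_ci(sub$tpr, sub$tpr_lo, sub$tpr_hi),
      `d' (95% CI)` = fmt_ci(sub$d_prime, sub$d_prime_lo, sub$d_prime_hi),
      `c (95% CI)` = fmt_ci(sub$c, sub$c_lo, sub$c_hi),
      check.names = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
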