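# Shared fixtures and independent oracles, all built in code.

# hand-buildable panel: one record per row of the supplied ratings, for a
# single condition; ratings is a list: reviewer_id -> numeric vector over
# the scored roster (length 12), attention = c(mated, nonmated) ratings
tiny_panel <- function(ratings, condition = "no_mask",
                       attention = c(3, -3), study = 1L) {
  roster <- default_roster()
  scored <- roster[!roster$is_attention, ]
  att <- roster[roster$is_attention, ]
  labs <- facebias:::variant_labels(roster)$A
  rows <- lapply(names(ratings), function(rid) {
    stopifnot(length(ratings[[rid]]) == 12)
    lab <- if (condition == "control") rep("NONE", 12) else
      unname(labs[scored$pair_id])
    rbind(
      data.frame(study = study, condition = condition, variant = "A",
                 reviewer_id = rid, pair_id = scored$pair_id,
                 source = scored$source, mated = scored$mated,
                 algorithm_decision = lab,
                 rating = as.integer(ratings[[rid]]), is_attention = FALSE,
                 stringsAsFactors = FALSE),
      data.frame(study = study, condition = condition, variant = "A",
                 reviewer_id = rid, pair_id = att$pair_id,
                 source = att$source, mated = att$mated,
                 algorithm_decision = if (condition == "control") "NONE" else
                   c("SAME", "DIFFERENT"),
                 rating = as.integer(attention), is_attention = TRUE,
                 stringsAsFactors = FALSE))
  })
  reviewer_panel(do.call(rbind, rows), roster)
}

sim_filtered <- function(...) {
  attention_filter(simulate_panel(simulation_config(...)))$panel
}

# brute-force per-trial recount of condition-level rates: loops over raw
# records, independent of reviewer_cells/tapply machinery
oracle_rates <- function(panel, condition, decision_label, theta = 0.5) {
  rec <- panel$records
  rec <- rec[rec$condition == condition & !rec$is_attention &
               rec$algorithm_decision == decision_label, ]
  revs <- unique(rec$reviewer_id)
  tprs <- fprs <- numeric(0)
  for (r in revs) {
    h <- m <- fa <- nm <- 0
    for (i in which(rec$reviewer_id == r)) {
      same <- rec$rating[i] > theta
      if (rec$mated[i]) { m <- m + 1; if (same) h <- h + 1 }
      else { nm <- nm + 1; if (same) fa <- fa + 1 }
    }
    tprs <- c(tprs, h / m); fprs <- c(fprs, fa / nm)
  }
  list(tpr = mean(tprs), fpr = mean(fprs))
}

# hand sums-of-squares oracle for the balanced two-group x two-label
# split-plot ANOVA; long has columns group, label, reviewer_id, acc
oracle_mixed_anova <- function(long) {
  g <- mean(long$acc)
  groups <- sort(unique(as.character(long$group)))
  labels <- sort(unique(as.character(long$label)))
  grp_mean <- sapply(groups, function(a) mean(long$acc[long$group == a]))
  lab_mean <- sapply(labels, function(b) mean(long$acc[long$label == b]))
  grp_of <- sapply(split(as.character(long$group), long$reviewer_id), `[`, 1)
  subj_mean <- sapply(split(long$acc, long$reviewer_id), mean)
  n_g <- sapply(groups, function(a) sum(grp_of == a))
  N <- length(subj_mean)
  ss_a <- 2 * sum(n_g * (grp_mean - g)^2)
  ss_s <- 2 * sum((subj_mean - grp_mean[grp_of])^2)
  ss_b <- N * sum((lab_mean - g)^2)
  ss_ab <- 0
  for (a in groups) for (b in labels) {
    cell <- mean(long$acc[long$group == a & long$label == b])
    ss_ab <- ss_ab + n_g[[a]] *
      (cell - grp_mean[[a]] - lab_mean[[b]] + g)^2
  }
  ss_e <- sum((long$acc - g)^2) - ss_a - ss_s - ss_b - ss_ab
  df_s <- N - length(groups)
  data.frame(
    effect = c("between", "within", "interaction"),
    F = c((ss_a / (length(groups) - 1)) / (ss_s / df_s),
          (ss_b / (length(labels) - 1)) / (ss_e / df_s),
          (ss_ab / ((length(groups) - 1) * (length(labels) - 1))) /
            (ss_e / df_s)),
    df_den = c(df_s, df_s, df_s))
}

# random balanced two-condition panel for ANOVA property tests
random_balanced_panel <- function(n_per, seed) {
  sim_filtered(n_per_condition = n_per, conditions = c("no_mask", "mask"),
               d_prime = c(no_mask = runif(1, 0.8, 2),
                           mask = runif(1, 0.5, 1.5)),
               delta_c = c(no_mask = runif(1, 0, 0.4),
                           mask = runif(1, 0, 0.6)),
               seed = seed)
}
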