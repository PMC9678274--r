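#' Default face-pair roster
#'
#' The task roster: 14 pairs, of which 12 are scored (8 GFMT-style and 4
#' MEDS-style, split 6 mated / 6 non-mated and balanced within source) and
#' 2 are celebrity attention checks (1 mated, 1 non-mated). The identifiers
#' are synthetic; the composition mirrors the tasks the generator emulates.
#'
#' @return data.frame with columns `pair_id`, `source`, `mated`,
#'   `is_attention`.
#' @export
default_roster <- function() {
  data.frame(
    pair_id = c(sprintf("gfmt_%02d", 1:8), sprintf("meds_%02d", 1:4),
                "celeb_01", "celeb_02"),
    source = c(rep("GFMT", 8), rep("MEDS", 4), rep("CELEBRITY", 2)),
    mated = c(rep(c(TRUE, FALSE), each = 4), rep(c(TRUE, FALSE), each = 2),
              TRUE, FALSE),
    is_attention = c(rep(FALSE, 12), TRUE, TRUE),
    stringsAsFactors = FALSE)
}

#' Configuration for the synthetic reviewer generator
#'
#' Parameters of the equal-variance Gaussian observer used to emulate
#' reviewer panels. Per condition the generator takes a sensitivity
#' `d_prime` and a label-coupling strength `delta_c`; defaults echo the
#' values measured in the two studies (no-mask d' about 1.7 with
#' delta_c 0.21; masked d' about 0.9 with delta_c 0.45 without accuracy
#' framing, 0.16 / 0.25 with the 65% / 95% framing; control d' about 1.55
#' with no labels).
#'
#' @param n_per_condition reviewers per condition: single count or named
#'   vector over `conditions`.
#' @param conditions condition codes to simulate.
#' @param d_prime named numeric, population sensitivity per condition.
#' @param delta_c named numeric, criterion-shift magnitude per condition
#'   (ignored for control).
#' @param base_offsets six strictly increasing offsets placing the rating
#'   criteria around each reviewer's own midpoint d'/2. The default
#'   spacing (0.4 latent-axis units between adjacent criteria) is
#'   calibrated so simulated panels reproduce the mean absolute
#'   similarity-confidence the studies report (about 1.9 of a possible 3).
#' @param sd_dprime between-reviewer sd of d' (draws truncated at 0).
#' @param sd_offset between-reviewer sd of a shared criterion offset.
#' @param attention_error_rate probability a reviewer is inattentive and
#'   answers both celebrity pairs with flipped sign.
#' @param study study number stamped on the records.
#' @param roster face-pair roster, see [default_roster()].
#' @param seed integer seed; the generator is fully deterministic given it.
#' @return list of class `simulation_config`.
#' @export
#' @examples
#' simulation_config(n_per_condition = 50, seed = 1)
simulation_config <- function(n_per_condition = 50,
                              conditions = c("control", "no_mask", "mask"),
                              d_prime = c(control = 1.55, no_mask = 1.7,
                                          mask = 0.9, alg65 = 0.95,
                                          alg95 = 1.0),
                              delta_c = c(control = 0, no_mask = 0.21,
                                          mask = 0.45, alg65 = 0.16,
                                          alg95 = 0.25),
                              base_offsets = c(-1.0, -0.6, -0.2,
                                               0.2, 0.6, 1.0),
                              sd_dprime = 0.3, sd_offset = 0.2,
                              attention_error_rate = 0,
                              study = 1L, roster = default_roster(),
                              seed = 1L) {
  conditions <- match.arg(conditions, fb_conditions, several.ok = TRUE)
  if (length(n_per_condition) == 1L)
    n_per_condition <- stats::setNames(rep(n_per_condition,
                                           length(conditions)), conditions)
  if (!all(conditions %in% names(n_per_condition)))
    fb_stop("n_per_condition must cover every condition",
            class = "facebias_config")
  if (length(base_offsets) != 6 || is.unsorted(base_offsets, strictly = TRUE))
    fb_stop("base_offsets must be 6 strictly increasing values",
            class = "facebias_config")
  if (!all(conditions %in% names(d_prime)) ||
      !all(conditions %in% names(delta_c)))
    fb_stop("d_prime and delta_c must name every condition",
            class = "facebias_config")
  if (any(d_prime < 0))
    fb_stop("d_prime must be >= 0", class = "facebias_config")
  if (attention_error_rate < 0 || attention_error_rate >= 1)
    fb_stop("attention_error_rate must lie in [0, 1)",
            class = "facebias_config")
  if (sum(roster$is_attention) != 2 ||
      sum(roster$mated & !roster$is_attention) !=
      sum(!roster$mated & !roster$is_attention))
    fb_stop("roster needs 2 attention pairs and a balanced scored split",
            class = "facebias_config")
  structure(list(n_per_condition = n_per_condition, conditions = conditions,
                 d_prime = d_prime, delta_c = delta_c,
                 base_offsets = base_offsets, sd_dprime = sd_dprime,
                 sd_offset = sd_offset,
                 attention_error_rate = attention_error_rate,
                 study = as.integer(study), roster = roster,
                 seed = as.integer(seed)),
            class = "simulation_config")
}

# Label assignment per variant: within each mated class, variant A shows
# SAME on the odd-position pairs, variant B on the even-position pairs, so
# every reviewer sees 3 mated + 3 non-mated trials under each label.
variant_labels <- function(roster) {
  scored <- roster[!roster$is_attention, ]
  lab <- function(flip) {
    out <- character(nrow(scored))
    for (m in c(TRUE, FALSE)) {
      idx <- which(scored$mated == m)
      odd <- seq_along(idx) %% 2 == 1
      out[idx[odd]]  <- if (flip) "DIFFERENT" else "SAME"
      out[idx[!odd]] <- if (flip) "SAME" else "DIFFERENT"
    }
    stats::setNames(out, scored$pair_id)
  }
  list(A = lab(FALSE), B = lab(TRUE))
}

#' Simulate a reviewer panel
#'
#' Draws panels from an equal-variance Gaussian observer. Each reviewer r
#' gets a sensitivity `d_r` (normal around the condition d', sd
#' `sd_dprime`, truncated at 0) and a criterion offset `o_r` (normal, sd
#' `sd_offset`). The six rating criteria sit at `d_r/2 + base_offsets +
#' o_r`; when the trial carries a DIFFERENT label all six shift by
#' `+delta_c/2`, and by `-delta_c/2` for SAME, so the injected criterion
#' shift equals `delta_c` at every threshold while sensitivity is
#' untouched. Latent familiarity is `N(d_r, 1)` for mated pairs and
#' `N(0, 1)` for non-mated; the rating is the number of criteria below the
#' draw, minus 3. Attention pairs are answered correctly (+3 mated /
#' -3 non-mated) unless the reviewer is inattentive (probability
#' `attention_error_rate`), in which case both attention ratings are
#' sign-flipped.
#'
#' @param config a [simulation_config()].
#' @return a [reviewer_panel()]; fully deterministic given `config$seed`.
#' @export
#' @examples
#' pan <- simulate_panel(simulation_config(n_per_condition = 10, seed = 9))
#' table(pan$records$condition)
simulate_panel <- function(config) {
  if (!inherits(config, "simulation_config"))
    fb_stop("config must be a simulation_config", class = "facebias_config")
  labs <- variant_labels(config$roster)
  scored <- config$roster[!config$roster$is_attention, ]
  att <- config$roster[config$roster$is_attention, ]
  with_seed(config$seed, {
    blocks <- lapply(config$conditions, function(cond) {
      n <- config$n_per_condition[[cond]]
      d0 <- config$d_prime[[cond]]
      dc <- if (cond == "control") 0 else config$delta_c[[cond]]
      d_r <- pmax(0, stats::rnorm(n, d0, config$sd_dprime))
      o_r <- stats::rnorm(n, 0, config$sd_offset)
      variant <- sample(c("A", "B"), n, replace = TRUE)
      inattentive <- stats::runif(n) < config$attention_error_rate
      rid <- sprintf("%s_r%04d", cond, seq_len(n))

      ns <- nrow(scored)
      rev_idx <- rep(seq_len(n), each = ns)
      pair <- rep(scored$pair_id, n)
      mated <- rep(scored$mated, n)
      label <- if (cond == "control") rep("NONE", n * ns) else
        unlist(lapply(variant, function(v) labs[[v]][scored$pair_id]),
               use.names = FALSE)
      shift <- ifelse(label == "DIFFERENT", dc / 2,
                      ifelse(label == "SAME", -dc / 2, 0))
      x <- stats::rnorm(n * ns, mean = ifelse(mated, d_r[rev_idx], 0), sd = 1)
      base <- d_r[rev_idx] / 2 + o_r[rev_idx] + shift
      rating <- integer(n * ns)
      for (k in 1:6) rating <- rating + (x > base + config$base_offsets[k])
      rating <- rating - 3L

      att_rating <- ifelse(rep(att$mated, n), 3L, -3L) *
        ifelse(rep(inattentive, each = nrow(att)), -1L, 1L)
      rec_scored <- data.frame(
        study = config$study, condition = cond,
        variant = variant[rev_idx], reviewer_id = rid[rev_idx],
        pair_id = pair, source = rep(scored$source, n), mated = mated,
        algorithm_decision = label, rating = as.integer(rating),
        is_attention = FALSE, stringsAsFactors = FALSE)
      rec_att <- data.frame(
        study = config$study, condition = cond,
        variant = rep(variant, each = nrow(att)),
        reviewer_id = rep(rid, each = nrow(att)),
        pair_id = rep(att$pair_id, n), source = rep(att$source, n),
        mated = rep(att$mated, n),
        algorithm_decision = if (cond == "control") "NONE" else
          rep(c("SAME", "DIFFERENT"), n),
        rating = as.integer(att_rating), is_attention = TRUE,
        stringsAsFactors = FALSE)
      rbind(rec_scored, rec_att)
    })
    reviewer_panel(do.call(rbind, blocks), config$roster)
  })
}

#' Simulate trust-question records
#'
#' Independent Bernoulli draws per reviewer and phase of the probability
#' that a reviewer says they would trust the algorithm (or, in control,
#' another person) to make identity decisions.
#'
#' @param config a [simulation_config()] (supplies conditions, counts and
#'   the seed).
#' @param p_pre,p_post named probabilities per condition; `p_post = NULL`
#'   simulates a pre-task question only (study 1 design).
#' @return data.frame of trust records (`reviewer_id`, `condition`,
#'   `phase`, `agrees`).
#' @export
#' @examples
#' cfg <- simulation_config(n_per_condition = 100, seed = 4)
#' tr <- simulate_trust(cfg, p_pre = c(control = 0.77, no_mask = 0.69,
#'                                     mask = 0.69))
#' trust_proportion(tr, "control", "pre")
simulate_trust <- function(config, p_pre, p_post = NULL) {
  if (!all(config$conditions %in% names(p_pre)))
    fb_stop("p_pre must name every condition", class = "facebias_config")
  if (any(p_pre < 0 | p_pre > 1) || any(p_post < 0 | p_post > 1))
    fb_stop("trust probabilities must lie in [0, 1]",
            class = "facebias_config")
  with_seed(derive_seed(config$seed, "trust"), {
    out <- lapply(config$conditions, function(cond) {
      n <- config$n_per_condition[[cond]]
      rid <- sprintf("%s_r%04d", cond, seq_len(n))
      pre <- data.frame(reviewer_id = rid, condition = cond, phase = "pre",
                        agrees = stats::runif(n) < p_pre[[cond]],
                        stringsAsFactors = FALSE)
      if (is.null(p_post)) return(pre)
      rbind(pre, data.frame(reviewer_id = rid, condition = cond,
                            phase = "post",
                            agrees = stats::runif(n) < p_post[[cond]],
                            stringsAsFactors = FALSE))
    })
    do.call(rbind, out)
  })
}
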