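# Signal-detection scoring of same-different trial tables: per-condition
# d-prime, exclusion rules, integration scores and the group-level fusion
# classification from the four planned paired comparisons.

#' Sensitivity (d-prime) from hit and false-alarm counts
#'
#' "Different" is the signal response: hits are "different" responses on
#' truly different trials, false alarms "different" responses on truly same
#' trials; `d' = z(hit rate) - z(false-alarm rate)`. The log-linear
#' correction (default) adds 0.5 to each count and 1 to each denominator
#' before forming rates, keeping d-prime finite at perfect or zero rates.
#'
#' @param n_hits,n_fas Hit and false-alarm counts.
#' @param n_signal,n_noise Numbers of "different" (signal) and "same" (noise)
#'   trials.
#' @param correction `"loglinear"` (default) or `"none"`.
#' @return d-prime (numeric scalar).
#' @export
compute_dprime <- function(n_hits, n_fas, n_signal, n_noise,
                           correction = c("loglinear", "none")) {
  correction <- match.arg(correction)
  if (n_signal <= 0 || n_noise <= 0) {
    sf_data_error("`n_signal` and `n_noise` must be positive")
  }
  if (n_hits < 0 || n_fas < 0 || n_hits > n_signal || n_fas > n_noise) {
    sf_data_error("counts must satisfy 0 <= n_hits <= n_signal, 0 <= n_fas <= n_noise")
  }
  if (correction == "loglinear") {
    h <- (n_hits + 0.5) / (n_signal + 1)
    f <- (n_fas + 0.5) / (n_noise + 1)
  } else {
    h <- n_hits / n_signal
    f <- n_fas / n_noise
  }
  stats::qnorm(h) - stats::qnorm(f)
}

#' Score one subject's trials into per-condition d-primes
#'
#' @param trials A data.frame with columns `condition`, `truth`
#'   (`"same"`/`"different"`) and `response` (same coding); additional
#'   columns (`subject_id`, `group`, `trial`) are carried through as
#'   attributes when constant.
#' @param correction Passed to [compute_dprime()].
#' @param require Conditions that must be present; defaults to the five
#'   analysed conditions (the texture-reversed condition `T-` is scored when
#'   present but flagged out of analysis).
#' @return A `condition_scores` data.frame with one row per condition:
#'   `condition`, `n_signal`, `n_noise`, `n_hits`, `n_fas`, `dprime`,
#'   `analyzed`.
#' @export
score_subject <- function(trials, correction = "loglinear",
                          require = ANALYZED_CONDITIONS) {
  need <- c("condition", "truth", "response")
  if (!all(need %in% names(trials))) {
    sf_data_error(paste("trial table must have columns:",
                        paste(need, collapse = ", ")))
  }
  bad_resp <- !trials$response %in% c("same", "different")
  if (any(bad_resp)) {
    sf_data_error(sprintf("invalid response values in rows: %s",
                          paste(utils::head(which(bad_resp), 5), collapse = ", ")))
  }
  present <- unique(as.character(trials$condition))
  missing <- setdiff(require, present)
  if (length(missing)) {
    sf_data_error(paste("incomplete data; missing condition(s):",
                        paste(missing, collapse = ", ")))
  }
  conds <- intersect(CONDITIONS, present)
  rows <- lapply(conds, function(cc) {
    tr <- trials[trials$condition == cc, ]
    sig <- tr$truth == "different"
    data.frame(
      condition = cc,
      n_signal = sum(sig), n_noise = sum(!sig),
      n_hits = sum(sig & tr$response == "different"),
      n_fas = sum(!sig & tr$response == "different")
    )
  })
  out <- do.call(rbind, rows)
  out$dprime <- mapply(compute_dprime, out$n_hits, out$n_fas,
                       out$n_signal, out$n_noise,
                       MoreArgs = list(correction = correction))
  out$analyzed <- out$condition %in% ANALYZED_CONDITIONS
  class(out) <- c("condition_scores", class(out))
  out
}

#' Score a multi-subject trial table into wide per-subject d-primes
#'
#' @param trials Data.frame with columns `subject_id`, `group`, `condition`,
#'   `truth`, `response`.
#' @inheritParams score_subject
#' @return Data.frame with one row per subject: `subject_id`, `group`, and
#'   one d-prime column per condition present.
#' @export
score_cohort <- function(trials, correction = "loglinear",
                         require = ANALYZED_CONDITIONS) {
  if (!all(c("subject_id", "group") %in% names(trials))) {
    sf_data_error("trial table must have `subject_id` and `group` columns")
  }
  ids <- unique(trials$subject_id)
  rows <- lapply(ids, function(id) {
    tr <- trials[trials$subject_id == id, ]
    sc <- score_subject(tr, correction = correction, require = require)
    w <- as.data.frame(as.list(stats::setNames(sc$dprime, sc$condition)),
                       check.names = FALSE)
    cbind(data.frame(subject_id = id, group = tr$group[1],
                     stringsAsFactors = FALSE), w)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Apply the single-cue exclusion rule
#'
#' Subjects at or below chance (d-prime <= 0) on any of the single-cue
#' conditions `T+`, `D+` or `D-` are excluded; a d-prime of exactly 0 is
#' excluded. Combined-cue performance never triggers exclusion.
#'
#' @param scores Wide per-subject score table from [score_cohort()].
#' @return List with `retained` (score rows kept) and `excluded`
#'   (data.frame `subject_id`, `reason`).
#' @export
apply_exclusions <- function(scores) {
  single <- c("T+", "D+", "D-")
  if (!all(single %in% names(scores))) {
    sf_data_error("score table must contain single-cue conditions T+, D+, D-")
  }
  reasons <- apply(scores[single], 1, function(v) {
    bad <- single[v <= 0]
    if (length(bad)) paste0(bad, " <= 0", collapse = "; ") else NA_character_
  })
  keep <- is.na(reasons)
  list(
    retained = scores[keep, , drop = FALSE],
    excluded = data.frame(subject_id = scores$subject_id[!keep],
                          reason = reasons[!keep],
                          stringsAsFactors = FALSE)
  )
}

#' Congruent and incongruent integration scores
#'
#' Per subject: the congruent score is d'(T+D+) minus the better single cue
#' (max of T+ and D+); the incongruent score is d'(T+D-) minus the worse
#' single cue (min of T+ and D-). Positive congruent scores indicate a
#' precision gain from combining congruent cues; negative incongruent scores
#' indicate the cost of mandatorily fusing conflicting cues.
#'
#' @inheritParams apply_exclusions
#' @return Data.frame `subject_id`, `group` (if present), `congruent`,
#'   `incongruent`.
#' @export
integration_scores <- function(scores) {
  need <- c("T+", "D+", "D-", "T+D+", "T+D-")
  miss <- setdiff(need, names(scores))
  if (length(miss)) {
    sf_data_error(paste("missing condition(s) for integration scores:",
                        paste(miss, collapse = ", ")))
  }
  out <- data.frame(subject_id = scores$subject_id,
                    stringsAsFactors = FALSE)
  if ("group" %in% names(scores)) out$group <- scores$group
  out$congruent <- scores[["T+D+"]] - pmax(scores[["T+"]], scores[["D+"]])
  out$incongruent <- scores[["T+D-"]] - pmin(scores[["T+"]], scores[["D-"]])
  out
}

#' Single-cue difference scores
#'
#' Checks on the balance of single-cue reliabilities: the congruent
#' difference score d'(T+) - d'(D+) and the incongruent difference score
#' d'(T+) - d'(D-).
#'
#' @inheritParams apply_exclusions
#' @return Data.frame `subject_id`, `group` (if present), `congruent_diff`,
#'   `incongruent_diff`.
#' @export
cue_difference_scores <- function(scores) {
  need <- c("T+", "D+", "D-")
  miss <- setdiff(need, names(scores))
  if (length(miss)) {
    sf_data_error(paste("missing condition(s):", paste(miss, collapse = ", ")))
  }
  out <- data.frame(subject_id = scores$subject_id,
                    stringsAsFactors = FALSE)
  if ("group" %in% names(scores)) out$group <- scores$group
  out$congruent_diff <- scores[["T+"]] - scores[["D+"]]
  out$incongruent_diff <- scores[["T+"]] - scores[["D-"]]
  out
}

#' Classify a group's fusion pattern from planned paired comparisons
#'
#' Runs the four planned paired t-tests (T+D+ vs T+, T+D+ vs D+, T+D- vs T+,
#' T+D- vs D-) at level `alpha`. Congruent integration is declared only if
#' both congruent comparisons are significant with T+D+ greater than each
#' single cue; incongruent fusion only if both incongruent comparisons are
#' significant with T+D- smaller. The (congruent, incongruent) pattern maps
#' to: (yes, yes) mandatory fusion, (yes, no) selective fusion, (no, no) no
#' fusion, (no, yes) indeterminate.
#'
#' @param scores Wide per-subject score table for one group (>= 2 subjects).
#' @param alpha Two-sided significance level per comparison.
#' @return List with `pattern` (character), `congruent`/`incongruent`
#'   (logical) and `tests` (data.frame of the four comparisons).
#' @export
classify_fusion_pattern <- function(scores, alpha = 0.05) {
  if (nrow(scores) < 2) sf_stat_error("need at least 2 subjects to classify")
  comparisons <- list(
    c("T+D+", "T+"), c("T+D+", "D+"),
    c("T+D-", "T+"), c("T+D-", "D-")
  )
  tests <- do.call(rbind, lapply(comparisons, function(cp) {
    # exactly tied scores fall through paired_t's zero-difference case
    # (t = 0, p = 1): ties carry no evidence of integration
    tt <- paired_t(scores[[cp[1]]], scores[[cp[2]]])
    data.frame(combined = cp[1], single = cp[2], t = tt$t, df = tt$df,
               p = tt$p, mean_diff = tt$mean_diff,
               stringsAsFactors = FALSE)
  }))
  congruent <- all(tests$p[1:2] < alpha) && all(tests$mean_diff[1:2] > 0)
  incongruent <- all(tests$p[3:4] < alpha) && all(tests$mean_diff[3:4] < 0)
  pattern <- if (congruent && incongruent) "mandatory_fusion"
    else if (congruent) "selective_fusion"
    else if (incongruent) "indeterminate"
    else "no_fusion"
  list(pattern = pattern, congruent = congruent, incongruent = incongruent,
       tests = tests)
}
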