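# Synthetic cohorts: subject populations with known ground-truth fusion
# regimes, the blocked trial schedule, and end-to-end study simulation.

#' Specification of a synthetic two-group study
#'
#' Defaults mirror the study design being emulated: 16 subjects in an
#' ASD-like group simulated under selective fusion and 14 in a typical
#' group under mandatory fusion; 6 conditions x 30 trials presented in 18
#' blocks of 10 (5 + 5 trials of a condition pair per block); comparisons at
#' +/- 12.5 degrees around a 45-degree standard. Per-subject cue noise SDs
#' are lognormal (median 5 degrees, geometric SD 1.3), a population chosen so
#' that analytic single-cue sensitivities fall in the d' ~ 1.0-1.5 range
#' under the default criterion of half the slant step. A single lognormal
#' deviate is shared between the two cues per subject (`cue_correlation = 1`):
#' observers differ in overall precision while relative cue reliability stays
#' at the population median.
#'
#' @param n_per_group Named counts, e.g. `c(ASD = 16, TD = 14)`.
#' @param regime_by_group Named fusion regime per group.
#' @param sigma_median,sigma_gsd Median (degrees) and geometric SD of the
#'   lognormal cue-noise population (applies to both cues).
#' @param cue_correlation Correlation of the two cues' log-noise deviates in
#'   [0, 1].
#' @param trials_per_condition Trials per condition (divisible by 10 for the
#'   paired-block design).
#' @param standard,delta Standard slant and increment magnitude (degrees).
#' @param criterion,gate_k,lapse Observer decision parameters, shared by all
#'   subjects (see [observer_params()]).
#' @param seed Integer master seed; every subject gets an independent
#'   substream derived from it.
#' @return An object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_per_group = c(ASD = 16, TD = 14),
                        regime_by_group = c(ASD = "selective_fusion",
                                            TD = "mandatory_fusion"),
                        sigma_median = 5, sigma_gsd = 1.3,
                        cue_correlation = 1,
                        trials_per_condition = 30,
                        standard = 45, delta = 12.5,
                        criterion = 6.25, gate_k = 2, lapse = 0,
                        seed = 1L) {
  if (is.null(names(n_per_group)) || any(!nzchar(names(n_per_group)))) {
    sf_spec_error("`n_per_group` must be a named vector of group sizes")
  }
  if (any(n_per_group < 1)) sf_spec_error("group sizes must be positive")
  miss <- setdiff(names(n_per_group), names(regime_by_group))
  if (length(miss)) {
    sf_spec_error(paste("no regime given for group(s):",
                        paste(miss, collapse = ", ")))
  }
  bad <- setdiff(unlist(regime_by_group), REGIMES)
  if (length(bad)) {
    sf_spec_error(paste("unknown regime(s):", paste(bad, collapse = ", ")))
  }
  check_number(sigma_median, "sigma_median", lower = 1e-9)
  check_number(sigma_gsd, "sigma_gsd", lower = 1)
  check_number(cue_correlation, "cue_correlation", lower = 0, upper = 1)
  check_number(trials_per_condition, "trials_per_condition", lower = 2)
  check_number(seed, "seed")
  structure(
    list(n_per_group = n_per_group, regime_by_group = regime_by_group,
         sigma_median = sigma_median, sigma_gsd = sigma_gsd,
         cue_correlation = cue_correlation,
         trials_per_condition = trials_per_condition,
         standard = standard, delta = delta,
         criterion = criterion, gate_k = gate_k, lapse = lapse,
         seed = as.integer(seed)),
    class = "cohort_spec"
  )
}

#' Blocked trial schedule
#'
#' Conditions are presented in blocks of 10 trials, each block containing 5
#' trials of each member of one condition pair (D+/D-, T+/T-, T+D+/T+D-), so
#' neither direction of slant difference is predictable within a block.
#' Block order and within-block trial order are randomised; across the
#' session every condition has exactly half "same" and half "different"
#' trials.
#'
#' @param spec A [cohort_spec()] (only the design fields are used).
#' @param seed Optional integer seed (local to this call).
#' @return A `design_schedule` data.frame with columns `trial`, `block`,
#'   `condition`, `truth`.
#' @export
build_schedule <- function(spec, seed = NULL) {
  tpc <- spec$trials_per_condition
  if (tpc %% 5 != 0 || tpc %% 2 != 0) {
    sf_spec_error("`trials_per_condition` must be divisible by 5 and even")
  }
  pairs <- list(c("D+", "D-"), c("T+", "T-"), c("T+D+", "T+D-"))
  blocks_per_pair <- tpc / 5
  with_seed(seed, {
    # per condition: a balanced truth sequence split into 5-trial block slots
    slots <- list()
    for (cond in CONDITIONS) {
      truth <- sample(rep(c("same", "different"), each = tpc / 2))
      slots[[cond]] <- split(truth, rep(seq_len(blocks_per_pair), each = 5))
    }
    block_defs <- do.call(rbind, lapply(seq_along(pairs), function(i) {
      data.frame(pair = i, slot = seq_len(blocks_per_pair))
    }))
    block_defs <- block_defs[sample(nrow(block_defs)), ]
    rows <- lapply(seq_len(nrow(block_defs)), function(b) {
      pr <- pairs[[block_defs$pair[b]]]
      sl <- block_defs$slot[b]
      df <- data.frame(
        block = b,
        condition = rep(pr, each = 5),
        truth = c(slots[[pr[1]]][[sl]], slots[[pr[2]]][[sl]]),
        stringsAsFactors = FALSE
      )
      df[sample(nrow(df)), ]
    })
    out <- do.call(rbind, rows)
    out$trial <- seq_len(nrow(out))
    rownames(out) <- NULL
    out <- out[, c("trial", "block", "condition", "truth")]
    class(out) <- c("design_schedule", class(out))
    out
  })
}

#' Generate a cohort of synthetic observers
#'
#' Draws per-subject cue noise SDs from the lognormal population of the spec
#' and assigns each subject the regime of its group. Every subject gets a
#' deterministic RNG substream seed derived from the master seed, so adding
#' subjects or groups does not perturb existing subjects' data.
#'
#' @param spec A [cohort_spec()].
#' @return Data.frame with one row per subject: `subject_id`, `group`,
#'   `regime`, `sigma_T`, `sigma_D`, `stream_seed`, plus the shared decision
#'   parameters as attributes on the spec carried in `attr(, "spec")`.
#' @export
generate_cohort <- function(spec) {
  groups <- names(spec$n_per_group)
  rows <- list()
  idx <- 0L
  for (g in groups) {
    ng <- spec$n_per_group[[g]]
    for (i in seq_len(ng)) {
      idx <- idx + 1L
      stream <- substream_seed(spec$seed, idx)
      sig <- with_seed(stream, {
        z1 <- stats::rnorm(1)
        z2 <- spec$cue_correlation * z1 +
          sqrt(1 - spec$cue_correlation^2) * stats::rnorm(1)
        spec$sigma_median * spec$sigma_gsd^c(z1, z2)
      })
      rows[[idx]] <- data.frame(
        subject_id = sprintf("%s%02d", g, i), group = g,
        regime = spec$regime_by_group[[g]],
        sigma_T = sig[1], sigma_D = sig[2],
        stream_seed = stream, stringsAsFactors = FALSE
      )
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "spec") <- spec
  out
}

subject_params <- function(row, spec) {
  observer_params(
    sigma_T = row$sigma_T, sigma_D = row$sigma_D,
    sigma_c = if (row$regime == "no_fusion") Inf else 0,
    criterion = spec$criterion, regime = row$regime,
    gate_k = spec$gate_k, lapse = spec$lapse
  )
}

#' Run a full simulated study
#'
#' Simulates every subject's responses over the schedule. Each subject uses
#' an independent RNG substream (offset from their cohort stream so cohort
#' generation and response simulation never share draws); given (spec, seed)
#' the trial table is fully deterministic.
#'
#' @param cohort Output of [generate_cohort()].
#' @param schedule Output of [build_schedule()]; the same schedule is used
#'   for all subjects.
#' @return Trial table data.frame: `subject_id`, `group`, `condition`,
#'   `trial`, `truth`, `response`.
#' @export
run_study <- function(cohort, schedule) {
  spec <- attr(cohort, "spec")
  if (is.null(spec)) sf_spec_error("`cohort` must come from generate_cohort()")
  out <- vector("list", nrow(cohort))
  for (i in seq_len(nrow(cohort))) {
    row <- cohort[i, ]
    params <- subject_params(row, spec)
    resp <- rep(NA_character_, nrow(schedule))
    with_seed(substream_seed(row$stream_seed, 104729L), {
      for (cond in CONDITIONS) {   # fixed order => reproducible stream use
        sel <- schedule$condition == cond
        if (!any(sel)) next
        resp[sel] <- simulate_responses(params, cond, schedule$truth[sel],
                                        spec$standard, spec$delta)
      }
    })
    out[[i]] <- data.frame(
      subject_id = row$subject_id, group = row$group,
      condition = schedule$condition, trial = schedule$trial,
      truth = schedule$truth, response = resp,
      stringsAsFactors = FALSE
    )
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

## Simulate one single-group cohort condition-wise (no block schedule;
## trials are exchangeable) and classify its fusion pattern.
simulate_and_classify <- function(spec, group, alpha = 0.05,
                                  analytic = FALSE) {
  cohort <- generate_cohort(spec)
  cohort <- cohort[cohort$group == group, , drop = FALSE]
  scores <- matrix(NA_real_, nrow(cohort), length(ANALYZED_CONDITIONS),
                   dimnames = list(NULL, ANALYZED_CONDITIONS))
  for (i in seq_len(nrow(cohort))) {
    params <- subject_params(cohort[i, ], spec)
    if (analytic) {
      scores[i, ] <- vapply(ANALYZED_CONDITIONS, function(cond) {
        analytic_condition_dprime(params, cond, spec$standard,
                                  spec$delta)$dprime
      }, numeric(1))
    } else {
      with_seed(substream_seed(cohort$stream_seed[i], 104729L), {
        for (cond in ANALYZED_CONDITIONS) {
          tr <- simulate_condition(params, cond, spec$trials_per_condition,
                                   standard = spec$standard,
                                   delta = spec$delta)
          sig <- tr$truth == "different"
          scores[i, cond] <- compute_dprime(
            sum(sig & tr$response == "different"),
            sum(!sig & tr$response == "different"),
            sum(sig), sum(!sig)
          )
        }
      })
    }
  }
  sc <- as.data.frame(scores, check.names = FALSE)
  sc$subject_id <- cohort$subject_id
  classify_fusion_pattern(sc, alpha = alpha)$pattern
}

#' Fusion-regime recovery study
#'
#' Generates replicate single-group cohorts under each fusion regime,
#' simulates and scores them, classifies each cohort with
#' [classify_fusion_pattern()], and tabulates classification accuracy
#' against the generating regime per regime and trials-per-condition cell.
#'
#' @param n_replicates Replicate cohorts per cell (>= 2).
#' @param regimes Regimes to study.
#' @param trials_grid Trials-per-condition values; `Inf` uses analytic
#'   d-primes (the infinite-trials limit).
#' @param n_subjects Subjects per cohort.
#' @param spec Template [cohort_spec()] supplying the population and
#'   decision parameters.
#' @param alpha Significance level for the planned comparisons.
#' @param seed Master seed.
#' @return Data.frame: `regime`, `trials_per_condition`, `n_replicates`,
#'   `accuracy` (fraction of cohorts classified as their generating regime).
#' @export
recovery_report <- function(n_replicates = 50, regimes = REGIMES,
                            trials_grid = c(30, 300), n_subjects = 16,
                            spec = cohort_spec(), alpha = 0.05,
                            seed = 1L) {
  if (n_replicates < 2) sf_spec_error("`n_replicates` must be >= 2")
  grid <- expand.grid(regime = regimes, trials = trials_grid,
                      stringsAsFactors = FALSE)
  acc <- numeric(nrow(grid))
  for (k in seq_len(nrow(grid))) {
    regime <- grid$regime[k]
    tpc <- grid$trials[k]
    hits <- 0L
    for (r in seq_len(n_replicates)) {
      sp <- spec
      sp$n_per_group <- c(G = n_subjects)
      sp$regime_by_group <- c(G = regime)
      if (is.finite(tpc)) sp$trials_per_condition <- tpc
      sp$seed <- substream_seed(seed, k * 100003L + r)
      got <- simulate_and_classify(sp, "G", alpha = alpha,
                                   analytic = !is.finite(tpc))
      hits <- hits + (got == regime)
    }
    acc[k] <- hits / n_replicates
  }
  data.frame(regime = grid$regime, trials_per_condition = grid$trials,
             n_replicates = n_replicates, accuracy = acc,
             stringsAsFactors = FALSE)
}
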