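# Coupling-prior observer model for the same-different slant task.
#
# Each cue yields a noisy Gaussian slant estimate; a Gaussian prior on the
# between-cue discrepancy (the coupling prior, SD sigma_c) governs how
# strongly the two estimates are bound. sigma_c = 0 forces a single fused
# percept (mandatory fusion, reliability-weighted average); sigma_c = Inf
# leaves the cues independent (no fusion). The selective regime fuses only
# when the within-disc discrepancy is small relative to its expected spread.

#' Fusion regimes, condition codes and the analysed condition set
#'
#' `REGIMES` lists the three cue-binding regimes an observer can follow.
#' `CONDITIONS` lists the six task conditions (single-cue `T+`, `T-`, `D+`,
#' `D-`; combined congruent `T+D+`; combined incongruent `T+D-`).
#' `ANALYZED_CONDITIONS` drops `T-`, which is scored but excluded from all
#' analyses (the texture cue carries little usable slant information in that
#' direction in real displays).
#'
#' @name constants
#' @aliases REGIMES CONDITIONS ANALYZED_CONDITIONS
#' @export REGIMES CONDITIONS ANALYZED_CONDITIONS
NULL

REGIMES <- c("no_fusion", "mandatory_fusion", "selective_fusion")
CONDITIONS <- c("T+", "T-", "D+", "D-", "T+D+", "T+D-")
ANALYZED_CONDITIONS <- c("T+", "D+", "D-", "T+D+", "T+D-")

#' Observer parameters
#'
#' @param sigma_T,sigma_D SDs of the texture and disparity slant-estimate
#'   noise (degrees), > 0.
#' @param sigma_c Coupling-prior SD on the between-cue discrepancy (degrees);
#'   0 mandates full fusion, `Inf` leaves cues uncoupled.
#' @param criterion Decision criterion on the absolute between-disc percept
#'   difference (degrees); "different" is reported when it is exceeded.
#' @param regime Fusion regime: `"no_fusion"`, `"mandatory_fusion"` or
#'   `"selective_fusion"`.
#' @param gate_k Selective-regime gate: cues are kept separate when the
#'   within-disc discrepancy exceeds `gate_k * sqrt(sigma_T^2 + sigma_D^2)`.
#' @param lapse Lapse rate in [0, 0.1]; on lapse trials the response is
#'   uniform at random.
#' @return An object of class `observer_params`.
#' @export
observer_params <- function(sigma_T = 5, sigma_D = 5, sigma_c = 0,
                            criterion = 6.25,
                            regime = c("mandatory_fusion", "no_fusion",
                                       "selective_fusion"),
                            gate_k = 2, lapse = 0) {
  regime <- match.arg(regime)
  check_number(sigma_T, "sigma_T", lower = 1e-12)
  check_number(sigma_D, "sigma_D", lower = 1e-12)
  check_number(sigma_c, "sigma_c", lower = 0, allow_inf = TRUE)
  check_number(criterion, "criterion", lower = 1e-12)
  check_number(gate_k, "gate_k", lower = 0)
  check_number(lapse, "lapse", lower = 0, upper = 0.1)
  structure(
    list(sigma_T = sigma_T, sigma_D = sigma_D, sigma_c = sigma_c,
         criterion = criterion, regime = regime, gate_k = gate_k,
         lapse = lapse),
    class = "observer_params"
  )
}

#' One same-different trial stimulus
#'
#' The standard disc is slanted at `standard` via every cue the condition
#' carries; on "different" trials the comparison differs by `delta` with the
#' condition's sign per cue (in the incongruent condition `T+D-`, +delta via
#' texture and -delta via disparity).
#'
#' @param condition One of `"T+", "T-", "D+", "D-", "T+D+", "T+D-"`.
#' @param truth `"same"` or `"different"`.
#' @param standard Standard slant (degrees).
#' @param delta Slant increment magnitude (degrees).
#' @return A `trial_stimulus` with per-cue standard/comparison slants and
#'   which cues the condition exposes.
#' @export
trial_stimulus <- function(condition, truth = c("different", "same"),
                           standard = 45, delta = 12.5) {
  truth <- match.arg(truth)
  info <- condition_info(condition)
  diff <- as.numeric(truth == "different")
  structure(
    list(condition = condition, truth = truth,
         cues = info$cues,
         texture_standard = standard, disparity_standard = standard,
         texture_comparison = standard + diff * info$sign_T * delta,
         disparity_comparison = standard + diff * info$sign_D * delta),
    class = "trial_stimulus"
  )
}

condition_info <- function(condition) {
  switch(as.character(condition),
    "T+"   = list(cues = "T",            sign_T = 1,  sign_D = 0),
    "T-"   = list(cues = "T",            sign_T = -1, sign_D = 0),
    "D+"   = list(cues = "D",            sign_T = 0,  sign_D = 1),
    "D-"   = list(cues = "D",            sign_T = 0,  sign_D = -1),
    "T+D+" = list(cues = c("T", "D"),    sign_T = 1,  sign_D = 1),
    "T+D-" = list(cues = c("T", "D"),    sign_T = 1,  sign_D = -1),
    sf_spec_error(sprintf("unknown condition '%s'", condition))
  )
}

#' Draw noisy single-cue slant estimates
#'
#' @param true_texture,true_disparity True cue-specified slants (degrees).
#' @param params An [observer_params()].
#' @param n Number of independent draws.
#' @return List with numeric vectors `est_T` and `est_D`.
#' @export
sample_cue_estimates <- function(true_texture, true_disparity, params,
                                 n = 1L) {
  list(est_T = stats::rnorm(n, true_texture, params$sigma_T),
       est_D = stats::rnorm(n, true_disparity, params$sigma_D))
}

#' Coupling-prior fusion of two cue estimates
#'
#' Maximum a posteriori slant estimates under independent Gaussian
#' likelihoods for the two cues and a zero-mean Gaussian prior of SD
#' `sigma_c` on the between-cue discrepancy. As `sigma_c -> 0` both MAP
#' estimates collapse onto the reliability-weighted average
#' `w_T * est_T + w_D * est_D`, `w_T = sigma_D^2 / (sigma_T^2 + sigma_D^2)`;
#' as `sigma_c -> Inf` the cues are returned unfused. The scalar percept
#' `slant` is the precision-weighted readout of the two MAP estimates (which
#' equals the full-fusion average for every positive coupling weight; the
#' per-cue percepts, by contrast, shrink toward each other as the prior
#' narrows).
#'
#' @param est_T,est_D Cue estimates (degrees); vectors of equal length.
#' @param params An [observer_params()].
#' @return List with `slant` (fused scalar percept), `est_T_map`,
#'   `est_D_map` (per-cue MAP percepts) and `w_T` (texture weight).
#' @export
fuse_estimates <- function(est_T, est_D, params) {
  if (!is.finite(params$sigma_T) && !is.finite(params$sigma_D)) {
    sf_spec_error("both cue variances are non-finite")
  }
  a <- 1 / params$sigma_T^2
  bb <- 1 / params$sigma_D^2
  w_T <- bb^-1 / (a^-1 + bb^-1)  # = sigma_D^2/(sigma_T^2+sigma_D^2)
  avg <- w_T * est_T + (1 - w_T) * est_D
  if (params$sigma_c == 0) {
    return(list(slant = avg, est_T_map = avg, est_D_map = avg, w_T = w_T))
  }
  if (is.infinite(params$sigma_c)) {
    return(list(slant = avg, est_T_map = est_T, est_D_map = est_D, w_T = w_T))
  }
  g <- 1 / params$sigma_c^2
  det <- a * bb + g * (a + bb)
  sT <- (a * (bb + g) * est_T + g * bb * est_D) / det
  sD <- (g * a * est_T + bb * (a + g) * est_D) / det
  list(slant = avg, est_T_map = sT, est_D_map = sD, w_T = w_T)
}

## Vectorised decision core. est_* are length-n vectors (NA for absent cues).
## Returns logical vector: TRUE = "different".
decide_core <- function(params, cues,
                        est_T_std, est_D_std, est_T_cmp, est_D_cmp) {
  c0 <- params$criterion
  if (length(cues) == 1L) {
    d <- if (cues == "T") est_T_cmp - est_T_std else est_D_cmp - est_D_std
    return(abs(d) > c0)
  }
  dT <- est_T_cmp - est_T_std
  dD <- est_D_cmp - est_D_std
  switch(params$regime,
    no_fusion = {
      # rely on the single more reliable cue (tie -> texture)
      if (params$sigma_T <= params$sigma_D) abs(dT) > c0 else abs(dD) > c0
    },
    mandatory_fusion = {
      f_std <- fuse_estimates(est_T_std, est_D_std, params)$slant
      f_cmp <- fuse_estimates(est_T_cmp, est_D_cmp, params)$slant
      abs(f_cmp - f_std) > c0
    },
    selective_fusion = {
      gate <- params$gate_k * sqrt(params$sigma_T^2 + params$sigma_D^2)
      conflict <- abs(est_T_std - est_D_std) > gate |
        abs(est_T_cmp - est_D_cmp) > gate
      f_std <- fuse_estimates(est_T_std, est_D_std, params)$slant
      f_cmp <- fuse_estimates(est_T_cmp, est_D_cmp, params)$slant
      fused_resp <- abs(f_cmp - f_std) > c0
      separate_resp <- abs(dT) > c0 | abs(dD) > c0   # max rule
      ifelse(conflict, separate_resp, fused_resp)
    }
  )
}

#' Simulate one same-different response
#'
#' Draws noisy cue estimates for both discs of the trial, forms percepts
#' according to the observer's fusion regime, and responds "different" when
#' the absolute between-disc percept difference exceeds the criterion.
#' Single-cue conditions expose only the relevant cue. Under selective
#' fusion, a within-disc discrepancy beyond the gate keeps the cues separate
#' and either cue's difference may trigger "different" (max rule). Lapse
#' trials respond uniformly at random.
#'
#' @param stim A [trial_stimulus()].
#' @param params An [observer_params()].
#' @return `"same"` or `"different"` (uses the current RNG stream).
#' @export
decide_same_different <- function(stim, params) {
  if (!inherits(stim, "trial_stimulus")) {
    sf_spec_error("`stim` must be a trial_stimulus")
  }
  need_T <- "T" %in% stim$cues
  need_D <- "D" %in% stim$cues
  est <- function(need, mu, sigma) {
    if (need) stats::rnorm(1, mu, sigma) else NA_real_
  }
  resp <- decide_core(
    params, stim$cues,
    est(need_T, stim$texture_standard, params$sigma_T),
    est(need_D, stim$disparity_standard, params$sigma_D),
    est(need_T, stim$texture_comparison, params$sigma_T),
    est(need_D, stim$disparity_comparison, params$sigma_D)
  )
  if (params$lapse > 0 && stats::runif(1) < params$lapse) {
    resp <- stats::runif(1) < 0.5
  }
  if (resp) "different" else "same"
}

## Vectorised trial simulation for one condition given a truth vector.
## Returns character vector of responses. Consumes the current RNG stream.
simulate_responses <- function(params, condition, truth, standard = 45,
                               delta = 12.5) {
  info <- condition_info(condition)
  n <- length(truth)
  diff <- as.numeric(truth == "different")
  tex_cmp <- standard + diff * info$sign_T * delta
  dis_cmp <- standard + diff * info$sign_D * delta
  need_T <- "T" %in% info$cues
  need_D <- "D" %in% info$cues
  est_T_std <- if (need_T) stats::rnorm(n, standard, params$sigma_T) else rep(NA_real_, n)
  est_D_std <- if (need_D) stats::rnorm(n, standard, params$sigma_D) else rep(NA_real_, n)
  est_T_cmp <- if (need_T) stats::rnorm(n, tex_cmp, params$sigma_T) else rep(NA_real_, n)
  est_D_cmp <- if (need_D) stats::rnorm(n, dis_cmp, params$sigma_D) else rep(NA_real_, n)
  resp <- decide_core(params, info$cues,
                      est_T_std, est_D_std, est_T_cmp, est_D_cmp)
  if (params$lapse > 0) {
    lapse <- stats::runif(n) < params$lapse
    resp[lapse] <- stats::runif(sum(lapse)) < 0.5
  }
  ifelse(resp, "different", "same")
}

#' Simulate a balanced block of trials for one condition
#'
#' Exactly half the trials are "same" and half "different", in randomised
#' order.
#'
#' @param params An [observer_params()].
#' @param condition Condition code.
#' @param n_trials Even trial count.
#' @param seed Optional integer seed (local to this call).
#' @param standard,delta Standard slant and increment (degrees).
#' @return A data.frame with columns `condition`, `trial`, `truth`,
#'   `response`.
#' @export
simulate_condition <- function(params, condition, n_trials = 30, seed = NULL,
                               standard = 45, delta = 12.5) {
  if (n_trials %% 2 != 0 || n_trials < 2) {
    sf_spec_error("`n_trials` must be even and >= 2")
  }
  condition_info(condition)  # validates
  with_seed(seed, {
    truth <- sample(rep(c("same", "different"), each = n_trials / 2))
    response <- simulate_responses(params, condition, truth, standard, delta)
    data.frame(condition = condition, trial = seq_len(n_trials),
               truth = truth, response = response,
               stringsAsFactors = FALSE)
  })
}

#' Quadratic-summation benchmark for combined-cue sensitivity
#'
#' The optimal-integration prediction for the combined-cue condition from the
#' two single-cue sensitivities: `sqrt(dprime_T^2 + dprime_D^2)`.
#'
#' @param dprime_T,dprime_D Single-cue sensitivities (>= 0).
#' @return Predicted combined-cue d-prime.
#' @export
predicted_dprime_fused <- function(dprime_T, dprime_D) {
  if (any(dprime_T < 0) || any(dprime_D < 0)) {
    sf_spec_error("single-cue d-prime inputs must be non-negative")
  }
  sqrt(dprime_T^2 + dprime_D^2)
}

## ---- Closed-form performance under the differencing decision rule ----

## P(respond "different") when the between-disc percept difference is
## N(delta_eff, sd_diff^2) and the criterion is c.
response_rate <- function(delta_eff, sd_diff, criterion) {
  stats::pnorm((-criterion - delta_eff) / sd_diff) +
    stats::pnorm((criterion - delta_eff) / sd_diff, lower.tail = FALSE)
}

#' Analytic per-condition d-prime for a simulated observer
#'
#' Closed-form hit and false-alarm rates under the differencing rule (exact
#' for single-cue conditions, no-fusion and mandatory-fusion regimes; for the
#' selective regime the gate is treated as independent of the estimates, a
#' mixture approximation). Used for infinite-trial limits in recovery
#' studies.
#'
#' @inheritParams simulate_condition
#' @return List with `hit`, `fa` and `dprime` (z(hit) - z(fa), uncorrected).
#' @export
analytic_condition_dprime <- function(params, condition, standard = 45,
                                      delta = 12.5) {
  info <- condition_info(condition)
  sT <- params$sigma_T; sD <- params$sigma_D; c0 <- params$criterion
  dT <- info$sign_T * delta
  dD <- info$sign_D * delta
  if (length(info$cues) == 1L) {
    s <- if (info$cues == "T") sT else sD
    d <- if (info$cues == "T") dT else dD
    hit <- response_rate(d, sqrt(2) * s, c0)
    fa <- response_rate(0, sqrt(2) * s, c0)
  } else {
    w <- fuse_estimates(0, 0, params)$w_T
    sf <- sqrt(w^2 * sT^2 + (1 - w)^2 * sD^2)
    rate_fused <- function(delT, delD)
      response_rate(w * delT + (1 - w) * delD, sqrt(2) * sf, c0)
    rate_best <- function(delT, delD) {
      if (sT <= sD) response_rate(delT, sqrt(2) * sT, c0)
      else response_rate(delD, sqrt(2) * sD, c0)
    }
    rate_max <- function(delT, delD) {
      1 - (1 - response_rate(delT, sqrt(2) * sT, c0)) *
        (1 - response_rate(delD, sqrt(2) * sD, c0))
    }
    switch(params$regime,
      no_fusion = {
        hit <- rate_best(dT, dD); fa <- rate_best(0, 0)
      },
      mandatory_fusion = {
        hit <- rate_fused(dT, dD); fa <- rate_fused(0, 0)
      },
      selective_fusion = {
        sdisc <- sqrt(sT^2 + sD^2)
        gate <- params$gate_k * sdisc
        p_gate <- function(mean_disc) {
          # P(either disc's discrepancy exceeds the gate)
          p_std <- response_rate(0, sdisc, gate)
          p_cmp <- response_rate(mean_disc, sdisc, gate)
          1 - (1 - p_std) * (1 - p_cmp)
        }
        pg_diff <- p_gate(dT - dD)
        pg_same <- p_gate(0)
        hit <- pg_diff * rate_max(dT, dD) + (1 - pg_diff) * rate_fused(dT, dD)
        fa <- pg_same * rate_max(0, 0) + (1 - pg_same) * rate_fused(0, 0)
      }
    )
  }
  list(hit = hit, fa = fa, dprime = stats::qnorm(hit) - stats::qnorm(fa))
}
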