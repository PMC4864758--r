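# Coupling-prior observer: cue sampling, fusion, decisions and measured
# sensitivities against closed-form oracles.

test_that("cue estimates are unbiased with the requested noise", {
  p <- observer_params(sigma_T = 3, sigma_D = 7)
  set.seed(1)
  est <- sample_cue_estimates(40, 52, p, n = 1e5)
  expect_lt(abs(mean(est$est_T) - 40), 3 * 3 / sqrt(1e5))
  expect_lt(abs(mean(est$est_D) - 52), 3 * 7 / sqrt(1e5))
  expect_equal(sd(est$est_T), 3, tolerance = 0.02)
  # noiseless limit
  p0 <- observer_params(sigma_T = 1e-12, sigma_D = 1e-12)
  est0 <- sample_cue_estimates(40, 52, p0, n = 3)
  expect_equal(est0$est_T, rep(40, 3), tolerance = 1e-9)
  # reproducibility
  set.seed(9); a <- sample_cue_estimates(0, 0, p, n = 5)
  set.seed(9); b <- sample_cue_estimates(0, 0, p, n = 5)
  expect_identical(a, b)
})

test_that("fusion reproduces the closed-form reliability weighting", {
  p_eq <- observer_params(sigma_T = 2, sigma_D = 2, sigma_c = 0)
  expect_equal(fuse_estimates(40, 50, p_eq)$slant, 45)
  p_uneq <- observer_params(sigma_T = 1, sigma_D = 2, sigma_c = 0)
  f <- fuse_estimates(40, 50, p_uneq)
  expect_equal(f$w_T, 4 / 5)
  expect_equal(f$slant, 42)
  # uncoupled limit returns the cues unfused
  p_inf <- observer_params(sigma_T = 1, sigma_D = 2, sigma_c = Inf)
  f_inf <- fuse_estimates(40, 50, p_inf)
  expect_equal(f_inf$est_T_map, 40)
  expect_equal(f_inf$est_D_map, 50)
})

test_that("finite coupling-prior MAP matches the dense grid posterior", {
  cases <- list(
    c(est_T = 40, est_D = 50, sT = 1, sD = 2, sc = 3),
    c(est_T = 45, est_D = 38, sT = 4, sD = 3, sc = 6),
    c(est_T = 60, est_D = 20, sT = 5, sD = 5, sc = 10),
    c(est_T = 44, est_D = 46, sT = 2, sD = 7, sc = 0.5)
  )
  for (cs in cases) {
    p <- observer_params(sigma_T = cs["sT"], sigma_D = cs["sD"],
                         sigma_c = cs["sc"])
    f <- fuse_estimates(cs["est_T"], cs["est_D"], p)
    o <- oracle_grid_map(cs["est_T"], cs["est_D"],
                         cs["sT"], cs["sD"], cs["sc"])
    expect_lt(abs(unname(f$est_T_map) - o[1]), 0.01)
    expect_lt(abs(unname(f$est_D_map) - o[2]), 0.01)
    # shrinkage: MAP estimates lie between the raw cues
    expect_true(min(cs["est_T"], cs["est_D"]) <= f$est_T_map + 1e-9 &&
                  f$est_T_map <= max(cs["est_T"], cs["est_D"]) + 1e-9)
  }
  expect_error(
    fuse_estimates(1, 2, structure(list(sigma_T = Inf, sigma_D = Inf,
                                        sigma_c = 1),
                                   class = "observer_params")),
    class = "slantfuse_spec_error")
})

test_that("noiseless observers are perfect and lapses are random", {
  p0 <- observer_params(sigma_T = 1e-12, sigma_D = 1e-12)
  set.seed(2)
  expect_equal(decide_same_different(trial_stimulus("T+", "different"), p0),
               "different")
  expect_equal(decide_same_different(trial_stimulus("T+", "same"), p0),
               "same")
  expect_equal(decide_same_different(trial_stimulus("T+D+", "different"), p0),
               "different")
  tr <- simulate_condition(p0, "D+", 30, seed = 3)
  expect_true(all(tr$truth == tr$response))
  # full-lapse observer responds at chance regardless of truth
  pl <- observer_params(sigma_T = 1e-12, sigma_D = 1e-12, lapse = 0.1)
  set.seed(4)
  tr <- do.call(rbind, lapply(1:60, function(i)
    simulate_condition(pl, "T+", 30)))
  err <- mean(tr$truth != tr$response)
  expect_gt(err, 0.02)  # ~ lapse/2 = 0.05
  expect_lt(err, 0.08)
})

test_that("single-cue response rates match the Gaussian tail closed form", {
  p <- equal_observer(sigma = 5)
  set.seed(11)
  n <- 1e5
  tr <- simulate_condition(p, "D+", n)
  hit <- mean(tr$response[tr$truth == "different"] == "different")
  fa <- mean(tr$response[tr$truth == "same"] == "different")
  an <- analytic_condition_dprime(p, "D+")
  binom3 <- function(r) 3 * sqrt(r * (1 - r) / (n / 2))
  expect_lt(abs(hit - an$hit), binom3(an$hit))
  expect_lt(abs(fa - an$fa), binom3(an$fa))
  # empirical d' close to the analytic value
  expect_equal(dprime_of(tr), an$dprime, tolerance = 0.02)
})

test_that("balanced designs are enforced and produced", {
  p <- equal_observer()
  tr <- simulate_condition(p, "T+", 30, seed = 1)
  expect_equal(sum(tr$truth == "same"), 15)
  expect_equal(sum(tr$truth == "different"), 15)
  expect_error(simulate_condition(p, "T+", 31), class = "slantfuse_spec_error")
  expect_error(simulate_condition(p, "X+", 30), class = "slantfuse_spec_error")
})

test_that("quadratic summation benchmark behaves", {
  expect_equal(predicted_dprime_fused(1.3, 0), 1.3)
  expect_equal(predicted_dprime_fused(1, 1), sqrt(2))
  expect_error(predicted_dprime_fused(-1, 1), class = "slantfuse_spec_error")
})

test_that("regime limits: sigma_c endpoints reproduce the named regimes", {
  # sigma_c = 0 scalar percept equals the weighted average used by the
  # mandatory regime; sigma_c = Inf leaves per-cue percepts untouched, which
  # with best-single-cue reporting is the no-fusion observer
  p <- observer_params(sigma_T = 3, sigma_D = 4, sigma_c = 0)
  f <- fuse_estimates(41, 47, p)
  w <- 16 / 25
  expect_equal(f$slant, w * 41 + (1 - w) * 47)
  expect_equal(f$est_T_map, f$est_D_map)
  # decision equivalence under shared estimates
  est <- list(ts = 44, ds = 46, tc = 58, dc = 57)
  for (reg in c("mandatory_fusion", "selective_fusion")) {
    pr <- observer_params(sigma_T = 3, sigma_D = 4, sigma_c = 0, regime = reg,
                          gate_k = 100)  # gate never triggers
    expect_equal(
      slantfuse:::decide_core(pr, c("T", "D"), est$ts, est$ds, est$tc, est$dc),
      slantfuse:::decide_core(p, c("T", "D"), est$ts, est$ds, est$tc, est$dc))
  }
  # selective with gate 0 always separates: equals the max rule
  psel <- observer_params(sigma_T = 3, sigma_D = 4, regime = "selective_fusion",
                          gate_k = 0)
  expect_true(slantfuse:::decide_core(psel, c("T", "D"), 45, 45, 45 + 7, 45 - 1))
})

test_that("fusion regimes produce the predicted d-prime orderings", {
  # large-n orderings via the analytic rates (equal reliabilities)
  p_man <- equal_observer(sigma = 5, regime = "mandatory_fusion")
  singles <- sapply(c("T+", "D+", "D-"), function(cc)
    analytic_condition_dprime(p_man, cc)$dprime)
  man_cong <- analytic_condition_dprime(p_man, "T+D+")$dprime
  man_incong <- analytic_condition_dprime(p_man, "T+D-")$dprime
  expect_gt(man_cong, max(singles[c("T+", "D+")]))
  expect_lt(man_incong, min(singles[c("T+", "D-")]))
  p_sel <- equal_observer(sigma = 5, regime = "selective_fusion")
  sel_cong <- analytic_condition_dprime(p_sel, "T+D+")$dprime
  sel_incong <- analytic_condition_dprime(p_sel, "T+D-")$dprime
  expect_gt(sel_cong, max(singles[c("T+", "D+")]))
  expect_gte(sel_incong, min(singles[c("T+", "D-")]) - 0.05)
  # and the same orderings hold in moderate simulation
  set.seed(21)
  sim_d <- function(p, cc) dprime_of(simulate_condition(p, cc, 4000))
  expect_gt(sim_d(p_man, "T+D+"), sim_d(p_man, "T+"))
  expect_lt(sim_d(p_man, "T+D-"), sim_d(p_man, "D-"))
  expect_gt(sim_d(p_sel, "T+D-"), sim_d(p_man, "T+D-"))
})

test_that("measured d-prime is non-increasing in cue noise", {
  sigmas <- c(2, 4, 6, 9)
  for (cond in c("T+", "T+D+", "T+D-")) {
    d <- sapply(sigmas, function(s)
      analytic_condition_dprime(equal_observer(sigma = s), cond)$dprime)
    expect_true(all(diff(d) <= 1e-9))
  }
})

test_that("no-fusion observers ride their more reliable cue", {
  p <- observer_params(sigma_T = 8, sigma_D = 2, regime = "no_fusion",
                       sigma_c = Inf)
  an <- analytic_condition_dprime(p, "T+D+")
  an_D <- analytic_condition_dprime(p, "D+")
  expect_equal(an$dprime, an_D$dprime)
  # and in simulation the combined condition matches the better single cue
  set.seed(31)
  d_comb <- dprime_of(simulate_condition(p, "T+D+", 2e4))
  expect_equal(d_comb, an_D$dprime, tolerance = 0.1)
})
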