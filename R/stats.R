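# Inferential battery: paired t with Cohen's d, pooled two-sample t from
# summary statistics, a transparent 2x2 mixed ANOVA, partial eta squared,
# and the dual-planned-comparison alpha bound.

#' Paired t-test with Cohen's d
#'
#' Standard paired t on the differences, two-sided p, and the paired-design
#' effect size `|t| / sqrt(n)` (the mean difference in units of the
#' difference SD).
#'
#' Identical vectors (a uniformly zero difference) carry no evidence and
#' give t = 0, p = 1; a constant *nonzero* difference (infinite t) is flagged
#' as degenerate data instead.
#'
#' @param x,y Numeric vectors of equal length (n >= 2).
#' @return List with `t`, `df`, `p`, `cohens_d`, `mean_diff`, `n`.
#' @export
paired_t <- function(x, y) {
  if (length(x) != length(y)) sf_data_error("`x` and `y` must have equal length")
  n <- length(x)
  if (n < 2) sf_data_error("paired t needs n >= 2")
  d <- x - y
  if (stats::sd(d) < 1e-12) {
    if (max(abs(d)) > 1e-12) {
      sf_stat_error("degenerate data: constant nonzero difference (infinite t)")
    }
    return(list(t = 0, df = n - 1, p = 1, cohens_d = 0, mean_diff = 0, n = n))
  }
  tt <- stats::t.test(x, y, paired = TRUE)
  list(t = unname(tt$statistic), df = unname(tt$parameter),
       p = tt$p.value, cohens_d = abs(unname(tt$statistic)) / sqrt(n),
       mean_diff = mean(d), n = n)
}

#' Cohen's d for a paired design from t and n
#'
#' @param t Paired t statistic.
#' @param n Number of pairs (>= 2).
#' @return `|t| / sqrt(n)`.
#' @export
cohens_d_from_t <- function(t, n) {
  if (any(n < 2)) sf_data_error("`n` must be >= 2")
  abs(t) / sqrt(n)
}

#' Pooled-variance two-sample t-test
#'
#' Student's t with pooled variance and `df = n1 + n2 - 2`, computable either
#' from raw vectors (`x`, `y`) or from summary statistics (`m`, `sd`, `n`
#' per group); both routes give identical results.
#'
#' @param x,y Optional raw data vectors.
#' @param m1,sd1,n1,m2,sd2,n2 Summary statistics, used when `x`/`y` absent.
#' @return List with `t`, `df`, `p` (two-sided), `mean_diff`.
#' @export
two_sample_pooled_t <- function(x = NULL, y = NULL,
                                m1 = NULL, sd1 = NULL, n1 = NULL,
                                m2 = NULL, sd2 = NULL, n2 = NULL) {
  if (!is.null(x) || !is.null(y)) {
    if (length(x) < 2 || length(y) < 2) sf_data_error("need n >= 2 per group")
    m1 <- mean(x); sd1 <- stats::sd(x); n1 <- length(x)
    m2 <- mean(y); sd2 <- stats::sd(y); n2 <- length(y)
  }
  if (is.null(m1) || is.null(sd1) || is.null(n1) ||
      is.null(m2) || is.null(sd2) || is.null(n2)) {
    sf_spec_error("supply either raw vectors or complete summary statistics")
  }
  if (n1 < 2 || n2 < 2) sf_data_error("need n >= 2 per group")
  if (sd1 <= 0 || sd2 <= 0) sf_data_error("group SDs must be positive")
  df <- n1 + n2 - 2
  sp2 <- ((n1 - 1) * sd1^2 + (n2 - 1) * sd2^2) / df
  t <- (m1 - m2) / sqrt(sp2 * (1 / n1 + 1 / n2))
  list(t = t, df = df, p = 2 * stats::pt(-abs(t), df), mean_diff = m1 - m2)
}

#' Partial eta squared from F and its degrees of freedom
#'
#' @param F F statistic (>= 0).
#' @param df1,df2 Numerator and denominator degrees of freedom.
#' @return `F * df1 / (F * df1 + df2)`, in [0, 1).
#' @export
partial_eta_sq <- function(F, df1, df2) {
  if (any(F < 0)) sf_spec_error("`F` must be non-negative")
  F * df1 / (F * df1 + df2)
}

#' 2x2 mixed ANOVA (one within-subject, one between-subject factor)
#'
#' Split-plot decomposition for two within-subject conditions and two
#' groups, computed explicitly from the subject mean and difference scores
#' rather than an opaque model fit. The between-subject stratum tests the
#' group effect against subjects-within-groups; the within stratum tests the
#' condition main effect (on the unweighted mean of the group difference
#' means, so unequal group sizes do not bias the marginal) and the
#' group-by-condition interaction against the condition-by-subject residual.
#' With equal group sizes this reproduces the classical balanced split-plot
#' table exactly.
#'
#' @param condition1,condition2 Per-subject scores under the two
#'   within-subject conditions (e.g. congruent and incongruent integration
#'   scores), equal length.
#' @param group Group label per subject (exactly two levels, >= 2 subjects
#'   each).
#' @return List of three results (`condition`, `group`, `interaction`), each
#'   with `F`, `df1`, `df2`, `p`, `partial_eta_sq`.
#' @export
mixed_anova_2x2 <- function(condition1, condition2, group) {
  n <- length(condition1)
  if (length(condition2) != n || length(group) != n) {
    sf_data_error("inputs must have equal length")
  }
  if (anyNA(condition1) || anyNA(condition2) || anyNA(group)) {
    sf_data_error("complete cases required")
  }
  group <- as.factor(as.character(group))
  if (nlevels(group) != 2) sf_data_error("`group` must have exactly 2 levels")
  ns <- table(group)
  if (any(ns < 2)) sf_stat_error("singular design: need >= 2 subjects per group")
  m <- (condition1 + condition2) / 2      # subject means (between stratum)
  d <- condition1 - condition2            # subject differences (within stratum)
  n1 <- ns[1]; n2 <- ns[2]
  g1 <- group == levels(group)[1]

  ## between-subject stratum
  mbar1 <- mean(m[g1]); mbar2 <- mean(m[!g1]); mbar <- mean(m)
  ss_group <- 2 * (n1 * (mbar1 - mbar)^2 + n2 * (mbar2 - mbar)^2)
  ss_subj <- 2 * (sum((m[g1] - mbar1)^2) + sum((m[!g1] - mbar2)^2))
  df2 <- n - 2

  ## within-subject stratum (computed on difference scores; SS reported in
  ## the observation metric, i.e. halved)
  dbar1 <- mean(d[g1]); dbar2 <- mean(d[!g1])
  ss_d_err <- sum((d[g1] - dbar1)^2) + sum((d[!g1] - dbar2)^2)
  ss_werr <- ss_d_err / 2
  inv_n <- 1 / as.numeric(n1) + 1 / as.numeric(n2)
  theta <- (dbar1 + dbar2) / 2            # unweighted condition contrast
  phi <- dbar1 - dbar2                    # interaction contrast
  ss_cond <- 2 * theta^2 / inv_n
  ss_int <- phi^2 / inv_n / 2

  ## a zero effect SS gives F = 0 even when the error SS is also zero
  ## (identical scores everywhere); a nonzero effect over a zero error SS is
  ## a singular design
  f_ratio <- function(ss_eff, ss_err) {
    if (ss_eff <= 1e-24) return(0)
    if (ss_err <= 1e-24) {
      sf_stat_error("singular design: zero error variance with nonzero effect")
    }
    (ss_eff / 1) / (ss_err / df2)
  }
  F_group <- f_ratio(ss_group, ss_subj)
  F_cond <- f_ratio(ss_cond, ss_werr)
  F_int <- f_ratio(ss_int, ss_werr)

  res <- function(F, ss_eff, ss_err) {
    list(F = unname(F), df1 = 1, df2 = df2,
         p = stats::pf(unname(F), 1, df2, lower.tail = FALSE),
         partial_eta_sq = partial_eta_sq(unname(F), 1, df2),
         ss_effect = unname(ss_eff), ss_error = unname(ss_err))
  }
  list(condition = res(F_cond, ss_cond, ss_werr),
       group = res(F_group, ss_group, ss_subj),
       interaction = res(F_int, ss_int, ss_werr))
}

#' Joint type-I error bound for a dual planned comparison
#'
#' Requiring both of two independent comparisons to be significant at level
#' `alpha` bounds the joint type-I error by `alpha^2`.
#'
#' @param alpha Per-comparison significance level in (0, 1].
#' @return `alpha^2`.
#' @export
dual_test_alpha <- function(alpha) {
  if (any(alpha <= 0 | alpha > 1)) sf_spec_error("`alpha` must be in (0, 1]")
  alpha^2
}
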