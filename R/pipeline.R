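# Pipeline orchestration: YAML config, simulate -> score -> test -> report,
# regression checks against the published summary statistics, and stimulus
# export.

#' Default pipeline configuration
#'
#' Nested list mirroring the YAML schema: `viewing` (distance_cm, iod_cm),
#' `display` (width_deg), `stimulus` (width_cm, depth_cm), `texture`
#' (grid_cm, jitter_cm), `dots` (grid_cm, jitter_cm), `design`
#' (trials_per_condition, standard_deg, delta_deg), `observer`
#' (criterion_deg, gate_k, lapse), `population` (sigma_median_deg,
#' sigma_gsd, cue_correlation), `groups` (per-group n and regime),
#' `analysis` (alpha), and `seed`.
#'
#' @return Named nested list of defaults.
#' @export
default_config <- function() {
  list(
    viewing = list(distance_cm = 175, iod_cm = 6.2),
    display = list(width_deg = 13),
    stimulus = list(width_cm = 16, depth_cm = 10),
    texture = list(grid_cm = 1, jitter_cm = 0.225),
    dots = list(grid_cm = 1, jitter_cm = 1.5),
    design = list(trials_per_condition = 30, standard_deg = 45,
                  delta_deg = 12.5),
    observer = list(criterion_deg = 6.25, gate_k = 2, lapse = 0),
    population = list(sigma_median_deg = 5, sigma_gsd = 1.3,
                      cue_correlation = 1),
    groups = list(ASD = list(n = 16, regime = "selective_fusion"),
                  TD = list(n = 14, regime = "mandatory_fusion")),
    analysis = list(alpha = 0.05),
    seed = 1L
  )
}

## Recursive merge of user config over defaults; unknown keys are a schema
## error carrying the offending field path.
merge_config <- function(base, user, path = character()) {
  for (key in names(user)) {
    here <- c(path, key)
    if (!key %in% names(base)) {
      sf_spec_error(paste0("unknown config field: ",
                           paste(here, collapse = ".")))
    }
    if (is.list(base[[key]]) && !identical(key, "groups")) {
      if (!is.list(user[[key]])) {
        sf_spec_error(paste0("config field must be a mapping: ",
                             paste(here, collapse = ".")))
      }
      base[[key]] <- merge_config(base[[key]], user[[key]], here)
    } else {
      base[[key]] <- user[[key]]
    }
  }
  base
}

#' Read and validate a YAML pipeline configuration
#'
#' Missing fields fall back to [default_config()]; unknown or malformed
#' fields raise a schema error naming the field path.
#'
#' @param path Path to a YAML file, or `NULL` for pure defaults.
#' @return Validated config list.
#' @export
read_config <- function(path = NULL) {
  cfg <- default_config()
  if (!is.null(path)) {
    if (!file.exists(path)) sf_spec_error(paste("config file not found:", path))
    user <- yaml::read_yaml(path)
    cfg <- merge_config(cfg, user)
  }
  for (g in names(cfg$groups)) {
    grp <- cfg$groups[[g]]
    if (is.null(grp$n) || is.null(grp$regime)) {
      sf_spec_error(paste0("config field groups.", g,
                           " must have `n` and `regime`"))
    }
    if (!grp$regime %in% REGIMES) {
      sf_spec_error(paste0("unknown regime in groups.", g, ".regime: ",
                           grp$regime))
    }
  }
  cfg
}

config_to_cohort_spec <- function(cfg) {
  n <- vapply(cfg$groups, function(g) as.numeric(g$n), numeric(1))
  regimes <- vapply(cfg$groups, function(g) g$regime, character(1))
  cohort_spec(
    n_per_group = n, regime_by_group = regimes,
    sigma_median = cfg$population$sigma_median_deg,
    sigma_gsd = cfg$population$sigma_gsd,
    cue_correlation = cfg$population$cue_correlation,
    trials_per_condition = cfg$design$trials_per_condition,
    standard = cfg$design$standard_deg, delta = cfg$design$delta_deg,
    criterion = cfg$observer$criterion_deg, gate_k = cfg$observer$gate_k,
    lapse = cfg$observer$lapse, seed = cfg$seed
  )
}

#' Simulate a full study to disk
#'
#' Generates the cohort, the blocked schedule and every subject's responses,
#' and writes `trials.csv`, `ground_truth.json` (per-subject noise SDs and
#' regimes, for recovery scoring) and `manifest.json` (config snapshot,
#' seed, package version, per-artifact MD5 checksums).
#'
#' @param config Config list from [read_config()] / [default_config()].
#' @param out_dir Output directory (created if needed).
#' @return Invisibly, a list with `trials`, `cohort`, `schedule`,
#'   `manifest`.
#' @export
pipeline_simulate <- function(config = default_config(), out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  spec <- config_to_cohort_spec(config)
  cohort <- generate_cohort(spec)
  schedule <- build_schedule(spec, seed = substream_seed(spec$seed, 1L))
  trials <- run_study(cohort, schedule)

  trials_path <- file.path(out_dir, "trials.csv")
  truth_path <- file.path(out_dir, "ground_truth.json")
  utils::write.csv(trials, trials_path, row.names = FALSE, quote = FALSE)
  jsonlite::write_json(
    list(subjects = cohort[c("subject_id", "group", "regime",
                             "sigma_T", "sigma_D")]),
    truth_path, dataframe = "rows", auto_unbox = TRUE, digits = NA
  )
  manifest <- list(
    package = "slantfuse",
    version = as.character(utils::packageVersion("slantfuse")),
    seed = spec$seed,
    config = config,
    n_trials = nrow(trials),
    artifacts = list(
      trials = list(path = "trials.csv",
                    md5 = unname(tools::md5sum(trials_path))),
      ground_truth = list(path = "ground_truth.json",
                          md5 = unname(tools::md5sum(truth_path)))
    )
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(list(trials = trials, cohort = cohort, schedule = schedule,
                 manifest = manifest))
}

read_trials <- function(path) {
  if (!file.exists(path)) sf_data_error(paste("trial table not found:", path))
  tr <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("subject_id", "group", "condition", "trial", "truth", "response")
  miss <- setdiff(need, names(tr))
  if (length(miss)) {
    sf_data_error(paste("trial table missing column(s):",
                        paste(miss, collapse = ", ")))
  }
  bad <- which(!tr$truth %in% c("same", "different") |
                 !tr$response %in% c("same", "different") |
                 !tr$condition %in% CONDITIONS)
  if (length(bad)) {
    sf_data_error(sprintf("malformed trial rows (first few): %s",
                          paste(utils::head(bad, 5), collapse = ", ")))
  }
  tr
}

#' Analyse a trial table
#'
#' Scores each subject into per-condition d-primes, applies the single-cue
#' exclusion rule, computes integration and single-cue difference scores,
#' classifies each group's fusion pattern from the planned comparisons, and
#' (with two groups) runs the 2x2 mixed ANOVA on the integration scores.
#'
#' @param trials Trial-table data.frame or path to a CSV with columns
#'   `subject_id, group, condition, trial, truth, response`.
#' @param alpha Significance level for all planned comparisons.
#' @param out_dir If non-NULL, writes `scores.csv` and `results.json` there.
#' @return List with `scores`, `excluded`, `integration`, `cue_differences`,
#'   `classification` (per group), `anova` (or NULL), `condition_means`.
#' @export
pipeline_analyze <- function(trials, alpha = 0.05, out_dir = NULL) {
  if (is.character(trials)) trials <- read_trials(trials)
  scores <- score_cohort(trials)
  excl <- apply_exclusions(scores)
  retained <- excl$retained
  if (nrow(retained) < 2) sf_data_error("fewer than 2 subjects retained")
  integ <- integration_scores(retained)
  diffs <- cue_difference_scores(retained)
  groups <- unique(retained$group)
  classification <- lapply(stats::setNames(groups, groups), function(g) {
    classify_fusion_pattern(retained[retained$group == g, , drop = FALSE],
                            alpha = alpha)
  })
  anova <- NULL
  if (length(groups) == 2 && all(table(retained$group) >= 2)) {
    anova <- mixed_anova_2x2(integ$congruent, integ$incongruent, integ$group)
  }
  cond_cols <- intersect(CONDITIONS, names(retained))
  condition_means <- do.call(rbind, lapply(groups, function(g) {
    sub <- retained[retained$group == g, cond_cols, drop = FALSE]
    data.frame(group = g, condition = cond_cols,
               mean = colMeans(sub),
               se = apply(sub, 2, stats::sd) / sqrt(nrow(sub)),
               n = nrow(sub), stringsAsFactors = FALSE)
  }))
  rownames(condition_means) <- NULL
  res <- list(scores = scores, excluded = excl$excluded,
              integration = integ, cue_differences = diffs,
              classification = classification, anova = anova,
              condition_means = condition_means, alpha = alpha)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    utils::write.csv(scores, file.path(out_dir, "scores.csv"),
                     row.names = FALSE, quote = FALSE)
    json <- list(
      alpha = alpha,
      excluded = excl$excluded,
      classification = lapply(classification, function(cl) {
        list(pattern = cl$pattern, congruent = cl$congruent,
             incongruent = cl$incongruent, tests = cl$tests)
      }),
      anova = anova,
      condition_means = condition_means,
      integration_means = lapply(stats::setNames(groups, groups), function(g) {
        sub <- integ[integ$group == g, ]
        list(congruent = mean(sub$congruent),
             incongruent = mean(sub$incongruent))
      })
    )
    jsonlite::write_json(json, file.path(out_dir, "results.json"),
                         dataframe = "rows", auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
  }
  res
}

#' Regression checks of the published summary statistics
#'
#' Recomputes every recomputable printed statistic of the study being
#' emulated from its printed inputs (t and n for Cohen's d; F and df for
#' partial eta squared; group means/SDs/sizes for the pooled two-sample
#' t-tests; the per-comparison alpha for the dual-test bound) and compares
#' each with the printed value at printed-precision tolerance. Rows flagged
#' `reproducible = FALSE` are statistics documented as internally
#' inconsistent in the source; they are reported but not required to match.
#'
#' @return Data.frame with one row per check: `id`, `type`, `computed`,
#'   `printed`, `tolerance`, `reproducible`, `pass`.
#' @export
paper_checks <- function() {
  path <- system.file("extdata", "reported-statistics.csv",
                      package = "slantfuse")
  fx <- utils::read.csv(path, stringsAsFactors = FALSE)
  fx$computed <- NA_real_
  for (i in seq_len(nrow(fx))) {
    fx$computed[i] <- switch(fx$type[i],
      cohens_d = cohens_d_from_t(fx$p1[i], fx$p2[i]),
      partial_eta_sq = partial_eta_sq(fx$p1[i], fx$p2[i], fx$p3[i]),
      pooled_t = abs(two_sample_pooled_t(
        m1 = fx$p1[i], sd1 = fx$p2[i], n1 = fx$p3[i],
        m2 = fx$p4[i], sd2 = fx$p5[i], n2 = fx$p6[i])$t),
      dual_alpha = dual_test_alpha(fx$p1[i]),
      sf_spec_error(paste("unknown check type:", fx$type[i]))
    )
  }
  fx$pass <- abs(fx$computed - fx$printed) <= fx$tolerance + 1e-9
  fx[c("id", "type", "computed", "printed", "tolerance",
       "reproducible", "pass")]
}

#' Build and optionally export one stimulus pair
#'
#' Constructs the standard and comparison discs for a condition (standard on
#' a random side), generates the appropriate surface pattern (Voronoi tiles
#' for texture-bearing conditions, uniform screen-density dots for
#' disparity-only conditions) and computes the two-eye projections.
#'
#' @param condition Condition code.
#' @param truth `"different"` (default) or `"same"`.
#' @param geometry A [viewing_geometry()].
#' @param seed Integer seed for pattern jitter and layout randomisation.
#' @param standard,delta Standard slant and increment (degrees).
#' @param depth_cm Magnitude of the disc depth offsets (cm); each disc's sign
#'   is drawn at random.
#' @return List of class `stimulus_pair` with `condition`, `truth`,
#'   `standard`, `comparison` (each a `conflict_projection`), and
#'   `monocular_eye` (`"left"` for texture-only conditions, else NA).
#' @export
stimulus_pair <- function(condition, truth = "different",
                          geometry = viewing_geometry(), seed = NULL,
                          standard = 45, delta = 12.5, depth_cm = 10) {
  stim <- trial_stimulus(condition, truth, standard, delta)
  with_seed(seed, {
    sides <- sample(c("left", "right"))
    signs <- sample(c(-1, 1), 2, replace = TRUE)
    build <- function(slant_T, slant_D, side, sign) {
      sp <- plane_spec(slant_texture_deg = slant_T,
                       slant_disparity_deg = slant_D,
                       depth_offset_cm = sign * depth_cm, side = side)
      if ("T" %in% stim$cues) {
        pat <- make_texture_tiles(sp)
      } else {
        pat <- make_dot_pattern(sp, geometry)
      }
      project_conflict_stimulus(sp, pat, geometry)
    }
    # single-cue conditions: the unused cue is slaved to the carried cue so
    # the physical object is a single coherent plane
    st_T <- stim$texture_standard; st_D <- stim$disparity_standard
    cm_T <- stim$texture_comparison; cm_D <- stim$disparity_comparison
    if (!"T" %in% stim$cues) { st_T <- st_D; cm_T <- cm_D }
    if (!"D" %in% stim$cues) { st_D <- st_T; cm_D <- cm_T }
    structure(
      list(condition = condition, truth = truth,
           standard = build(st_T, st_D, sides[1], signs[1]),
           comparison = build(cm_T, cm_D, sides[2], signs[2]),
           monocular_eye = if (identical(stim$cues, "T")) "left" else NA),
      class = "stimulus_pair"
    )
  })
}

#' Export a stimulus pair as JSON
#'
#' One document per pair: condition, plane specifications and per-eye vertex
#' or dot arrays for both discs.
#'
#' @param pair A [stimulus_pair()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
export_stimulus_json <- function(pair, path) {
  disc_doc <- function(pr) {
    list(spec = unclass(pr$spec), kind = pr$kind, element = pr$element,
         left = pr$left, right = pr$right, cyclopean = pr$cyclopean)
  }
  doc <- list(condition = pair$condition, truth = pair$truth,
              monocular_eye = pair$monocular_eye,
              standard = disc_doc(pair$standard),
              comparison = disc_doc(pair$comparison))
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = 9,
                       matrix = "rowmajor")
  invisible(path)
}

#' Render one eye's view of a stimulus pair as SVG
#'
#' Minimal schematic rendering (tile outlines or dots), mainly for visual
#' sanity checks of exported geometry.
#'
#' @param pair A [stimulus_pair()].
#' @param path Output file path.
#' @param eye `"left"`, `"right"` or `"cyclopean"`.
#' @return `path`, invisibly.
#' @export
write_stimulus_svg <- function(pair, path, eye = c("left", "right",
                                                   "cyclopean")) {
  eye <- match.arg(eye)
  discs <- list(pair$standard, pair$comparison)
  all_xy <- do.call(rbind, lapply(discs, function(d) d[[eye]]))
  pad <- 1
  x0 <- min(all_xy[, 1]) - pad; x1 <- max(all_xy[, 1]) + pad
  y0 <- min(all_xy[, 2]) - pad; y1 <- max(all_xy[, 2]) + pad
  scale <- 20  # px per cm
  w <- (x1 - x0) * scale; h <- (y1 - y0) * scale
  tx <- function(x) (x - x0) * scale
  ty <- function(y) (y1 - y) * scale   # flip: SVG y grows downward
  lines <- c(sprintf(
    '<svg xmlns="http://www.w3.org/2000/svg" width="%.0f" height="%.0f" viewBox="0 0 %.0f %.0f">',
    w, h, w, h),
    sprintf('<rect width="%.0f" height="%.0f" fill="white"/>', w, h))
  for (d in discs) {
    xy <- d[[eye]]
    if (d$kind == "dots") {
      lines <- c(lines, sprintf(
        '<circle cx="%.2f" cy="%.2f" r="1.5" fill="black"/>',
        tx(xy[, 1]), ty(xy[, 2])))
    } else {
      for (el in unique(d$element)) {
        v <- xy[d$element == el, , drop = FALSE]
        pts <- paste(sprintf("%.2f,%.2f", tx(v[, 1]), ty(v[, 2])),
                     collapse = " ")
        lines <- c(lines, sprintf(
          '<polygon points="%s" fill="none" stroke="black" stroke-width="0.5"/>',
          pts))
      }
    }
  }
  writeLines(c(lines, "</svg>"), path)
  invisible(path)
}

#' Bar chart of per-condition group means with SE whiskers
#'
#' @param condition_means The `condition_means` table from
#'   [pipeline_analyze()].
#' @return Invisibly, the bar midpoints.
#' @export
plot_condition_means <- function(condition_means) {
  groups <- unique(condition_means$group)
  conds <- intersect(ANALYZED_CONDITIONS, unique(condition_means$condition))
  m <- sapply(groups, function(g) {
    sub <- condition_means[condition_means$group == g, ]
    sub$mean[match(conds, sub$condition)]
  })
  s <- sapply(groups, function(g) {
    sub <- condition_means[condition_means$group == g, ]
    sub$se[match(conds, sub$condition)]
  })
  old <- graphics::par(mfrow = c(1, length(groups)))
  on.exit(graphics::par(old))
  mids <- lapply(seq_along(groups), function(i) {
    b <- graphics::barplot(m[, i], names.arg = conds, ylim = c(0, max(m + s) * 1.15),
                           main = groups[i], ylab = "d'")
    graphics::arrows(b, m[, i] - s[, i], b, m[, i] + s[, i],
                     angle = 90, code = 3, length = 0.04)
    b
  })
  invisible(mids)
}
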