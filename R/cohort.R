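#' Cohort specification for the synthetic study generator
#'
#' Defines the statistical structure of a simulated surveillance cohort:
#' three outcome groups (A = no rejection / no treatment change, B = mild
#' rejection / augmented maintenance therapy, C = rejection / new
#' treatment), a per-case baseline native T1, additive group T1 shifts,
#' focal hotspots for rejection cases, graft-dysfunction marker columns
#' calibrated to a target correlation with realized peak T1, and a biopsy
#' fibrosis percentage drawn independently of group.
#'
#' The default group fractions (0.74 / 0.12 / 0.14) mirror a 50-case
#' surveillance cohort with 37 / 6 / 7 cases per group. Baseline T1 is
#' drawn from N(`baseline_t1_mean`, `baseline_t1_sd`), by default centered
#' in the 900-1050 ms normal range. Group shifts and hotspot parameters are
#' calibration choices of the generator (see the package vignette).
#'
#' @param n_cases number of cases (>= 3).
#' @param group_fractions named fractions for groups A, B, C; must sum to 1.
#' @param group_t1_shift ms added to baseline T1 per group (A, B, C).
#' @param hotspot_rate expected hotspot count per group; B/C cases always
#'   receive at least one hotspot when their rate is positive.
#' @param marker_correlation target Pearson |r| between peak T1 and each
#'   marker column.
#' @param fibrosis_mean,fibrosis_sd percent fibrosis distribution
#'   (independent of group).
#' @param baseline_t1_mean,baseline_t1_sd per-case baseline T1 (ms).
#' @param hotspot_delta_range,hotspot_width_range uniform ranges for
#'   hotspot T1 elevation (ms) and angular width (degrees).
#' @param seed integer master seed; all randomness derives from it.
#' @return A `cohort_spec`.
#' @export
cohort_spec <- function(n_cases = 50L,
                        group_fractions = c(A = 0.74, B = 0.12, C = 0.14),
                        group_t1_shift = c(A = 0, B = 40, C = 80),
                        hotspot_rate = c(A = 0, B = 1.5, C = 2.5),
                        marker_correlation = 0.45,
                        fibrosis_mean = 7.6, fibrosis_sd = 4.5,
                        baseline_t1_mean = 975, baseline_t1_sd = 25,
                        hotspot_delta_range = c(120, 250),
                        hotspot_width_range = c(50, 90),
                        seed = 1L) {
  if (n_cases < 3L) stop("n_cases must be >= 3")
  if (any(group_fractions < 0)) stop("group fractions must be nonnegative")
  if (abs(sum(group_fractions) - 1) > 1e-9) stop("group fractions must sum to 1")
  if (length(group_fractions) != 3L) stop("need fractions for groups A, B, C")
  structure(list(n_cases = as.integer(n_cases),
                 group_fractions = group_fractions,
                 group_t1_shift = group_t1_shift,
                 hotspot_rate = hotspot_rate,
                 marker_correlation = marker_correlation,
                 fibrosis_mean = fibrosis_mean, fibrosis_sd = fibrosis_sd,
                 baseline_t1_mean = baseline_t1_mean,
                 baseline_t1_sd = baseline_t1_sd,
                 hotspot_delta_range = hotspot_delta_range,
                 hotspot_width_range = hotspot_width_range,
                 seed = as.integer(seed)),
            class = "cohort_spec")
}

#' Graft-dysfunction marker definitions
#'
#' The marker columns generated for each case, with plausible population
#' means/SDs and the sign of their association with peak T1 (positive for
#' filling pressures and BNP, negative for ejection fraction and
#' volumes). Units: BNP pg/mL, LVEF %, pressures mmHg, volumes mL.
#'
#' @return Data frame with columns `name`, `mean`, `sd`, `sign`,
#'   `truncate_at`.
#' @export
marker_definitions <- function() {
  data.frame(
    name = c("bnp", "lvef", "mitral_e_over_eprime", "ra_mean",
             "rv_systolic", "rvedp", "pa_mean", "wedge", "lvedv", "rvedv"),
    mean = c(800, 63, 8, 10, 28, 11, 18, 12, 110, 100),
    sd   = c(600, 5, 2, 4, 5, 4, 5, 5, 30, 30),
    sign = c(1, -1, -1, 1, 1, 1, 1, 1, -1, -1),
    truncate_at = c(5, NA, NA, NA, NA, NA, NA, NA, NA, NA),
    stringsAsFactors = FALSE)
}

# Per-group biopsy grade probabilities (rows: grades 0R/1R/2R). Group A is
# mostly 0R with occasional 1R; group B mostly 1R; group C 1R with some 2R.
grade_probs <- function() {
  cbind(A = c("0R" = 0.84, "1R" = 0.16, "2R" = 0),
        B = c("0R" = 0.30, "1R" = 0.70, "2R" = 0),
        C = c("0R" = 0,    "1R" = 5 / 7, "2R" = 2 / 7))
}

#' Generate a synthetic study cohort
#'
#' Draws group labels per the spec fractions, simulates one T1 study per
#' case ([generate_t1_study()]) with a case-specific baseline (baseline +
#' group shift) and, for rejection cases, focal hotspots (the first hotspot
#' is always placed on the texture analysis slice), quantifies mean/peak T1
#' through the segmental pipeline, then generates marker columns as linear
#' functions of realized peak T1 plus Gaussian noise calibrated to the
#' target correlation, biopsy grades from per-group probabilities, and a
#' fibrosis percentage independent of group. Fully reproducible from
#' `spec$seed`.
#'
#' @param spec a [cohort_spec()].
#' @param config a [phantom_config()] shared by all cases.
#' @param keep_studies return the generated image stacks (default TRUE;
#'   set FALSE for large-n statistical simulations).
#' @param markers generate the marker columns (default TRUE).
#' @return List: `table` (cohort data frame: case_id, group, biopsy_grade,
#'   baseline_t1, n_hotspots, mean_t1, peak_t1, n_abnormal, fibrosis
#'   percent, markers), `studies` (list of `t1_study` or NULL), `spec`,
#'   `config`, `hotspots` (per-case hotspot lists).
#' @export
generate_cohort <- function(spec, config = phantom_config(),
                            keep_studies = TRUE, markers = TRUE) {
  stopifnot(inherits(spec, "cohort_spec"), inherits(config, "phantom_config"))
  n <- spec$n_cases
  defs <- marker_definitions()
  tex_slice <- which(slice_levels(config$n_slices) == "mid")[1]
  analyzed <- which(slice_levels(config$n_slices) != "excluded")

  draws <- with_seed(spec$seed, {
    group <- sample(c("A", "B", "C"), n, replace = TRUE,
                    prob = spec$group_fractions)
    baseline <- rnorm(n, spec$baseline_t1_mean, spec$baseline_t1_sd) +
      unname(spec$group_t1_shift[group])
    gp <- grade_probs()
    grade <- vapply(group, function(g) {
      sample(rownames(gp), 1, prob = gp[, g])
    }, character(1), USE.NAMES = FALSE)
    n_hot <- vapply(group, function(g) {
      r <- spec$hotspot_rate[[g]]
      if (r <= 0) 0L else max(1L, rpois(1, r))
    }, integer(1), USE.NAMES = FALSE)
    hotspots <- vector("list", n)
    for (i in seq_len(n)) {
      if (n_hot[i] == 0L) { hotspots[[i]] <- rep(list(list()), config$n_slices); next }
      per_slice <- rep(list(list()), config$n_slices)
      slice_of <- c(tex_slice,
                    sample(analyzed, n_hot[i] - 1L, replace = TRUE))
      for (h in seq_len(n_hot[i])) {
        hs <- hotspot_spec(
          center_angle = runif(1, 0, 360),
          angular_width = runif(1, spec$hotspot_width_range[1],
                                spec$hotspot_width_range[2]),
          radial_span = runif(1, 0.6, 1),
          delta_t1 = runif(1, spec$hotspot_delta_range[1],
                           spec$hotspot_delta_range[2]))
        s <- slice_of[h]
        per_slice[[s]] <- c(per_slice[[s]], list(hs))
      }
      hotspots[[i]] <- per_slice
    }
    fibrosis <- pmax(0.2, rnorm(n, spec$fibrosis_mean, spec$fibrosis_sd))
    case_seeds <- sample.int(.Machine$integer.max - 1L, n)
    eps <- matrix(rnorm(n * nrow(defs)), n, nrow(defs))
    list(group = group, baseline = baseline, grade = grade, n_hot = n_hot,
         hotspots = hotspots, fibrosis = fibrosis, case_seeds = case_seeds,
         eps = eps)
  })

  if (length(unique(draws$group)) < 3L) {
    warning("n_cases too small to realize all three groups; proceeding")
  }

  rois <- NULL
  studies <- if (keep_studies) vector("list", n) else NULL
  mean_t1 <- peak_t1 <- numeric(n)
  n_abn <- integer(n)
  for (i in seq_len(n)) {
    cfg_i <- config
    cfg_i$baseline_t1 <- draws$baseline[i]
    study <- generate_t1_study(cfg_i, draws$hotspots[[i]],
                               seed = draws$case_seeds[i],
                               case_id = sprintf("case_%02d", i))
    if (is.null(rois)) rois <- study_rois(study, cfg_i)
    seg <- segmental_t1(study, rois)
    mean_t1[i] <- seg$global_mean_t1
    peak_t1[i] <- seg$peak_t1
    n_abn[i] <- seg$n_abnormal
    if (keep_studies) studies[[i]] <- study
  }

  tab <- data.frame(case_id = sprintf("case_%02d", seq_len(n)),
                    group = draws$group, biopsy_grade = draws$grade,
                    baseline_t1 = draws$baseline, n_hotspots = draws$n_hot,
                    mean_t1 = mean_t1, peak_t1 = peak_t1,
                    n_abnormal = n_abn,
                    fibrosis_percent = draws$fibrosis,
                    stringsAsFactors = FALSE)
  if (markers) {
    z <- if (sd(peak_t1) > 0) (peak_t1 - mean(peak_t1)) / sd(peak_t1)
         else rep(0, n)
    r <- spec$marker_correlation
    for (m in seq_len(nrow(defs))) {
      val <- defs$mean[m] + defs$sign[m] * r * defs$sd[m] * z +
        defs$sd[m] * sqrt(1 - r^2) * draws$eps[, m]
      if (!is.na(defs$truncate_at[m])) val <- pmax(defs$truncate_at[m], val)
      tab[[defs$name[m]]] <- val
    }
  }
  list(table = tab, studies = studies, spec = spec, config = config,
       hotspots = draws$hotspots)
}
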