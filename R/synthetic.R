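#' Default microRNA panel names
#'
#' Synthetic stand-in names for a cardiovascular-disease qPCR array panel.
#'
#' @param n_mirs Panel size. Default 84.
#' @return Character vector of microRNA names.
#' @export
mir_panel <- function(n_mirs = 84) {
  sprintf("miR-sim-%03d", seq_len(n_mirs))
}

#' Assay annotation for a synthetic Ct panel
#'
#' Targets plus the control assays used by the two normalization stages: an
#' array-control panel (screening) and SNORD61 + cel-miR-39 (validation).
#'
#' @param panel Character vector of target microRNA names.
#' @param n_array_controls Number of array-control assays. Default 4.
#' @return Data frame with columns `assay`, `role`.
#' @export
assay_annotation <- function(panel, n_array_controls = 4) {
  data.frame(
    assay = c(panel, sprintf("array-ctrl-%d", seq_len(n_array_controls)),
              "SNORD61", "cel-miR-39"),
    role = c(rep("target", length(panel)),
             rep("array_control", n_array_controls), "snord61", "cel_mir_39"),
    stringsAsFactors = FALSE)
}

#' Configuration for the synthetic cohort generator
#'
#' Defaults emulate a cohort of postmenopausal overweight/obese women with
#' device-measured sitting behavior: age truncated normal centered at 65.9
#' (SD 6.6, minimum 55), BMI centered at 32.8 (SD 5.0, minimum 25), waist
#' correlated with BMI, physical functioning (0-100) negatively correlated
#' with the latent sitting propensity, about a third Hispanic, three parent
#' studies. Per-person mean sitting bout duration is lognormal centered near
#' 39 min with spread covering roughly 25-64 min between the extreme
#' quartiles.
#'
#' @param n_participants Cohort size (at least 8).
#' @param n_days Accelerometer days per participant. Default 7.
#' @param n_mirs Target panel size. Default 84.
#' @param true_effect_mirs Named numeric vector: per-microRNA effect size,
#'   expressed as the expected log2-expression difference between the top and
#'   bottom latent-sitting-propensity quartile groups (internally a linear
#'   shift per unit latent propensity). Empty = null cohort.
#' @param confounding_strength Shared path coefficient from the covariate
#'   score (age/BMI composite) into both the latent sitting propensity and
#'   log2 expression; 0 disables confounding. The default 0.2 yields
#'   age/BMI contrasts between the extreme sitting-pattern groups of roughly
#'   0.3-0.4 pooled SD.
#' @param bout_meanlog,bout_sdlog Population lognormal of per-person mean
#'   sitting bout duration (minutes). Defaults `log(39)` and 0.45.
#' @param bout_sdlog_within Within-person lognormal spread of individual bout
#'   durations. Default 0.75.
#' @param mvpa_meanlog,mvpa_sdlog Population lognormal of per-person daily
#'   MVPA minutes. Defaults `log(15.5)` and 1.18.
#' @param sit_fraction Baseline fraction of wear time spent sitting. Default
#'   0.67.
#' @param hispanic_fraction Proportion Hispanic. Default 0.34.
#' @param missing_rate MCAR missingness applied to waist circumference and
#'   physical functioning. Default 0.03.
#' @param expr_noise_sd SD of log2-expression noise. Default 0.5.
#' @param wear_short_prob Probability that a day has a short (non-adherent,
#'   under 10 h) wear window, so device wear days vary across participants.
#'   Default 0.12.
#' @param nonwear_minutes Length of an all-zero non-wear run injected into
#'   each day's wear window (0 = none). Default 0.
#' @param nd_cap Ct value above which an assay is reported not-detected
#'   (`Inf` = never). Default `Inf`.
#' @param seed Integer seed.
#' @return A validated list of class `"cohort_config"`.
#' @export
cohort_config <- function(n_participants,
                          n_days = 7,
                          n_mirs = 84,
                          true_effect_mirs = numeric(0),
                          confounding_strength = 0.2,
                          bout_meanlog = log(39),
                          bout_sdlog = 0.45,
                          bout_sdlog_within = 0.75,
                          mvpa_meanlog = log(15.5),
                          mvpa_sdlog = 1.18,
                          sit_fraction = 0.67,
                          hispanic_fraction = 0.34,
                          missing_rate = 0.03,
                          expr_noise_sd = 0.5,
                          wear_short_prob = 0.12,
                          nonwear_minutes = 0,
                          nd_cap = Inf,
                          seed = 1L) {
  cfg <- as.list(environment())
  bad <- function(field, msg) {
    stop("invalid config field `", field, "`: ", msg, call. = FALSE)
  }
  if (!is.numeric(n_participants) || n_participants < 8) {
    bad("n_participants", "must be at least 8 (quartiles must be formable)")
  }
  if (n_days < 1) bad("n_days", "must be positive")
  if (n_mirs < 1) bad("n_mirs", "must be positive")
  panel <- mir_panel(n_mirs)
  if (length(true_effect_mirs)) {
    if (is.null(names(true_effect_mirs)) || any(!nzchar(names(true_effect_mirs)))) {
      bad("true_effect_mirs", "must be a named numeric vector")
    }
    outside <- setdiff(names(true_effect_mirs), panel)
    if (length(outside)) {
      bad("true_effect_mirs",
          paste("not in the panel:", paste(outside, collapse = ", ")))
    }
  }
  for (f in c("hispanic_fraction", "missing_rate")) {
    v <- cfg[[f]]
    if (!is.numeric(v) || v < 0 || v > 1) bad(f, "must be in [0, 1]")
  }
  if (sit_fraction <= 0 || sit_fraction >= 1) {
    bad("sit_fraction", "must be in (0, 1)")
  }
  if (confounding_strength < 0 || confounding_strength >= 1) {
    bad("confounding_strength", "must be in [0, 1)")
  }
  if (expr_noise_sd < 0) bad("expr_noise_sd", "must be nonnegative")
  if (wear_short_prob < 0 || wear_short_prob > 1) {
    bad("wear_short_prob", "must be in [0, 1]")
  }
  if (nonwear_minutes < 0) bad("nonwear_minutes", "must be nonnegative")
  cfg$panel <- panel
  class(cfg) <- "cohort_config"
  cfg
}

# expected gap E[Z | Z > q3] - E[Z | Z < q1] for a standard normal; converts a
# quartile-contrast effect size to a per-unit-propensity slope
.quartile_contrast <- function() 2 * stats::dnorm(stats::qnorm(0.75)) / 0.25

# truncated-normal draws by inverse-CDF on the admissible tail; `mean` is the
# target mean AFTER truncation (the location parameter is calibrated so the
# generated sample matches the configured population mean)
rtruncnorm_min <- function(n, mean, sd, min) {
  trunc_mean <- function(mu) {
    a <- (min - mu) / sd
    mu + sd * stats::dnorm(a) / (1 - stats::pnorm(a))
  }
  mu <- stats::uniroot(function(m) trunc_mean(m) - mean,
                       lower = mean - 4 * sd, upper = mean + sd,
                       tol = 1e-10)$root
  p0 <- stats::pnorm(min, mu, sd)
  stats::qnorm(stats::runif(n, p0, 1), mu, sd)
}

#' Generate a synthetic participant cohort
#'
#' Draws covariates (age, BMI, waist circumference, physical functioning,
#' Hispanic indicator, parent study) together with a latent sitting propensity
#' that is partially driven by the covariate score (confounding) and in turn
#' drives the per-person mean sitting bout duration, the sitting fraction and
#' physical functioning. The ground truth needed for parameter-recovery tests
#' is returned alongside and is never consumed by the analysis modules.
#'
#' @param config A [cohort_config()].
#' @return List with `covariates` (data frame, one row per participant, with
#'   MCAR missingness applied to waist and physical functioning) and `truth`
#'   (list: latent propensity `z`, covariate score, per-person behavioral
#'   parameters, complete pre-missingness covariates, per-microRNA effects).
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(config$seed)
  n <- config$n_participants

  id <- sprintf("P%04d", seq_len(n))
  age <- rtruncnorm_min(n, 65.9, 6.6, 55)
  bmi <- rtruncnorm_min(n, 32.8, 5.0, 25)
  waist <- 101.4 + 2.5 * (bmi - 32.8) + stats::rnorm(n, 0, 9.8)
  hispanic <- stats::rbinom(n, 1, config$hispanic_fraction)
  parent_study <- sample(c("CoM", "RFH", "MENU"), n, replace = TRUE,
                         prob = c(0.30, 0.59, 0.11))

  cscore <- as.numeric(scale(scale(age) + scale(bmi)))
  cs <- config$confounding_strength
  z <- cs * cscore + sqrt(1 - cs^2) * stats::rnorm(n)

  # coupling sized so extreme propensity quartiles differ by ~18 points
  # (about 0.7 pooled SD), with overall SD near 29
  phys_func <- pmin(100, pmax(0, 61.2 - 7 * z + stats::rnorm(n, 0, 28)))
  bout_mean_true <- exp(config$bout_meanlog + config$bout_sdlog * z)
  mvpa_true <- exp(config$mvpa_meanlog + config$mvpa_sdlog * stats::rnorm(n))
  walking_true <- exp(log(30) + 0.5 * stats::rnorm(n))
  sit_fraction_true <- stats::plogis(stats::qlogis(config$sit_fraction) +
                                       0.25 * z)

  complete <- data.frame(participant_id = id, age = age, bmi = bmi,
                         waist = waist, phys_func = phys_func,
                         hispanic = hispanic, parent_study = parent_study,
                         stringsAsFactors = FALSE)
  covariates <- complete
  if (config$missing_rate > 0) {
    for (v in c("waist", "phys_func")) {
      drop <- stats::runif(n) < config$missing_rate
      covariates[[v]][drop] <- NA_real_
    }
  }

  effects <- stats::setNames(numeric(config$n_mirs), config$panel)
  if (length(config$true_effect_mirs)) {
    effects[names(config$true_effect_mirs)] <- config$true_effect_mirs
  }

  list(covariates = covariates,
       truth = list(z = stats::setNames(z, id),
                    covariate_score = stats::setNames(cscore, id),
                    bout_mean_true = stats::setNames(bout_mean_true, id),
                    mvpa_true = stats::setNames(mvpa_true, id),
                    walking_true = stats::setNames(walking_true, id),
                    sit_fraction_true = stats::setNames(sit_fraction_true, id),
                    covariates_complete = complete,
                    mir_effects_log2 = effects,
                    quartile_contrast = .quartile_contrast()))
}

#' Generate minute-epoch activity records
#'
#' For each participant and day, builds a wear window of roughly 14-16 hours
#' as an alternating renewal process of sitting and non-sitting bouts. Sitting
#' bout durations are lognormal around the participant's true mean bout
#' duration; non-sitting minutes are partitioned into standing, daily-life
#' movement, walking and MVPA according to the participant's true daily
#' targets. Counts are drawn per posture class: sitting/standing 0-99 cpm,
#' daily movement 100-759, walking 760-1951, MVPA 1952-5000. Minutes outside
#' the wear window have zero counts; an optional all-zero non-wear run can be
#' injected inside the window.
#'
#' @param cohort Output of [generate_cohort()] (or a list with `covariates`
#'   and `truth` carrying `bout_mean_true`, `mvpa_true`, `walking_true`,
#'   `sit_fraction_true`).
#' @param config The [cohort_config()] used to generate the cohort.
#' @return Data frame of minute epochs: `participant_id`, `day_index`,
#'   `minute_index`, `counts`, `posture`.
#' @export
generate_activity <- function(cohort, config) {
  stopifnot(inherits(config, "cohort_config"))
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(config$seed + 1L)

  ids <- cohort$covariates$participant_id
  tr <- cohort$truth
  n_days <- config$n_days
  sw <- config$bout_sdlog_within
  day_len <- 1440L

  res_counts <- vector("list", length(ids) * n_days)
  res_posture <- vector("list", length(ids) * n_days)
  k <- 0L
  for (i in seq_along(ids)) {
    m_sit <- unname(tr$bout_mean_true[i])
    s_frac <- unname(tr$sit_fraction_true[i])
    m_non <- m_sit * (1 - s_frac) / s_frac
    for (d in seq_len(n_days)) {
      k <- k + 1L
      start <- round(stats::runif(1, 360, 420))
      if (stats::runif(1) < config$wear_short_prob) {
        len <- round(stats::runif(1, 330, 570))  # non-adherent day (< 10 h)
      } else {
        len <- round(stats::rnorm(1, 900, 30))
        len <- max(810L, min(len, day_len - start - 95L))
      }

      # alternating sitting / non-sitting bouts filling the wear window
      n_guess <- ceiling(len / (m_sit + m_non) * 3) + 10L
      repeat {
        sit_len <- pmax(1L, round(stats::rlnorm(n_guess,
                                                log(m_sit) - sw^2 / 2, sw)))
        non_len <- pmax(1L, round(stats::rlnorm(n_guess,
                                                log(m_non) - sw^2 / 2, sw)))
        lens <- as.vector(rbind(sit_len, non_len))
        is_sit <- rep(c(TRUE, FALSE), n_guess)
        if (stats::runif(1) < 0.5) {  # start the day standing half the time
          lens <- lens[-1L]; is_sit <- is_sit[-1L]
        }
        if (sum(lens) >= len) break
        n_guess <- n_guess * 2L
      }
      cum <- cumsum(lens)
      last <- which(cum >= len)[1L]
      lens <- lens[seq_len(last)]
      lens[last] <- lens[last] - (cum[last] - len)
      is_sit <- is_sit[seq_len(last)]
      keep <- lens > 0L
      lens <- lens[keep]; is_sit <- is_sit[keep]

      sit_min <- rep(is_sit, lens)
      n_non <- sum(!sit_min)
      posture <- character(len)
      posture[sit_min] <- "sit"
      if (n_non > 0L) {
        mvpa_t <- unname(tr$mvpa_true[i])
        walk_t <- unname(tr$walking_true[i])
        other <- max(n_non - mvpa_t - walk_t, 1)
        pr <- c(stand = 0.6 * other, move = 0.4 * other,
                walk = walk_t, mvpa = mvpa_t)
        cls <- sample(names(pr), n_non, replace = TRUE, prob = pr / sum(pr))
        posture[!sit_min] <- ifelse(cls == "mvpa", "walk", cls)
        counts_non <- integer(n_non)
        counts_non[cls == "stand"] <- sample(0:99, sum(cls == "stand"), TRUE)
        counts_non[cls == "move"] <- sample(100:759, sum(cls == "move"), TRUE)
        counts_non[cls == "walk"] <- sample(760:1951, sum(cls == "walk"), TRUE)
        counts_non[cls == "mvpa"] <- sample(1952:5000, sum(cls == "mvpa"), TRUE)
      }
      counts <- integer(len)
      counts[sit_min] <- sample(0:99, sum(sit_min), TRUE)
      if (n_non > 0L) counts[!sit_min] <- counts_non

      day_counts <- integer(day_len)
      day_posture <- rep("stand", day_len)
      span <- (start + 1L):(start + len)
      day_counts[span] <- counts
      day_posture[span] <- posture
      if (config$nonwear_minutes > 0L) {
        L <- min(config$nonwear_minutes, len)
        at <- start + sample.int(len - L + 1L, 1L)
        day_counts[at:(at + L - 1L)] <- 0L
      }
      res_counts[[k]] <- day_counts
      res_posture[[k]] <- day_posture
    }
  }
  data.frame(
    participant_id = rep(rep(ids, each = n_days), each = day_len),
    day_index = rep(rep(seq_len(n_days), times = length(ids)), each = day_len),
    minute_index = rep(seq_len(day_len), times = length(ids) * n_days),
    counts = unlist(res_counts, use.names = FALSE),
    posture = unlist(res_posture, use.names = FALSE),
    stringsAsFactors = FALSE)
}

#' Generate a synthetic Ct matrix
#'
#' Log2 expression of each target microRNA is a per-assay baseline plus the
#' configured effect (a linear shift in the latent sitting propensity, scaled
#' so the configured size equals the expected log2 contrast between extreme
#' propensity quartiles), plus a covariate-score confounding term and
#' lognormal noise. Ct values are a control baseline minus log2 expression;
#' control assays (array-control panel, SNORD61, cel-miR-39) are generated
#' with low variance. Cts above `nd_cap` are reported not-detected (`NA`).
#'
#' @param cohort Output of [generate_cohort()].
#' @param truth The `truth` component of the cohort (defaults to
#'   `cohort$truth`).
#' @param config The [cohort_config()].
#' @return List with `ct` (matrix, rows = assays, columns = participants) and
#'   `assays` (annotation data frame, see [assay_annotation()]).
#' @export
generate_ct <- function(cohort, truth = cohort$truth, config) {
  stopifnot(inherits(config, "cohort_config"))
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(config$seed + 2L)

  ids <- cohort$covariates$participant_id
  n <- length(ids)
  panel <- config$panel
  ann <- assay_annotation(panel)
  z <- truth$z
  cscore <- truth$covariate_score
  slopes <- truth$mir_effects_log2 / truth$quartile_contrast

  baseline <- stats::rnorm(length(panel), 0, 0.5)
  log2expr <- outer(baseline, rep(1, n)) +
    outer(slopes, z) +
    config$confounding_strength * outer(rep(1, length(panel)), cscore) +
    matrix(stats::rnorm(length(panel) * n, 0, config$expr_noise_sd),
           nrow = length(panel))
  ct_target <- 26 - log2expr

  n_ctrl <- nrow(ann) - length(panel)
  ctrl_levels <- c(rep(26, sum(ann$role == "array_control")), 25, 22)
  ct_ctrl <- matrix(stats::rnorm(n_ctrl * n, rep(ctrl_levels, n), 0.15),
                    nrow = n_ctrl)
  ct <- rbind(ct_target, ct_ctrl)
  dimnames(ct) <- list(ann$assay, ids)
  if (is.finite(config$nd_cap)) ct[ct > config$nd_cap] <- NA_real_
  list(ct = ct, assays = ann)
}

#' Generate a complete synthetic study bundle
#'
#' Convenience wrapper: cohort covariates + ground truth, minute-epoch
#' activity records and a Ct matrix, all from one configuration.
#'
#' @param config A [cohort_config()].
#' @return List with `config`, `covariates`, `truth`, `epochs`, `ct`,
#'   `assays`.
#' @export
generate_study <- function(config) {
  cohort <- generate_cohort(config)
  epochs <- generate_activity(cohort, config)
  ctd <- generate_ct(cohort, config = config)
  list(config = config, covariates = cohort$covariates, truth = cohort$truth,
       epochs = epochs, ct = ctd$ct, assays = ctd$assays)
}

#' Simulate a confounded treatment-outcome cohort with known effect
#'
#' A compact generator for weighting-calibration studies: four standard-normal
#' covariates, a logistic treatment assignment driven by three of them
#' (strength `confounding`), and a continuous outcome equal to
#' `effect * treat` plus a covariate signal plus unit-variance noise. The true
#' average treatment effect equals `effect` exactly, so bias and confidence-
#' interval coverage of weighting estimators can be measured directly.
#'
#' @param n Sample size.
#' @param effect True average treatment effect.
#' @param confounding Scale of the covariate effect on treatment assignment.
#' @param seed Integer seed.
#' @return Data frame with `y`, `treat`, `x1`..`x4`; the true effect is
#'   attached as `attr(, "true_ate")`.
#' @export
simulate_treatment_cohort <- function(n, effect = 1, confounding = 1,
                                      seed = 1L) {
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  x1 <- stats::rnorm(n); x2 <- stats::rnorm(n)
  x3 <- stats::rnorm(n); x4 <- stats::rnorm(n)
  eta <- confounding * (0.8 * x1 + 0.6 * x2 - 0.6 * x3)
  treat <- stats::rbinom(n, 1, stats::plogis(eta))
  y <- effect * treat + 1.0 * x1 + 0.8 * x2 - 0.8 * x3 + stats::rnorm(n)
  out <- data.frame(y = y, treat = treat, x1 = x1, x2 = x2, x3 = x3, x4 = x4)
  attr(out, "true_ate") <- effect
  out
}
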