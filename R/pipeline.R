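#' Assemble the weighting covariate set
#'
#' Joins the activity summaries and the participant covariate table into the
#' seven-confounder set used for propensity weighting: physical functioning,
#' MVPA, device wear days, device wear time, waist circumference, BMI and age.
#'
#' @param summaries Activity summaries from [summarize_activity()].
#' @param covariates Participant covariate table.
#' @return Data frame with `participant_id` and the seven numeric covariates.
#' @export
weighting_covariates <- function(summaries, covariates) {
  m <- match(summaries$participant_id, covariates$participant_id)
  if (anyNA(m)) {
    stop("participants in summaries missing from the covariate table",
         call. = FALSE)
  }
  data.frame(participant_id = summaries$participant_id,
             phys_func = covariates$phys_func[m],
             mvpa = summaries$mvpa,
             wear_days = summaries$wear_days,
             wear_time = summaries$mean_wear_time,
             waist = covariates$waist[m],
             bmi = covariates$bmi[m],
             age = covariates$age[m],
             stringsAsFactors = FALSE)
}

# aggregate member-level covariates to pool level
pool_covariates <- function(covset, pools, method = c("mean", "median")) {
  method <- match.arg(method)
  f <- if (method == "mean") mean else stats::median
  pool_ids <- unique(pools$pool_id)
  num <- names(covset)[vapply(covset, is.numeric, logical(1))]
  rows <- lapply(pool_ids, function(p) {
    members <- pools$participant_id[pools$pool_id == p]
    sub <- covset[match(members, covset$participant_id), num, drop = FALSE]
    as.data.frame(lapply(sub, f))
  })
  out <- cbind(data.frame(pool_id = pool_ids, stringsAsFactors = FALSE),
               do.call(rbind, rows))
  out$group <- pools$group[match(out$pool_id, pools$pool_id)]
  out
}

stage_log <- function(verbose, stage, ...) {
  if (verbose) message(sprintf("[%s] %s", stage, sprintf(...)))
  invisible(NULL)
}

#' Screening stage: pooled-sample microRNA screen
#'
#' Chains the full first-stage workflow: activity summaries, IS/SS
#' classification, RNA pool planning, in-silico Ct pooling, screening-stage
#' relative expression, covariate imputation, pool-level CBPS weighting,
#' bootstrapped weighted ATEs per microRNA, and the two-step rank-then-
#' dispersion selection.
#'
#' @param epochs Minute-epoch data frame (see [summarize_activity()]).
#' @param covariates Participant covariate table (`participant_id`, `age`,
#'   `bmi`, `waist`, `phys_func`, `hispanic`, `parent_study`).
#' @param ct Ct matrix with one column per participant.
#' @param assays Assay annotation data frame.
#' @param B Bootstrap resamples. Default 1000.
#' @param seed Integer seed driving pooling, imputation and the bootstrap.
#' @param min_wear,min_days Adherence thresholds (minutes/day and days).
#' @param ci Confidence-interval method for [ate_bootstrap()].
#' @param pool_aggregate How pool-level covariates are formed from members
#'   (`"mean"` or `"median"`).
#' @param n_top,n_select Two-step selection sizes. Defaults 10 and 5.
#' @param verbose Emit per-stage log messages. Default TRUE.
#' @return Object of class `"sitmir_screening"`: summaries, group
#'   assignments, pool plan, expression matrix, pool covariates, ATE table,
#'   selection, and pre/post-weighting balance.
#' @export
run_screening <- function(epochs, covariates, ct, assays, B = 1000, seed = 1L,
                          min_wear = 600, min_days = 4,
                          ci = c("normal", "percentile"),
                          pool_aggregate = c("mean", "median"),
                          n_top = 10, n_select = 5, verbose = TRUE) {
  ci <- match.arg(ci)
  pool_aggregate <- match.arg(pool_aggregate)

  summaries <- summarize_activity(epochs, min_wear = min_wear,
                                  min_days = min_days)
  stage_log(verbose, "activity", "%d participants, %d adherent",
            nrow(summaries), sum(summaries$adherent))

  groups <- classify_groups(summaries)
  n_is <- sum(groups$group == "IS"); n_ss <- sum(groups$group == "SS")
  stage_log(verbose, "classify", "IS = %d, SS = %d", n_is, n_ss)
  if (n_is < 2L || n_ss < 2L) {
    stop("screening needs at least 2 participants per sitter group",
         call. = FALSE)
  }

  ps <- covariates$parent_study[match(groups$participant_id,
                                      covariates$participant_id)]
  pools <- rbind(
    make_pools(groups$participant_id[groups$group == "IS"],
               ps[groups$group == "IS"], group = "IS", seed = seed + 1L),
    make_pools(groups$participant_id[groups$group == "SS"],
               ps[groups$group == "SS"], group = "SS", seed = seed + 2L))
  stage_log(verbose, "pools", "%d pools planned",
            length(unique(pools$pool_id)))

  pooled <- pool_ct(ct, pools)
  expr <- relative_expression(pooled, assays, stage = "screening")
  stage_log(verbose, "expression", "%d target assays x %d pools",
            nrow(expr), ncol(expr))

  covset <- weighting_covariates(summaries, covariates)
  covset <- covset[covset$participant_id %in% pools$participant_id, ,
                   drop = FALSE]
  if (anyNA(covset)) covset <- impute_pmm(covset, seed = seed + 3L)
  pcov <- pool_covariates(covset, pools, method = pool_aggregate)
  treat <- as.numeric(pcov$group == "SS")
  covmat <- pcov[, c("phys_func", "mvpa", "wear_days", "wear_time",
                     "waist", "bmi", "age")]

  # pool-level samples are small; accept best-achievable balance when the
  # exact root does not exist (see ?ate_bootstrap)
  ate <- ate_bootstrap(expr[, pcov$pool_id, drop = FALSE], covmat, treat,
                       B = B, seed = seed, ci = ci, balance = "best")
  stage_log(verbose, "ate",
            "%d microRNAs screened (B = %d, %d redrawn, residual %.1e)",
            nrow(ate), B, ate$n_boot_failed[1L], ate$full_fit_residual[1L])

  full <- cbps_core(cbind(`(Intercept)` = 1, as.matrix(covmat)), treat)
  w <- stabilized_weights(full$pi, treat)
  balance <- balance_report(covmat, treat, w)

  selection <- rank_and_select(ate, n_top = n_top, n_select = n_select)
  stage_log(verbose, "select", "selected: %s",
            paste(selection$selected, collapse = ", "))

  structure(list(summaries = summaries, groups = groups, pools = pools,
                 expr = expr, pool_covariates = pcov, weights = w,
                 balance = balance, ate_table = ate, selection = selection,
                 B = B, seed = seed, ci = ci),
            class = "sitmir_screening")
}

#' @export
print.sitmir_screening <- function(x, ...) {
  cat("Screening stage (pooled samples)\n")
  cat(sprintf("  %d adherent participants; IS = %d, SS = %d; %d pools\n",
              sum(x$summaries$adherent), sum(x$groups$group == "IS"),
              sum(x$groups$group == "SS"), length(unique(x$pools$pool_id))))
  pre <- max(abs(x$balance$terms$smd_unweighted[x$balance$terms$type == "mean"]))
  post <- max(abs(x$balance$terms$smd_weighted[x$balance$terms$type == "mean"]))
  cat(sprintf("  max |standardized difference| pre %.3f -> post %.3g\n",
              pre, post))
  cat(sprintf("  selected (top %d by |standardized ATE|, then SD): %s\n",
              length(x$selection$top),
              paste(x$selection$selected, collapse = ", ")))
  invisible(x)
}

#' Validation stage: individual-sample confirmation of selected microRNAs
#'
#' Augments the sitter groups with Hispanic participants from the second MVPA
#' quartile, computes validation-stage relative expression on individual
#' samples, re-estimates CBPS weights at the individual level, bootstraps
#' weighted ATEs for the selected microRNAs, applies the strict zero-exclusion
#' significance rule, and reports pairwise correlations among validated
#' microRNAs plus a weighted group-by-ethnicity interaction regression.
#'
#' @param selected Character vector of microRNA names carried forward from
#'   screening (e.g. `run_screening(...)$selection$selected`).
#' @param summaries Activity summaries from [summarize_activity()].
#' @param groups Group assignments from [classify_groups()].
#' @param covariates Participant covariate table (with `hispanic`).
#' @param ct Individual-sample Ct matrix.
#' @param assays Assay annotation.
#' @param B,seed,ci As in [run_screening()].
#' @param verbose Emit per-stage log messages.
#' @return Object of class `"sitmir_validation"`: augmented groups, ATE table
#'   with significance flags, correlations among validated microRNAs, and the
#'   interaction regression tables.
#' @export
run_validation <- function(selected, summaries, groups, covariates, ct,
                           assays, B = 1000, seed = 1L,
                           ci = c("normal", "percentile"), verbose = TRUE) {
  ci <- match.arg(ci)
  if (!length(selected)) stop("no selected microRNAs supplied", call. = FALSE)

  aug <- augment_hispanic(groups, covariates)
  n_isp <- sum(aug$group_plus == "IS+"); n_ssp <- sum(aug$group_plus == "SS+")
  stage_log(verbose, "augment", "IS+ = %d, SS+ = %d", n_isp, n_ssp)

  members <- aug$participant_id[aug$group_plus != "none"]
  treat <- as.numeric(aug$group_plus[aug$group_plus != "none"] == "SS+")

  expr_all <- relative_expression(ct[, members, drop = FALSE], assays,
                                  stage = "validation")
  missing_sel <- setdiff(selected, rownames(expr_all))
  if (length(missing_sel)) {
    stop("selected microRNA(s) absent from the validation panel: ",
         paste(missing_sel, collapse = ", "), call. = FALSE)
  }
  expr <- expr_all[selected, , drop = FALSE]

  covset <- weighting_covariates(
    summaries[match(members, summaries$participant_id), , drop = FALSE],
    covariates)
  if (anyNA(covset)) covset <- impute_pmm(covset, seed = seed + 3L)
  covmat <- covset[, c("phys_func", "mvpa", "wear_days", "wear_time",
                       "waist", "bmi", "age")]

  ate <- ate_bootstrap(expr, covmat, treat, B = B, seed = seed, ci = ci)
  ate <- validate_significance(ate)
  stage_log(verbose, "validate", "%d of %d significant",
            sum(ate$significant, na.rm = TRUE), nrow(ate))

  validated <- ate$mir[which(ate$significant)]
  correlations <- NULL
  if (length(validated) >= 2L) {
    pairs <- utils::combn(validated, 2L, simplify = FALSE)
    correlations <- do.call(rbind, lapply(pairs, function(pr) {
      r <- pearson_correlation(expr[pr[1L], ], expr[pr[2L], ],
                               group = ifelse(treat == 1, "SS+", "IS+"))
      cbind(mir_a = pr[1L], mir_b = pr[2L], r)
    }))
  }

  full <- cbps_core(cbind(`(Intercept)` = 1, as.matrix(covmat)), treat)
  w <- stabilized_weights(full$pi, treat)
  hisp <- covariates$hispanic[match(members, covariates$participant_id)]
  interactions <- lapply(stats::setNames(selected, selected), function(m) {
    tryCatch(interaction_wls(expr[m, ], treat, hisp, w),
             error = function(e) NULL)
  })

  structure(list(groups_plus = aug, ate_table = ate, validated = validated,
                 correlations = correlations, interactions = interactions,
                 weights = w, B = B, seed = seed, ci = ci),
            class = "sitmir_validation")
}

#' @export
print.sitmir_validation <- function(x, ...) {
  cat("Validation stage (individual samples)\n")
  cat(sprintf("  IS+ = %d, SS+ = %d\n",
              sum(x$groups_plus$group_plus == "IS+"),
              sum(x$groups_plus$group_plus == "SS+")))
  tab <- x$ate_table
  for (i in seq_len(nrow(tab))) {
    cat(sprintf("  %-14s ATE %8.4f  95%% CI (%.4f, %.4f)%s  std ATE %6.3f\n",
                tab$mir[i], tab$ate[i], tab$ci_lower[i], tab$ci_upper[i],
                ifelse(isTRUE(tab$significant[i]), "*", " "),
                tab$standardized_ate[i]))
  }
  cat("  * zero strictly outside the 95% CI\n")
  invisible(x)
}

#' Run the full synthetic-study pipeline
#'
#' Generates a synthetic study bundle from a [cohort_config()] and runs the
#' screening and validation stages end to end. Deterministic under fixed
#' seeds.
#'
#' @param config A [cohort_config()].
#' @param B Bootstrap resamples per stage.
#' @param seed Analysis seed (pooling, imputation, bootstraps); the generator
#'   seed lives in `config`.
#' @param ci Confidence-interval method.
#' @param verbose Emit per-stage log messages.
#' @return Object of class `"sitmir_study"`: the study bundle plus
#'   `screening` and `validation` results.
#' @export
run_study <- function(config, B = 1000, seed = 1L,
                      ci = c("normal", "percentile"), verbose = TRUE) {
  ci <- match.arg(ci)
  bundle <- generate_study(config)
  screening <- run_screening(bundle$epochs, bundle$covariates, bundle$ct,
                             bundle$assays, B = B, seed = seed, ci = ci,
                             verbose = verbose)
  validation <- run_validation(screening$selection$selected,
                               screening$summaries, screening$groups,
                               bundle$covariates, bundle$ct, bundle$assays,
                               B = B, seed = seed + 100L, ci = ci,
                               verbose = verbose)
  structure(list(bundle = bundle, screening = screening,
                 validation = validation),
            class = "sitmir_study")
}

#' @export
print.sitmir_study <- function(x, ...) {
  print(x$screening)
  print(x$validation)
  invisible(x)
}
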