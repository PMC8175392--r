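#' Weighted average treatment effect with bootstrap standard deviation
#'
#' Screens one or many expression rows for a group effect. The ATE is the
#' difference of stabilized-IPTW-weighted mean expression, arm 1 minus arm 0,
#' with weights from a just-identified CBPS fit on the full sample. Its
#' bootstrap SD comes from `B` resamples drawn with replacement stratified by
#' arm (arm sizes preserved); the propensity model is re-fit and the weights
#' re-derived inside every resample, so propensity-estimation variability is
#' propagated into the SD. In a small resample the exact-balance root need not
#' exist (the arms' covariate hulls may fail to intersect); such refits use
#' the best-achievable balance, the minimizer of the squared moment norm, and
#' are counted in `n_boot_inexact`. Resamples where the re-fit errors outright
#' are redrawn (at most 10% of `B` failures are tolerated). The 95% CI
#' defaults to the normal approximation `ATE +/- 1.96 * boot_sd`; a percentile
#' CI is available.
#'
#' @param expr Numeric vector (one outcome) or matrix with outcomes in rows
#'   and samples in columns.
#' @param covariates Data frame/matrix of confounders (one row per sample).
#' @param treat 0/1 group indicator per sample.
#' @param B Number of bootstrap resamples. Default 1000.
#' @param seed Integer seed for the resampling.
#' @param ci 95% CI construction: `"normal"` (default) or `"percentile"`.
#' @param balance `"exact"` (default): the full-sample CBPS must attain the
#'   exact-balance root or the call errors; `"best"`: accept the
#'   best-achievable balance (moment-norm minimizer) when the root does not
#'   exist, as is common at pool level where few samples per arm leave the
#'   arms' covariate hulls disjoint. The achieved residual is recorded in the
#'   `full_fit_residual` column.
#' @return Data frame with one row per outcome: `mir`, `ate`, `boot_sd`,
#'   `standardized_ate`, `ci_lower`, `ci_upper`, `significant` (zero strictly
#'   outside the CI), `unweighted_sd` (SD of expression across all samples,
#'   both groups), `n_boot_failed`, `n_boot_inexact`, `full_fit_residual`.
#' @export
ate_bootstrap <- function(expr, covariates, treat, B = 1000, seed = 1L,
                          ci = c("normal", "percentile"),
                          balance = c("exact", "best")) {
  ci <- match.arg(ci)
  balance <- match.arg(balance)
  if (is.null(dim(expr))) {
    expr <- matrix(expr, nrow = 1L,
                   dimnames = list("outcome", names(expr)))
  }
  expr <- as.matrix(expr)
  treat <- as.numeric(treat)
  X <- cbind(`(Intercept)` = 1, as.matrix(covariates))
  n <- length(treat)
  if (ncol(expr) != n || nrow(X) != n) {
    stop("`expr` columns, `covariates` rows and `treat` must align",
         call. = FALSE)
  }
  usable <- function(y, t) sum(!is.na(y) & t == 1) >= 2 &&
    sum(!is.na(y) & t == 0) >= 2

  const <- apply(X[, -1L, drop = FALSE], 2L, function(col) {
    stats::sd(col) == 0
  })
  if (any(const)) {
    warning("dropping constant covariate(s): ",
            paste(names(const)[const], collapse = ", "))
    X <- X[, c(TRUE, !const), drop = FALSE]
  }

  full <- cbps_core(X, treat)
  if (!full$converged && (balance == "exact" || anyNA(full$pi))) {
    stop("CBPS did not converge on the full sample (residual ",
         format(full$residual_norm, digits = 3), ")", call. = FALSE)
  }
  w_full <- stabilized_weights(full$pi, treat)
  ates <- weighted_ate(expr, treat, w_full)

  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  i1 <- which(treat == 1); i0 <- which(treat == 0)
  boot <- matrix(NA_real_, nrow = nrow(expr), ncol = B)
  failed <- 0L
  inexact <- 0L
  max_fail <- ceiling(0.10 * B)
  b <- 1L
  while (b <= B) {
    idx <- c(sample(i1, length(i1), replace = TRUE),
             sample(i0, length(i0), replace = TRUE))
    core <- tryCatch(
      cbps_core(X[idx, , drop = FALSE], treat[idx], init = full$beta_std),
      error = function(e) NULL)
    if (is.null(core) || anyNA(core$pi)) {
      failed <- failed + 1L
      if (failed > max_fail) {
        stop("more than 10% of bootstrap resamples failed to refit CBPS",
             call. = FALSE)
      }
      next
    }
    # in small resamples the exact-balance root need not exist; the refit then
    # delivers the best-achievable balance (moment-norm minimizer)
    if (!isTRUE(core$converged)) inexact <- inexact + 1L
    wb <- stabilized_weights(core$pi, treat[idx])
    boot[, b] <- weighted_ate(expr[, idx, drop = FALSE], treat[idx], wb)
    b <- b + 1L
  }

  boot_sd <- apply(boot, 1L, stats::sd, na.rm = TRUE)
  if (ci == "normal") {
    lo <- ates - 1.96 * boot_sd
    hi <- ates + 1.96 * boot_sd
  } else {
    qs <- apply(boot, 1L, stats::quantile, probs = c(0.025, 0.975),
                na.rm = TRUE)
    lo <- qs[1L, ]; hi <- qs[2L, ]
  }
  estimable <- vapply(seq_len(nrow(expr)),
                      function(i) usable(expr[i, ], treat), logical(1))
  out <- data.frame(
    mir = if (is.null(rownames(expr))) paste0("row", seq_len(nrow(expr)))
          else rownames(expr),
    ate = ates, boot_sd = boot_sd,
    standardized_ate = ates / boot_sd,
    ci_lower = lo, ci_upper = hi,
    significant = lo > 0 | hi < 0,
    unweighted_sd = apply(expr, 1L, stats::sd, na.rm = TRUE),
    n_boot_failed = failed,
    n_boot_inexact = inexact,
    full_fit_residual = full$residual_norm,
    stringsAsFactors = FALSE)
  out[!estimable, c("ate", "boot_sd", "standardized_ate", "ci_lower",
                    "ci_upper", "unweighted_sd")] <- NA_real_
  out$significant[!estimable] <- NA
  rownames(out) <- NULL
  out
}

# weighted mean difference (arm 1 minus arm 0) per expression row; NA-aware
weighted_ate <- function(expr, treat, w) {
  t1 <- treat == 1; t0 <- !t1
  m <- function(cols) {
    e <- expr[, cols, drop = FALSE]
    ww <- matrix(w[cols], nrow = nrow(e), ncol = sum(cols), byrow = TRUE)
    ww[is.na(e)] <- NA
    rowSums(e * ww, na.rm = TRUE) / rowSums(ww, na.rm = TRUE)
  }
  m(t1) - m(t0)
}

#' Two-step biomarker selection: standardized-ATE rank, then dispersion
#'
#' Ranks records by absolute standardized ATE (descending) and keeps the top
#' `n_top`; within that set, keeps the `n_select` records with the largest
#' unweighted SD. The second step guards against candidates whose high
#' standardized ATE is driven by an artificially small dispersion rather than
#' a large effect. Ties are broken by absolute ATE (descending), then name.
#'
#' @param ate_table Data frame as returned by [ate_bootstrap()] (columns
#'   `mir`, `ate`, `standardized_ate`, `unweighted_sd`).
#' @param n_top Size of the first-step rank list. Default 10.
#' @param n_select Number of records retained from the top list. Default 5.
#' @return List with `ranked` (full table, ranked, with `rank` column),
#'   `top` (names of the first-step list) and `selected` (final names).
#' @export
rank_and_select <- function(ate_table, n_top = 10, n_select = 5) {
  tab <- ate_table[!is.na(ate_table$standardized_ate), , drop = FALSE]
  if (nrow(tab) < 1L) stop("no estimable records to rank", call. = FALSE)
  o <- order(-abs(tab$standardized_ate), -abs(tab$ate), tab$mir)
  tab <- tab[o, , drop = FALSE]
  tab$rank <- seq_len(nrow(tab))
  top <- tab[seq_len(min(n_top, nrow(tab))), , drop = FALSE]
  o2 <- order(-top$unweighted_sd, -abs(top$standardized_ate),
              -abs(top$ate), top$mir)
  sel <- top$mir[o2][seq_len(min(n_select, nrow(top)))]
  rownames(tab) <- NULL
  list(ranked = tab, top = top$mir, selected = sel)
}

#' Flag significant records by strict zero exclusion
#'
#' A record is significant when zero lies strictly outside its 95% confidence
#' interval; an interval touching zero at either endpoint is not significant.
#'
#' @param ate_table Data frame with `ci_lower` and `ci_upper` columns.
#' @return `ate_table` with a recomputed logical `significant` column.
#' @export
validate_significance <- function(ate_table) {
  ate_table$significant <- ate_table$ci_lower > 0 | ate_table$ci_upper < 0
  ate_table
}

#' Pearson correlation, optionally stratified by group
#'
#' @param x,y Paired numeric vectors.
#' @param group Optional stratification factor; correlations are reported per
#'   stratum and combined.
#' @return Data frame with `stratum`, `n` and `r`. Zero-variance strata are
#'   reported as `NA`.
#' @export
pearson_correlation <- function(x, y, group = NULL) {
  one <- function(xs, ys, label) {
    ok <- is.finite(xs) & is.finite(ys)
    xs <- xs[ok]; ys <- ys[ok]
    r <- if (length(xs) < 3 || stats::sd(xs) == 0 || stats::sd(ys) == 0) {
      NA_real_
    } else {
      stats::cor(xs, ys)
    }
    data.frame(stratum = label, n = length(xs), r = r,
               stringsAsFactors = FALSE)
  }
  out <- one(x, y, "combined")
  if (!is.null(group)) {
    for (g in sort(unique(group))) {
      out <- rbind(out, one(x[group == g], y[group == g], as.character(g)))
    }
  }
  rownames(out) <- NULL
  out
}

#' Weighted interaction regression of expression on group and ethnicity
#'
#' Weighted least squares of expression on group, ethnicity and their product
#' using stabilized IPTW weights, with heteroskedasticity-robust (HC0)
#' standard errors and a Wald test for the interaction term. All four
#' group-by-ethnicity cells must be nonempty.
#'
#' @param y Expression values.
#' @param group 0/1 sitter-group indicator.
#' @param hispanic 0/1 ethnicity indicator.
#' @param weights Positive weights (unit weights give ordinary least squares).
#' @return Data frame with `term`, `estimate`, `se_hc0`, `z`, `p_value`.
#' @export
interaction_wls <- function(y, group, hispanic,
                            weights = rep(1, length(y))) {
  cells <- table(factor(group, levels = c(0, 1)),
                 factor(hispanic, levels = c(0, 1)))
  if (any(cells == 0)) {
    empty <- which(cells == 0, arr.ind = TRUE)[1L, ]
    stop(sprintf("empty design cell: group=%s, hispanic=%s",
                 rownames(cells)[empty[1L]], colnames(cells)[empty[2L]]),
         call. = FALSE)
  }
  d <- data.frame(y = y, group = group, hispanic = hispanic, w = weights)
  fit <- stats::lm(y ~ group * hispanic, data = d, weights = w)
  V <- sandwich::vcovHC(fit, type = "HC0")
  est <- stats::coef(fit)
  se <- sqrt(diag(V))
  z <- est / se
  data.frame(term = names(est), estimate = unname(est), se_hc0 = unname(se),
             z = unname(z), p_value = unname(2 * stats::pnorm(-abs(z))),
             stringsAsFactors = FALSE)
}
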