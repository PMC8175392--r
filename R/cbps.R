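#' Covariate balancing propensity score (just-identified)
#'
#' Fits a logistic propensity model `pi(x) = plogis(x' beta)` whose
#' coefficients solve the just-identified ATE balance moment conditions
#'
#' \deqn{\frac{1}{n}\sum_i \Big[\frac{T_i}{\pi_\beta(x_i)} -
#'   \frac{1 - T_i}{1 - \pi_\beta(x_i)}\Big] x_i = 0,}
#'
#' where the design `x` includes the intercept. At the solution the
#' inverse-probability-weighted means of every covariate are exactly equal
#' between the two arms (first-moment balance holds to solver tolerance),
#' which is the defining property of this estimator. The system is solved by
#' damped Newton iteration with step halving, initialized at the logistic
#' maximum-likelihood estimate, on internally standardized covariates; a
#' derivative-free polish of the squared moment norm is used as a fallback
#' when Newton stalls. Coefficients are reported on the original scale.
#'
#' @param formula Model formula `treatment ~ covariates`; the response must be
#'   coercible to 0/1.
#' @param data Data frame holding the variables.
#' @param tol Convergence tolerance on the maximum absolute moment residual
#'   (standardized scale). Default `1e-8`.
#' @param max_iter Maximum Newton iterations. Default 200.
#' @return An object of class `"cbps"` with components `coefficients`
#'   (original scale), `propensities`, `treat`, `residual_norm`, `converged`,
#'   `treated_fraction`, plus the model frame pieces needed by `predict`.
#' @seealso [stabilized_weights()], [balance_report()]
#' @examples
#' d <- data.frame(t = rbinom(100, 1, 0.4), x = rnorm(100))
#' fit <- cbps(t ~ x, d)
#' summary(fit)
#' @export
cbps <- function(formula, data, tol = 1e-8, max_iter = 200) {
  mf <- stats::model.frame(formula, data, na.action = stats::na.fail)
  treat <- stats::model.response(mf)
  treat <- as.numeric(treat)
  if (!all(treat %in% c(0, 1))) {
    stop("treatment must be binary 0/1", call. = FALSE)
  }
  if (length(unique(treat)) < 2L) {
    stop("both treatment levels must be present", call. = FALSE)
  }
  X <- stats::model.matrix(attr(mf, "terms"), mf)
  core <- cbps_core(X, treat, tol = tol, max_iter = max_iter)
  if (!core$converged) {
    stop("CBPS did not converge (moment residual ",
         format(core$residual_norm, digits = 3),
         "); consider reducing covariates or checking overlap",
         call. = FALSE)
  }
  structure(
    list(coefficients = core$beta, propensities = core$pi, treat = treat,
         residual_norm = core$residual_norm, converged = core$converged,
         iterations = core$iterations,
         treated_fraction = mean(treat),
         terms = attr(mf, "terms"), xlevels = stats::.getXlevels(attr(mf, "terms"), mf),
         call = match.call()),
    class = "cbps")
}

# Newton solver on a raw design matrix (intercept included). Used directly by
# the bootstrap machinery where formula dispatch would dominate runtime.
# When the exact-balance root does not exist (common in small resamples,
# where the arms' covariate hulls need not intersect), the minimizer of the
# squared moment norm is returned with converged = FALSE: the caller decides
# whether best-achievable balance is acceptable.
cbps_core <- function(X, treat, tol = 1e-8, max_iter = 200, init = NULL) {
  n <- nrow(X)
  p <- ncol(X)
  # standardize non-intercept columns (the intercept is always column 1)
  if (!all(X[, 1L] == 1)) {
    stop("design must include an intercept as its first column", call. = FALSE)
  }
  is_int <- seq_len(p) == 1L
  ctr <- ifelse(is_int, 0, colMeans(X))
  scl <- ifelse(is_int, 1, apply(X, 2L, stats::sd))
  if (any(scl == 0)) {
    stop("constant covariate in the pooled sample", call. = FALSE)
  }
  Z <- sweep(sweep(X, 2L, ctr, `-`), 2L, scl, `/`)

  moment <- function(beta) {
    eta <- drop(Z %*% beta)
    pi_ <- stats::plogis(eta)
    pi_ <- pmin(pmax(pi_, 1e-9), 1 - 1e-9)
    d <- treat / pi_ - (1 - treat) / (1 - pi_)
    list(g = crossprod(Z, d)[, 1L] / n, pi = pi_, eta = eta)
  }
  jac <- function(pi_) {
    w <- -(treat * (1 - pi_) / pi_ + (1 - treat) * pi_ / (1 - pi_))
    crossprod(Z, Z * w) / n
  }

  beta <- init
  if (is.null(beta)) {
    ml <- tryCatch(
      suppressWarnings(stats::glm.fit(Z, treat,
                                      family = stats::binomial())$coefficients),
      error = function(e) NULL)
    beta <- if (is.null(ml) || anyNA(ml)) rep(0, p) else ml
  }
  m <- moment(beta)
  gnorm <- max(abs(m$g))
  converged <- FALSE
  it <- 0L
  while (it < max_iter) {
    it <- it + 1L
    if (gnorm < tol) { converged <- TRUE; break }
    J <- jac(m$pi)
    step <- tryCatch(solve(J, m$g), error = function(e) NULL)
    if (is.null(step) || anyNA(step)) break
    lam <- 1
    improved <- FALSE
    for (h in 1:40) {
      cand <- beta - lam * step
      mc <- moment(cand)
      if (max(abs(mc$g)) < gnorm) {
        beta <- cand; m <- mc; gnorm <- max(abs(mc$g)); improved <- TRUE
        break
      }
      lam <- lam / 2
    }
    if (!improved) break
  }
  if (!converged && gnorm < tol) converged <- TRUE
  if (!converged) {
    # polish / best-achievable balance: minimize the squared moment norm
    obj <- function(b) sum(moment(b)$g^2)
    grad <- function(b) {
      mb <- moment(b)
      2 * drop(crossprod(jac(mb$pi), mb$g))
    }
    op <- tryCatch(stats::optim(beta, obj, grad, method = "BFGS",
                                control = list(maxit = 100, reltol = 1e-10)),
                   error = function(e) NULL)
    if (!is.null(op) && sum(moment(op$par)$g^2) <= sum(m$g^2)) {
      beta <- op$par
      m <- moment(beta)
      gnorm <- max(abs(m$g))
      converged <- gnorm < tol
    }
  }
  # back-transform to original covariate scale
  beta_orig <- beta / scl
  beta_orig[is_int] <- beta[is_int] -
    sum((beta[!is_int] * ctr[!is_int] / scl[!is_int]))
  names(beta_orig) <- colnames(X)
  list(beta = beta_orig, pi = m$pi, residual_norm = gnorm,
       converged = converged, iterations = it, beta_std = beta)
}

#' @export
print.cbps <- function(x, ...) {
  cat("Covariate balancing propensity score (just-identified)\n")
  cat("Call: ", deparse(x$call), "\n", sep = "")
  cat(sprintf("n = %d (treated fraction %.3f), moment residual %.2e in %d iterations\n",
              length(x$treat), x$treated_fraction, x$residual_norm,
              x$iterations))
  cat("Coefficients:\n")
  print(round(x$coefficients, 5))
  invisible(x)
}

#' @export
summary.cbps <- function(object, ...) {
  w <- stabilized_weights(object)
  out <- list(call = object$call, coefficients = object$coefficients,
              residual_norm = object$residual_norm,
              propensity_range = range(object$propensities),
              weight_range = range(w),
              arm_mean_weight = tapply(w, object$treat, mean))
  class(out) <- "summary.cbps"
  out
}

#' @export
print.summary.cbps <- function(x, ...) {
  cat("CBPS fit:", deparse(x$call), "\n")
  cat("Coefficients:\n"); print(round(x$coefficients, 5))
  cat(sprintf("Moment residual: %.2e\n", x$residual_norm))
  cat(sprintf("Propensity range: [%.4f, %.4f]\n",
              x$propensity_range[1], x$propensity_range[2]))
  cat(sprintf("Stabilized weights: range [%.3f, %.3f], arm means %.6f / %.6f\n",
              x$weight_range[1], x$weight_range[2],
              x$arm_mean_weight[1], x$arm_mean_weight[2]))
  invisible(x)
}

#' @export
coef.cbps <- function(object, ...) object$coefficients

#' Predicted propensity scores
#'
#' @param object A fitted [cbps()] model.
#' @param newdata Optional data frame; fitted propensities returned when
#'   omitted.
#' @param ... Unused.
#' @return Numeric vector of propensities in (0, 1).
#' @export
predict.cbps <- function(object, newdata = NULL, ...) {
  if (is.null(newdata)) return(object$propensities)
  tt <- stats::delete.response(object$terms)
  mf <- stats::model.frame(tt, newdata, xlev = object$xlevels)
  X <- stats::model.matrix(tt, mf)
  drop(stats::plogis(X %*% object$coefficients))
}

#' @export
fitted.cbps <- function(object, ...) object$propensities

#' Moment-condition residuals of a CBPS fit
#'
#' Per-sample inverse-probability contrast `T/pi - (1-T)/(1-pi)`; its design-
#' weighted average is the moment vector driven to zero by the fit.
#'
#' @param object A fitted [cbps()] model.
#' @param ... Unused.
#' @export
residuals.cbps <- function(object, ...) {
  object$treat / object$propensities -
    (1 - object$treat) / (1 - object$propensities)
}

#' Stabilized inverse-probability-of-treatment weights
#'
#' `w_i = pbar / pi_i` for treated samples and `(1 - pbar) / (1 - pi_i)` for
#' controls, where `pbar` is the observed treated fraction. By default weights
#' are additionally normalized to mean 1 within each arm (a Hajek rescaling
#' that leaves every weighted mean unchanged); when first-moment balance holds
#' the two arm factors coincide.
#'
#' @param fit A fitted [cbps()] model, or a numeric vector of propensities.
#' @param treat Treatment indicator (required when `fit` is a propensity
#'   vector).
#' @param normalize Normalize weights to mean 1 within each arm. Default TRUE.
#' @return Numeric vector of positive weights.
#' @export
stabilized_weights <- function(fit, treat = NULL, normalize = TRUE) {
  if (inherits(fit, "cbps")) {
    pi_ <- fit$propensities
    treat <- fit$treat
  } else {
    pi_ <- fit
    if (is.null(treat)) stop("`treat` required with raw propensities",
                             call. = FALSE)
  }
  if (any(pi_ <= 0 | pi_ >= 1)) {
    stop("propensities must lie strictly inside (0, 1)", call. = FALSE)
  }
  pbar <- mean(treat)
  w <- ifelse(treat == 1, pbar / pi_, (1 - pbar) / (1 - pi_))
  if (normalize) {
    w[treat == 1] <- w[treat == 1] / mean(w[treat == 1])
    w[treat == 0] <- w[treat == 0] / mean(w[treat == 0])
  }
  w
}

#' @export
weights.cbps <- function(object, normalize = TRUE, ...) {
  stabilized_weights(object, normalize = normalize)
}

#' Covariate balance diagnostics
#'
#' For every covariate, squared covariate and pairwise product, reports the
#' unweighted and weighted standardized average difference
#' `(weighted mean in arm 1 - weighted mean in arm 0) / pooled unweighted SD`
#' (pooled SD = square root of the average of the two arms' unweighted
#' variances). For every raw covariate it also reports the weighted
#' Kolmogorov-Smirnov statistic, the maximum gap between arm-wise weighted
#' empirical distribution functions. Zero-variance terms are skipped with a
#' warning.
#'
#' @param covariates Data frame or numeric matrix of covariates.
#' @param treat 0/1 treatment indicator.
#' @param weights Positive weights (e.g. from [stabilized_weights()]); unit
#'   weights reproduce the classical unweighted diagnostics.
#' @return List with `terms` (data frame: `term`, `type`, `smd_unweighted`,
#'   `smd_weighted`) and `ks` (data frame: `term`, `ks_weighted`).
#' @export
balance_report <- function(covariates, treat, weights = rep(1, length(treat))) {
  X <- as.matrix(covariates)
  if (is.null(colnames(X))) colnames(X) <- paste0("x", seq_len(ncol(X)))
  nm <- colnames(X)
  terms <- list()
  add_term <- function(v, label, type) {
    s1 <- stats::sd(v[treat == 1]); s0 <- stats::sd(v[treat == 0])
    pooled <- sqrt((s1^2 + s0^2) / 2)
    if (!is.finite(pooled) || pooled == 0) {
      warning("skipping zero-variance term: ", label)
      return(NULL)
    }
    wm <- function(w) {
      (sum(w[treat == 1] * v[treat == 1]) / sum(w[treat == 1])) -
        (sum(w[treat == 0] * v[treat == 0]) / sum(w[treat == 0]))
    }
    data.frame(term = label, type = type,
               smd_unweighted = wm(rep(1, length(v))) / pooled,
               smd_weighted = wm(weights) / pooled,
               stringsAsFactors = FALSE)
  }
  for (j in seq_along(nm)) {
    terms[[length(terms) + 1L]] <- add_term(X[, j], nm[j], "mean")
    terms[[length(terms) + 1L]] <- add_term(X[, j]^2,
                                            paste0(nm[j], "^2"), "square")
  }
  if (ncol(X) >= 2L) {
    for (j in seq_len(ncol(X) - 1L)) {
      for (k in seq((j + 1L), ncol(X))) {
        terms[[length(terms) + 1L]] <-
          add_term(X[, j] * X[, k], paste0(nm[j], ":", nm[k]), "interaction")
      }
    }
  }
  ks <- data.frame(term = nm,
                   ks_weighted = vapply(seq_along(nm), function(j) {
                     weighted_ks(X[, j], treat, weights)
                   }, numeric(1)),
                   stringsAsFactors = FALSE)
  list(terms = do.call(rbind, terms), ks = ks)
}

# maximum gap between arm-wise weighted empirical CDFs
weighted_ks <- function(x, treat, w) {
  pts <- sort(unique(x))
  F1 <- cumsum_weighted(x[treat == 1], w[treat == 1], pts)
  F0 <- cumsum_weighted(x[treat == 0], w[treat == 0], pts)
  max(abs(F1 - F0))
}

cumsum_weighted <- function(x, w, pts) {
  o <- order(x)
  x <- x[o]; w <- w[o] / sum(w)
  cw <- cumsum(w)
  idx <- findInterval(pts, x)
  c(0, cw)[idx + 1L]
}

#' Single imputation by chained equations with predictive mean matching
#'
#' Fills missing cells of a numeric covariate table by iterating over
#' variables with missingness: each is regressed on all other covariates
#' (using currently filled values), predicted means are computed for all rows,
#' and every missing cell is replaced by the observed value of one of the
#' `k_donors` rows whose predicted means are closest (donor drawn at random,
#' seeded). A single completed dataset is returned, so every imputed value is
#' an observed value of its variable.
#'
#' @param data Data frame of numeric covariates (non-numeric columns are
#'   passed through untouched and not used as predictors).
#' @param k_donors Number of nearest donors to draw from. Default 5.
#' @param n_cycles Number of chained-equation sweeps. Default 10.
#' @param seed Integer seed.
#' @return `data` with missing numeric cells imputed.
#' @export
impute_pmm <- function(data, k_donors = 5, n_cycles = 10, seed = 1L) {
  num <- vapply(data, is.numeric, logical(1))
  X <- as.data.frame(data[num])
  miss <- vapply(X, anyNA, logical(1))
  if (!any(miss)) return(data)
  all_missing <- names(X)[vapply(X, function(v) all(is.na(v)), logical(1))]
  if (length(all_missing)) {
    stop("variable(s) entirely missing: ",
         paste(all_missing, collapse = ", "), call. = FALSE)
  }
  for (v in names(X)[miss]) {
    if (sum(!is.na(X[[v]])) < k_donors) {
      stop("variable '", v, "' has fewer than ", k_donors,
           " observed values", call. = FALSE)
    }
  }
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)

  na_idx <- lapply(X, function(v) which(is.na(v)))
  # initialize missing cells with random observed draws
  for (v in names(X)[miss]) {
    obs <- X[[v]][!is.na(X[[v]])]
    X[[v]][na_idx[[v]]] <- sample(obs, length(na_idx[[v]]), replace = TRUE)
  }
  vars <- names(X)[miss]
  for (cycle in seq_len(n_cycles)) {
    for (v in vars) {
      others <- setdiff(names(X), v)
      fml <- stats::reformulate(others, response = v)
      obs_rows <- setdiff(seq_len(nrow(X)), na_idx[[v]])
      fit <- stats::lm(fml, data = X[obs_rows, , drop = FALSE])
      pred <- stats::predict(fit, newdata = X)
      for (i in na_idx[[v]]) {
        d <- abs(pred[obs_rows] - pred[i])
        donors <- obs_rows[order(d)][seq_len(min(k_donors, length(obs_rows)))]
        X[[v]][i] <- X[[v]][donors[sample.int(length(donors), 1L)]]
      }
    }
  }
  data[num] <- X
  data
}
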