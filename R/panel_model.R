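#' Fixed-effects (within) panel regression
#'
#' Estimates \code{y_it = alpha_i + x_it' beta + eps_it} by the within
#' transformation: entity means are subtracted from \code{y} and every
#' regressor, and ordinary least squares is run on the demeaned data.
#' This removes all time-invariant entity heterogeneity and is
#' algebraically identical to least squares with a full set of entity
#' dummies (LSDV). Degrees of freedom are \code{N - n_entities - K},
#' which classical standard errors use; cluster-robust-by-entity errors
#' are available via \code{se}.
#'
#' Regressors with no within-entity variation are not identified; each is
#' dropped with a warning. The reported constant is the grand-mean
#' adjustment \code{mean(y) - mean(x)' beta} (the average entity effect).
#' AIC/BIC come from the Gaussian log-likelihood of the within residuals,
#' counting the \code{n_entities} estimated effects (plus slopes and the
#' error variance) as parameters.
#'
#' @param formula Model formula, e.g. \code{A ~ POO + ODR + ...}; no
#'   intercept term is needed (entity effects absorb it).
#' @param data data.frame containing the variables plus the index columns.
#' @param index Length-2 character vector naming the entity and time
#'   columns (default \code{c("province", "year")}).
#' @param se \code{"classical"} (default) or \code{"cluster"} (by entity).
#' @param time_effects Also sweep out time means (two-way within).
#'   Default \code{FALSE} (one-way model).
#' @return Object of class \code{c("panel_fe", "panel_fit")} with
#'   coefficient table, vcov, fit statistics and residuals; supports
#'   \code{print}, \code{summary}, \code{coef}, \code{vcov},
#'   \code{confint}, \code{fitted}, \code{residuals}, \code{predict},
#'   \code{nobs}, \code{logLik}, \code{AIC}, \code{BIC}.
#' @seealso [panel_re()], [hausman_test()]
#' @export
#' @examples
#' d <- data.frame(province = rep(c("Beijing", "Tianjin"), each = 2),
#'                 year = rep(c(2005, 2010), 2),
#'                 x = c(1, 2, 3, 5))
#' d$y <- ifelse(d$province == "Beijing", 0.2, 0.6) + 1.0 * d$x
#' coef(panel_fe(y ~ x, d))   # exactly 1
panel_fe <- function(formula, data, index = c("province", "year"),
                     se = c("classical", "cluster"), time_effects = FALSE) {
  se <- match.arg(se)
  pd <- prepare_panel_frame(formula, data, index)
  y <- pd$y; X <- pd$X; entity <- pd$entity; time <- pd$time

  # drop regressors without within variation
  ydm <- demean_by(y, entity)
  Xdm <- apply(X, 2L, demean_by, g = entity)
  if (time_effects) {
    ydm <- demean_by(ydm, time)
    Xdm <- apply(Xdm, 2L, demean_by, g = time)
  }
  keep <- apply(Xdm, 2L, function(col) max(abs(col)) > 1e-10)
  if (!any(keep)) stop("no regressor has within variation")
  if (any(!keep))
    warning("dropped regressor(s) without within variation: ",
            paste(colnames(X)[!keep], collapse = ", "))
  X <- X[, keep, drop = FALSE]
  Xdm <- Xdm[, keep, drop = FALSE]

  N <- length(y)
  n_ent <- length(unique(entity))
  K <- ncol(Xdm)
  dof <- N - n_ent - K - if (time_effects) length(unique(time)) - 1L else 0L
  if (dof <= 0) stop("not enough degrees of freedom: N - n - K = ", dof)

  fit <- stats::lm.fit(Xdm, ydm)
  beta <- fit$coefficients
  resid <- fit$residuals
  rss <- sum(resid^2)
  sigma2 <- rss / dof
  XtXinv <- chol2inv(chol(crossprod(Xdm)))
  dimnames(XtXinv) <- list(colnames(Xdm), colnames(Xdm))
  V <- if (se == "classical") {
    sigma2 * XtXinv
  } else {
    meat <- matrix(0, K, K)
    for (g in unique(entity)) {
      idx <- entity == g
      sc <- crossprod(Xdm[idx, , drop = FALSE], resid[idx])
      meat <- meat + tcrossprod(sc)
    }
    adj <- (n_ent / (n_ent - 1)) * ((N - 1) / dof)
    adj * XtXinv %*% meat %*% XtXinv
  }

  tss <- sum(ydm^2)
  r2_within <- if (tss > 0) 1 - rss / tss else NA_real_
  F_stat <- (r2_within / K) / ((1 - r2_within) / dof)
  F_p <- stats::pf(F_stat, K, dof, lower.tail = FALSE)

  const <- mean(y) - sum(colMeans(X) * beta)
  ent_means_y <- tapply(y, entity, mean)
  ent_means_xb <- tapply(drop(X %*% beta), entity, mean)
  effects <- stats::setNames(as.numeric(ent_means_y - ent_means_xb),
                             names(ent_means_y))

  n_par <- K + n_ent + 1L  # slopes + entity effects + error variance
  ll <- -N / 2 * (log(2 * pi * rss / N) + 1)

  structure(list(
    call = match.call(), formula = formula, estimator = "fixed",
    coefficients = beta, vcov = V, se_type = se,
    residuals = resid, fitted = y - resid,
    entity = entity, time = time, effects = effects, constant = const,
    nobs = N, n_entities = n_ent, K = K, dof = dof,
    sigma2 = sigma2, r2 = r2_within, F = F_stat, F_p = F_p,
    logLik = ll, n_par = n_par,
    y_mean = mean(y), y_sd = stats::sd(y),
    time_effects = time_effects
  ), class = c("panel_fe", "panel_fit"))
}

#' Random-effects panel regression (feasible GLS)
#'
#' Estimates the random-effects model by the standard two-step
#' variance-components method: the idiosyncratic variance comes from the
#' within residuals, the entity-effect variance from the between
#' (entity-means) regression, and the slopes from OLS on quasi-demeaned
#' data \code{z_it - theta_i * mean_i(z)} with
#' \code{theta_i = 1 - sqrt(sigma_e^2 / (T_i sigma_u^2 + sigma_e^2))}.
#' A negative entity-variance estimate is clamped to zero with a warning,
#' in which case the estimator degenerates to pooled OLS.
#'
#' @inheritParams panel_fe
#' @return Object of class \code{c("panel_re", "panel_fit")}; same
#'   methods as [panel_fe()]. The coefficient vector includes the
#'   \code{(Intercept)}.
#' @export
panel_re <- function(formula, data, index = c("province", "year")) {
  pd <- prepare_panel_frame(formula, data, index)
  y <- pd$y; X <- pd$X; entity <- pd$entity
  N <- length(y)
  n_ent <- length(unique(entity))
  if (n_ent < 2L) stop("random effects need at least 2 entities")
  K <- ncol(X)

  # step 1: idiosyncratic variance from within residuals
  ydm <- demean_by(y, entity)
  Xdm <- apply(X, 2L, demean_by, g = entity)
  wfit <- stats::lm.fit(Xdm, ydm)
  sigma2_e <- sum(wfit$residuals^2) / (N - n_ent - K)

  # step 2: entity variance from the between regression
  yb <- tapply(y, entity, mean)
  Xb <- apply(X, 2L, function(col) tapply(col, entity, mean))
  Ti <- as.vector(table(entity)[names(yb)])
  Xb1 <- cbind(`(Intercept)` = 1, Xb)
  if (n_ent <= K + 1L) stop("too few entities for the between regression")
  bfit <- stats::lm.fit(Xb1, yb)
  s2_between <- sum(bfit$residuals^2) / (n_ent - K - 1L)
  Tbar <- 1 / mean(1 / Ti)  # harmonic mean handles unbalanced panels
  sigma2_u <- s2_between - sigma2_e / Tbar
  if (sigma2_u < 0) {
    warning("negative entity-variance estimate clamped to 0 ",
            "(degenerates to pooled OLS)")
    sigma2_u <- 0
  }

  theta <- 1 - sqrt(sigma2_e / (Ti * sigma2_u + sigma2_e))
  th <- theta[match(entity, names(yb))]
  yq <- y - th * yb[match(entity, names(yb))]
  Xq <- X - Xb[match(entity, names(yb)), , drop = FALSE] * th
  Xq1 <- cbind(`(Intercept)` = 1 - th, Xq)
  fit <- stats::lm.fit(Xq1, yq)
  beta <- fit$coefficients
  resid <- fit$residuals
  dof <- N - K - 1L
  sigma2 <- sum(resid^2) / dof
  XtXinv <- chol2inv(chol(crossprod(Xq1)))
  dimnames(XtXinv) <- list(colnames(Xq1), colnames(Xq1))
  V <- sigma2 * XtXinv

  tss <- sum((yq - mean(yq))^2)
  rss <- sum(resid^2)
  r2 <- if (tss > 0) 1 - rss / tss else NA_real_
  F_stat <- (r2 / K) / ((1 - r2) / dof)
  ll <- -N / 2 * (log(2 * pi * rss / N) + 1)

  structure(list(
    call = match.call(), formula = formula, estimator = "random",
    coefficients = beta, vcov = V, se_type = "classical",
    residuals = resid, fitted = y - resid,
    entity = entity, time = pd$time,
    constant = unname(beta["(Intercept)"]),
    nobs = N, n_entities = n_ent, K = K, dof = dof,
    sigma2 = sigma2, sigma2_e = sigma2_e, sigma2_u = sigma2_u,
    theta = theta,
    r2 = r2, F = F_stat,
    F_p = stats::pf(F_stat, K, dof, lower.tail = FALSE),
    logLik = ll, n_par = K + 3L,
    y_mean = mean(y), y_sd = stats::sd(y),
    time_effects = FALSE
  ), class = c("panel_re", "panel_fit"))
}

#' Hausman specification test
#'
#' Compares the fixed-effects and random-effects estimates of the common
#' slope coefficients. Under the null that entity effects are
#' uncorrelated with the regressors both estimators are consistent and RE
#' is efficient, so \code{H = d' [V_FE - V_RE]^{-1} d} with
#' \code{d = b_FE - b_RE} is chi-square with K degrees of freedom. When
#' the covariance difference is not positive definite the Moore-Penrose
#' pseudo-inverse is used (with a warning) and the statistic is truncated
#' at zero. A small p-value favours the fixed-effects specification.
#'
#' @param fe A [panel_fe()] fit.
#' @param re A [panel_re()] fit (or any \code{panel_fit} sharing slopes).
#' @param threshold Decision threshold for the recommendation (0.05).
#' @return Object of class \code{"hausman_test"}: \code{statistic},
#'   \code{df}, \code{p_value}, \code{recommendation}.
#' @export
hausman_test <- function(fe, re, threshold = 0.05) {
  common <- intersect(names(stats::coef(fe)), names(stats::coef(re)))
  common <- setdiff(common, "(Intercept)")
  if (length(common) == 0L) stop("no common slope coefficients")
  d <- stats::coef(fe)[common] - stats::coef(re)[common]
  Vd <- stats::vcov(fe)[common, common, drop = FALSE] -
    stats::vcov(re)[common, common, drop = FALSE]
  Vd <- (Vd + t(Vd)) / 2
  ev <- eigen(Vd, symmetric = TRUE)
  H <- if (all(ev$values > 1e-12 * max(abs(ev$values), 1e-300))) {
    drop(t(d) %*% solve(Vd, d))
  } else {
    warning("covariance difference not positive definite; ",
            "using pseudo-inverse")
    pos <- ev$values > 1e-10 * max(abs(ev$values))
    Vinv <- ev$vectors[, pos, drop = FALSE] %*%
      ((1 / ev$values[pos]) * t(ev$vectors[, pos, drop = FALSE]))
    max(0, drop(t(d) %*% Vinv %*% d))
  }
  df <- length(common)
  p <- stats::pchisq(H, df, lower.tail = FALSE)
  structure(list(statistic = H, df = df, p_value = p,
                 recommendation = if (p < threshold) "fixed" else "random",
                 threshold = threshold),
            class = "hausman_test")
}

#' @export
print.hausman_test <- function(x, ...) {
  cat("Hausman specification test (FE vs RE)\n")
  cat(sprintf("  chi-square = %.3f, df = %d, p = %.4f\n",
              x$statistic, x$df, x$p_value))
  cat("  recommendation:", x$recommendation, "effects (threshold",
      x$threshold, ")\n")
  invisible(x)
}

# ---- shared machinery -----------------------------------------------------

prepare_panel_frame <- function(formula, data, index) {
  if (length(index) != 2L || !all(index %in% names(data)))
    stop("index must name the entity and time columns of `data`")
  data <- as.data.frame(data)
  rownames(data) <- NULL
  mf <- stats::model.frame(formula, data = data, na.action = stats::na.omit)
  used <- as.integer(rownames(mf))
  tt <- stats::terms(formula, data = data)
  X <- stats::model.matrix(stats::delete.response(tt), mf)
  X <- X[, colnames(X) != "(Intercept)", drop = FALSE]
  y <- stats::model.response(mf)
  entity <- as.character(data[[index[1L]]][used])
  time <- data[[index[2L]]][used]
  tab <- table(entity)
  if (!any(tab >= 2L))
    stop("within estimation needs >= 2 time points for >= 1 entity")
  list(y = y, X = X, entity = entity, time = time)
}

demean_by <- function(v, g) {
  v - stats::ave(v, g)
}

#' @export
coef.panel_fit <- function(object, ...) object$coefficients

#' @export
vcov.panel_fit <- function(object, ...) object$vcov

#' @export
nobs.panel_fit <- function(object, ...) object$nobs

#' @export
residuals.panel_fit <- function(object, ...) object$residuals

#' @export
fitted.panel_fit <- function(object, ...) object$fitted

#' @export
logLik.panel_fit <- function(object, ...) {
  structure(object$logLik, df = object$n_par, nobs = object$nobs,
            class = "logLik")
}

#' @export
confint.panel_fit <- function(object, parm, level = 0.95, ...) {
  cf <- stats::coef(object)
  if (missing(parm)) parm <- names(cf)
  se <- sqrt(diag(object$vcov))[parm]
  tcrit <- stats::qt(1 - (1 - level) / 2, object$dof)
  out <- cbind(cf[parm] - tcrit * se, cf[parm] + tcrit * se)
  colnames(out) <- sprintf("%.1f %%", 100 * c((1 - level) / 2,
                                              1 - (1 - level) / 2))
  out
}

#' Predict from a panel fit
#'
#' For fixed effects, predictions add the estimated entity effect when the
#' entity was in the estimation sample, else the average effect (the
#' constant). Random-effects predictions use the GLS intercept and slopes.
#'
#' @param object A \code{panel_fit}.
#' @param newdata data.frame with the regressor columns (and, for FE, the
#'   entity column). Defaults to the fitted values.
#' @param index Entity/time column names (as in the fit).
#' @param ... Unused.
#' @return Numeric vector of predictions.
#' @export
predict.panel_fit <- function(object, newdata = NULL,
                              index = c("province", "year"), ...) {
  if (is.null(newdata)) return(object$fitted)
  tt <- stats::delete.response(stats::terms(object$formula, data = newdata))
  X <- stats::model.matrix(tt, stats::model.frame(tt, newdata))
  X <- X[, names(stats::coef(object))[names(stats::coef(object)) %in%
                                        colnames(X)], drop = FALSE]
  base <- drop(X %*% stats::coef(object)[colnames(X)])
  if (object$estimator == "fixed") {
    eff <- object$effects[as.character(newdata[[index[1L]]])]
    eff[is.na(eff)] <- object$constant
    base + unname(eff)
  } else {
    base + if ("(Intercept)" %in% names(stats::coef(object)))
      stats::coef(object)["(Intercept)"] else 0
  }
}

#' Coefficient table of a panel fit
#'
#' @param object A \code{panel_fit}.
#' @param level Confidence level (default 0.95).
#' @param ... Unused.
#' @return \code{summary.panel_fit}: list with the coefficient table
#'   (estimate, SE, t, p, CI bounds, significance stars at 1/5/10 percent)
#'   and the fit block (R2, F, AIC, BIC, observation count, dependent
#'   variable mean/SD).
#' @export
summary.panel_fit <- function(object, level = 0.95, ...) {
  cf <- stats::coef(object)
  se <- sqrt(diag(object$vcov))
  tval <- cf / se
  pval <- 2 * stats::pt(abs(tval), object$dof, lower.tail = FALSE)
  ci <- confint.panel_fit(object, level = level)
  stars <- ifelse(pval < 0.01, "***",
                  ifelse(pval < 0.05, "**", ifelse(pval < 0.1, "*", "")))
  tab <- data.frame(estimate = cf, std_error = se, t_value = tval,
                    p_value = pval, ci_lower = ci[, 1L], ci_upper = ci[, 2L],
                    stars = stars, stringsAsFactors = FALSE)
  out <- list(
    coefficients = tab, estimator = object$estimator,
    constant = object$constant, r2 = object$r2,
    F = object$F, F_p = object$F_p,
    nobs = object$nobs, n_entities = object$n_entities,
    aic = -2 * object$logLik + 2 * object$n_par,
    bic = -2 * object$logLik + log(object$nobs) * object$n_par,
    y_mean = object$y_mean, y_sd = object$y_sd, se_type = object$se_type)
  class(out) <- "summary.panel_fit"
  out
}

#' @export
print.summary.panel_fit <- function(x, digits = 4, ...) {
  cat(switch(x$estimator,
             fixed = "Fixed-effects (within) panel regression",
             random = "Random-effects (FGLS) panel regression",
             "Pooled panel regression"), "\n")
  tab <- x$coefficients
  tab[1:6] <- lapply(tab[1:6], round, digits = digits)
  print.data.frame(tab)
  cat("---\nSignif.: *** p<0.01, ** p<0.05, * p<0.1 (",
      x$se_type, " SEs)\n", sep = "")
  if (x$estimator == "fixed")
    cat(sprintf("Constant (grand-mean adj.): %.*f\n", digits, x$constant))
  cat(sprintf("R-squared: %.3f | F: %.3f (p = %.4f) | obs: %d (%d entities)\n",
              x$r2, x$F, x$F_p, x$nobs, x$n_entities))
  cat(sprintf("Mean dep. var: %.3f | SD dep. var: %.3f | AIC: %.3f | BIC: %.3f\n",
              x$y_mean, x$y_sd, x$aic, x$bic))
  invisible(x)
}

#' @export
print.panel_fit <- function(x, ...) {
  cat(switch(x$estimator,
             fixed = "Fixed-effects (within) panel fit",
             random = "Random-effects (FGLS) panel fit"),
      "-", x$nobs, "obs,", x$n_entities, "entities\n")
  print(round(stats::coef(x), 4))
  invisible(x)
}
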