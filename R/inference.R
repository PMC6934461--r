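# Regression models on observed and permuted data: GLMM wrappers, stepwise
# deviance reduction, Tukey-style contrasts with Sidak adjustment, the
# negative-binomial hurdle model for encounter durations, prediction,
# repeatability (ICC) and small worked-example utilities.

#' Fit a (mixed) regression model by maximum likelihood
#'
#' Thin wrapper dispatching on the presence of random-effect terms: `lmer` /
#' `glmer` (Laplace) when the formula contains `(...|...)` bars, `lm` /
#' `glm` otherwise.  All fits use maximum likelihood (no REML) so deviance
#' tests between nested fits are valid.  Families: `gaussian`, `poisson`
#' (log), `gamma` (log), `lognormal` (gaussian on `log10(y + 1)`, the
#' transformed-strength scale).
#'
#' @param formula model formula (lme4 syntax for random effects).
#' @param data model data.
#' @param family one of `"gaussian"`, `"poisson"`, `"gamma"`, `"lognormal"`.
#' @return object of class `fox_fit`: list with the underlying `model`,
#'   `coefficients` (term, estimate, se), `vcov` (fixed effects), `varcorr`
#'   (group, variance), `logLik`, `converged`, `family`, `formula`, `data`.
#' @export
fit_model <- function(formula, data,
                      family = c("gaussian", "poisson", "gamma",
                                 "lognormal")) {
  family <- match.arg(family)
  has_bars <- !is.null(lme4::findbars(formula))
  dat <- data
  if (family == "lognormal") {
    resp <- all.vars(formula)[1]
    dat[[resp]] <- strength_transform(dat[[resp]])
  }
  fam_obj <- switch(family,
                    gaussian = gaussian(), lognormal = gaussian(),
                    poisson = poisson(link = "log"),
                    gamma = Gamma(link = "log"))
  if (has_bars) {
    model <- if (family %in% c("gaussian", "lognormal")) {
      lme4::lmer(formula, data = dat, REML = FALSE)
    } else {
      suppressWarnings(lme4::glmer(formula, data = dat, family = fam_obj))
    }
    beta <- lme4::fixef(model)
    V <- as.matrix(vcov(model))
    vc <- as.data.frame(lme4::VarCorr(model))
    varcorr <- data.frame(group = vc$grp, variance = vc$vcov,
                          stringsAsFactors = FALSE)
    converged <- length(model@optinfo$conv$lme4$messages) == 0
  } else {
    model <- if (family %in% c("gaussian", "lognormal")) {
      lm(formula, data = dat)
    } else {
      glm(formula, data = dat, family = fam_obj)
    }
    beta <- coef(model)
    V <- vcov(model)
    varcorr <- data.frame(group = character(0), variance = numeric(0))
    converged <- if (inherits(model, "glm")) model$converged else TRUE
  }
  structure(list(model = model,
                 coefficients = data.frame(term = names(beta),
                                           estimate = unname(beta),
                                           se = sqrt(diag(V)),
                                           row.names = NULL,
                                           stringsAsFactors = FALSE),
                 vcov = V, varcorr = varcorr,
                 logLik = as.numeric(logLik(model)),
                 converged = converged,
                 family = family, formula = formula, data = dat),
            class = "fox_fit")
}

#' @export
print.fox_fit <- function(x, ...) {
  cat(sprintf("fox_fit (%s%s), logLik %.2f%s\n", x$family,
              if (nrow(x$varcorr)) ", mixed" else "",
              x$logLik, if (x$converged) "" else " [NOT CONVERGED]"))
  print(x$coefficients)
  invisible(x)
}

# fixed-effects design matrix for new data, honouring the fit's factor levels
fixed_design <- function(fit, newdata) {
  f <- lme4::nobars(fit$formula)
  tt <- delete.response(terms(f))
  for (v in all.vars(tt)) {
    orig <- fit$data[[v]]
    if (is.character(orig) || is.factor(orig)) {
      newdata[[v]] <- factor(newdata[[v]], levels = levels(factor(orig)))
    }
  }
  model.matrix(tt, newdata)
}

#' Stepwise model reduction by deviance testing
#'
#' Iteratively removes the least-supported removable fixed-effect term
#' (respecting marginality: interactions drop before their main effects)
#' while the likelihood-ratio deviance test of the removal has P > `alpha`.
#' Random effects are never touched; the floor is an intercept-only fixed
#' part.  Deviance tests use a chi-square reference with df equal to the
#' parameter-count difference.
#'
#' @param formula maximal model formula.
#' @param data model data.
#' @param family as in [fit_model()].
#' @param alpha retention threshold (default 0.05).
#' @return list: formula (minimal), fit (`fox_fit`), trail (data.frame of
#'   tested removals: term, lrt, df, p, dropped).
#' @export
stepwise_reduce <- function(formula, data, family = "gaussian",
                            alpha = 0.05) {
  fit <- fit_model(formula, data, family)
  trail <- list()
  repeat {
    fixed <- lme4::nobars(fit$formula)
    cand <- stats::drop.scope(terms(fixed))
    if (length(cand) == 0) break
    best <- NULL
    for (tm in cand) {
      red_formula <- update(fit$formula, paste(". ~ . -", tm))
      red <- fit_model(red_formula, data, family)
      df <- nrow(fit$coefficients) - nrow(red$coefficients)
      lrt <- 2 * (fit$logLik - red$logLik)
      p <- if (df > 0) 1 - pchisq(max(lrt, 0), df) else NA_real_
      if (is.null(best) || (!is.na(p) && p > best$p)) {
        best <- list(term = tm, lrt = lrt, df = df, p = p, fit = red,
                     formula = red_formula)
      }
    }
    drop_it <- !is.na(best$p) && best$p > alpha
    trail[[length(trail) + 1L]] <- data.frame(
      term = best$term, lrt = best$lrt, df = best$df, p = best$p,
      dropped = drop_it, stringsAsFactors = FALSE)
    if (!drop_it) break
    fit <- best$fit
  }
  list(formula = fit$formula, fit = fit,
       trail = if (length(trail)) do.call(rbind, trail) else
         data.frame(term = character(0), lrt = numeric(0), df = integer(0),
                    p = numeric(0), dropped = logical(0)))
}

#' Sidak correction for multiple testing
#'
#' @param p vector of raw P-values.
#' @param m family size (defaults to `length(p)`).
#' @return adjusted P-values `1 - (1 - p)^m`.
#' @export
sidak_adjust <- function(p, m = length(p)) {
  pmin(1, 1 - (1 - p)^m)
}

#' Tukey-style pairwise contrasts of factor-cell means
#'
#' All pairwise comparisons of `compare`-factor levels within each cell of
#' the `by` factors (e.g. seasons within each sex-status cell), on the link
#' scale, using the fixed-effect covariance of the fit.  Numeric covariates
#' are held at their mean.  P-values are Sidak-adjusted within each family
#' (one `by` cell = one family).
#'
#' @param fit a `fox_fit`.
#' @param compare name of the factor whose levels are compared.
#' @param by character vector of conditioning factors (may be empty).
#' @return data.frame: family, contrast, estimate, se, z, p, p_sidak.
#' @export
tukey_contrasts <- function(fit, compare, by = character(0)) {
  dat <- fit$data
  lev <- function(v) levels(factor(dat[[v]]))
  grid_vars <- c(compare, by)
  grid <- expand.grid(lapply(stats::setNames(grid_vars, grid_vars), lev),
                      stringsAsFactors = FALSE)
  f <- lme4::nobars(fit$formula)
  num_vars <- setdiff(all.vars(delete.response(terms(f))), grid_vars)
  for (v in num_vars) {
    if (is.numeric(dat[[v]])) {
      grid[[v]] <- mean(dat[[v]], na.rm = TRUE)
    } else {
      grid[[v]] <- lev(v)[1]
    }
  }
  X <- fixed_design(fit, grid)
  beta <- fit$coefficients$estimate
  V <- fit$vcov
  fam_key <- if (length(by)) {
    interaction(grid[by], drop = TRUE, sep = ":")
  } else {
    factor(rep("all", nrow(grid)))
  }
  out <- list()
  for (famv in levels(fam_key)) {
    rows <- which(fam_key == famv)
    levs <- grid[rows, compare]
    if (length(rows) < 2) next
    prs <- utils::combn(seq_along(rows), 2)
    res <- data.frame(
      family = famv,
      contrast = paste(levs[prs[1, ]], levs[prs[2, ]], sep = " - "),
      estimate = NA_real_, se = NA_real_, stringsAsFactors = FALSE)
    for (k in seq_len(ncol(prs))) {
      l <- X[rows[prs[1, k]], ] - X[rows[prs[2, k]], ]
      res$estimate[k] <- sum(l * beta)
      res$se[k] <- sqrt(drop(t(l) %*% V %*% l))
    }
    res$z <- res$estimate / res$se
    res$p <- 2 * pnorm(-abs(res$z))
    res$p_sidak <- sidak_adjust(res$p, m = nrow(res))
    out[[length(out) + 1L]] <- res
  }
  do.call(rbind, out)
}

#' Model predictions with confidence intervals
#'
#' Inverse-link predictions at fixed covariate values with 95% (by default)
#' confidence intervals from the fixed-effect covariance; random effects are
#' set to zero.  Warns when numeric covariates fall outside the observed
#' range.
#'
#' @param fit a `fox_fit`.
#' @param newdata data.frame of covariate values.
#' @param level confidence level.
#' @return `newdata` with columns fit, lwr, upr (response scale).
#' @export
predict_rates <- function(fit, newdata, level = 0.95) {
  f <- lme4::nobars(fit$formula)
  for (v in all.vars(delete.response(terms(f)))) {
    if (is.numeric(fit$data[[v]]) && v %in% names(newdata)) {
      rng <- range(fit$data[[v]], na.rm = TRUE)
      if (any(newdata[[v]] < rng[1] | newdata[[v]] > rng[2])) {
        warning("extrapolating beyond the observed range of ", v)
      }
    }
  }
  X <- fixed_design(fit, newdata)
  beta <- fit$coefficients$estimate
  eta <- drop(X %*% beta)
  se <- sqrt(rowSums((X %*% fit$vcov) * X))
  z <- qnorm(1 - (1 - level) / 2)
  inv <- switch(fit$family,
                gaussian = identity,
                lognormal = function(x) 10^x - 1,
                poisson = exp, gamma = exp)
  newdata$fit <- inv(eta)
  newdata$lwr <- inv(eta - z * se)
  newdata$upr <- inv(eta + z * se)
  newdata
}

#' Days between associations from a daily rate
#'
#' A contact rate of r associations/day extrapolates to one association
#' every `round(1 / r)` days (e.g. 0.073/day -> every 14 days).
#'
#' @param rate numeric vector of daily association rates.
#' @return integer days; NA (with a warning) where the rate is not positive.
#' @export
days_between_associations <- function(rate) {
  out <- rep(NA_integer_, length(rate))
  ok <- !is.na(rate) & rate > 0
  if (any(!ok)) warning("non-positive rates are undefined; returning NA")
  out[ok] <- as.integer(round(1 / rate[ok]))
  out
}

#' Between-season repeatability of network position (ICC)
#'
#' Intercept-only mixed model with individual and territory random effects;
#' the intra-class correlation is the share of total variance attributable
#' to individual identity,
#' `ICC = var_ind / (var_ind + var_terr + var_res)`.  ICC < 0.3 is low
#' repeatability, > 0.7 high.
#'
#' @param data data.frame with one row per fox-network.
#' @param value_col column holding the centrality value.
#' @param fox_col,territory_col grouping columns.
#' @return list: icc, variance_individual, variance_territory,
#'   variance_residual, class ("low"/"moderate"/"high"), n.
#' @export
icc_repeatability <- function(data, value_col, fox_col = "fox",
                              territory_col = "territory") {
  df <- data.frame(value = data[[value_col]],
                   fox = data[[fox_col]],
                   territory = data[[territory_col]])
  df <- df[complete.cases(df), ]
  if (max(table(df$fox)) < 2) {
    warning("every individual has a single observation; ICC unidentifiable")
    return(list(icc = NA_real_, variance_individual = NA_real_,
                variance_territory = NA_real_, variance_residual = NA_real_,
                class = NA_character_, n = nrow(df)))
  }
  one_terr <- length(unique(df$territory)) < 2
  f <- if (one_terr) {
    value ~ 1 + (1 | fox)  # territory variance unidentifiable: set to 0
  } else {
    value ~ 1 + (1 | fox) + (1 | territory)
  }
  m <- suppressMessages(lme4::lmer(f, data = df, REML = FALSE))
  vc <- as.data.frame(lme4::VarCorr(m))
  v_ind <- vc$vcov[vc$grp == "fox"]
  v_ter <- if (one_terr) 0 else vc$vcov[vc$grp == "territory"]
  v_res <- vc$vcov[vc$grp == "Residual"]
  icc <- v_ind / (v_ind + v_ter + v_res)
  list(icc = icc, variance_individual = v_ind, variance_territory = v_ter,
       variance_residual = v_res,
       class = if (icc < 0.3) "low" else if (icc > 0.7) "high" else "moderate",
       n = nrow(df))
}

#' Paired Wilcoxon signed-rank test for non-resident sex bias
#'
#' Exact paired Wilcoxon signed-rank test on per-territory male vs female
#' non-resident counts, with effect size `r = Z / sqrt(n)` from the
#' normal-approximation Z of the signed-rank statistic.
#'
#' @param male,female paired per-territory counts.
#' @return list: W (min of the two signed-rank sums), V (positive-rank sum),
#'   p (exact two-sided where possible), z, r, n (non-zero pairs).
#' @export
nonresident_sex_test <- function(male, female) {
  stopifnot(length(male) == length(female))
  d <- male - female
  d <- d[d != 0]
  n <- length(d)
  if (n == 0) stop("all paired differences are zero; test undefined")
  rk <- rank(abs(d))
  v_pos <- sum(rk[d > 0])
  v_neg <- sum(rk[d < 0])
  mu <- n * (n + 1) / 4
  sig <- sqrt(n * (n + 1) * (2 * n + 1) / 24)
  # Z oriented on the reported W = min(V+, V-), so r <= 0 with |r| the
  # effect magnitude (the SOCPROG/field reporting convention)
  z <- (min(v_pos, v_neg) - mu) / sig
  wt <- suppressWarnings(wilcox.test(male, female, paired = TRUE,
                                     exact = TRUE))
  list(W = min(v_pos, v_neg), V = v_pos, p = wt$p.value, z = z,
       r = z / sqrt(n), n = n)
}

#' Collinearity diagnostics for model covariates
#'
#' Spearman rank correlations and variance inflation factors (each
#' covariate regressed on all others; `VIF = 1 / (1 - R^2)`).  Constant
#' covariates get NA; VIFs above the threshold are flagged with a warning.
#'
#' @param covariates data.frame of numeric covariates (>= 2 columns).
#' @param threshold VIF warning threshold (default 5).
#' @return list: spearman (correlation matrix), vif (named vector).
#' @export
collinearity_check <- function(covariates, threshold = 5) {
  stopifnot(ncol(covariates) >= 2)
  X <- as.data.frame(covariates)
  rho <- cor(X, method = "spearman")
  vif <- vapply(seq_along(X), function(j) {
    y <- X[[j]]
    if (var(y) == 0) return(NA_real_)
    others <- X[, -j, drop = FALSE]
    if (any(vapply(others, var, numeric(1)) == 0)) {
      others <- others[, vapply(others, var, numeric(1)) > 0, drop = FALSE]
    }
    if (ncol(others) == 0) return(1)
    # a perfect fit is the point of the diagnostic: silence lm's warning
    r2 <- suppressWarnings(
      summary(lm(y ~ ., data = cbind(y = y, others)))$r.squared)
    if (r2 >= 1 - 1e-12) Inf else 1 / (1 - r2)
  }, numeric(1))
  names(vif) <- names(X)
  high <- which(vif > threshold)
  if (length(high)) {
    warning("VIF above ", threshold, " for: ",
            paste(names(vif)[high], collapse = ", "))
  }
  list(spearman = rho, vif = vif)
}

#' Residual dispersion ratio for a Poisson fit
#'
#' Sum of squared Pearson residuals over the residual degrees of freedom;
#' values well above 1 indicate overdispersion.  Reported as a diagnostic
#' (no hard threshold).
#'
#' @param fit a `fox_fit` with a poisson family.
#' @return the dispersion ratio (scalar).
#' @export
dispersion_ratio <- function(fit) {
  m <- fit$model
  if (inherits(m, "merMod")) {
    r <- stats::residuals(m, type = "pearson")
    df <- length(r) - nrow(fit$coefficients) - nrow(fit$varcorr)
  } else {
    r <- stats::residuals(m, type = "pearson")
    df <- stats::df.residual(m)
  }
  sum(r^2) / df
}
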