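# Negative-binomial mixed-effects hurdle model for encounter durations.
# Most encounters are recorded as 0 seconds (start-only or touching visits),
# so a logistic mixed model separates zero from positive durations and a
# zero-truncated negative binomial with a log link models the positive
# seconds.  Both parts take the 'before midnight' x season interaction as
# fixed effects and a dyad random intercept.

# log P(Y = y | Y > 0) for NB(mu, theta), vectorised over a matrix mu
ltnb <- function(y, mu, theta) {
  lp0 <- theta * (log(theta) - log(theta + mu))       # log P(0)
  dnbinom(y, size = theta, mu = mu, log = TRUE) - log1p(-exp(lp0))
}

# zero-truncated NB regression with one Gaussian random intercept,
# fitted by Gauss-Hermite quadrature over the random effect
fit_tnb_re <- function(y, X, group, nagq = 15L, max_theta = 1e4) {
  stopifnot(all(y >= 1), nrow(X) == length(y), length(group) == length(y))
  group <- as.factor(group)
  gh <- lme4::GHrule(nagq)           # z, w: E[f(Z)] ~ sum w * f(z), Z ~ N(0,1)
  z <- gh[, "z"]; lw <- log(gh[, "w"])
  p <- ncol(X)
  nll <- function(par) {
    beta <- par[seq_len(p)]
    theta <- min(exp(par[p + 1]), max_theta)
    sigma <- exp(par[p + 2])
    eta <- drop(X %*% beta)
    # n x K log densities at each quadrature node
    ll <- vapply(seq_along(z), function(k) {
      ltnb(y, exp(eta + sigma * z[k]), theta)
    }, numeric(length(y)))
    by_group <- rowsum(ll, group)                    # G x K
    -sum(apply(sweep(by_group, 2, lw, "+"), 1, function(r) {
      m <- max(r); m + log(sum(exp(r - m)))
    }))
  }
  init_fit <- suppressWarnings(glm.fit(X, y, family = poisson()))
  par0 <- c(init_fit$coefficients, log_theta = 0, log_sigma = log(0.5))
  par0[is.na(par0)] <- 0
  opt <- optim(par0, nll, method = "BFGS", hessian = TRUE,
               control = list(maxit = 500))
  se <- rep(NA_real_, length(par0))
  h_ok <- all(is.finite(opt$hessian))
  if (h_ok) {
    vc <- tryCatch(solve(opt$hessian), error = function(e) NULL)
    if (!is.null(vc)) se <- sqrt(pmax(diag(vc), 0))
  }
  list(coefficients = data.frame(term = colnames(X),
                                 estimate = unname(opt$par[seq_len(p)]),
                                 se = se[seq_len(p)],
                                 row.names = NULL, stringsAsFactors = FALSE),
       theta = exp(opt$par[p + 1]), sigma = exp(opt$par[p + 2]),
       logLik = -opt$value, converged = opt$convergence == 0)
}

#' Negative-binomial mixed hurdle model for encounter durations
#'
#' Two-part model: a logistic mixed regression (dyad random intercept)
#' separates zero from positive durations, and a zero-truncated negative
#' binomial with log link (dyad random intercept, Gauss-Hermite quadrature)
#' models positive durations in seconds.  Default fixed effects in both
#' parts: the `before_midnight` x `season` interaction.
#'
#' @param data data.frame with duration_s (integer seconds >= 0),
#'   before_midnight (logical), season, and a dyad id column.
#' @param fixed right-hand-side formula for the fixed effects of both parts.
#' @param dyad_col name of the dyad id column.
#' @param nagq quadrature nodes for the positive part.
#' @return object of class `fox_hurdle`: list with `zero` (a `fox_fit` or
#'   NULL when degenerate), `positive` (truncated-NB fit or NULL),
#'   `p_zero_degenerate`, `p_positive_degenerate`, and `data` summaries.
#' @export
fit_hurdle_duration <- function(data, fixed = ~ before_midnight * season,
                                dyad_col = "dyad", nagq = 15L) {
  stopifnot(all(data$duration_s >= 0))
  df <- data
  df$.dyad <- as.factor(df[[dyad_col]])
  df$.pos <- as.numeric(df$duration_s > 0)
  n_pos <- sum(df$.pos)
  zero_fit <- NULL
  if (n_pos > 0 && n_pos < nrow(df)) {
    zf <- update(fixed, .pos ~ . + (1 | .dyad))
    zero_fit <- structure(
      list(model = suppressWarnings(
        lme4::glmer(zf, data = df, family = binomial())),
        formula = zf, family = "binomial", data = df),
      class = "fox_fit")
    m <- zero_fit$model
    beta <- lme4::fixef(m)
    zero_fit$coefficients <- data.frame(term = names(beta),
                                        estimate = unname(beta),
                                        se = sqrt(diag(as.matrix(vcov(m)))),
                                        row.names = NULL,
                                        stringsAsFactors = FALSE)
    zero_fit$vcov <- as.matrix(vcov(m))
    zero_fit$converged <- length(m@optinfo$conv$lme4$messages) == 0
  }
  pos_fit <- NULL
  if (n_pos >= 2) {
    pos <- df[df$.pos == 1, ]
    X <- model.matrix(fixed, pos)
    keep <- colnames(X) == "(Intercept)" | apply(X, 2, var) > 0
    pos_fit <- fit_tnb_re(pos$duration_s, X[, keep, drop = FALSE],
                          pos$.dyad, nagq = nagq)
  }
  structure(list(zero = zero_fit, positive = pos_fit,
                 p_zero_degenerate = n_pos == nrow(df),
                 p_positive_degenerate = n_pos == 0,
                 n = nrow(df), n_positive = n_pos,
                 fixed = fixed),
            class = "fox_hurdle")
}

#' @export
print.fox_hurdle <- function(x, ...) {
  cat(sprintf("fox_hurdle: %d encounters, %d positive\n", x$n, x$n_positive))
  if (!is.null(x$zero)) {
    cat("zero part (logistic, P(positive)):\n")
    print(x$zero$coefficients)
  } else cat("zero part degenerate\n")
  if (!is.null(x$positive)) {
    cat(sprintf("positive part (truncated NB, theta %.3g, sigma %.3g):\n",
                x$positive$theta, x$positive$sigma))
    print(x$positive$coefficients)
  } else cat("positive part degenerate\n")
  invisible(x)
}

#' Predicted mean encounter duration from a hurdle fit
#'
#' Combines the two parts with random effects at zero: the predicted mean is
#' `P(positive) * mu / (1 - P0(mu, theta))`, the probability of a non-zero
#' encounter times the truncated-NB mean.
#'
#' @param fit a `fox_hurdle`.
#' @param newdata covariate values (before_midnight, season, ...).
#' @return numeric vector of predicted mean durations (seconds).
#' @export
predict_hurdle_mean <- function(fit, newdata) {
  stopifnot(!is.null(fit$zero), !is.null(fit$positive))
  Xz <- model.matrix(fit$fixed, newdata)
  bz <- fit$zero$coefficients$estimate
  names(bz) <- fit$zero$coefficients$term
  p_pos <- stats::plogis(drop(Xz[, names(bz), drop = FALSE] %*% bz))
  bp <- fit$positive$coefficients$estimate
  names(bp) <- fit$positive$coefficients$term
  Xp <- model.matrix(fit$fixed, newdata)
  mu <- exp(drop(Xp[, names(bp), drop = FALSE] %*% bp))
  theta <- fit$positive$theta
  p0 <- (theta / (theta + mu))^theta
  p_pos * mu / (1 - p0)
}
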