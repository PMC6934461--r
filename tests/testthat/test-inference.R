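# model fitting, contrasts, hurdle durations, ICC, worked examples

test_that("Poisson GLMM recovers known coefficients within 3 SE", {
  set.seed(100)
  n <- 5000
  season <- sample(c("spring", "winter"), n, replace = TRUE)
  id <- sample(sprintf("f%02d", 1:40), n, replace = TRUE)
  b_id <- rnorm(40, 0, 0.3)
  names(b_id) <- sprintf("f%02d", 1:40)
  eta <- log(0.2) + 0.5 * (season == "winter") + b_id[id]
  y <- rpois(n, exp(eta))
  df <- data.frame(y = y, season = factor(season,
                                          levels = c("spring", "winter")),
                   id = id)
  fit <- fit_model(y ~ season + (1 | id), df, family = "poisson")
  co <- fit$coefficients
  expect_lt(abs(co$estimate[co$term == "(Intercept)"] - log(0.2)),
            3 * co$se[co$term == "(Intercept)"])
  expect_lt(abs(co$estimate[co$term == "seasonwinter"] - 0.5),
            3 * co$se[co$term == "seasonwinter"])
  expect_true(fit$converged)
  expect_equal(fit$varcorr$group, "id")
})

test_that("gaussian LMM with a zero-variance group collapses to OLS", {
  set.seed(101)
  df <- data.frame(y = rnorm(60, 2), x = rnorm(60),
                   g = rep(c("a", "b", "c"), 20))
  df$y <- df$y + 0.8 * df$x
  fit <- fit_model(y ~ x + (1 | g), df)
  ols <- lm(y ~ x, df)
  expect_lt(fit$varcorr$variance[fit$varcorr$group == "g"], 1e-6)
  expect_equal(fit$coefficients$estimate, unname(coef(ols)),
               tolerance = 1e-4)
})

test_that("stepwise reduction drops noise and keeps real interactions", {
  set.seed(102)
  n <- 400
  df <- data.frame(x = rnorm(n), z = rnorm(n),
                   f = sample(c("u", "v"), n, replace = TRUE))
  df$y <- 1 + 0.8 * df$x + 1.2 * df$x * (df$f == "v") + rnorm(n)
  red <- stepwise_reduce(y ~ x * f + z, df, family = "gaussian")
  kept <- attr(terms(red$formula), "term.labels")
  expect_true("x:f" %in% kept)
  expect_false("z" %in% kept)
  # pure noise model reduces to the intercept-only floor
  df$y2 <- rnorm(n)
  red2 <- stepwise_reduce(y2 ~ z, df)
  expect_equal(attr(terms(red2$formula), "term.labels"), character(0))
})

test_that("Sidak adjustment and Tukey-style contrasts", {
  expect_equal(sidak_adjust(0.01, 1), 0.01)
  expect_equal(sidak_adjust(0.01, 6), 1 - 0.99^6)
  set.seed(103)
  n <- 600
  df <- data.frame(sex = sample(c("F", "M"), n, replace = TRUE),
                   season = sample(c("spring", "summer"), n, replace = TRUE))
  df$y <- 2 + 1 * (df$sex == "M") + rnorm(n)
  fit <- fit_model(y ~ sex * season, df)
  ct <- tukey_contrasts(fit, compare = "sex", by = "season")
  expect_equal(nrow(ct), 2)  # F-M within each season
  expect_true(all(abs(ct$estimate + 1) < 0.5))
  expect_true(all(ct$p_sidak >= ct$p - 1e-12))
  # contrasts of a null factor are not significant (family-wise)
  df$y0 <- rnorm(n)
  fit0 <- fit_model(y0 ~ sex * season, df)
  ct0 <- tukey_contrasts(fit0, compare = "season", by = "sex")
  expect_true(all(ct0$p_sidak > 0.001))
})

test_that("predictions invert the link with calibrated intervals", {
  set.seed(104)
  df <- data.frame(y = rpois(500, 2))
  fit <- fit_model(y ~ 1, df, family = "poisson")
  pr <- predict_rates(fit, data.frame(x = 1))
  expect_equal(pr$fit, mean(df$y), tolerance = 1e-6)
  expect_true(pr$lwr < pr$fit && pr$fit < pr$upr)
  # monotone link: predictions increase in a positive coefficient
  df2 <- data.frame(x = runif(400, 0, 2))
  df2$y <- rpois(400, exp(0.2 + 0.9 * df2$x))
  fit2 <- fit_model(y ~ x, df2, family = "poisson")
  grid <- data.frame(x = c(0.2, 0.8, 1.5))
  pr2 <- predict_rates(fit2, grid)
  expect_true(all(diff(pr2$fit) > 0))
  expect_warning(predict_rates(fit2, data.frame(x = 99)), "extrapolating")
  # link / inverse-link consistency
  expect_equal(log(exp(1.234)), 1.234, tolerance = 1e-10)
})

test_that("prediction intervals achieve near-nominal coverage", {
  set.seed(105)
  hits <- 0L; n_rep <- 200L
  for (r in seq_len(n_rep)) {
    df <- data.frame(y = rpois(80, 2))
    fit <- fit_model(y ~ 1, df, family = "poisson")
    pr <- predict_rates(fit, data.frame(z = 1))
    if (pr$lwr <= 2 && 2 <= pr$upr) hits <- hits + 1L
  }
  # 95% nominal; allow 3 binomial SE
  expect_gt(hits / n_rep, 0.95 - 3 * sqrt(0.05 * 0.95 / n_rep))
})

test_that("days between associations matches the reciprocal rule", {
  expect_equal(days_between_associations(1.0), 1L)
  expect_equal(days_between_associations(c(0.5, 0.25)), c(2L, 4L))
  expect_warning(out <- days_between_associations(c(0.1, 0)), "undefined")
  expect_true(is.na(out[2]))
})

test_that("hurdle model recovers simulated zero and positive parts", {
  set.seed(106)
  n_dyad <- 60; per <- 12
  dyad <- rep(sprintf("d%02d", 1:n_dyad), each = per)
  before <- rep(c(TRUE, FALSE), length.out = n_dyad * per)
  b_d <- rnorm(n_dyad, 0, 0.4); names(b_d) <- sprintf("d%02d", 1:n_dyad)
  # zero part: P(positive) = plogis(-0.85 + 1.0*before) ~ 0.3 baseline
  p_pos <- plogis(-0.85 + 1.0 * before + b_d[dyad])
  pos <- rbinom(n_dyad * per, 1, p_pos)
  # positive part: truncated NB, mu = exp(5.3 + 0.4*before) ~ 200 s
  mu <- exp(5.3 + 0.4 * before + b_d[dyad])
  y <- integer(n_dyad * per)
  for (i in which(pos == 1)) {
    repeat { v <- rnbinom(1, size = 1.2, mu = mu[i]); if (v > 0) break }
    y[i] <- v
  }
  df <- data.frame(duration_s = y, before_midnight = before,
                   season = "spring", dyad = dyad)
  fit <- fit_hurdle_duration(df, fixed = ~ before_midnight, nagq = 9)
  zc <- fit$zero$coefficients
  expect_lt(abs(zc$estimate[zc$term == "before_midnightTRUE"] - 1.0),
            3 * zc$se[zc$term == "before_midnightTRUE"])
  pc <- fit$positive$coefficients
  expect_lt(abs(pc$estimate[pc$term == "(Intercept)"] - 5.3),
            3 * pc$se[pc$term == "(Intercept)"])
  expect_lt(abs(pc$estimate[pc$term == "before_midnightTRUE"] - 0.4),
            3 * pc$se[pc$term == "before_midnightTRUE"])
  # combined mean prediction tracks the simulation average
  newd <- data.frame(before_midnight = TRUE, season = "spring")
  pred <- predict_hurdle_mean(fit, newd)
  emp <- mean(y[before])
  expect_lt(abs(pred - emp) / emp, 0.25)
  # degenerate parts are flagged
  df0 <- df; df0$duration_s <- 0L
  fit0 <- fit_hurdle_duration(df0, fixed = ~ before_midnight)
  expect_true(fit0$p_positive_degenerate)
  expect_null(fit0$zero)
})

test_that("ICC classification and degenerate cases", {
  # zero individual variance -> ICC ~ 0
  set.seed(107)
  df <- data.frame(fox = rep(sprintf("f%02d", 1:50), each = 4),
                   territory = rep(sprintf("t%d", 1:5), each = 40))
  df$value <- rnorm(200)
  out <- icc_repeatability(df, "value")
  expect_lt(out$icc, 0.1)
  expect_equal(out$class, "low")
  # single observation per fox is unidentifiable
  df1 <- df[!duplicated(df$fox), ]
  expect_warning(out1 <- icc_repeatability(df1, "value"), "unidentifiable")
  expect_true(is.na(out1$icc))
})

test_that("Wilcoxon signed-rank: extreme case and exact-enumeration oracle", {
  # 7 pairs, all male > female -> W = 0
  male <- c(5, 4, 6, 3, 7, 2, 8); female <- c(1, 2, 3, 1, 2, 0, 4)
  out <- nonresident_sex_test(male, female)
  expect_equal(out$W, 0)
  expect_lt(out$p, 0.05)
  expect_lt(out$r, 0)  # negative Z convention: W at the bottom of its range
  expect_equal(abs(out$r), abs(out$z) / sqrt(7))
  # identical pairs undefined
  expect_error(nonresident_sex_test(c(1, 2), c(1, 2)), "undefined")
  # random pairs match enumeration (n <= 10, tie-free)
  set.seed(108)
  for (r in 1:8) {
    n <- sample(5:9, 1)
    d <- sample(c(-1, 1), n, replace = TRUE) * sample(seq(10, 90, 10), n)
    m <- abs(d) * (d > 0); f <- abs(d) * (d < 0)
    out <- nonresident_sex_test(m, f)
    expect_equal(out$p, oracle_wilcoxon_p(d), tolerance = 1e-10)
  }
})

test_that("collinearity check reports rank correlation and VIFs", {
  set.seed(109)
  x <- rnorm(200); z <- rnorm(200)
  chk <- collinearity_check(data.frame(x = x, z = z))
  expect_lt(abs(chk$spearman[1, 2]), 0.2)
  expect_true(all(abs(chk$vif - 1) < 0.1))
  expect_warning(chk2 <- collinearity_check(data.frame(x = x, x2 = x)),
                 "VIF above")
  expect_true(is.infinite(chk2$vif[1]) || chk2$vif[1] > 100)
})

test_that("dispersion ratio flags overdispersion and not equidispersion", {
  set.seed(110)
  df <- data.frame(y = rpois(800, 3))
  fit <- fit_model(y ~ 1, df, family = "poisson")
  expect_lt(abs(dispersion_ratio(fit) - 1), 0.2)
  df$y2 <- rnbinom(800, size = 0.6, mu = 3)  # strongly overdispersed
  fit2 <- fit_model(y2 ~ 1, df, family = "poisson")
  expect_gt(dispersion_ratio(fit2), 1.5)
})
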