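test_that("latent correlation formulas reproduce known arithmetic", {
  lc <- latent_correlations(0.758, 1.226, 0.293, 0.473)
  expect_equal(lc$combined_correlation, 0.766 / sqrt(1.758 * 2.226),
               tolerance = 1e-12)
  expect_equal(lc$re_correlation, 0.293 / sqrt(0.758 * 1.226),
               tolerance = 1e-12)
  expect_equal(lc$icc_left, 0.758 / 1.758, tolerance = 1e-12)
  expect_equal(lc$icc_right, 1.226 / 2.226, tolerance = 1e-12)

  # degenerate: no random effects
  lc0 <- latent_correlations(0, 0, 0, 0.3)
  expect_true(is.na(lc0$re_correlation))
  expect_equal(lc0$icc_left, 0)
  expect_equal(lc0$icc_right, 0)
  expect_equal(lc0$combined_correlation, 0.3)
})

test_that("correlation summary matches the formulas with plausible CIs", {
  fit <- fixture_fit()
  cs <- correlation_summary(fit)
  e <- fit$estimates
  lc <- latent_correlations(e$var_left, e$var_right, e$cov_lr, e$rho_err)
  for (q in cs$quantity)
    expect_equal(cs$estimate[cs$quantity == q], unname(lc[[q]]),
                 tolerance = 1e-10)
  expect_true(all(cs$se > 0))
  expect_true(all(cs$lower <= cs$estimate & cs$estimate <= cs$upper))
  expect_true(all(abs(cs$estimate[grepl("correlation", cs$quantity)]) <= 1))
  iccs <- cs$estimate[grepl("icc", cs$quantity)]
  expect_true(all(iccs >= 0 & iccs < 1))
})

test_that("closed-form population-averaged margin equals quadrature", {
  fit <- fixture_fit()
  p <- length(fit$estimates$beta_left)
  X <- fit$prep$X
  u <- unpack_parameters(fit$theta, p)
  closed <- mean(pnorm(drop(X %*% u$beta_left) / sqrt(1 + u$var_left)))
  # oracle: 50-node univariate quadrature of Phi(eta + b), b ~ N(0, var)
  gh <- pracma::gaussHermite(50)
  eta <- drop(X %*% u$beta_left)
  quad <- mean(vapply(eta, function(e)
    sum(gh$w * pnorm(e + sqrt(2 * u$var_left) * gh$x)) / sqrt(pi),
    numeric(1)))
  expect_equal(closed, quad, tolerance = 1e-8)
  expect_equal(marginal_prediction(fit, "LO")$probability, closed,
               tolerance = 1e-12)
})

test_that("margins are exactly 1/2 for a null model", {
  fit <- fixture_fit()
  p <- length(fit$estimates$beta_left)
  th0 <- c(rep(0, 2 * p), -30, 0, -30, 0)
  expect_equal(marginal_prediction(fit, "LO", theta = th0)$probability, 0.5,
               tolerance = 1e-12)
  expect_equal(joint_marginal_prediction(fit, theta = th0)$probability, 0.25,
               tolerance = 1e-9)
})

test_that("joint prediction collapses to the product under independence", {
  fit <- fixture_fit()
  p <- length(fit$estimates$beta_left)
  th <- fit$theta
  th[2 * p + 2] <- 0          # cov_lr = 0
  th[2 * p + 4] <- 0          # rho_err = 0
  jl <- joint_marginal_prediction(fit, theta = th)$probability
  # product computed record-wise, then averaged
  u <- unpack_parameters(th, p)
  X <- fit$prep$X
  prod_rec <- mean(pnorm(drop(X %*% u$beta_left) / sqrt(1 + u$var_left)) *
                     pnorm(drop(X %*% u$beta_right) / sqrt(1 + u$var_right)))
  expect_equal(jl, prod_rec, tolerance = 1e-10)
})

test_that("joint prediction never exceeds either margin", {
  fit <- fixture_fit()
  tab <- margins_table(fit)
  for (st in unique(tab$stratum)) {
    rows <- tab[tab$stratum == st, ]
    expect_lte(rows$probability[rows$outcome == "joint"],
               min(rows$probability[rows$outcome %in% c("LO", "RO")]) + 1e-9)
  }
})

test_that("share-weighted stratum margins reproduce the overall margin", {
  fit <- fixture_fit()
  rec <- fit$prep$records
  overall <- marginal_prediction(fit, "LO")$probability
  levs <- levels(rec$sonographer_id)
  shares <- table(rec$sonographer_id)[levs] / nrow(rec)
  parts <- vapply(levs, function(s)
    marginal_prediction(fit, "LO", c(sonographer = s),
                        average = "stratum")$probability, numeric(1))
  expect_equal(sum(shares * parts), overall, tolerance = 1e-8)
})

test_that("unknown strata are rejected by name", {
  fit <- fixture_fit()
  expect_error(marginal_prediction(fit, "LO", c(sonographer = "Z")),
               "unknown sonographer level 'Z'")
  expect_error(marginal_prediction(fit, "LO", c(taster = "A")),
               "unknown stratum type")
})

test_that("empirical Bayes means behave like posterior expectations", {
  fit <- fixture_fit()
  eb <- empirical_bayes(fit)
  expect_equal(nrow(eb), fit$n_scans)

  rec <- fit$prep$records
  agg <- tapply(rec$y_left, rec$scan_id,
                function(y) mean(y, na.rm = TRUE))
  all1 <- names(agg)[agg == 1]
  all0 <- names(agg)[agg == 0]
  expect_gt(min(length(all1), length(all0)), 0)
  # scans where every review confirmed sit above scans where none did
  expect_gt(mean(eb$eb_left[eb$scan_id %in% all1]),
            mean(eb$eb_left[eb$scan_id %in% all0]))
  # posterior means average out near zero at the MLE
  expect_lt(abs(mean(eb$eb_left)), 0.05)
  expect_lt(abs(mean(eb$eb_right)), 0.05)

  # near-zero prior variance shrinks everything to the prior mean
  thsmall <- fit$theta
  p <- length(fit$estimates$beta_left)
  thsmall[c(2 * p + 1, 2 * p + 3)] <- -8
  thsmall[2 * p + 2] <- 0
  fit2 <- fit; fit2$theta <- thsmall
  eb2 <- empirical_bayes(fit2)
  expect_lt(max(abs(c(eb2$eb_left, eb2$eb_right))), 1e-5)

  expect_error(empirical_bayes(fit, scan_id = "nope"), "unknown scan")
})

test_that("tetrachoric correlation matches a margin-constrained oracle", {
  tabs <- list(matrix(c(40, 12, 8, 40), 2, 2),
               matrix(c(100, 30, 45, 60), 2, 2),
               matrix(c(12, 20, 25, 9), 2, 2))
  for (tab in tabs) {
    est <- tetrachoric(tab)
    # oracle: the 2x2 MLE fits the margins exactly, so rho solves
    # P(Z1 > c1, Z2 > c2; rho) = p11-hat with thresholds at margin quantiles
    n <- sum(tab)
    c1 <- qnorm(1 - sum(tab[2, ]) / n)
    c2 <- qnorm(1 - sum(tab[, 2]) / n)
    f <- function(r)
      mvtnorm::pmvnorm(lower = c(c1, c2),
                       corr = matrix(c(1, r, r, 1), 2)) - tab[2, 2] / n
    r_star <- uniroot(f, c(-0.999, 0.999), tol = 1e-12)$root
    expect_equal(est$rho, r_star, tolerance = 1e-5)
    expect_true(est$se > 0)
  }
})

test_that("tetrachoric handles degenerate tables", {
  expect_warning(r1 <- tetrachoric(matrix(c(50, 0, 0, 50), 2, 2)), "boundary")
  expect_equal(r1$rho, 1)
  expect_warning(r2 <- tetrachoric(matrix(c(0, 30, 30, 0), 2, 2)), "boundary")
  expect_equal(r2$rho, -1)
  # independent margins: estimate near zero
  tab <- round(200 * outer(c(0.3, 0.7), c(0.4, 0.6)))
  est <- tetrachoric(tab)
  expect_lt(abs(est$rho), 0.02)
  expect_error(tetrachoric(matrix(c(5, 5, 0, 0), 2, 2)), "margins")
})

test_that("standard bivariate probit is the zero-variance special case", {
  nm <- names(study_parameters()$beta_left)
  b <- setNames(c(0.5, 0.3, -0.4, 0.2, 0.6, -0.2, 0.1, rep(0.15, 7)), nm)
  pars <- true_parameters(b, b, 0, 0, 0, 0.4)
  dat <- generate_audit_dataset(pars, small_design(scans = 40), seed = 61)
  std <- suppressWarnings(standard_biprobit(dat))
  expect_equal(std$estimates$var_left, 0)
  expect_equal(std$estimates$var_right, 0)
  # recovers the generating latent correlation
  se_rho <- sqrt(std$natural$vcov["rho_err", "rho_err"])
  expect_lt(abs(std$estimates$rho_err - 0.4), 3 * se_rho)
  # the free-variance fit agrees when the truth has no random effects
  free <- suppressWarnings(fit_biprobit(dat, model_spec(nodes = 8)))
  expect_lt(free$estimates$var_left, 0.1)
  expect_lt(abs(free$estimates$rho_err - std$estimates$rho_err), 0.05)
  expect_lt(max(abs(free$natural$par[1:28] - std$natural$par[1:28])), 0.05)
})

test_that("delta-method standard errors agree with a cluster bootstrap", {
  nm <- names(study_parameters()$beta_left)
  b <- setNames(c(0.7, 0.4, -0.3, 0.2, 0.5, -0.1, 0.3, rep(0, 7)), nm)
  pars <- true_parameters(b, b, 0.6, 0.9, 0.25, 0.45)
  dat <- generate_audit_dataset(pars, small_design(scans = 25), seed = 71)
  spec <- model_spec("none", nodes = 6)
  fit <- suppressWarnings(fit_biprobit(dat, spec))

  stat_fun <- function(f) c(
    margin_lo = marginal_prediction(f, "LO")$probability,
    joint = joint_marginal_prediction(f)$probability,
    icc_left = correlation_summary(f)$estimate[4],
    rho_err = f$estimates$rho_err)

  delta_se <- c(
    margin_lo = marginal_prediction(fit, "LO")$se,
    joint = joint_marginal_prediction(fit)$se,
    icc_left = correlation_summary(fit)$se[4],
    rho_err = sqrt(fit$natural$vcov["rho_err", "rho_err"]))

  set.seed(81)
  B <- 100
  boot <- matrix(NA_real_, B, 4)
  for (i in seq_len(B)) {
    bf <- tryCatch(
      suppressWarnings(fit_biprobit(bootstrap_data(dat), spec,
                                    start = fit$theta, vcov = FALSE)),
      error = function(e) NULL)
    if (!is.null(bf) && bf$converged) boot[i, ] <- stat_fun(bf)
  }
  boot_se <- apply(boot, 2, stats::sd, na.rm = TRUE)
  expect_gt(sum(!is.na(boot[, 1])), 0.9 * B)
  ratio <- delta_se / boot_se
  expect_true(all(ratio > 0.75 & ratio < 1.33),
              info = paste("SE ratios:", paste(round(ratio, 3),
                                               collapse = ", ")))
})
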