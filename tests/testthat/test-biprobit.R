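test_that("bivariate normal CDF agrees with an independent implementation", {
  set.seed(4)
  for (i in 1:200) {
    h <- runif(1, -4, 4); k <- runif(1, -4, 4); r <- runif(1, -0.9999, 0.9999)
    ref <- mvtnorm::pmvnorm(upper = c(h, k),
                            corr = matrix(c(1, r, r, 1), 2),
                            algorithm = mvtnorm::Miwa(steps = 1024))
    expect_lt(abs(pbvnorm(h, k, r) - ref), 5e-10)
  }
  # limits
  expect_equal(pbvnorm(Inf, 1, 0.5), pnorm(1))
  expect_equal(pbvnorm(-Inf, 1, 0.5), 0)
  expect_equal(pbvnorm(1, 2, 1), pnorm(1))
  expect_equal(pbvnorm(1, -1, -1), 0)
})

test_that("pack/unpack is a bijection onto valid parameter sets", {
  set.seed(10)
  for (i in 1:25) {
    p <- sample(1:6, 1)
    bl <- rnorm(p); br <- rnorm(p)
    vl <- runif(1, 0.05, 3); vr <- runif(1, 0.05, 3)
    cv <- runif(1, -1, 1) * sqrt(vl * vr) * 0.95
    rho <- runif(1, -0.95, 0.95)
    th <- pack_parameters(bl, br, vl, vr, cv, rho)
    u <- unpack_parameters(th, p)
    expect_equal(u$beta_left, bl)
    expect_equal(u$var_left, vl)
    expect_equal(u$var_right, vr)
    expect_equal(u$cov_lr, cv)
    expect_equal(u$rho_err, rho)
    # any unconstrained vector gives a PSD covariance and |rho| < 1
    th2 <- rnorm(2 * p + 4, sd = 2)
    u2 <- unpack_parameters(th2, p)
    S <- matrix(c(u2$var_left, u2$cov_lr, u2$cov_lr, u2$var_right), 2)
    expect_gte(min(eigen(S, symmetric = TRUE)$values), -1e-12)
    expect_lt(abs(u2$rho_err), 1)
  }
})

test_that("single-review likelihood matches the orthant closed form", {
  # one scan, one review, both confirmed, betas 0, rho = 0.5, variance ~ 0:
  # contribution is Phi2(0, 0; 0.5) = 1/4 + asin(0.5) / (2 pi)
  df <- data.frame(scan_id = "S1", volunteer_id = "V1", sonographer_id = "A",
                   expert_id = "1", qualification = "gynaecologist",
                   y_left = 1L, y_right = 1L)
  dat <- as_audit_data(df)
  theta <- c(0, 0, -30, 0, -30, atanh(0.5))
  nll <- suppressWarnings(biprobit_nll(theta, dat, model_spec(nodes = 5)))
  expect_equal(as.numeric(nll), -log(0.25 + asin(0.5) / (2 * pi)),
               tolerance = 1e-10)
})

test_that("likelihood reduces to independent probits at zero variance and rho", {
  dat <- small_data(seed = 13, scans = 6)
  spec <- model_spec("expert", nodes = 9)
  prep <- suppressWarnings(ovaudit:::prepare_model_data(dat, spec))
  p <- ncol(prep$X)
  set.seed(1); bl <- rnorm(p, sd = 0.3); br <- rnorm(p, sd = 0.3)
  theta <- c(bl, br, -30, 0, -30, 0)
  nll <- as.numeric(suppressWarnings(biprobit_nll(theta, dat, spec)))
  # oracle: two separate univariate probit log-likelihoods
  ll_uni <- function(y, eta) {
    obs <- y >= 0
    sum(log(pnorm((2 * y[obs] - 1) * eta[obs])))
  }
  ref <- -(ll_uni(prep$yl, drop(prep$X %*% bl)) +
             ll_uni(prep$yr, drop(prep$X %*% br)))
  expect_equal(nll, ref, tolerance = 1e-8)
})

test_that("likelihood splits into two univariate RE probits when cov and rho are zero", {
  dat <- small_data(seed = 17, scans = 5)
  spec <- model_spec("expert", nodes = 30)
  prep <- suppressWarnings(ovaudit:::prepare_model_data(dat, spec))
  p <- ncol(prep$X)
  set.seed(2); bl <- rnorm(p, sd = 0.3); br <- rnorm(p, sd = 0.3)
  s2l <- 0.7; s2r <- 1.3
  theta <- c(bl, br, log(sqrt(s2l)), 0, log(sqrt(s2r)), 0)
  nll <- as.numeric(suppressWarnings(biprobit_nll(theta, dat, spec)))

  # oracle: univariate Gauss-Hermite RE probit per equation, written anew
  gh <- pracma::gaussHermite(40)
  re_probit_ll <- function(y, eta, s2) {
    total <- 0
    for (s in unique(prep$records$scan_id)) {
      at <- prep$records$scan_id == s
      ys <- y[at]; es <- eta[at]
      obs <- ys >= 0
      if (!any(obs)) next
      vals <- vapply(seq_along(gh$x), function(j) {
        b <- sqrt(2 * s2) * gh$x[j]
        prod(pnorm((2 * ys[obs] - 1) * (es[obs] + b)))
      }, numeric(1))
      total <- total + log(sum(gh$w * vals) / sqrt(pi))
    }
    total
  }
  ref <- -(re_probit_ll(prep$yl, drop(prep$X %*% bl), s2l) +
             re_probit_ll(prep$yr, drop(prep$X %*% br), s2r))
  expect_equal(nll, ref, tolerance = 1e-8)
})

test_that("analytic gradient matches finite differences", {
  dat <- small_data(seed = 19, scans = 4)
  spec <- model_spec("expert", nodes = 6)
  prep <- suppressWarnings(ovaudit:::prepare_model_data(dat, spec))
  p <- ncol(prep$X)
  set.seed(3)
  theta <- c(rnorm(2 * p, sd = 0.4), log(0.8), 0.25, log(0.9), atanh(0.4))
  rule <- ovaudit:::ghq_rule(6)
  g <- ovaudit:::nll_raw(theta, prep, rule, want_grad = TRUE)$grad
  gfd <- ovaudit:::fd_gradient(function(t) ovaudit:::nll_raw(t, prep, rule),
                               theta)
  expect_lt(max(abs(g - gfd) / (1 + abs(gfd))), 1e-5)
})

test_that("quadrature is converged at 12 nodes (doubling changes little)", {
  dat <- generate_audit_dataset(study_parameters(), nominal_study_design(),
                                seed = 42)
  p <- study_parameters()
  th <- pack_parameters(p$beta_left, p$beta_right, p$var_left, p$var_right,
                        p$cov_lr, p$rho_err)
  n12 <- as.numeric(biprobit_nll(th, dat, model_spec(nodes = 12)))
  n24 <- as.numeric(biprobit_nll(th, dat, model_spec(nodes = 24)))
  expect_lt(abs(n12 - n24) / abs(n24), 1e-4)
})

test_that("adaptive and non-adaptive quadrature agree", {
  dat <- small_data(seed = 23, scans = 8)
  p <- study_parameters()
  th <- pack_parameters(p$beta_left, p$beta_right, p$var_left, p$var_right,
                        p$cov_lr, p$rho_err)
  plain <- as.numeric(suppressWarnings(
    biprobit_nll(th, dat, model_spec(nodes = 25))))
  adapt <- as.numeric(suppressWarnings(
    biprobit_nll(th, dat, model_spec(nodes = 12, adaptive = TRUE))))
  expect_lt(abs(plain - adapt) / abs(plain), 1e-5)
})

test_that("estimates are invariant to record order", {
  dat <- small_data(seed = 29, scans = 10)
  spec <- model_spec("expert", nodes = 8)
  f1 <- suppressWarnings(fit_biprobit(dat, spec))
  set.seed(1)
  perm <- sample(nrow(dat$records))
  dat2 <- suppressMessages(as_audit_data(dat$records[perm, ]))
  f2 <- suppressWarnings(fit_biprobit(dat2, spec))
  expect_lt(max(abs(f1$natural$par - f2$natural$par)), 1e-3)
  expect_equal(f1$loglik, f2$loglik, tolerance = 1e-8)
})

test_that("the fitted model recovers the generating parameters", {
  dat <- generate_audit_dataset(study_parameters(), nominal_study_design(),
                                seed = 42)
  fit <- suppressWarnings(fit_biprobit(dat, model_spec("expert", nodes = 12)))
  expect_true(fit$converged)
  truth <- study_parameters()
  est <- fit$estimates
  se <- sqrt(diag(fit$natural$vcov))
  for (q in c("var_left", "var_right", "cov_lr", "rho_err")) {
    expect_lt(abs(est[[q]] - truth[[q]]), 4 * se[[q]])
  }
  # fixed effects too (a representative handful)
  nm <- c("LO:(Intercept)", "LO:sonographer_idC", "RO:expert_id5")
  tr <- c(truth$beta_left["(Intercept)"], truth$beta_left["sonographerC"],
          truth$beta_right["expert5"])
  expect_true(all(abs(fit$natural$par[nm] - tr) < 4 * se[nm]))
})

test_that("Wald machinery behaves on trivial and joint constraints", {
  fit <- fixture_fit()
  # single-parameter test at its own estimate: statistic 0, p = 1
  R <- matrix(0, 1, length(fit$natural$par),
              dimnames = list(NULL, names(fit$natural$par)))
  R[, "rho_err"] <- 1
  w0 <- wald_test(fit, R = R, r = fit$estimates$rho_err)
  expect_equal(w0$statistic, 0, tolerance = 1e-10)
  expect_equal(w0$p.value, 1)

  # joint block test on the sonographer contrasts
  terms <- grep("^LO:sonographer", names(fit$natural$par), value = TRUE)
  wj <- wald_test(fit, terms = terms)
  expect_equal(wj$df, 6)
  expect_gt(wj$statistic, 0)
  expect_lt(wj$p.value, 0.5)

  # cross-equation equality test runs and gives a valid p
  wx <- ovaudit:::wald_cross_equation(fit, "^sonographer")
  expect_equal(wx$df, 6)
  expect_gte(wx$p.value, 0)

  expect_error(wald_test(fit, terms = "no_such_term"), "unknown")
  expect_error(wald_test(fit, R = rbind(R, R)), "full row rank")
})

test_that("separation and aliasing are reported", {
  df <- fixture_df()
  df$y_left[df$sonographer_id == "B"] <- 1L
  expect_warning(
    ovaudit:::prepare_model_data(as_audit_data(df), model_spec("none",
                                                               nodes = 4)),
    "separation")

  # expert perfectly collinear with sonographer
  ali <- data.frame(
    scan_id = rep(sprintf("S%d", 1:8), each = 1),
    volunteer_id = sprintf("V%d", 1:8),
    sonographer_id = rep(c("A", "B"), each = 4),
    expert_id = rep(c("1", "2"), each = 4),
    qualification = rep(c("gynaecologist", "radiologist"), each = 4),
    y_left = c(1, 0, 1, 0, 1, 1, 0, 0),
    y_right = c(0, 1, 1, 0, 1, 0, 1, 0)
  )
  expect_error(
    suppressWarnings(
      ovaudit:::prepare_model_data(as_audit_data(ali),
                                   model_spec("expert", nodes = 4))),
    "aliased")
})

test_that("all model variants fit and nest correctly", {
  dat <- fixture_data()
  fits <- suppressWarnings(fit_all_variants(dat, nodes = 6))
  expect_named(fits, c("expert", "qualification", "none"))
  expect_true(all(vapply(fits, function(f) f$converged, logical(1))))
  # qualification contrasts are against gynaecologist
  expect_true(all(c("LO:qualificationradiologist",
                    "LO:qualificationsonographer") %in%
                    names(fits$qualification$natural$par)))
  # the no-expert model is nested in the expert model
  expect_lte(fits$none$loglik, fits$expert$loglik)
  expect_lte(fits$qualification$loglik, fits$expert$loglik)
})

test_that("expert effects test is non-significant when truth has none", {
  nm <- names(study_parameters()$beta_left)
  b <- setNames(c(0.8, 0.3, -0.2, 0.5, 0, 0.4, -0.3, rep(0, 7)), nm)
  pars <- true_parameters(b, b, 0.6, 0.9, 0.2, 0.4)
  dat <- generate_audit_dataset(pars, small_design(scans = 20), seed = 55)
  fit <- suppressWarnings(fit_biprobit(dat, model_spec("expert", nodes = 8)))
  terms <- grep(":expert_id", names(fit$natural$par), value = TRUE)
  w <- wald_test(fit, terms = terms)
  expect_equal(w$df, 14)
  expect_gt(w$p.value, 0.001)
})
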