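#' Model specification for the random-effects bivariate probit
#'
#' @param variant Fixed-effects variant: `"expert"` (sonographer + expert,
#'   the full audit model), `"qualification"` (sonographer + reviewer
#'   qualification, since experts are nested in qualification the two cannot
#'   both be included), or `"none"` (sonographer only). The same design
#'   matrix is used for both outcome equations.
#' @param nodes Gauss-Hermite quadrature nodes per random-effect dimension.
#' @param adaptive Use per-scan adaptive recentering of the quadrature grid
#'   (mode/curvature). Slower (no analytic gradient); the non-adaptive rule
#'   with `nodes = 12` is accurate to well below reporting precision at the
#'   variance scales seen in these audits.
#' @return Object of class `model_spec`.
#' @export
model_spec <- function(variant = c("expert", "qualification", "none"),
                       nodes = 12, adaptive = FALSE) {
  variant <- match.arg(variant)
  stopifnot(nodes >= 2)
  structure(list(variant = variant, nodes = as.integer(nodes),
                 adaptive = isTRUE(adaptive)), class = "model_spec")
}

#' Pack / unpack the unconstrained parameter vector
#'
#' The optimiser works on an unconstrained vector: both fixed-effect
#' equations, a log-Cholesky parameterisation of the random-intercept
#' covariance (log diagonal, free off-diagonal), and `atanh` of the error
#' correlation. Any unconstrained vector therefore maps to a valid positive
#' semi-definite covariance and `|rho| < 1`.
#'
#' @param beta_left,beta_right Fixed-effect vectors (equal length).
#' @param var_left,var_right Random-intercept variances (> 0 for packing).
#' @param cov_lr Random-intercept covariance.
#' @param rho_err Error correlation in (-1, 1).
#' @return `pack_parameters()`: numeric vector of length
#'   `2 * length(beta_left) + 4`. `unpack_parameters()`: list with the
#'   natural-scale components.
#' @export
pack_parameters <- function(beta_left, beta_right, var_left, var_right,
                            cov_lr, rho_err) {
  stopifnot(length(beta_left) == length(beta_right),
            var_left > 0, abs(rho_err) < 1)
  L11 <- sqrt(var_left)
  L21 <- cov_lr / L11
  d <- var_right - L21^2
  if (d <= 0) stop("random-effect covariance must be positive definite to pack")
  c(beta_left, beta_right, log(L11), L21, log(sqrt(d)), atanh(rho_err))
}

#' @rdname pack_parameters
#' @param theta Packed parameter vector.
#' @param p Number of fixed effects per equation.
#' @export
unpack_parameters <- function(theta, p) {
  stopifnot(length(theta) == 2 * p + 4)
  L11 <- exp(theta[2 * p + 1])
  L21 <- theta[2 * p + 2]
  L22 <- exp(theta[2 * p + 3])
  list(beta_left = theta[seq_len(p)],
       beta_right = theta[p + seq_len(p)],
       var_left = L11^2,
       var_right = L21^2 + L22^2,
       cov_lr = L11 * L21,
       rho_err = tanh(theta[2 * p + 4]),
       L = matrix(c(L11, L21, 0, L22), 2, 2))
}

expert_sort <- function(x) {
  u <- unique(x)
  if (!anyNA(suppressWarnings(as.numeric(u)))) u[order(as.numeric(u))]
  else sort(u)
}

prepare_model_data <- function(data, spec) {
  stopifnot(inherits(data, "audit_data"), inherits(spec, "model_spec"))
  rec <- data$records
  rec <- rec[order(rec$scan_id), , drop = FALSE]
  rownames(rec) <- NULL

  rec$sonographer_id <- factor(rec$sonographer_id,
                               levels = sort(unique(rec$sonographer_id)))
  rec$expert_id <- factor(rec$expert_id,
                          levels = expert_sort(rec$expert_id))
  if (spec$variant == "qualification") {
    if (anyNA(rec$qualification))
      stop("qualification variant requires a qualification for every record")
    qlev <- intersect(c("gynaecologist", "radiologist", "sonographer"),
                      unique(rec$qualification))
    qlev <- c(qlev, setdiff(unique(rec$qualification), qlev))
    rec$qualification <- factor(rec$qualification, levels = qlev)
  }

  # factors with a single observed level carry no contrast and are dropped
  terms <- switch(spec$variant,
    expert = c("sonographer_id", "expert_id"),
    qualification = c("sonographer_id", "qualification"),
    none = "sonographer_id")
  usable <- vapply(terms, function(f) nlevels(factor(rec[[f]])) > 1,
                   logical(1))
  if (any(!usable))
    warning("factor(s) with a single level dropped from the design: ",
            paste(terms[!usable], collapse = ", "), call. = FALSE)
  terms <- terms[usable]
  formula <- if (length(terms))
    stats::reformulate(terms) else ~ 1

  X <- model.matrix(formula, rec)

  qrx <- qr(X)
  if (qrx$rank < ncol(X)) {
    aliased <- colnames(X)[qrx$pivot[(qrx$rank + 1):ncol(X)]]
    stop("design matrix is rank deficient; aliased column(s): ",
         paste(aliased, collapse = ", "))
  }

  # flag potential separation: a factor level whose observed outcomes are
  # all 0 or all 1 for either equation
  for (f in terms) {
    for (lv in levels(rec[[f]])) {
      at <- rec[[f]] == lv
      for (oc in c("y_left", "y_right")) {
        y <- rec[[oc]][at]
        y <- y[!is.na(y)]
        if (length(y) > 0 && (all(y == 0) || all(y == 1)))
          warning("possible separation: ", f, " level '", lv,
                  "' has all-", y[1], " ", oc, " outcomes", call. = FALSE)
      }
    }
  }

  r <- rle(rec$scan_id)
  list(X = X,
       yl = ifelse(is.na(rec$y_left), -1L, rec$y_left),
       yr = ifelse(is.na(rec$y_right), -1L, rec$y_right),
       scan_ptr = as.integer(c(0L, cumsum(r$lengths))),
       scan_ids = r$values,
       records = rec,
       formula = formula)
}

nll_raw <- function(theta, prep, rule, adaptive = FALSE, want_grad = FALSE) {
  if (adaptive) {
    biprobit_nll_adaptive_cpp(theta, prep$X, prep$yl, prep$yr, prep$scan_ptr,
                              rule$x, rule$w)
  } else {
    res <- biprobit_nll_cpp(theta, prep$X, prep$yl, prep$yr, prep$scan_ptr,
                            rule$x, rule$w, want_grad)
    if (want_grad) res else res$nll
  }
}

#' Negative log-likelihood of the random-effects bivariate probit
#'
#' Minus the sum over scans of the log marginal likelihood: within a scan the
#' random-intercept pair is integrated out by tensor-product Gauss-Hermite
#' quadrature (after a Cholesky transformation of the random-effect
#' covariance); each review contributes a bivariate-normal orthant
#' probability with correlation `+/- rho_err` when both outcomes are
#' observed, or a univariate probit term when only one is.
#'
#' @param theta Packed parameter vector, see [pack_parameters()].
#' @param data An `audit_data` object.
#' @param spec A [model_spec()].
#' @return Scalar negative log-likelihood with attribute `"gradient"` (the
#'   analytic gradient; omitted for adaptive quadrature).
#' @export
biprobit_nll <- function(theta, data, spec = model_spec()) {
  prep <- prepare_model_data(data, spec)
  rule <- ghq_rule(spec$nodes)
  if (spec$adaptive) {
    nll_raw(theta, prep, rule, adaptive = TRUE)
  } else {
    res <- nll_raw(theta, prep, rule, want_grad = TRUE)
    structure(res$nll, gradient = res$grad)
  }
}

probit_start <- function(X, y) {
  obs <- y >= 0
  b <- tryCatch({
    f <- suppressWarnings(glm.fit(X[obs, , drop = FALSE], y[obs],
                                  family = binomial("probit")))
    coef(f)
  }, error = function(e) rep(0, ncol(X)))
  b[!is.finite(b)] <- 0
  pmin(pmax(b, -5), 5)
}

#' Fit the random-effects bivariate probit by maximum likelihood
#'
#' Quasi-Newton maximisation from univariate-probit starting values, with the
#' random-effect covariance kept positive semi-definite by a log-Cholesky
#' parameterisation and `|rho| < 1` by `atanh`. The covariance matrix of the
#' estimates is the inverse of a numerically differentiated observed
#' information matrix (central differences of the analytic gradient).
#' Non-convergence sets `converged = FALSE`; it never throws.
#'
#' @param data An `audit_data` object with at least 2 scans and both outcome
#'   types observed.
#' @param spec A [model_spec()].
#' @param start Optional packed starting vector.
#' @param random_effects If `FALSE`, the random-intercept covariance is
#'   pinned to zero, giving the standard (no random effects) bivariate probit
#'   with one record per observation; see [standard_biprobit()].
#' @param vcov Compute the covariance matrix of the estimates (numerically
#'   differentiated observed information). Set `FALSE` to skip when only
#'   point estimates are needed (e.g. large bias-only simulations).
#' @return Object of class `biprobit_fit` with elements `estimates` (natural
#'   scale), `theta`, `vcov` (packed scale), `natural` (natural-scale
#'   parameters and delta-method covariance), `loglik`, `converged`,
#'   `n_scans`, `n_records`, `n_assessments`, `spec`.
#' @export
fit_biprobit <- function(data, spec = model_spec(), start = NULL,
                         random_effects = TRUE, vcov = TRUE) {
  stopifnot(inherits(data, "audit_data"))
  if (data$n_scans < 2) stop("need at least 2 scans")
  if (all(is.na(data$records$y_left)) || all(is.na(data$records$y_right)))
    stop("need both outcome types in the data")

  prep <- prepare_model_data(data, spec)
  p <- ncol(prep$X)
  npar <- 2 * p + 4

  theta0 <- start %||% c(probit_start(prep$X, prep$yl),
                         probit_start(prep$X, prep$yr),
                         log(sqrt(0.5)), 0, log(sqrt(0.5)), 0)
  stopifnot(length(theta0) == npar)

  free <- if (random_effects) seq_len(npar) else c(seq_len(2 * p), npar)
  base <- theta0
  # pinned covariance: log-Cholesky diagonal at -30 puts the variances at a
  # numerical zero, so unpacking and post-estimation see var = 0
  if (!random_effects) base[(2 * p + 1):(2 * p + 3)] <- c(-30, 0, -30)
  expand <- function(par) { th <- base; th[free] <- par; th }

  rule <- if (random_effects) ghq_rule(spec$nodes) else list(x = 0, w = sqrt(pi))

  make_obj <- function(rl) {
    if (spec$adaptive && random_effects) {
      obj <- function(par) nll_raw(expand(par), prep, rl, adaptive = TRUE)
      gr <- function(par) fd_gradient(obj, par)
    } else {
      obj <- function(par) nll_raw(expand(par), prep, rl)
      gr <- function(par)
        nll_raw(expand(par), prep, rl, want_grad = TRUE)$grad[free]
    }
    list(obj = obj, gr = gr)
  }

  ctl <- list(iter.max = 500, eval.max = 2000, rel.tol = 1e-8)
  fo <- make_obj(rule)
  opt <- nlminb(theta0[free], fo$obj, fo$gr, control = ctl)

  theta_hat <- expand(opt$par)
  g <- fo$gr(opt$par)
  converged <- opt$convergence == 0 ||
    sqrt(sum(g^2)) < 1e-5 * (1 + abs(opt$objective))

  V <- matrix(0, npar, npar)
  if (vcov) {
    H <- fd_hessian_forward(fo$gr, opt$par)
    vcov_free <- tryCatch(chol2inv(chol(H)), error = function(e) {
      warning("observed information not positive definite; ",
              "using pseudo-inverse", call. = FALSE)
      MASS::ginv(H)
    })
    V[free, free] <- vcov_free
  }

  est <- unpack_parameters(theta_hat, p)
  names(est$beta_left) <- names(est$beta_right) <- colnames(prep$X)
  if (!random_effects) est[c("var_left", "var_right", "cov_lr")] <- list(0, 0, 0)

  nat_names <- c(paste0("LO:", colnames(prep$X)),
                 paste0("RO:", colnames(prep$X)),
                 "var_left", "var_right", "cov_lr", "rho_err")
  J <- natural_jacobian(theta_hat, p, random_effects)
  nat_par <- setNames(c(est$beta_left, est$beta_right, est$var_left,
                        est$var_right, est$cov_lr, est$rho_err), nat_names)
  nat_vcov <- J %*% V %*% t(J)
  dimnames(nat_vcov) <- list(nat_names, nat_names)

  structure(list(
    estimates = est,
    theta = theta_hat,
    vcov = V,
    natural = list(par = nat_par, vcov = nat_vcov),
    loglik = -opt$objective,
    converged = converged,
    gradient = g,
    n_scans = data$n_scans,
    n_records = data$n_records,
    n_assessments = data$n_assessments,
    spec = spec,
    random_effects = random_effects,
    prep = prep,
    opt = opt[c("convergence", "iterations", "message")]
  ), class = "biprobit_fit")
}

# Jacobian of the natural parameters (betas, var_l, var_r, cov, rho) with
# respect to the packed vector.
natural_jacobian <- function(theta, p, random_effects = TRUE) {
  u <- unpack_parameters(theta, p)
  L11 <- u$L[1, 1]; L21 <- u$L[2, 1]; L22 <- u$L[2, 2]
  n_nat <- 2 * p + 4
  J <- matrix(0, n_nat, 2 * p + 4)
  J[seq_len(2 * p), seq_len(2 * p)] <- diag(2 * p)
  if (random_effects) {
    J[2 * p + 1, 2 * p + 1] <- 2 * L11^2                   # var_l / l1
    J[2 * p + 2, 2 * p + 2] <- 2 * L21                     # var_r / L21
    J[2 * p + 2, 2 * p + 3] <- 2 * L22^2                   # var_r / l2
    J[2 * p + 3, 2 * p + 1] <- L11 * L21                   # cov / l1
    J[2 * p + 3, 2 * p + 2] <- L11                         # cov / L21
  }
  J[2 * p + 4, 2 * p + 4] <- 1 - u$rho_err^2
  J
}

#' @export
logLik.biprobit_fit <- function(object, ...) {
  structure(object$loglik,
            df = length(object$theta) - if (object$random_effects) 0L else 3L,
            class = "logLik")
}

#' @export
vcov.biprobit_fit <- function(object, scale = c("natural", "packed"), ...) {
  scale <- match.arg(scale)
  if (scale == "natural") object$natural$vcov else object$vcov
}

#' @export
coef.biprobit_fit <- function(object, ...) object$natural$par

#' @export
print.biprobit_fit <- function(x, digits = 3, ...) {
  cat("Random-effects bivariate probit fit (variant: ", x$spec$variant,
      ")\n", sep = "")
  cat(sprintf("  log-likelihood %.3f | %d scans, %d reviews, %d assessments\n",
              x$loglik, x$n_scans, x$n_records, x$n_assessments))
  cat("  converged:", x$converged, "\n")
  e <- x$estimates
  cat(sprintf("  RE variances (LO, RO): %.*f, %.*f | covariance %.*f\n",
              digits, e$var_left, digits, e$var_right, digits, e$cov_lr))
  cat(sprintf("  error correlation: %.*f\n", digits, e$rho_err))
  invisible(x)
}

#' Wald test of linear constraints on the model parameters
#'
#' Tests `R theta = r` on the natural parameter scale (fixed effects, the
#' random-effect variances/covariance, and the error correlation), using the
#' delta-method covariance of the natural parameters. The statistic is
#' `(R theta - r)' (R V R')^{-1} (R theta - r)`, chi-square with `nrow(R)`
#' degrees of freedom.
#'
#' @param fit A `biprobit_fit`.
#' @param terms Character vector of natural-parameter names to test jointly
#'   against zero (shortcut for an identity-row `R`). See
#'   `names(coef(fit))`.
#' @param R Constraint matrix; columns must be named after natural parameters
#'   or have `length(coef(fit))` columns in that order.
#' @param r Right-hand side (default zero).
#' @return List with `statistic`, `df`, `p.value`.
#' @export
wald_test <- function(fit, terms = NULL, R = NULL, r = 0) {
  stopifnot(inherits(fit, "biprobit_fit"))
  par <- fit$natural$par
  V <- fit$natural$vcov
  if (is.null(R)) {
    if (is.null(terms)) stop("supply either terms or R")
    bad <- setdiff(terms, names(par))
    if (length(bad)) stop("unknown parameter(s): ", paste(bad, collapse = ", "))
    R <- matrix(0, length(terms), length(par),
                dimnames = list(terms, names(par)))
    R[cbind(seq_along(terms), match(terms, names(par)))] <- 1
  } else {
    R <- as.matrix(R)
    if (!is.null(colnames(R))) {
      full <- matrix(0, nrow(R), length(par),
                     dimnames = list(NULL, names(par)))
      bad <- setdiff(colnames(R), names(par))
      if (length(bad)) stop("unknown parameter(s) in R: ",
                            paste(bad, collapse = ", "))
      full[, colnames(R)] <- R
      R <- full
    }
    if (ncol(R) != length(par)) stop("R has wrong number of columns")
  }
  if (qr(R)$rank < nrow(R)) stop("constraint matrix is not full row rank")
  r <- rep_len(r, nrow(R))
  d <- drop(R %*% par) - r
  stat <- drop(t(d) %*% solve(R %*% V %*% t(R), d))
  df <- nrow(R)
  list(statistic = stat, df = df, p.value = pchisq(stat, df, lower.tail = FALSE))
}

# Joint test that the LO and RO coefficient blocks matching `pattern` are
# equal across equations.
wald_cross_equation <- function(fit, pattern) {
  nm <- names(fit$estimates$beta_left)
  sel <- grep(pattern, nm, value = TRUE)
  if (!length(sel)) stop("no coefficients match pattern '", pattern, "'")
  R <- matrix(0, length(sel), length(fit$natural$par),
              dimnames = list(sel, names(fit$natural$par)))
  R[cbind(seq_along(sel), match(paste0("LO:", sel), colnames(R)))] <- 1
  R[cbind(seq_along(sel), match(paste0("RO:", sel), colnames(R)))] <- -1
  wald_test(fit, R = R)
}

block_terms <- function(fit, eq, pattern) {
  nm <- names(fit$estimates$beta_left)
  paste0(eq, ":", grep(pattern, nm, value = TRUE))
}

#' Fit all fixed-effects variants of the audit model
#'
#' Fits the expert, qualification and sonographer-only variants. The
#' qualification variant reports contrasts against gynaecologist (the
#' reference qualification).
#'
#' @param data An `audit_data` object.
#' @param nodes,adaptive Passed to [model_spec()].
#' @return Named list of `biprobit_fit` objects
#'   (`expert`, `qualification`, `none`).
#' @export
fit_all_variants <- function(data, nodes = 12, adaptive = FALSE) {
  variants <- c("expert", "qualification", "none")
  out <- lapply(variants, function(v)
    fit_biprobit(data, model_spec(v, nodes = nodes, adaptive = adaptive)))
  names(out) <- variants
  out
}

#' Flat coefficient table in the audit report layout
#'
#' Fixed effects for both equations (estimate, SE, symmetric 95% CI), joint
#' block p-values per factor, cross-equation (LO vs RO) block p-values, and
#' the random-effect / correlation rows on the natural scale.
#'
#' @param fit A `biprobit_fit`.
#' @return Data frame with columns section, term, estimate, se, l95, u95,
#'   p_block, p_left_vs_right.
#' @export
fit_table <- function(fit) {
  stopifnot(inherits(fit, "biprobit_fit"))
  par <- fit$natural$par
  se <- sqrt(pmax(diag(fit$natural$vcov), 0))
  z <- ci_level_z()
  nmb <- names(fit$estimates$beta_left)

  blocks <- list()
  if (any(grepl("^sonographer", nmb))) blocks$sonographer <- "^sonographer"
  if (any(grepl("^expert", nmb))) blocks$expert <- "^expert"
  if (any(grepl("^qualification", nmb))) blocks$qualification <- "^qualification"
  blocks$constant <- "^\\(Intercept\\)$"

  rows <- list()
  for (eq in c("LO", "RO")) {
    for (bn in names(blocks)) {
      sel <- grep(blocks[[bn]], nmb, value = TRUE)
      terms <- paste0(eq, ":", sel)
      pb <- tryCatch(wald_test(fit, terms = terms)$p.value,
                     error = function(e) NA_real_)
      px <- if (eq == "LO")
        tryCatch(wald_cross_equation(fit, blocks[[bn]])$p.value,
                 error = function(e) NA_real_) else NA_real_
      rows[[length(rows) + 1L]] <- data.frame(
        section = paste("fixed", eq), term = sel, estimate = par[terms],
        se = se[terms], l95 = par[terms] - z * se[terms],
        u95 = par[terms] + z * se[terms],
        p_block = c(pb, rep(NA_real_, length(sel) - 1L)),
        p_left_vs_right = c(px, rep(NA_real_, length(sel) - 1L)),
        stringsAsFactors = FALSE)
    }
  }
  rand_terms <- c("var_left", "var_right", "cov_lr", "rho_err")
  p_var_eq <- if (fit$random_effects) {
    R <- matrix(0, 1, length(par), dimnames = list(NULL, names(par)))
    R[, "var_left"] <- 1; R[, "var_right"] <- -1
    tryCatch(wald_test(fit, R = R)$p.value, error = function(e) NA_real_)
  } else NA_real_
  rows[[length(rows) + 1L]] <- data.frame(
    section = "random", term = rand_terms, estimate = par[rand_terms],
    se = se[rand_terms], l95 = par[rand_terms] - z * se[rand_terms],
    u95 = par[rand_terms] + z * se[rand_terms],
    p_block = c(p_var_eq, rep(NA_real_, 3)),
    p_left_vs_right = NA_real_, stringsAsFactors = FALSE)
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Standard bivariate probit (no random effects)
#'
#' Fits the bivariate probit treating every review as an independent
#' observation, i.e. [fit_biprobit()] with the random-intercept covariance
#' pinned to zero. Its single latent correlation is directly comparable to
#' the tetrachoric correlation of the raw outcome table once fixed effects
#' are adjusted for.
#'
#' @param data An `audit_data` object.
#' @param spec A [model_spec()] (quadrature settings are ignored as no
#'   integration is needed).
#' @return A `biprobit_fit` with zero variance components.
#' @export
standard_biprobit <- function(data, spec = model_spec()) {
  fit_biprobit(data, spec, random_effects = FALSE)
}
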