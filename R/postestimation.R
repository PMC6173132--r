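#' Derived latent correlations and ICCs from variance components
#'
#' Pure formulas mapping the random-intercept covariance components and error
#' correlation of the random-effects bivariate probit to the derived
#' quantities reported for an audit:
#' * random-effect correlation `cov_lr / sqrt(var_left * var_right)` (`NA`
#'   when either variance is zero — undefined, never 0);
#' * the error correlation itself;
#' * the combined latent (tetrachoric) correlation of the paired LO/RO
#'   outcome for one scan and occasion,
#'   `(cov_lr + rho_err) / sqrt((1 + var_left) * (1 + var_right))`;
#' * per-outcome intraclass correlations `var / (var + 1)` (share of latent
#'   variance attributable to the scan, the latent errors having unit
#'   variance).
#'
#' @param var_left,var_right Random-intercept variances.
#' @param cov_lr Random-intercept covariance.
#' @param rho_err Error correlation.
#' @return Named list with `re_correlation`, `err_correlation`,
#'   `combined_correlation`, `icc_left`, `icc_right`.
#' @examples
#' latent_correlations(0.758, 1.226, 0.293, 0.473)$combined_correlation
#' @export
latent_correlations <- function(var_left, var_right, cov_lr, rho_err) {
  list(
    re_correlation = if (var_left > 0 && var_right > 0)
      cov_lr / sqrt(var_left * var_right) else NA_real_,
    err_correlation = rho_err,
    combined_correlation =
      (cov_lr + rho_err) / sqrt((1 + var_left) * (1 + var_right)),
    icc_left = var_left / (var_left + 1),
    icc_right = var_right / (var_right + 1)
  )
}

# scalar functions of the packed parameter vector, used for delta-method SEs
corr_fun <- function(which, p) {
  function(theta) {
    u <- unpack_parameters(theta, p)
    latent_correlations(u$var_left, u$var_right, u$cov_lr,
                        u$rho_err)[[which]]
  }
}

#' Correlation and ICC summary of a fitted model
#'
#' The five derived quantities of [latent_correlations()] evaluated at the
#' estimates, with delta-method standard errors and symmetric natural-scale
#' confidence intervals.
#'
#' @param fit A converged `biprobit_fit`.
#' @param level Confidence level.
#' @return Data frame with quantity, estimate, se, lower, upper.
#' @export
correlation_summary <- function(fit, level = 0.95) {
  stopifnot(inherits(fit, "biprobit_fit"))
  p <- length(fit$estimates$beta_left)
  qs <- c("re_correlation", "err_correlation", "combined_correlation",
          "icc_left", "icc_right")
  z <- ci_level_z(level)
  rows <- lapply(qs, function(q) {
    f <- corr_fun(q, p)
    est <- f(fit$theta)
    if (is.na(est))
      return(data.frame(quantity = q, estimate = NA_real_, se = NA_real_,
                        lower = NA_real_, upper = NA_real_))
    g <- fd_gradient(f, fit$theta)
    se <- sqrt(max(0, drop(t(g) %*% fit$vcov %*% g)))
    data.frame(quantity = q, estimate = est, se = se,
               lower = est - z * se, upper = est + z * se,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

stratum_records <- function(fit, stratum, average = "population") {
  rec <- fit$prep$records
  if (identical(stratum, "overall")) return(list(rec = rec, type = "overall",
                                                 label = "overall"))
  if (is.null(names(stratum)) || length(stratum) != 1L)
    stop("stratum must be \"overall\" or a single named value, ",
         "e.g. c(sonographer = \"B\")")
  key <- names(stratum)
  col <- switch(key, sonographer = "sonographer_id", expert = "expert_id",
                qualification = "qualification",
                stop("unknown stratum type '", key, "'"))
  if (!col %in% all.vars(fit$prep$formula) && col != "sonographer_id")
    stop("factor '", key, "' is not in the fitted model")
  lev <- levels(rec[[col]]) %||% unique(rec[[col]])
  if (!stratum %in% lev)
    stop("unknown ", key, " level '", stratum, "'")
  if (average == "stratum") {
    rec <- rec[rec[[col]] == stratum, , drop = FALSE]
  } else {
    rec[[col]] <- factor(rep(stratum, nrow(rec)), levels = lev)
  }
  list(rec = rec, type = key, label = unname(stratum))
}

margin_prob <- function(theta, p, X, outcome) {
  u <- unpack_parameters(theta, p)
  if (outcome == "LO") {
    mean(pnorm(drop(X %*% u$beta_left) / sqrt(1 + u$var_left)))
  } else {
    mean(pnorm(drop(X %*% u$beta_right) / sqrt(1 + u$var_right)))
  }
}

joint_prob <- function(theta, p, X) {
  u <- unpack_parameters(theta, p)
  ql <- drop(X %*% u$beta_left) / sqrt(1 + u$var_left)
  qr <- drop(X %*% u$beta_right) / sqrt(1 + u$var_right)
  rs <- (u$cov_lr + u$rho_err) /
    sqrt((1 + u$var_left) * (1 + u$var_right))
  mean(pbvnorm(ql, qr, rs))
}

raw_for <- function(fit, type, label, outcome) {
  rp <- raw_proportions(structure(list(records = fit$prep$records),
                                  class = "audit_data"))
  key <- if (type == "overall") "overall" else type
  hit <- rp$stratum_type == key & rp$stratum == label &
    rp$outcome == c(LO = "LO", RO = "RO", joint = "joint")[outcome]
  if (any(hit)) rp$proportion[hit][1] else NA_real_
}

finish_margin <- function(fit, pfun, type, label, outcome, level, theta) {
  est <- pfun(theta)
  g <- fd_gradient(pfun, theta)
  se <- sqrt(max(0, drop(t(g) %*% fit$vcov %*% g)))
  z <- ci_level_z(level)
  data.frame(stratum_type = type, stratum = label, outcome = outcome,
             probability = est, se = se,
             l95 = max(0, est - z * se), u95 = min(1, est + z * se),
             raw = raw_for(fit, type, label, outcome),
             stringsAsFactors = FALSE)
}

#' Population-averaged marginal prediction
#'
#' Probability of a confirmed outcome, averaged over the estimation sample
#' with the random effect integrated out analytically: the average of
#' `pnorm(x'beta / sqrt(1 + var))` over the fitted records. For a factor
#' stratum the level is forced for every record and other covariates are kept
#' as observed (the convention of Stata's `margins`). Standard errors are by
#' the delta method.
#'
#' @param fit A converged `biprobit_fit`.
#' @param outcome `"LO"` or `"RO"`.
#' @param stratum `"overall"` or a single named level, e.g.
#'   `c(sonographer = "B")`, `c(expert = "3")`.
#' @param level Confidence level.
#' @param average For a factor stratum, `"population"` (default) forces the
#'   level for every record and keeps other covariates as observed;
#'   `"stratum"` averages only over the records observed at that level, so
#'   that share-weighted stratum margins reproduce the overall margin
#'   exactly.
#' @param theta Advanced: evaluate at a parameter vector other than the MLE.
#' @return One-row data frame: stratum_type, stratum, outcome, probability,
#'   se, l95, u95, raw (the matching raw proportion).
#' @export
marginal_prediction <- function(fit, outcome = c("LO", "RO"),
                                stratum = "overall", level = 0.95,
                                average = c("population", "stratum"),
                                theta = fit$theta) {
  stopifnot(inherits(fit, "biprobit_fit"))
  outcome <- match.arg(outcome)
  average <- match.arg(average)
  p <- length(fit$estimates$beta_left)
  s <- stratum_records(fit, stratum, average)
  X <- model.matrix(fit$prep$formula, s$rec)
  pfun <- function(th) margin_prob(th, p, X, outcome)
  finish_margin(fit, pfun, s$type, s$label, outcome, level, theta)
}

#' Population-averaged joint prediction for both ovaries
#'
#' Probability that both LO and RO are confirmed in the same examination,
#' incorporating the estimated correlation of both the random intercepts and
#' the error terms: the average over the sample of
#' `Phi2(eta_L / sqrt(1 + var_L), eta_R / sqrt(1 + var_R); rho*)` with
#' `rho* = (cov_LR + rho_err) / sqrt((1 + var_L)(1 + var_R))`.
#'
#' @inheritParams marginal_prediction
#' @return One-row data frame as in [marginal_prediction()].
#' @export
joint_marginal_prediction <- function(fit, stratum = "overall", level = 0.95,
                                      average = c("population", "stratum"),
                                      theta = fit$theta) {
  stopifnot(inherits(fit, "biprobit_fit"))
  average <- match.arg(average)
  p <- length(fit$estimates$beta_left)
  s <- stratum_records(fit, stratum, average)
  X <- model.matrix(fit$prep$formula, s$rec)
  pfun <- function(th) joint_prob(th, p, X)
  finish_margin(fit, pfun, s$type, s$label, "joint", level, theta)
}

#' Full table of marginal predictions
#'
#' LO, RO and joint population-averaged predictions overall, per sonographer
#' and per expert (when the expert factor is in the model), with raw
#' proportions alongside.
#'
#' @param fit A converged `biprobit_fit`.
#' @param level Confidence level.
#' @return Data frame, one row per stratum and outcome.
#' @export
margins_table <- function(fit, level = 0.95) {
  rec <- fit$prep$records
  strata <- list("overall")
  for (s in levels(rec$sonographer_id))
    strata <- c(strata, list(c(sonographer = s)))
  if (any(grepl("^expert", names(fit$estimates$beta_left))))
    for (e in levels(rec$expert_id))
      strata <- c(strata, list(c(expert = e)))
  out <- list()
  for (oc in c("LO", "RO")) {
    for (s in strata)
      out[[length(out) + 1L]] <-
        marginal_prediction(fit, outcome = oc, stratum = s, level = level)
  }
  for (s in strata)
    out[[length(out) + 1L]] <-
      joint_marginal_prediction(fit, stratum = s, level = level)
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Empirical Bayes means of the scan random intercepts
#'
#' Posterior means `E[b | y]` of each scan's (LO, RO) random intercepts given
#' its observed outcomes at the fitted parameters, computed by Gauss-Hermite
#' quadrature.
#'
#' @param fit A converged `biprobit_fit`.
#' @param scan_id Optional scan identifier(s) to return; default all scans.
#' @param nodes Quadrature nodes per dimension (default: the fit's setting).
#' @return Data frame with scan_id, sonographer_id, eb_left, eb_right.
#' @export
empirical_bayes <- function(fit, scan_id = NULL, nodes = NULL) {
  stopifnot(inherits(fit, "biprobit_fit"))
  rule <- ghq_rule(nodes %||% fit$spec$nodes)
  eb <- biprobit_eb_cpp(fit$theta, fit$prep$X, fit$prep$yl, fit$prep$yr,
                        fit$prep$scan_ptr, rule$x, rule$w)
  rec <- fit$prep$records
  first <- fit$prep$scan_ptr[-length(fit$prep$scan_ptr)] + 1L
  out <- data.frame(scan_id = fit$prep$scan_ids,
                    sonographer_id = as.character(rec$sonographer_id[first]),
                    eb_left = eb[, 1], eb_right = eb[, 2],
                    stringsAsFactors = FALSE)
  if (!is.null(scan_id)) {
    miss <- setdiff(scan_id, out$scan_id)
    if (length(miss)) stop("unknown scan(s): ", paste(miss, collapse = ", "))
    out <- out[match(scan_id, out$scan_id), , drop = FALSE]
    rownames(out) <- NULL
  }
  out
}

#' Tetrachoric correlation of a 2x2 table
#'
#' Maximum-likelihood estimate of the correlation of the latent bivariate
#' normal generating a 2x2 table of binary outcomes, with thresholds
#' estimated from the margins; the standard error comes from the observed
#' information. A zero cell puts the MLE on the boundary: the estimate is
#' reported as +/-1 with a warning and no standard error.
#'
#' @param table 2x2 matrix of counts with rows = first outcome (0, 1) and
#'   columns = second outcome (0, 1), as produced by `table(y1, y2)`.
#' @return List with `rho`, `se`, `thresholds`, `boundary`, `n`.
#' @export
tetrachoric <- function(table) {
  tab <- as.matrix(table)
  if (!all(dim(tab) == c(2, 2)) || any(tab < 0))
    stop("table must be a 2x2 matrix of non-negative counts")
  n <- sum(tab)
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0))
    stop("all four margins must be nonzero")

  p1 <- sum(tab[2, ]) / n   # P(first outcome = 1)
  p2 <- sum(tab[, 2]) / n
  c1 <- qnorm(1 - p1)       # latent thresholds
  c2 <- qnorm(1 - p2)

  if (any(tab == 0)) {
    rho <- if (tab[1, 2] == 0 || tab[2, 1] == 0) 1 else -1
    warning("zero cell: tetrachoric estimate at the boundary ", rho,
            call. = FALSE)
    return(list(rho = rho, se = NA_real_, thresholds = c(c1, c2),
                boundary = TRUE, n = n))
  }

  nll <- function(par) {
    t1 <- par[1]; t2 <- par[2]; rho <- tanh(par[3])
    p11 <- pbvnorm(-t1, -t2, rho)           # P(Z1 > t1, Z2 > t2)
    p10 <- pnorm(-t1) - p11
    p01 <- pnorm(-t2) - p11
    p00 <- 1 - p11 - p10 - p01
    pr <- pmax(c(p00, p01, p10, p11), 1e-12)
    -sum(c(tab[1, 1], tab[1, 2], tab[2, 1], tab[2, 2]) * log(pr))
  }
  # start rho at the odds-ratio (cosine) approximation
  orat <- (tab[1, 1] * tab[2, 2]) / (tab[1, 2] * tab[2, 1])
  rho0 <- cos(pi / (1 + sqrt(orat)))
  opt <- optim(c(c1, c2, atanh(min(max(rho0, -0.99), 0.99))), nll,
               method = "BFGS", control = list(maxit = 500, reltol = 1e-12))
  rho <- tanh(opt$par[3])
  H <- fd_hessian(function(x) fd_gradient(nll, x), opt$par)
  V <- tryCatch(chol2inv(chol(H)), error = function(e) MASS::ginv(H))
  se <- sqrt(max(0, V[3, 3])) * (1 - rho^2)
  list(rho = rho, se = se, thresholds = opt$par[1:2], boundary = FALSE, n = n)
}

#' 2x2 table of observed (LO, RO) outcomes
#'
#' Counts of the paired outcomes over reviews where both are observed;
#' feed into [tetrachoric()] for the raw-data tetrachoric correlation.
#'
#' @param data An `audit_data` object.
#' @return A 2x2 contingency table.
#' @export
outcome_table <- function(data) {
  stopifnot(inherits(data, "audit_data"))
  rec <- data$records
  ok <- !is.na(rec$y_left) & !is.na(rec$y_right)
  table(y_left = factor(rec$y_left[ok], levels = 0:1),
        y_right = factor(rec$y_right[ok], levels = 0:1))
}
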