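#' True parameters for the synthetic audit generator
#'
#' Ground-truth parameters of the random-effects bivariate probit data
#' generating process: fixed effects per equation (intercept, sonographer
#' contrasts vs the first sonographer, expert contrasts vs the first expert),
#' the 2x2 covariance of the scan random intercepts, and the correlation of
#' the review-level latent error terms.
#'
#' @param beta_left,beta_right Named numeric vectors of fixed effects, length
#'   `1 + (n_sonographers - 1) + (n_experts - 1)`.
#' @param var_left,var_right Random-intercept variances (>= 0).
#' @param cov_lr Random-intercept covariance; the implied 2x2 matrix must be
#'   positive semi-definite.
#' @param rho_err Latent error correlation, in (-1, 1).
#' @return Object of class `true_parameters`.
#' @seealso [study_parameters()] for the motivating audit's fitted values.
#' @export
true_parameters <- function(beta_left, beta_right, var_left, var_right,
                            cov_lr, rho_err) {
  stopifnot(length(beta_left) == length(beta_right))
  if (var_left < 0 || var_right < 0 ||
      cov_lr^2 > var_left * var_right + 1e-12)
    stop("random-effect covariance matrix must be positive semi-definite")
  if (abs(rho_err) >= 1) stop("|rho_err| must be < 1")
  structure(list(beta_left = beta_left, beta_right = beta_right,
                 var_left = var_left, var_right = var_right,
                 cov_lr = cov_lr, rho_err = rho_err),
            class = "true_parameters")
}

#' Fitted values from the motivating ovary-visualisation audit
#'
#' The full-model estimates from the UKCTOCS sonographer audit (7
#' sonographers A-G, 8 expert reviewers), used as default simulation truth so
#' that synthetic data reproduce the study conditions: LO/RO fixed effects,
#' random-intercept variances 0.758 and 1.226, covariance 0.293 and error
#' correlation 0.473.
#'
#' @return A [true_parameters()] object.
#' @export
study_parameters <- function() {
  nm <- c("(Intercept)", paste0("sonographer", LETTERS[2:7]),
          paste0("expert", 2:8))
  bl <- c(0.894, 0.577, 1.202, 0.196, 1.142, 0.773, 0.086,
          0.620, -0.354, -0.204, -1.047, -0.362, -1.130, -0.180)
  br <- c(1.003, 0.484, 1.602, 0.785, 2.470, 1.108, 0.360,
          0.528, -0.922, 0.020, -1.303, -0.546, -1.182, -0.501)
  true_parameters(setNames(bl, nm), setNames(br, nm),
                  var_left = 0.758, var_right = 1.226,
                  cov_lr = 0.293, rho_err = 0.473)
}

#' Design configuration for the synthetic audit
#'
#' Layout of the audit: sonographers, scans per sonographer, the partition of
#' experts into review groups (every expert in a scan's group reviews that
#' scan), per-outcome missingness probabilities and the RNG seed.
#'
#' @param n_sonographers Number of sonographers (labelled A, B, ...).
#' @param scans_per_sonographer Scans sampled per sonographer.
#' @param expert_groups List of character vectors of expert IDs; must be
#'   disjoint and jointly cover all experts.
#' @param qualification_map Named character vector mapping expert ID to
#'   qualification (gynaecologist / radiologist / sonographer).
#' @param miss_prob_left,miss_prob_right Probability that a review's LO (RO)
#'   outcome is missing, independently per outcome (missing completely at
#'   random).
#' @param seed Integer RNG seed (may also be supplied to
#'   [generate_audit_dataset()]).
#' @return Object of class `design_config`.
#' @export
design_config <- function(n_sonographers = 7, scans_per_sonographer = 51,
                          expert_groups = list(c("1", "2", "3"),
                                               c("4", "5", "6"),
                                               c("7", "8")),
                          qualification_map = c(
                            "1" = "gynaecologist", "2" = "gynaecologist",
                            "3" = "gynaecologist", "4" = "radiologist",
                            "5" = "radiologist", "6" = "sonographer",
                            "7" = "sonographer", "8" = "sonographer"),
                          miss_prob_left = 12 / 952,
                          miss_prob_right = 21 / 952,
                          seed = NULL) {
  experts <- unlist(expert_groups)
  if (anyDuplicated(experts))
    stop("expert groups must be disjoint")
  if (!setequal(names(qualification_map), experts))
    stop("qualification_map must cover exactly the experts in expert_groups")
  stopifnot(n_sonographers >= 1, scans_per_sonographer >= 0,
            miss_prob_left >= 0, miss_prob_left <= 1,
            miss_prob_right >= 0, miss_prob_right <= 1)
  structure(list(n_sonographers = n_sonographers,
                 scans_per_sonographer = scans_per_sonographer,
                 expert_groups = expert_groups,
                 qualification_map = qualification_map,
                 miss_prob_left = miss_prob_left,
                 miss_prob_right = miss_prob_right,
                 seed = seed),
            class = "design_config")
}

#' The nominal audit study design
#'
#' Seven sonographers with 51 scans each (357 scans), eight experts split
#' into review groups of sizes 3/3/2, scans allocated evenly to groups (119
#' per group) so that each expert reviews 17 scans per sonographer, and
#' sporadic per-outcome missingness at the rates observed in the audit.
#'
#' @param seed Optional RNG seed stored in the configuration.
#' @return A [design_config()] object.
#' @export
nominal_study_design <- function(seed = NULL) design_config(seed = seed)

#' Generate a synthetic audit dataset
#'
#' Simulates the random-effects bivariate probit data generating process on a
#' given audit layout. For each scan a pair of random intercepts is drawn
#' from a bivariate normal with the configured covariance; for each review by
#' an expert in the scan's group, unit-variance errors with correlation
#' `rho_err` are drawn; outcomes are the indicators `x'beta + b + e > 0`.
#' Each outcome is then independently set missing with the configured
#' probability, and reviews with both outcomes missing are dropped (as at
#' read time). Deterministic given the seed.
#'
#' @param params A [true_parameters()] object; contrast vectors must match
#'   the design's numbers of sonographers and experts.
#' @param design A [design_config()] object.
#' @param seed Integer seed; defaults to `design$seed`.
#' @return An `audit_data` object with attributes `truth` and `design`.
#' @export
generate_audit_dataset <- function(params, design = nominal_study_design(),
                                   seed = NULL) {
  stopifnot(inherits(params, "true_parameters"),
            inherits(design, "design_config"))
  seed <- seed %||% design$seed
  if (is.null(seed)) stop("a seed is required (argument or design$seed)")

  sono <- LETTERS[seq_len(design$n_sonographers)]
  experts <- unlist(design$expert_groups)
  p_expected <- 1 + (length(sono) - 1) + (length(experts) - 1)
  if (length(params$beta_left) != p_expected)
    stop("beta vectors have length ", length(params$beta_left),
         " but the design implies ", p_expected)

  Sigma <- matrix(c(params$var_left, params$cov_lr,
                    params$cov_lr, params$var_right), 2, 2)
  Sroot <- psd_sqrt(Sigma)

  with_seed(seed, {
    n_scan <- design$n_sonographers * design$scans_per_sonographer
    scan_id <- sprintf("S%04d", seq_len(n_scan))
    scan_sono <- rep(sono, each = design$scans_per_sonographer)
    # randomized allocation of scans to review groups, balanced within each
    # sonographer so every expert sees the same number of scans per
    # sonographer (17 under the nominal design)
    ng <- length(design$expert_groups)
    grp <- unlist(lapply(seq_len(design$n_sonographers), function(i)
      sample(rep(seq_len(ng), length.out = design$scans_per_sonographer))))

    # scan random intercepts
    b <- matrix(rnorm(2 * n_scan), n_scan, 2) %*% Sroot

    per_scan <- lengths(design$expert_groups)[grp]
    idx <- rep(seq_len(n_scan), per_scan)
    expert <- unlist(design$expert_groups[grp], use.names = FALSE)
    n_rec <- length(idx)

    f_sono <- factor(scan_sono[idx], levels = sono)
    f_exp <- factor(expert, levels = experts)
    X <- model.matrix(~ f_sono + f_exp)

    e1 <- rnorm(n_rec)
    e2 <- params$rho_err * e1 + sqrt(1 - params$rho_err^2) * rnorm(n_rec)

    yl <- as.integer(drop(X %*% params$beta_left) + b[idx, 1] + e1 > 0)
    yr <- as.integer(drop(X %*% params$beta_right) + b[idx, 2] + e2 > 0)
    yl[runif(n_rec) < design$miss_prob_left] <- NA_integer_
    yr[runif(n_rec) < design$miss_prob_right] <- NA_integer_

    df <- data.frame(
      scan_id = scan_id[idx],
      volunteer_id = scan_id[idx],
      sonographer_id = scan_sono[idx],
      expert_id = expert,
      qualification = unname(design$qualification_map[expert]),
      y_left = yl, y_right = yr,
      stringsAsFactors = FALSE
    )
    dat <- suppressMessages(as_audit_data(df))
    attr(dat, "truth") <- params
    attr(dat, "design") <- design
    dat
  })
}
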