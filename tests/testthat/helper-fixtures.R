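# Small deterministic fixtures and independent oracles shared across tests.

fixture_df <- function() {
  data.frame(
    scan_id = rep(c("S1", "S2", "S3"), each = 2),
    volunteer_id = rep(c("V1", "V2", "V3"), each = 2),
    sonographer_id = rep(c("A", "B", "A"), each = 2),
    expert_id = rep(c("1", "2"), 3),
    qualification = rep(c("gynaecologist", "radiologist"), 3),
    y_left = c(1, 1, 0, 1, 1, 0),
    y_right = c(1, 0, 1, 1, 0, 0),
    stringsAsFactors = FALSE
  )
}

write_fixture_csv <- function(df = fixture_df()) {
  path <- tempfile(fileext = ".csv")
  write.csv(df, path, row.names = FALSE, quote = FALSE, na = "")
  path
}

# a small synthetic study: nominal structure at reduced size
small_design <- function(scans = 15, miss = TRUE) {
  design_config(scans_per_sonographer = scans,
                miss_prob_left = if (miss) 12 / 952 else 0,
                miss_prob_right = if (miss) 21 / 952 else 0)
}

small_data <- function(seed = 7, scans = 15, miss = TRUE) {
  generate_audit_dataset(study_parameters(), small_design(scans, miss),
                         seed = seed)
}

# one shared moderate-size fit, computed lazily and cached for the session
.fit_cache <- new.env(parent = emptyenv())
fixture_fit <- function() {
  if (is.null(.fit_cache$fit)) {
    dat <- small_data(seed = 7, scans = 15)
    .fit_cache$fit <- suppressWarnings(
      fit_biprobit(dat, model_spec("expert", nodes = 8)))
    .fit_cache$data <- dat
  }
  .fit_cache$fit
}
fixture_data <- function() {
  fixture_fit()
  .fit_cache$data
}

# Independent vectorised Phi2 oracle: Gauss-Legendre on the Drezner t-form
# integral Phi2 = Phi(h)Phi(k) + (1/2pi) int_0^r exp(.)/sqrt(1-t^2) dt.
# Deliberately a different representation from the package's asin-form rule.
phi2_oracle <- function(h, k, r, n_nodes = 16) {
  gl <- pracma::gaussLegendre(n_nodes, 0, r)
  out <- pnorm(h) * pnorm(k)
  for (i in seq_len(n_nodes)) {
    t <- gl$x[i]
    out <- out + gl$w[i] / (2 * pi) *
      exp(-(h^2 - 2 * t * h * k + k^2) / (2 * (1 - t^2))) / sqrt(1 - t^2)
  }
  out
}

# Brute-force Monte-Carlo marginal log-likelihood of one scan: draw the
# random-intercept pair, average the exact conditional record likelihoods.
mc_scan_loglik <- function(rec, beta_l, beta_r, Sigma, rho, ndraws = 1e6,
                           seed = 99) {
  set.seed(seed)
  U <- chol(Sigma)
  B <- matrix(rnorm(2 * ndraws), ndraws, 2) %*% U
  lik <- rep(1, ndraws)
  X <- rec$X
  for (j in seq_len(nrow(X))) {
    etal <- sum(X[j, ] * beta_l) + B[, 1]
    etar <- sum(X[j, ] * beta_r) + B[, 2]
    yl <- rec$yl[j]; yr <- rec$yr[j]
    lik <- lik * if (yl >= 0 && yr >= 0) {
      sl <- 2 * yl - 1; sr <- 2 * yr - 1
      phi2_oracle(sl * etal, sr * etar, sl * sr * rho)
    } else if (yl >= 0) {
      pnorm((2 * yl - 1) * etal)
    } else {
      pnorm((2 * yr - 1) * etar)
    }
  }
  log(mean(lik))
}

# cluster (scan-level) bootstrap resample of an audit dataset; resampled
# scans get fresh ids so repeated draws stay distinct clusters
bootstrap_data <- function(data) {
  rec <- data$records
  ids <- unique(rec$scan_id)
  pick <- sample(ids, length(ids), replace = TRUE)
  pieces <- lapply(seq_along(pick), function(i) {
    out <- rec[rec$scan_id == pick[i], , drop = FALSE]
    out$scan_id <- sprintf("B%05d", i)
    out
  })
  suppressMessages(as_audit_data(do.call(rbind, pieces)))
}
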