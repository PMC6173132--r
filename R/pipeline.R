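#' Configuration for a full audit analysis run
#'
#' Either file mode (`input` points to a long-format CSV) or synthetic mode
#' (`synthetic = TRUE`, data generated from `params` + `design`).
#'
#' @param input Path to an input CSV (file mode), or `NULL`.
#' @param column_map Header mapping for file mode; see [default_column_map()].
#' @param synthetic Generate the data instead of reading a file.
#' @param params,design [true_parameters()] and [design_config()] for
#'   synthetic mode.
#' @param variants Model variants to fit (subset of
#'   `c("expert", "qualification", "none")`); the first is used for the
#'   margins table and empirical Bayes output.
#' @param nodes,adaptive Quadrature settings, see [model_spec()].
#' @param seed Integer seed (mandatory in synthetic mode).
#' @param out_dir Output directory for the result tables and run log.
#' @param digits Significant digits for the output CSVs.
#' @return Object of class `run_config`.
#' @export
run_config <- function(input = NULL, column_map = default_column_map(),
                       synthetic = is.null(input),
                       params = study_parameters(),
                       design = nominal_study_design(),
                       variants = c("expert", "qualification", "none"),
                       nodes = 12, adaptive = FALSE, seed = NULL,
                       out_dir = "ovaudit-results", digits = 6) {
  if (!synthetic && is.null(input))
    stop("file mode requires an input path")
  if (synthetic && (is.null(seed) && is.null(design$seed)))
    stop("synthetic mode requires a seed")
  variants <- match.arg(variants, c("expert", "qualification", "none"),
                        several.ok = TRUE)
  structure(list(input = input, column_map = column_map,
                 synthetic = synthetic, params = params, design = design,
                 variants = variants, nodes = nodes, adaptive = adaptive,
                 seed = seed, out_dir = out_dir, digits = digits),
            class = "run_config")
}

#' Load a run configuration from a YAML file
#'
#' Recognised top-level fields mirror [run_config()]; `params` and `design`
#' may be nested maps with the fields of [true_parameters()] and
#' [design_config()].
#'
#' @param path YAML file path.
#' @return A `run_config`.
#' @export
load_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  if (is.null(y)) y <- list()
  args <- y[intersect(names(y), c("input", "synthetic", "variants", "nodes",
                                  "adaptive", "seed", "out_dir", "digits"))]
  if (!is.null(y$column_map)) args$column_map <- unlist(y$column_map)
  if (!is.null(y$params))
    args$params <- do.call(true_parameters, lapply(y$params, unlist))
  if (!is.null(y$design)) {
    d <- y$design
    if (!is.null(d$expert_groups))
      d$expert_groups <- lapply(d$expert_groups, as.character)
    if (!is.null(d$qualification_map))
      d$qualification_map <- unlist(d$qualification_map)
    args$design <- do.call(design_config, d)
  }
  do.call(run_config, args)
}

write_table <- function(df, path, digits) {
  num <- vapply(df, is.numeric, logical(1))
  df[num] <- lapply(df[num], function(x) signif(x, digits))
  write.csv(df, path, row.names = FALSE, quote = FALSE, na = "")
  path
}

#' Run the full audit analysis
#'
#' Reads (or generates) the audit data, fits the requested model variants,
#' and writes the report tables: `counts.csv` (scan/assessment counts),
#' `table1.csv` (fixed and random effects for all variants), `table2.csv`
#' (population-averaged margins with raw proportions), `correlations.csv`
#' (ICCs and latent correlations per variant), `eb_effects.csv` (empirical
#' Bayes means) and `run.log`. Any stage error aborts with a stage-named
#' message and removes partial outputs.
#'
#' @param config A [run_config()].
#' @return Invisibly, a list with the data, fits and output file paths.
#' @export
run_audit <- function(config) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  files <- file.path(config$out_dir,
                     c("counts.csv", "raw_proportions.csv",
                       "design_summary.csv", "table1.csv", "table2.csv",
                       "correlations.csv", "eb_effects.csv", "run.log"))
  names(files) <- c("counts", "raw", "design", "table1", "table2",
                    "correlations", "eb", "log")
  created <- character(0)
  stage <- "setup"
  log <- character(0)
  t0 <- Sys.time()
  note <- function(...) log <<- c(log, paste0(...))

  res <- tryCatch({
    note("ovaudit run started ", format(t0))
    note("mode: ", if (config$synthetic) "synthetic" else
      paste0("file (", config$input, ")"))
    note("seed: ", config$seed %||% config$design$seed %||% "none",
         " | nodes: ", config$nodes, " | adaptive: ", config$adaptive)

    stage <- "data"
    data <- if (config$synthetic) {
      generate_audit_dataset(config$params, config$design, config$seed)
    } else {
      read_audit_csv(config$input, config$column_map)
    }
    note("scans: ", data$n_scans, " | reviews: ", data$n_records,
         " | assessments: ", data$n_assessments,
         " | dropped rows: ", data$n_dropped)

    stage <- "counts"
    counts <- data.frame(
      n_scans = data$n_scans,
      n_records = data$n_records,
      n_lo_assessments = sum(!is.na(data$records$y_left)),
      n_ro_assessments = sum(!is.na(data$records$y_right)),
      n_assessments = data$n_assessments,
      n_dropped = data$n_dropped)
    created <- c(created, write_table(counts, files["counts"], config$digits))

    stage <- "raw proportions"
    created <- c(created, write_table(raw_proportions(data), files["raw"],
                                      config$digits))
    ds <- as.data.frame(design_summary(data))
    names(ds) <- c("sonographer", "expert", "n_reviews")
    created <- c(created, write_table(ds, files["design"], config$digits))

    stage <- "model fitting"
    fits <- list()
    for (v in config$variants) {
      tv <- Sys.time()
      fits[[v]] <- fit_biprobit(data, model_spec(v, nodes = config$nodes,
                                                 adaptive = config$adaptive))
      note("variant '", v, "': converged=", fits[[v]]$converged,
           ", loglik=", sprintf("%.4f", fits[[v]]$loglik),
           ", elapsed=", sprintf("%.1fs", as.numeric(
             difftime(Sys.time(), tv, units = "secs"))))
    }

    stage <- "table1"
    t1 <- do.call(rbind, lapply(names(fits), function(v)
      cbind(variant = v, fit_table(fits[[v]]))))
    created <- c(created, write_table(t1, files["table1"], config$digits))

    stage <- "table2"
    t2 <- margins_table(fits[[1]])
    created <- c(created, write_table(t2, files["table2"], config$digits))

    stage <- "correlations"
    cors <- do.call(rbind, lapply(names(fits), function(v)
      cbind(variant = v, correlation_summary(fits[[v]]))))
    created <- c(created, write_table(cors, files["correlations"],
                                      config$digits))

    stage <- "empirical Bayes"
    eb <- empirical_bayes(fits[[1]])
    created <- c(created, write_table(eb, files["eb"], config$digits))

    note("finished ", format(Sys.time()), " (",
         sprintf("%.1fs", as.numeric(difftime(Sys.time(), t0,
                                              units = "secs"))), ")")
    writeLines(log, files["log"])
    list(data = data, fits = fits, files = files)
  }, error = function(e) {
    unlink(created)
    stop("stage '", stage, "' failed: ", conditionMessage(e), call. = FALSE)
  })
  invisible(res)
}

#' Parameter recovery study on synthetic audits
#'
#' Repeats generate-then-fit `n_replicates` times (replicate `i` uses seed
#' `seed + i`) and summarises, per natural parameter, the mean estimate,
#' bias, empirical standard error, mean model standard error and the coverage
#' of the 95% Wald confidence interval. Non-converged replicates are counted
#' and excluded.
#'
#' @param params,design Truth and layout for [generate_audit_dataset()].
#' @param n_replicates Number of replicates (0 returns an empty summary).
#' @param variant,nodes Model settings for the fits.
#' @param seed Master seed.
#' @param start `"truth"` starts each fit at the generating parameters (the
#'   usual choice in recovery studies — the maximiser is unchanged, the
#'   search is just shorter); `"probit"` uses the univariate-probit starts of
#'   [fit_biprobit()].
#' @return Data frame (one row per parameter) with attributes
#'   `n_nonconverged` and `estimates` (replicate-level matrix).
#' @export
run_recovery_study <- function(params = study_parameters(),
                               design = nominal_study_design(),
                               n_replicates = 100, variant = "expert",
                               nodes = 12, seed = 1,
                               start = c("truth", "probit")) {
  start <- match.arg(start)
  empty <- data.frame(parameter = character(0), truth = numeric(0),
                      mean_est = numeric(0), bias = numeric(0),
                      rel_bias = numeric(0), empirical_se = numeric(0),
                      mean_se = numeric(0), coverage = numeric(0))
  if (n_replicates == 0) return(empty)

  spec <- model_spec(variant, nodes = nodes)
  truth <- c(setNames(params$beta_left,
                      paste0("LO:", names(params$beta_left))),
             setNames(params$beta_right,
                      paste0("RO:", names(params$beta_right))),
             var_left = params$var_left, var_right = params$var_right,
             cov_lr = params$cov_lr, rho_err = params$rho_err)

  theta0 <- if (start == "truth" && variant == "expert")
    pack_parameters(params$beta_left, params$beta_right,
                    max(params$var_left, 1e-4),
                    max(params$var_right, 1e-4),
                    params$cov_lr, params$rho_err) else NULL

  ests <- ses <- NULL
  n_bad <- 0L
  for (i in seq_len(n_replicates)) {
    dat <- generate_audit_dataset(params, design, seed = seed + i)
    fit <- tryCatch(suppressWarnings(fit_biprobit(dat, spec, start = theta0)),
                    error = function(e) NULL)
    if (is.null(fit) || !fit$converged) { n_bad <- n_bad + 1L; next }
    ests <- rbind(ests, fit$natural$par)
    ses <- rbind(ses, sqrt(pmax(diag(fit$natural$vcov), 0)))
  }
  if (n_bad > 0)
    message(n_bad, " of ", n_replicates,
            " replicates excluded (non-converged or failed)")
  if (is.null(ests)) return(structure(empty, n_nonconverged = n_bad))

  # align on shared parameter names (generator truth uses generator naming)
  nm <- colnames(ests)
  tr <- truth[match(translate_names(nm), names(truth))]
  z <- ci_level_z()
  cover <- abs(sweep(ests, 2, tr)) <= z * ses
  out <- data.frame(
    parameter = nm, truth = unname(tr),
    mean_est = colMeans(ests),
    bias = colMeans(ests) - unname(tr),
    rel_bias = (colMeans(ests) - unname(tr)) / unname(tr),
    empirical_se = apply(ests, 2, stats::sd),
    mean_se = colMeans(ses),
    coverage = colMeans(cover),
    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  structure(out, n_nonconverged = n_bad, estimates = ests, ses = ses)
}

# fitted-model coefficient names -> generator truth names
translate_names <- function(nm) {
  nm <- sub("sonographer_id", "sonographer", nm)
  nm <- sub("expert_id", "expert", nm)
  nm
}
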