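#' Deterministic replication seeds
#'
#' Derives the seeds feeding one replication of one design cell from the
#' study root seed. The hash involves the model, sample size, test length,
#' and replication index — but never the estimation method — so every
#' method fitted within a replication consumes the identical data set
#' (paired comparison). Separate streams keep parameter draws, response
#' thresholds, and fitter randomness independent.
#'
#' @param root_seed integer root seed of the study.
#' @param model `"1PL"` or `"2PL"`.
#' @param S,L sample size and test length.
#' @param rep replication index (1-based).
#' @param stream 1 = parameter draw, 2 = response thresholds, 3 = fitter.
#' @return An integer seed in \[1, 2^31 - 2\].
#' @export
replication_seed <- function(root_seed, model, S, L, rep, stream = 1) {
  mix_seed(root_seed, model_code(model), S, L, rep, stream)
}

#' @rdname run_condition
#' @export
study_methods <- function(model = c("1PL", "2PL")) {
  model <- match.arg(model)
  bayes <- c(paste0("MCMC-", c("matched", "stdvague", "hierarchical")),
             paste0("VB-", c("matched", "stdvague", "hierarchical")))
  if (model == "1PL") c("CML", "MML", bayes) else c("MML", bayes)
}

# dispatch one method on one data set; returns irt_estimates
fit_one_method <- function(data, model, method, seed,
                           mcmc = list(), vb = list()) {
  if (method == "CML") {
    if (model != "1PL") stop("CML is only defined for the 1PL model")
    return(fit_cml(data))
  }
  if (method == "MML") return(fit_mml(data, model))
  parts <- strsplit(method, "-", fixed = TRUE)[[1]]
  if (length(parts) != 2 || !parts[1] %in% c("MCMC", "VB") ||
      !parts[2] %in% c("matched", "stdvague", "hierarchical")) {
    stop(sprintf("unknown estimation method '%s'", method))
  }
  prior <- make_prior(parts[2], model)
  if (parts[1] == "MCMC") {
    ctl <- modifyList(list(burnin = 5000, keep = 1000, chains = 1), mcmc)
    dr <- fit_mcmc(data, model, prior, chains = ctl$chains,
                   burnin = ctl$burnin, keep = ctl$keep, seed = seed)
    summarize_chains(dr)
  } else {
    # scale-aware default stopping rule: the bound is a sum over S x L
    # response terms, so the per-sweep improvement that leaves point
    # estimates stable (well below 0.01 on any parameter) scales with S*L
    ctl <- modifyList(list(tol = 1e-5 * nrow(data) * ncol(data),
                           max_sweeps = 300), vb)
    fit_vb(data, model, prior, tol = ctl$tol,
           max_sweeps = ctl$max_sweeps)$estimates
  }
}

#' Run one design cell of the simulation study
#'
#' For each replication: draw true parameters and a response matrix
#' (seeded so all methods share the data), fit the method, align the
#' estimates to the truth, and compute the per-replication recovery
#' metrics. Failures in individual replications are caught and recorded as
#' missing rows, never dropped silently.
#'
#' @param model `"1PL"` or `"2PL"`.
#' @param method one of [study_methods].
#' @param S,L sample size and test length.
#' @param R number of replications.
#' @param root_seed study root seed.
#' @param mcmc,vb named lists overriding the MCMC protocol (burnin 5000,
#'   keep 1000, chains 1) and VB controls (tol 1e-4, max_sweeps 500).
#' @param fitter optional replacement fitting function with signature
#'   `(data, model, method, seed, mcmc, vb)` returning [irt_estimates];
#'   an extension point (used, e.g., to test the failure bookkeeping).
#' @return A data frame (class `condition_summary`) with one row per
#'   replication: RMSE and mean-SE metrics, alignment `(s, t)`, the data
#'   checksum, and an `ok`/`error` record.
#' @export
run_condition <- function(model, method, S, L, R, root_seed,
                          mcmc = list(), vb = list(), fitter = NULL) {
  stopifnot(R >= 1)
  if (is.null(fitter)) {
    if (method == "CML" && model != "1PL") {
      stop("CML is only defined for the 1PL model")
    }
    if (!method %in% study_methods(model)) {
      stop(sprintf("unknown estimation method '%s'", method))
    }
    fitter <- fit_one_method
  }
  rows <- vector("list", R)
  for (r in seq_len(R)) {
    truth <- draw_parameters(S, L, model,
                             replication_seed(root_seed, model, S, L, r, 1))
    Y <- simulate_responses(truth,
                            replication_seed(root_seed, model, S, L, r, 2))
    checksum <- sum(Y * seq_along(Y)) %% 2147483647
    fit <- tryCatch(
      fitter(Y, model, method, replication_seed(root_seed, model, S, L, r, 3),
             mcmc = mcmc, vb = vb),
      error = function(e) e)
    if (inherits(fit, "error")) {
      rows[[r]] <- data.frame(
        model = model, method = method, S = S, L = L, rep = r,
        rmse_theta = NA_real_, rmse_b = NA_real_, rmse_a = NA_real_,
        rmse_p = NA_real_, mean_se_theta = NA_real_, mean_se_b = NA_real_,
        mean_se_a = NA_real_, align_s = NA_real_, align_t = NA_real_,
        checksum = checksum, ok = FALSE,
        error = conditionMessage(fit))
      next
    }
    al <- align_estimates(fit, truth, model)
    rows[[r]] <- data.frame(
      model = model, method = method, S = S, L = L, rep = r,
      rmse_theta = rmse(al$aligned$theta, truth$theta),
      rmse_b = rmse(al$aligned$b, truth$b),
      rmse_a = if (model == "2PL") rmse(al$aligned$a, truth$a) else 0,
      rmse_p = rmse(irf_matrix(fit$theta, fit$b, fit$a),
                    irf_matrix(truth$theta, truth$b, truth$a)),
      mean_se_theta = mean(fit$se_theta),
      mean_se_b = mean(fit$se_b),
      mean_se_a = mean(fit$se_a),
      align_s = al$s, align_t = al$t,
      checksum = checksum, ok = TRUE, error = "")
  }
  out <- do.call(rbind, rows)
  class(out) <- c("condition_summary", class(out))
  out
}

#' Read a study configuration file
#'
#' YAML with fields `models`, `sample_sizes`, `test_lengths`, `methods`
#' (optional; defaults to every method valid for each model),
#' `replications`, `root_seed`, and optional `mcmc` / `vb` control lists.
#'
#' @param path path to the YAML configuration.
#' @return A validated configuration list.
#' @export
read_study_config <- function(path) {
  if (!requireNamespace("yaml", quietly = TRUE)) {
    stop("the 'yaml' package is required to read configuration files")
  }
  cfg <- yaml::read_yaml(path)
  validate_study_config(cfg)
}

validate_study_config <- function(cfg) {
  cfg$models <- match.arg(cfg$models, c("1PL", "2PL"), several.ok = TRUE)
  stopifnot(all(cfg$sample_sizes >= 2), all(cfg$test_lengths >= 2),
            cfg$replications >= 1)
  cfg$root_seed <- cfg$root_seed %||% 1L
  cfg$mcmc <- cfg$mcmc %||% list()
  cfg$vb <- cfg$vb %||% list()
  cfg
}

#' Run a crossed simulation study with resumable per-cell persistence
#'
#' Iterates every (model, method, sample size, test length) cell of the
#' configuration, writing one `condition_summary` CSV per cell into
#' `outdir`. Cells whose file already exists are skipped, so an interrupted
#' study resumes where it stopped. A combined `summary.csv` is rewritten at
#' the end. Methods invalid for a model (CML under the 2PL) are skipped.
#'
#' @param config configuration list (see [read_study_config]) or a path to
#'   a YAML file.
#' @param outdir results directory (created if needed).
#' @param verbose print per-cell progress.
#' @return The combined summary data frame, invisibly.
#' @export
run_study <- function(config, outdir, verbose = TRUE) {
  if (is.character(config)) config <- read_study_config(config)
  config <- validate_study_config(config)
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  for (model in config$models) {
    methods <- config$methods %||% study_methods(model)
    methods <- intersect(methods, study_methods(model))
    for (method in methods) {
      for (S in config$sample_sizes) {
        for (L in config$test_lengths) {
          f <- file.path(outdir, sprintf("cell_%s_%s_S%d_L%d.csv",
                                         model, method, S, L))
          if (file.exists(f)) next
          t0 <- Sys.time()
          cs <- run_condition(model, method, S, L, config$replications,
                              config$root_seed, mcmc = config$mcmc,
                              vb = config$vb)
          if (verbose) {
            message(sprintf(
              "[irtlab] %s %s S=%d L=%d R=%d: %.1fs, %d failure(s)",
              model, method, S, L, config$replications,
              as.numeric(Sys.time() - t0, units = "secs"), sum(!cs$ok)))
          }
          write.csv(cs, f, row.names = FALSE)
        }
      }
    }
  }
  files <- list.files(outdir, pattern = "^cell_.*\\.csv$", full.names = TRUE)
  if (length(files) == 0) return(invisible(NULL))
  combined <- do.call(rbind, lapply(files, read.csv))
  write.csv(combined, file.path(outdir, "summary.csv"), row.names = FALSE)
  invisible(combined)
}

# per-cell means over successful replications
cell_means <- function(summary_df) {
  ok <- summary_df[summary_df$ok %in% TRUE, , drop = FALSE]
  if (nrow(ok) == 0) stop("no successful replications in summary")
  metrics <- c("rmse_theta", "rmse_b", "rmse_a", "rmse_p",
               "mean_se_theta", "mean_se_b", "mean_se_a")
  ag <- aggregate(ok[metrics],
                  by = ok[c("model", "method", "S", "L")], FUN = mean)
  cnt <- aggregate(list(n_ok = ok$rep),
                   by = ok[c("model", "method", "S", "L")], FUN = length)
  merge(ag, cnt)
}

marginal_over_cells <- function(cm, by, metrics) {
  aggregate(cm[metrics], by = cm[by], FUN = mean)
}

#' Marginal-mean report tables
#'
#' Equal-cell-weight marginal means of the recovery metrics, shaped like
#' the study's summary tables: `"T3"` (1PL, by estimation method), `"T4"`
#' (1PL, by sample size and by test length), `"T6"` (2PL, by test length),
#' `"T7"` (2PL, by sample size), `"T8"` (2PL, by estimation method).
#'
#' @param results a combined study summary data frame, a results directory
#'   produced by [run_study], or a single `condition_summary`.
#' @param table one of `"T3"`, `"T4"`, `"T6"`, `"T7"`, `"T8"`.
#' @return A data frame of marginal means (methods in rows or columns as
#'   appropriate for the table).
#' @export
tabulate_results <- function(results, table = c("T3", "T4", "T6", "T7",
                                                "T8")) {
  table <- match.arg(table)
  if (is.character(results)) {
    f <- file.path(results, "summary.csv")
    if (!file.exists(f)) stop("no summary.csv in results directory")
    results <- read.csv(f)
  }
  model <- if (table %in% c("T3", "T4")) "1PL" else "2PL"
  df <- results[results$model == model, , drop = FALSE]
  if (nrow(df) == 0) stop(sprintf("no %s results available", model))
  cm <- cell_means(df)

  wide <- function(long, rowvar, metric) {
    out <- reshape(long[c(rowvar, "method", metric)],
                   idvar = rowvar, timevar = "method", direction = "wide")
    names(out) <- sub(paste0("^", metric, "\\."), "", names(out))
    out
  }

  if (table == "T3") {
    m <- marginal_over_cells(cm, "method",
                             c("rmse_theta", "mean_se_theta", "rmse_b",
                               "mean_se_b", "rmse_p"))
    names(m) <- c("method", "ability_rmse", "ability_se",
                  "difficulty_rmse", "difficulty_se", "probability_rmse")
    return(m[order(m$method), ])
  }
  if (table == "T4") {
    byS <- marginal_over_cells(cm, c("method", "S"),
                               c("rmse_b", "mean_se_b"))
    byL <- marginal_over_cells(cm, c("method", "L"),
                               c("rmse_theta", "mean_se_theta", "rmse_p"))
    out <- rbind(
      cbind(metric = "diff_rmse", wide(byS, "S", "rmse_b")[, 1, drop = FALSE],
            wide(byS, "S", "rmse_b")[, -1]),
      cbind(metric = "diff_se", wide(byS, "S", "mean_se_b")[, 1, drop = FALSE],
            wide(byS, "S", "mean_se_b")[, -1]))
    outL <- rbind(
      cbind(metric = "ab_rmse", wide(byL, "L", "rmse_theta")[, 1,
                                                             drop = FALSE],
            wide(byL, "L", "rmse_theta")[, -1]),
      cbind(metric = "ab_se", wide(byL, "L", "mean_se_theta")[, 1,
                                                              drop = FALSE],
            wide(byL, "L", "mean_se_theta")[, -1]),
      cbind(metric = "p_rmse", wide(byL, "L", "rmse_p")[, 1, drop = FALSE],
            wide(byL, "L", "rmse_p")[, -1]))
    names(out)[2] <- "level"
    names(outL)[2] <- "level"
    return(rbind(out, outL))
  }
  if (table == "T6") {
    byL <- marginal_over_cells(cm, c("method", "L"),
                               c("rmse_theta", "mean_se_theta", "rmse_p"))
    out <- rbind(
      cbind(metric = "ability_rmse", wide(byL, "L", "rmse_theta")),
      cbind(metric = "ability_se", wide(byL, "L", "mean_se_theta")),
      cbind(metric = "probability_rmse", wide(byL, "L", "rmse_p")))
    names(out)[2] <- "level"
    return(out)
  }
  if (table == "T7") {
    byS <- marginal_over_cells(cm, c("method", "S"),
                               c("rmse_b", "mean_se_b", "rmse_a",
                                 "mean_se_a"))
    out <- rbind(
      cbind(metric = "difficulty_rmse", wide(byS, "S", "rmse_b")),
      cbind(metric = "difficulty_se", wide(byS, "S", "mean_se_b")),
      cbind(metric = "discrimination_rmse", wide(byS, "S", "rmse_a")),
      cbind(metric = "discrimination_se", wide(byS, "S", "mean_se_a")))
    names(out)[2] <- "level"
    return(out)
  }
  # T8
  m <- marginal_over_cells(cm, "method",
                           c("rmse_theta", "mean_se_theta", "rmse_b",
                             "mean_se_b", "rmse_a", "mean_se_a", "rmse_p"))
  names(m) <- c("method", "ability_rmse", "ability_se", "difficulty_rmse",
                "difficulty_se", "discrimination_rmse", "discrimination_se",
                "probability_rmse")
  m[order(m$method), ]
}
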