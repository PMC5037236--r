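rmse <- function(x, y) sqrt(mean((x - y)^2))

# likelihood-equivalent transform: theta' = s theta + t, b' = s b + t,
# a' = a / s, so that a'(theta' - b') = a (theta - b) for every person/item
apply_transform <- function(est, s, t) {
  est$theta <- s * est$theta + t
  est$b <- s * est$b + t
  est$a <- est$a / s
  est
}

align_objective <- function(est, truth, s, t, use_a) {
  tr <- apply_transform(est, s, t)
  J <- rmse(tr$theta, truth$theta) + rmse(tr$b, truth$b)
  if (use_a) J <- J + rmse(tr$a, truth$a)
  J
}

#' Shift/scale alignment of estimates before error computation
#'
#' The 2PL likelihood is invariant under a joint shift and scale of the
#' parameters, so estimates are only identified up to that transformation.
#' Before computing recovery errors, the estimates are transformed by
#' `theta' = s theta + t`, `b' = s b + t`, `a' = s a`, with `(s, t)` chosen
#' to minimize `J(s, t) = RMSE(theta) + RMSE(b) + RMSE(a)` against the true
#' values (a 21 x 21 grid pre-scan over s in \[0.5, 2\], t in \[-1, 1\],
#' refined by Nelder-Mead on `(log s, t)`). For the 1PL the scale is fixed
#' by the unit slopes: s = 1, only the shift `t` is optimized, and the
#' discrimination term is dropped from `J`.
#'
#' @param est an [irt_estimates] object.
#' @param truth the generating [irt_parameters].
#' @param model `"1PL"` or `"2PL"`; defaults to the estimate's model.
#' @return A list of class `irt_alignment`: `s`, `t`, `aligned` (the
#'   transformed estimates), `objective`.
#' @export
align_estimates <- function(est, truth, model = est$model) {
  stopifnot(length(est$theta) == length(truth$theta),
            length(est$b) == length(truth$b))
  if (sd(truth$theta) == 0 && sd(truth$b) == 0) {
    warning("degenerate truth (zero variance); alignment skipped")
    return(structure(list(s = 1, t = 0, aligned = est,
                          objective = align_objective(est, truth, 1, 0,
                                                      model == "2PL")),
                     class = "irt_alignment"))
  }
  if (model == "1PL") {
    opt <- optimize(function(t) align_objective(est, truth, 1, t, FALSE),
                    interval = c(-8, 8), tol = 1e-9)
    s <- 1
    t <- opt$minimum
    J <- opt$objective
  } else {
    grid_s <- seq(0.5, 2, length.out = 21)
    grid_t <- seq(-1, 1, length.out = 21)
    Jg <- outer(grid_s, grid_t,
                Vectorize(function(s, t) {
                  align_objective(est, truth, s, t, TRUE)
                }))
    ij <- arrayInd(which.min(Jg), dim(Jg))
    starts <- list(c(0, 0),
                   c(log(grid_s[ij[1]]), grid_t[ij[2]]))
    best <- NULL
    for (st0 in starts) {
      o <- optim(st0, function(p) {
        align_objective(est, truth, exp(p[1]), p[2], TRUE)
      }, method = "Nelder-Mead",
      control = list(reltol = 1e-12, maxit = 2000))
      if (is.null(best) || o$value < best$value) best <- o
    }
    s <- exp(best$par[1])
    t <- best$par[2]
    J <- best$value
  }
  structure(list(s = s, t = t, aligned = apply_transform(est, s, t),
                 objective = J), class = "irt_alignment")
}

#' @export
print.irt_alignment <- function(x, ...) {
  cat(sprintf("irt_alignment: s = %.4f, t = %.4f, J = %.5f\n",
              x$s, x$t, x$objective))
  invisible(x)
}

check_reps <- function(est_reps, truth_reps) {
  if (length(est_reps) != length(truth_reps) || length(est_reps) < 1) {
    stop("need matching, nonempty lists of replications")
  }
}

#' Average RMSE recovery metrics over replications
#'
#' Within each replication the root of the mean squared difference between
#' estimated and true values is taken over persons (`theta`), items (`b`,
#' `a`), or person-item response probabilities (`p`, computed through [irf]
#' from the estimated and the true parameters); the per-replication RMSEs
#' are then averaged with equal weight. Estimates should already be aligned
#' (see [align_estimates]) for the parameter metrics; the probability metric
#' is invariant to the alignment ambiguity and uses the estimates as given.
#'
#' @param est_reps list of [irt_estimates], one per replication.
#' @param truth_reps list of matching [irt_parameters].
#' @return The averaged RMSE (scalar).
#' @export
average_rmse_theta <- function(est_reps, truth_reps) {
  check_reps(est_reps, truth_reps)
  mean(mapply(function(e, tr) rmse(e$theta, tr$theta),
              est_reps, truth_reps))
}

#' @rdname average_rmse_theta
#' @export
average_rmse_b <- function(est_reps, truth_reps) {
  check_reps(est_reps, truth_reps)
  mean(mapply(function(e, tr) rmse(e$b, tr$b), est_reps, truth_reps))
}

#' @rdname average_rmse_theta
#' @export
average_rmse_a <- function(est_reps, truth_reps) {
  check_reps(est_reps, truth_reps)
  mean(mapply(function(e, tr) rmse(e$a, tr$a), est_reps, truth_reps))
}

#' @rdname average_rmse_theta
#' @export
average_rmse_p <- function(est_reps, truth_reps) {
  check_reps(est_reps, truth_reps)
  mean(mapply(function(e, tr) {
    rmse(irf_matrix(e$theta, e$b, e$a),
         irf_matrix(tr$theta, tr$b, tr$a))
  }, est_reps, truth_reps))
}

#' Average standard error over parameters and replications
#'
#' Mean of the reported SEs over parameters within each replication, then
#' averaged over replications.
#'
#' @param se_reps list of numeric SE vectors, one per replication.
#' @return The averaged SE (scalar).
#' @export
average_se <- function(se_reps) {
  if (length(se_reps) < 1) stop("need at least one replication")
  mean(vapply(se_reps, mean, numeric(1)))
}

#' Eta-squared effect sizes from the simulation-study ANOVA
#'
#' Fixed-effects ANOVA of one recovery metric on estimation method (EM),
#' sample size (SS), and test length (TL): three main effects, three two-way
#' interactions, the three-way interaction, and the residual. Effect sizes
#' are `eta^2 = SS_effect / SS_total`, reported in percent and labelled by
#' the conventional thresholds (large > 14%, medium 8-14%, small < 8%).
#' The design must be a balanced full factorial with a constant number of
#' replications per cell.
#'
#' @param observations data frame with factor columns `EM`, `SS`, `TL` and
#'   a numeric metric column.
#' @param metric name of the metric column (default `"value"`).
#' @return Data frame with columns `effect`, `ss`, `eta2_pct`, `size`.
#' @export
anova_eta2 <- function(observations, metric = "value") {
  need <- c("EM", "SS", "TL", metric)
  if (!all(need %in% names(observations))) {
    stop("observations must contain columns EM, SS, TL and the metric")
  }
  df <- data.frame(EM = factor(observations$EM),
                   SS = factor(observations$SS),
                   TL = factor(observations$TL),
                   y = observations[[metric]])
  counts <- table(df$EM, df$SS, df$TL)
  if (length(unique(as.vector(counts))) != 1 || counts[1] == 0) {
    stop("unbalanced design: every EM x SS x TL cell needs the same number",
         " of replications")
  }
  # constant factors (single level) drop out of the decomposition
  active <- c("EM", "SS", "TL")[vapply(df[c("EM", "SS", "TL")], nlevels,
                                       integer(1)) > 1]
  if (length(active) == 0) stop("no factor varies; nothing to decompose")
  fml <- stats::as.formula(paste("y ~", paste(active, collapse = " * ")))
  fit <- aov(fml, data = df)
  tab <- summary(fit)[[1]]
  ss <- tab[, "Sum Sq"]
  effects <- trimws(rownames(tab))
  tot <- sum(ss)
  eta2 <- if (tot > 1e-12 * (sum(df$y^2) + 1)) 100 * ss / tot else
    rep(0, length(ss))
  size <- ifelse(eta2 > 14, "large", ifelse(eta2 >= 8, "medium", "small"))
  size[effects == "Residuals"] <- ""
  data.frame(effect = effects, ss = ss, eta2_pct = eta2, size = size,
             row.names = NULL)
}
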