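# Independent oracles used across the test files. These deliberately avoid
# the package's own computational paths: brute-force enumeration, dense
# quadrature, polynomial convolution, and generic optimizers.

# elementary symmetric functions by polynomial convolution:
# coefficients of prod_k (1 + eps_k t)
esf_bruteforce <- function(eps) {
  poly <- 1
  for (e in eps) poly <- c(poly, 0) + c(0, poly * e)
  poly
}

# conditional Rasch log-likelihood computed from the brute-force ESFs
cml_loglik_bruteforce <- function(b, score_counts, item_totals) {
  eps <- exp(-b)
  gam <- esf_bruteforce(eps)
  sum(item_totals * (-b)) -
    sum(score_counts * log(gam))
}

# E[log(1 + e^Z)], Z ~ N(m, v), by 64-node Gauss-Hermite quadrature
softplus_gh <- function(m, v, nodes = 64) {
  gh <- statmod::gauss.quad(nodes, kind = "hermite")
  z <- m + sqrt(2 * v) * gh$nodes
  w <- gh$weights / sqrt(pi)
  lp <- ifelse(z > 30, z, log1p(exp(z)))
  sum(w * lp)
}

# Exact posterior summaries for tiny fixed-prior 1PL/2PL instances (L <= 2)
# by dense-grid quadrature, exploiting that abilities are iid given items:
#   p(b) prod_i G_i(b),  G_i(b) = int p(t) prod_k f(y_ik | t, b_k) dt
# Returns means and SDs of every theta_i and b_k, plus log marginal lik.
quad_posterior <- function(Y, a = rep(1, ncol(Y)),
                           theta_var = 1, b_var = 1,
                           n_t = 201, n_b = 201,
                           t_range = c(-8, 8),
                           b_range = c(-12, 12)) {
  S <- nrow(Y)
  L <- ncol(Y)
  stopifnot(L <= 2)
  tg <- seq(t_range[1], t_range[2], length.out = n_t)
  dt <- tg[2] - tg[1]
  bg <- seq(b_range[1], b_range[2], length.out = n_b)
  db <- bg[2] - bg[1]
  pt <- dnorm(tg, 0, sqrt(theta_var)) * dt
  pb <- dnorm(bg, 0, sqrt(b_var)) * db

  # f[[k]][t, b] likelihood of person-cell response y on item k
  cellf <- function(y, k) {
    eta <- a[k] * outer(tg, bg, "-")
    p <- plogis(eta)
    if (y == 1) p else 1 - p
  }

  if (L == 1) {
    G <- lapply(seq_len(S), function(i) cellf(Y[i, 1], 1))  # t x b
    Gi <- lapply(G, function(m) colSums(m * pt))            # over theta
    Git <- lapply(G, function(m) colSums(m * pt * tg))
    post_b <- pb * Reduce(`*`, Gi)
    Z <- sum(post_b)
    wb <- post_b / Z
    Eb <- sum(wb * bg)
    SDb <- sqrt(sum(wb * bg^2) - Eb^2)
    Eth <- SDth <- numeric(S)
    for (i in seq_len(S)) {
      # replace G_i by its theta-moment versions
      ratio1 <- Git[[i]] / Gi[[i]]
      Eth[i] <- sum(wb * ratio1)
      Git2 <- colSums(G[[i]] * pt * tg^2)
      Eth2 <- sum(wb * Git2 / Gi[[i]])
      SDth[i] <- sqrt(Eth2 - Eth[i]^2)
    }
    return(list(E_theta = Eth, SD_theta = SDth, E_b = Eb, SD_b = SDb,
                logZ = log(Z)))
  }

  f1 <- lapply(seq_len(S), function(i) cellf(Y[i, 1], 1))
  f2 <- lapply(seq_len(S), function(i) cellf(Y[i, 2], 2))
  # G_i(b1, b2) = sum_t pt f1(t,b1) f2(t,b2); moments via weighted variants
  Gfun <- function(i, wt) crossprod(f1[[i]] * wt, f2[[i]]) # b1 x b2
  G <- lapply(seq_len(S), function(i) Gfun(i, pt))
  post <- outer(pb, pb) * Reduce(`*`, G)
  Z <- sum(post)
  w <- post / Z
  Eb1 <- sum(w * bg)
  Eb2 <- sum(t(w) * bg)
  SDb1 <- sqrt(sum(w * bg^2) - Eb1^2)
  SDb2 <- sqrt(sum(t(w) * bg^2) - Eb2^2)
  Eth <- SDth <- numeric(S)
  for (i in seq_len(S)) {
    r1 <- Gfun(i, pt * tg) / G[[i]]
    r2 <- Gfun(i, pt * tg^2) / G[[i]]
    Eth[i] <- sum(w * r1)
    SDth[i] <- sqrt(sum(w * r2) - Eth[i]^2)
  }
  list(E_theta = Eth, SD_theta = SDth, E_b = c(Eb1, Eb2),
       SD_b = c(SDb1, SDb2), logZ = log(Z))
}

# batch-means Monte Carlo standard error of a chain mean
mcse_batch <- function(x, nbatch = 25) {
  n <- length(x)
  bs <- floor(n / nbatch)
  means <- vapply(seq_len(nbatch), function(j) {
    mean(x[((j - 1) * bs + 1):(j * bs)])
  }, numeric(1))
  sd(means) / sqrt(nbatch)
}

make_1pl_data <- function(S, L, seed) {
  tp <- draw_parameters(S, L, "1PL", seed = seed)
  list(truth = tp, Y = simulate_responses(tp, seed = seed + 1))
}
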