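#' Expected improvement acquisition function
#'
#' `EI = (mu - f_star) * Phi(z) + sigma * phi(z)` with
#' `z = (mu - f_star) / sigma`, the expected amount by which a Gaussian
#' posterior at a candidate point exceeds the incumbent best `f_star`
#' (maximization). At `sigma = 0` it degenerates to `max(mu - f_star, 0)`.
#'
#' @param mu,sigma posterior mean and standard deviation (vectorized).
#' @param f_star incumbent best objective value.
#' @return nonnegative expected improvement.
#' @export
expected_improvement <- function(mu, sigma, f_star) {
  stopifnot(all(sigma >= 0))
  out <- pmax(mu - f_star, 0)
  pos <- sigma > 0
  if (any(pos)) {
    z <- (mu[pos] - f_star) / sigma[pos]
    out[pos] <- (mu[pos] - f_star) * stats::pnorm(z) + sigma[pos] * stats::dnorm(z)
  }
  out
}

# --- minimal Gaussian-process regression ----------------------------------
# Squared-exponential kernel with per-dimension length scales; noise and
# signal variances and length scales fit by maximizing the log marginal
# likelihood with L-BFGS-B. Inputs are assumed scaled to [0,1]^d.

gp_kernel <- function(X1, X2, log_ls, log_sf) {
  d <- ncol(X1)
  K <- matrix(0, nrow(X1), nrow(X2))
  for (j in seq_len(d)) {
    diff <- outer(X1[, j], X2[, j], "-") / exp(log_ls[j])
    K <- K + diff^2
  }
  exp(2 * log_sf) * exp(-0.5 * K)
}

gp_fit <- function(X, y) {
  d <- ncol(X)
  ym <- mean(y); ys <- stats::sd(y); if (!is.finite(ys) || ys == 0) ys <- 1
  yc <- (y - ym) / ys
  nll <- function(theta) {
    log_ls <- theta[seq_len(d)]; log_sf <- theta[d + 1L]; log_sn <- theta[d + 2L]
    K <- gp_kernel(X, X, log_ls, log_sf) + diag(exp(2 * log_sn) + 1e-8, nrow(X))
    ch <- tryCatch(chol(K), error = function(e) NULL)
    if (is.null(ch)) return(1e10)
    alpha <- backsolve(ch, forwardsolve(t(ch), yc))
    0.5 * sum(yc * alpha) + sum(log(diag(ch))) + 0.5 * nrow(X) * log(2 * pi)
  }
  theta0 <- c(rep(log(0.3), d), log(1), log(0.1))
  op <- stats::optim(theta0, nll, method = "L-BFGS-B",
                     lower = c(rep(log(0.01), d), log(0.01), log(1e-4)),
                     upper = c(rep(log(10), d), log(10), log(1)))
  theta <- op$par
  log_ls <- theta[seq_len(d)]; log_sf <- theta[d + 1L]; log_sn <- theta[d + 2L]
  K <- gp_kernel(X, X, log_ls, log_sf) + diag(exp(2 * log_sn) + 1e-8, nrow(X))
  ch <- chol(K)
  alpha <- backsolve(ch, forwardsolve(t(ch), yc))
  list(X = X, ch = ch, alpha = alpha, log_ls = log_ls, log_sf = log_sf,
       ym = ym, ys = ys)
}

gp_predict <- function(fit, Xnew) {
  Ks <- gp_kernel(Xnew, fit$X, fit$log_ls, fit$log_sf)
  mu <- drop(Ks %*% fit$alpha) * fit$ys + fit$ym
  v <- forwardsolve(t(fit$ch), t(Ks))
  var <- pmax(exp(2 * fit$log_sf) - colSums(v^2), 1e-12)
  list(mu = mu, sigma = sqrt(var) * fit$ys)
}

#' Bayesian hyperparameter optimization with a GP surrogate
#'
#' Maximizes a black-box objective over a bounded box. After an initial
#' random design, each iteration fits a Gaussian process (squared-
#' exponential kernel, per-dimension length scales, hyperparameters by
#' marginal likelihood) to the observed (configuration, score) pairs and
#' evaluates the candidate with the highest expected improvement among a
#' random candidate set. Failed evaluations are recorded and excluded from
#' the surrogate.
#'
#' @param objective function(named list of values) -> scalar score
#'   (maximized); may error or return NA for a failed configuration.
#' @param search_space named list; each entry `c(lower, upper)` for a
#'   continuous dimension or `list(lower, upper, "int")` for integers.
#' @param n_iter GP-guided iterations after the initial design.
#' @param seed integer seed.
#' @param init_design number of initial random points.
#' @param n_candidates random candidates scored by EI per iteration.
#' @return list with `best` (configuration), `best_score`, and `trace`
#'   data.frame (one row per evaluation, incumbent column included).
#' @export
bayesian_optimize <- function(objective, search_space, n_iter = 15L, seed = 1L,
                              init_design = 5L, n_candidates = 1000L) {
  set.seed(substream_seed(seed, "bayesopt"))
  dims <- names(search_space)
  lower <- vapply(search_space, function(s) as.numeric(s[[1]]), numeric(1))
  upper <- vapply(search_space, function(s) as.numeric(s[[2]]), numeric(1))
  is_int <- vapply(search_space, function(s)
    length(s) >= 3 && identical(s[[3]], "int"), logical(1))
  decode <- function(u) {
    x <- lower + u * (upper - lower)
    x[is_int] <- round(x[is_int])
    stats::setNames(as.list(x), dims)
  }
  U <- matrix(stats::runif(init_design * length(dims)), init_design)
  scores <- rep(NA_real_, init_design)
  rows <- vector("list", 0)
  eval_point <- function(u) {
    cfg <- decode(u)
    val <- tryCatch(objective(cfg), error = function(e) NA_real_)
    if (!is.null(val) && length(val) == 1 && is.finite(val)) val else NA_real_
  }
  for (i in seq_len(init_design)) scores[i] <- eval_point(U[i, , drop = TRUE])
  for (it in seq_len(n_iter)) {
    ok <- is.finite(scores)
    if (sum(ok) >= 2L) {
      fit <- gp_fit(U[ok, , drop = FALSE], scores[ok])
      cand <- matrix(stats::runif(n_candidates * length(dims)), n_candidates)
      pr <- gp_predict(fit, cand)
      ei <- expected_improvement(pr$mu, pr$sigma, max(scores[ok]))
      u_next <- cand[which.max(ei), , drop = TRUE]
    } else {
      u_next <- stats::runif(length(dims))
    }
    U <- rbind(U, u_next)
    scores <- c(scores, eval_point(u_next))
  }
  ok <- is.finite(scores)
  if (!any(ok)) dti_stop("every objective evaluation failed")
  incumbent <- vapply(seq_along(scores), function(i)
    suppressWarnings(max(scores[seq_len(i)], na.rm = TRUE)), numeric(1))
  incumbent[!is.finite(incumbent)] <- NA_real_
  best_i <- which(scores == max(scores[ok]))[1]
  trace <- data.frame(iteration = seq_along(scores),
                      score = scores, incumbent = incumbent)
  for (j in seq_along(dims)) {
    x <- lower[j] + U[, j] * (upper[j] - lower[j])
    if (is_int[j]) x <- round(x)
    trace[[dims[j]]] <- x
  }
  list(best = decode(U[best_i, , drop = TRUE]), best_score = scores[best_i],
       trace = trace)
}
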