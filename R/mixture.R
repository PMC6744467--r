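# Beta mixture model of the straightness distribution, fitted by EM with
# the mean/precision parameterization (alpha = mu*phi, beta = (1-mu)*phi),
# and BIC-based selection of the number of groups.

.clamp01 <- function(x, eps = 1e-4) pmin(pmax(x, eps), 1 - eps)

# weighted beta log-likelihood given sufficient statistics
# Sw = sum w, S1 = sum w log x, S2 = sum w log(1-x)
.beta_wll <- function(mu, phi, Sw, S1, S2) {
  a <- mu * phi; b <- (1 - mu) * phi
  Sw * (lgamma(phi) - lgamma(a) - lgamma(b)) + (a - 1) * S1 + (b - 1) * S2
}

# maximize the weighted beta log-likelihood in (mu, phi), starting from the
# current parameters (generalized EM M-step: never returns a worse point)
.beta_mstep <- function(mu0, phi0, Sw, S1, S2) {
  mu0 <- unname(mu0); phi0 <- unname(phi0)
  par0 <- c(qlogis(.clamp01(mu0, 1e-6)), log(max(phi0, 1e-3)))
  nll <- function(par) {
    mu <- plogis(par[1]); phi <- exp(par[2])
    if (!is.finite(phi) || phi > 1e8) return(1e12)
    -.beta_wll(mu, phi, Sw, S1, S2)
  }
  grad <- function(par) {
    mu <- plogis(par[1]); phi <- exp(par[2])
    a <- mu * phi; b <- (1 - mu) * phi
    ga <- Sw * (digamma(phi) - digamma(a)) + S1
    gb <- Sw * (digamma(phi) - digamma(b)) + S2
    dmu <- mu * (1 - mu)
    -c((ga - gb) * phi * dmu, ga * a + gb * b)
  }
  opt <- tryCatch(optim(par0, nll, grad, method = "BFGS",
                        control = list(maxit = 100)),
                  error = function(e) list(par = par0, value = nll(par0)))
  if (opt$value <= nll(par0) && all(is.finite(opt$par)))
    c(mu = plogis(opt$par[1]), phi = exp(opt$par[2]))
  else c(mu = mu0, phi = phi0)
}

# method-of-moments beta parameters for a block of values
.beta_mom <- function(x) {
  m <- mean(x); v <- var(x)
  if (!is.finite(v)) v <- 1e-3  # singleton block
  v <- max(v, 1e-6)
  phi <- max(m * (1 - m) / v - 1, 2)
  c(mu = .clamp01(m, 1e-3), phi = min(phi, 5e3))
}

#' Fit a K-component beta mixture by EM
#'
#' Models values in (0, 1) (straightness indices) as a mixture of beta
#' densities in the mean/precision parameterization. Fitting is
#' expectation-maximization with multiple seeded restarts: restart 1
#' initializes from a quantile partition of the sorted data
#' (method-of-moments per block), later restarts from random partitions.
#' The best log-likelihood fit is kept. Values are clamped to
#' `[1e-4, 1 - 1e-4]` first (ST can be exactly 1 and the beta density is
#' undefined at the boundary).
#'
#' @param values numeric in (0, 1); needs `length(values) >= 10 * K`.
#' @param K number of components (>= 1).
#' @param seed integer seed; restarts use `seed + restart`.
#' @param restarts number of EM restarts (default 10).
#' @param max_iter maximum EM iterations per restart.
#' @param tol absolute log-likelihood improvement declaring convergence.
#' @return object of class `mixture_fit`: `weights`, `mu`, `phi`, `logL`,
#'   `BIC` (`-2 logL + (3K - 1) log n`), `responsibilities`, `logL_trace`,
#'   the clamped `values`, `K`, `n`.
#' @export
fit_beta_mixture <- function(values, K, seed = 1, restarts = 10,
                             max_iter = 500, tol = 1e-8) {
  if (K < 1) stop("K must be >= 1")
  x <- .clamp01(as.numeric(values))
  n <- length(x)
  if (n < 10 * K) stop("need at least 10*K observations (n = ", n, ", K = ", K, ")")
  lx <- log(x); l1x <- log1p(-x)

  run_em <- function(w, mu, phi) {
    ll_old <- -Inf; trace <- numeric(0)
    resp <- NULL
    for (it in seq_len(max_iter)) {
      ld <- matrix(0, n, K)
      for (k in seq_len(K)) {
        a <- mu[k] * phi[k]; b <- (1 - mu[k]) * phi[k]
        ld[, k] <- log(w[k]) + lgamma(phi[k]) - lgamma(a) - lgamma(b) +
          (a - 1) * lx + (b - 1) * l1x
      }
      mx <- do.call(pmax, as.data.frame(ld))
      lse <- mx + log(rowSums(exp(ld - mx)))
      ll <- sum(lse)
      if (!is.finite(ll)) return(NULL)  # numerically degenerate restart
      trace <- c(trace, ll)
      resp <- exp(ld - lse)
      if (is.finite(ll_old) && ll - ll_old < tol) break
      ll_old <- ll
      w <- colMeans(resp)
      if (any(w < 1e-6)) return(NULL)  # degenerate component
      for (k in seq_len(K)) {
        r <- resp[, k]
        upd <- .beta_mstep(mu[k], phi[k], sum(r), sum(r * lx), sum(r * l1x))
        mu[k] <- upd[["mu"]]; phi[k] <- upd[["phi"]]
      }
    }
    list(w = w, mu = mu, phi = phi, logL = ll, resp = resp, trace = trace,
         iters = it)
  }

  best <- NULL
  for (r in seq_len(restarts)) {
    set.seed(seed + r)
    xs <- sort(x)
    blocks <- if (K == 1) {
      list(xs)
    } else if (r == 1) {
      split(xs, cut(seq_len(n), K, labels = FALSE))
    } else {
      # random partition: cluster around K random data points
      centers <- sort(sample(x, K))
      split(x, apply(abs(outer(x, centers, "-")), 1, which.min))
    }
    if (length(blocks) < K) next
    init <- vapply(blocks, .beta_mom, numeric(2))
    mu <- unname(pmin(pmax(init["mu", ] + rnorm(K, 0, if (r == 1) 0 else 0.02),
                           1e-3), 1 - 1e-3))
    fit <- run_em(rep(1 / K, K), mu, unname(init["phi", ]))
    if (!is.null(fit) && (is.null(best) || fit$logL > best$logL)) best <- fit
  }
  if (is.null(best))
    stop("beta mixture EM failed for K = ", K,
         " (all restarts degenerate)")
  p <- 3 * K - 1
  structure(list(K = K, n = n, weights = best$w, mu = best$mu,
                 phi = best$phi, logL = best$logL,
                 BIC = -2 * best$logL + p * log(n),
                 responsibilities = best$resp, logL_trace = best$trace,
                 iterations = best$iters, values = x),
            class = "mixture_fit")
}

#' @export
print.mixture_fit <- function(x, ...) {
  cat(sprintf("<mixture_fit> K=%d, n=%d, logL=%.2f, BIC=%.2f\n",
              x$K, x$n, x$logL, x$BIC))
  tab <- data.frame(weight = round(x$weights, 4), mean = round(x$mu, 4),
                    precision = round(x$phi, 1))
  print(tab)
  invisible(x)
}

#' Select the number of mixture components by BIC
#'
#' Fits beta mixtures with `K = 1..K_max` and returns the K minimizing the
#' Bayesian Information Criterion, together with all fits. `K_max` is
#' capped at `floor(n / 10)` so every fit satisfies the sample-size
#' precondition.
#'
#' @inheritParams fit_beta_mixture
#' @param K_max largest component count to try (default 6).
#' @return list `K_best` (integer), `fits` (list of `mixture_fit`), `BIC`
#'   (numeric vector).
#' @export
select_k_bic <- function(values, K_max = 6, seed = 1, restarts = 10,
                         max_iter = 500, tol = 1e-8) {
  n <- length(values)
  K_hi <- min(K_max, max(1L, floor(n / 10)))
  if (K_hi < K_max)
    warning("K_max reduced to ", K_hi, " for n = ", n)
  fits <- vector("list", K_hi)
  for (K in seq_len(K_hi))
    fits[[K]] <- fit_beta_mixture(values, K, seed = seed, restarts = restarts,
                                  max_iter = max_iter, tol = tol)
  bic <- vapply(fits, function(f) f$BIC, numeric(1))
  list(K_best = which.min(bic), fits = fits, BIC = bic)
}

#' Classify observations into straightness groups
#'
#' Assigns each observation to its maximum-responsibility component.
#' Components are ordered by decreasing mean; with `K = 4` they are named
#' `straight`, `semi-straight`, `semi-curvy`, `curvy`. The summary reports
#' each group's mixing weight, empirical proportion, size, member mean and
#' minimum observed value.
#'
#' @param fit a converged `mixture_fit`.
#' @return list `labels` (integer, 1 = straightest), `group_names`,
#'   `summary` (data.frame).
#' @export
classify_groups <- function(fit) {
  ord <- order(fit$mu, decreasing = TRUE)
  rank_of <- match(seq_len(fit$K), ord)
  raw <- max.col(fit$responsibilities, ties.method = "first")
  labels <- rank_of[raw]
  nms <- if (fit$K == 4) c("straight", "semi-straight", "semi-curvy", "curvy")
  else paste0("group", seq_len(fit$K))
  summ <- do.call(rbind, lapply(seq_len(fit$K), function(g) {
    memb <- fit$values[labels == g]
    data.frame(group = nms[g], weight = fit$weights[ord[g]],
               proportion = length(memb) / fit$n, n = length(memb),
               mean_component = fit$mu[ord[g]],
               mean_members = if (length(memb)) mean(memb) else NA_real_,
               min_members = if (length(memb)) min(memb) else NA_real_)
  }))
  rownames(summ) <- NULL
  list(labels = labels, group_names = nms, summary = summ)
}
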