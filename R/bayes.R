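# Prior-stabilized Bayesian mixed model, fit by Gibbs sampling.
#
# The model is the same Gaussian random-intercept model as fit_lmm, with
# independent N(0, t^2) priors on every non-intercept fixed effect (flat on
# the intercept) and weak inverse-gamma priors on both variance components.
# The normal prior is what keeps estimates finite when a design cell is
# degenerate (e.g. an identically zero response for every participant in a
# treatment arm, where the unpenalized likelihood sends estimates and
# standard errors to infinity).

#' Prior specification for the stabilized model
#'
#' @param t prior scale (> 0) of the zero-mean normal prior on non-intercept
#'   fixed effects. By default `t` is a standard deviation; set
#'   `t_is_sd = FALSE` to interpret it as a variance.
#' @param t_is_sd logical; see above.
#' @return a `prior_spec` object.
#' @export
prior_spec <- function(t, t_is_sd = TRUE) {
  if (!is.finite(t) || t <= 0) stop("prior scale t must be > 0")
  structure(list(t = t, t_is_sd = t_is_sd), class = "prior_spec")
}

#' Fit the prior-stabilized Bayesian mixed model
#'
#' Gibbs sampler for `response ~ day * treatment + isSiesta + (1 |
#' participant)` with conjugate updates: joint multivariate-normal draw for
#' the fixed effects under the N(0, t^2) prior (flat on the intercept),
#' normal draws for the participant intercepts, and inverse-gamma draws for
#' the residual and participant variances (weak IG(0.001, 0.001)
#' hyperpriors). The first half of each chain is burn-in. Degenerate cells
#' (all-zero response in a treatment arm) are allowed. Split R-hat and a
#' crude effective sample size are attached; any R-hat above 1.1 flags the
#' fit unreliable.
#'
#' @param table endpoint table as for [fit_lmm()].
#' @param design a [model_design()].
#' @param prior a [prior_spec()].
#' @param chains,iters sampler settings (defaults 4 chains x 2000
#'   iterations).
#' @param seed integer seed; chain seeds derive from it.
#' @return a `bayes_fit`: `draws` (matrix, post-burn-in draws x parameters),
#'   `loglik` (draws x observations matrix of per-observation Gaussian
#'   log-likelihoods), `estimates` (posterior mean/sd per fixed effect),
#'   `diagnostics` (rhat, ess per parameter), `reliable`, plus the inputs
#'   needed to refit (`data`, `prior`, `chains`, `iters`, `seed`).
#' @export
fit_bayes_shrunk <- function(table, design, prior, chains = 4, iters = 2000,
                             seed = 1L) {
  stopifnot(inherits(design, "model_design"), inherits(prior, "prior_spec"))
  df <- prepare_model_frame(table, design)
  X <- stats::model.matrix(design$fixed, df)
  subj <- as.integer(factor(df$participant))
  gibbs_lmm(df$.response, X, subj, prior, chains, iters, seed, keep = TRUE)
}

# Core sampler, also used (with keep = FALSE internals) by the exact-refit
# LOO fallback. `drop_obs` removes observations before fitting but still
# returns their per-draw predictive log-density.
gibbs_lmm <- function(y, X, subj, prior, chains, iters, seed,
                      keep = TRUE, drop_obs = integer(0)) {
  t_sd <- if (prior$t_is_sd) prior$t else sqrt(prior$t)
  p <- ncol(X); n_all <- length(y)
  fit_idx <- setdiff(seq_len(n_all), drop_obs)
  yf <- y[fit_idx]; Xf <- X[fit_idx, , drop = FALSE]; sf <- subj[fit_idx]
  q <- max(subj)
  n <- length(yf)
  is_int <- colnames(X) == "(Intercept)"
  prior_prec <- ifelse(is_int, 0, 1 / t_sd^2)
  a0 <- b0 <- 0.001

  # joint (beta, u) block update: W = [X | Z] with Z the participant
  # indicator matrix; updating the blocks separately mixes poorly because
  # intercept-level fixed effects and the random-intercept mean trade off
  Zf <- matrix(0, n, q); Zf[cbind(seq_len(n), sf)] <- 1
  Wf <- cbind(Xf, Zf)
  WtW <- crossprod(Wf)
  Wty <- crossprod(Wf, yf)
  W_all <- cbind(X, {
    Z <- matrix(0, n_all, q); Z[cbind(seq_len(n_all), subj)] <- 1; Z
  })
  n_keep <- floor(iters / 2)
  draws <- matrix(NA_real_, chains * n_keep, p + 2,
                  dimnames = list(NULL, c(colnames(X), "sigma_participant", "sigma_resid")))
  loglik <- matrix(NA_real_, chains * n_keep, n_all)
  chain_id <- rep(seq_len(chains), each = n_keep)

  for (ch in seq_len(chains)) {
    with_seed(derive_seed(seed, ch, 7L, 7L), {
      s2e <- stats::var(yf) %||% 1
      if (!is.finite(s2e) || s2e <= 0) s2e <- 1
      s2u <- s2e / 2
      theta <- rep(0, p + q)
      row0 <- (ch - 1) * n_keep
      for (it in seq_len(iters)) {
        A <- WtW / s2e + diag(c(prior_prec, rep(1 / s2u, q)))
        R <- chol(A)
        m <- backsolve(R, forwardsolve(t(R), Wty / s2e))
        theta <- drop(m + backsolve(R, stats::rnorm(p + q)))
        beta <- theta[seq_len(p)]; u <- theta[p + seq_len(q)]
        rss <- sum((yf - drop(Wf %*% theta))^2)
        s2e <- 1 / stats::rgamma(1, a0 + n / 2, b0 + rss / 2)
        s2u <- 1 / stats::rgamma(1, a0 + q / 2, b0 + sum(u^2) / 2)
        if (it > iters - n_keep) {
          r <- row0 + it - (iters - n_keep)
          draws[r, ] <- c(beta, sqrt(s2u), sqrt(s2e))
          loglik[r, ] <- stats::dnorm(y, drop(W_all %*% theta), sqrt(s2e), log = TRUE)
        }
      }
    })
  }
  diag_tab <- mcmc_diagnostics(draws, chain_id)
  est <- data.frame(term = colnames(X),
                    mean = colMeans(draws[, seq_len(p), drop = FALSE]),
                    sd = apply(draws[, seq_len(p), drop = FALSE], 2, stats::sd))
  rownames(est) <- NULL
  structure(list(draws = draws, loglik = loglik, estimates = est,
                 diagnostics = diag_tab,
                 reliable = all(diag_tab$rhat < 1.1, na.rm = TRUE),
                 chain_id = chain_id,
                 y = y, X = X, subj = subj, prior = prior,
                 chains = chains, iters = iters, seed = seed),
            class = "bayes_fit")
}

# Split R-hat and autocorrelation-based effective sample size.
mcmc_diagnostics <- function(draws, chain_id) {
  split_chains <- function(v) {
    out <- list()
    for (ch in unique(chain_id)) {
      x <- v[chain_id == ch]
      h <- floor(length(x) / 2)
      out <- c(out, list(x[1:h], x[(h + 1):(2 * h)]))
    }
    out
  }
  rhat1 <- function(v) {
    cs <- split_chains(v)
    m <- length(cs); n <- length(cs[[1]])
    means <- vapply(cs, mean, numeric(1))
    vars <- vapply(cs, stats::var, numeric(1))
    W <- mean(vars); B <- n * stats::var(means)
    if (W <= 0) return(NA_real_)
    sqrt(((n - 1) / n * W + B / n) / W)
  }
  ess1 <- function(v) {
    n <- length(v)
    ac <- stats::acf(v, lag.max = min(100, n - 2), plot = FALSE)$acf[-1]
    neg <- which(ac < 0)
    if (length(neg)) ac <- ac[seq_len(neg[1] - 1)]
    max(1, n / (1 + 2 * sum(ac)))
  }
  data.frame(parameter = colnames(draws),
             rhat = apply(draws, 2, rhat1),
             ess = apply(draws, 2, ess1))
}

#' WAIC and PSIS-LOO for a Bayesian fit
#'
#' WAIC is `-2 * (lppd - p_waic)` with the effective-parameter penalty
#' `p_waic` equal to the sum of per-observation posterior log-likelihood
#' variances. LOO is computed by Pareto-smoothed importance sampling: per
#' observation the importance ratios are tail-smoothed with a generalized
#' Pareto fit and the shape diagnostic k is reported; observations with
#' k > 0.7 are recomputed exactly by refitting the sampler without them
#' (disable with `refit = FALSE`).
#'
#' @param post a `bayes_fit` from [fit_bayes_shrunk()].
#' @param refit logical: exact refit fallback for high-k points.
#' @return a `model_score`: `waic`, `p_waic`, `elpd_loo`, `looic`,
#'   `pointwise` (per-observation contributions and k values),
#'   `n_refit`.
#' @export
score_model <- function(post, refit = TRUE) {
  stopifnot(inherits(post, "bayes_fit"))
  ll <- post$loglik
  S <- nrow(ll)
  if (S < 100) stop("need at least 100 posterior draws, got ", S)
  lppd_i <- apply(ll, 2, log_mean_exp)
  p_i <- apply(ll, 2, stats::var)
  waic <- -2 * (sum(lppd_i) - sum(p_i))

  n <- ncol(ll)
  elpd_i <- numeric(n); k_i <- numeric(n)
  for (i in seq_len(n)) {
    ps <- psis_weights(-ll[, i])
    k_i[i] <- ps$k
    lw <- ps$log_weights
    elpd_i[i] <- log_sum_exp(lw + ll[, i]) - log_sum_exp(lw)
  }
  n_refit <- 0L
  if (refit) {
    bad <- which(is.finite(k_i) & k_i > 0.7)
    for (i in bad) {
      re <- gibbs_lmm(post$y, post$X, post$subj, post$prior,
                      chains = max(2, post$chains %/% 2),
                      iters = post$iters, seed = post$seed + 1000L + i,
                      drop_obs = i)
      elpd_i[i] <- log_mean_exp(re$loglik[, i])
      n_refit <- n_refit + 1L
    }
  }
  structure(list(waic = waic, p_waic = sum(p_i),
                 elpd_loo = sum(elpd_i), looic = -2 * sum(elpd_i),
                 pointwise = data.frame(elpd_loo = elpd_i, pareto_k = k_i,
                                        lppd = lppd_i, p_waic = p_i),
                 n_refit = n_refit), class = "model_score")
}

log_sum_exp <- function(x) { m <- max(x); m + log(sum(exp(x - m))) }
log_mean_exp <- function(x) log_sum_exp(x) - log(length(x))

# Pareto-smoothed importance sampling for one observation.
# `log_ratios` are log importance ratios (here: -loglik draws).
psis_weights <- function(log_ratios) {
  S <- length(log_ratios)
  lw <- log_ratios - max(log_ratios)
  M <- ceiling(min(0.2 * S, 3 * sqrt(S)))
  ord <- order(lw)
  tail_ids <- ord[(S - M + 1):S]
  cutoff <- lw[ord[S - M]]
  exp_tail <- exp(lw[tail_ids]) - exp(cutoff)
  if (all(exp_tail <= 0) || length(unique(exp_tail)) < 5)
    return(list(log_weights = lw, k = -Inf))
  gp <- gpd_fit(exp_tail[exp_tail > 0])
  if (!is.finite(gp$k)) return(list(log_weights = lw, k = gp$k))
  # replace tail weights by expected order statistics of the fitted GPD
  M2 <- length(tail_ids)
  probs <- (seq_len(M2) - 0.5) / M2
  qs <- gpd_quantile(probs, gp$k, gp$sigma)
  smoothed <- log(exp(cutoff) + qs)
  lw[tail_ids[order(lw[tail_ids])]] <- pmin(sort(smoothed), 0)
  list(log_weights = lw, k = gp$k)
}

# Zhang & Stephens (2009) profile-likelihood fit of the generalized Pareto
# distribution to exceedances x > 0; returns shape k and scale sigma.
gpd_fit <- function(x) {
  x <- sort(x)
  n <- length(x)
  if (n < 5) return(list(k = NA_real_, sigma = NA_real_))
  prior_b <- x[max(1, floor(n / 4 + 0.5))]
  m <- 30 + floor(sqrt(n))
  theta <- 1 / x[n] + (1 - sqrt(m / (seq_len(m) - 0.5))) / (3 * prior_b)
  prof <- vapply(theta, function(th) {
    k <- -mean(log1p(-th * x))
    n * (log(th / k) + k - 1)
  }, numeric(1))
  w <- exp(prof - max(prof)); w <- w / sum(w)
  th_hat <- sum(theta * w)
  k <- -mean(log1p(-th_hat * x))
  list(k = k, sigma = k / th_hat)
}

gpd_quantile <- function(p, k, sigma) {
  if (abs(k) < 1e-12) -sigma * log1p(-p) else sigma * ((1 - p)^(-k) - 1) / k
}

#' Sweep the prior scale t and locate the LOO inflection
#'
#' Fits the stabilized model over a grid of prior scales, tabulates WAIC and
#' LOO, and selects `t_star` at the inflection of the LOO curve: the
#' interior grid point with the largest discrete second difference of
#' `elpd_loo` against log(t). When the maximum curvature is within the
#' Monte-Carlo error of the elpd differences, the selection is flagged
#' `weak_inflection`.
#'
#' @param table endpoint table as for [fit_lmm()].
#' @param design a [model_design()].
#' @param t_grid strictly increasing grid of >= 5 positive prior scales.
#' @param seed integer seed (per-t seeds derive from it).
#' @param chains,iters sampler settings per fit.
#' @param refit passed to [score_model()].
#' @return a `sweep_result`: `table` (t, waic, elpd_loo, looic), `t_star`,
#'   `curvature`, `weak_inflection`, `fits` (list of `bayes_fit`).
#' @export
sweep_hyperparameter <- function(table, design, t_grid, seed = 1L,
                                 chains = 2, iters = 1000, refit = FALSE) {
  t_grid <- as.numeric(t_grid)
  if (length(t_grid) < 5) stop("t grid must have at least 5 values")
  if (any(t_grid <= 0)) stop("t grid values must be positive")
  if (any(diff(t_grid) <= 0)) stop("t grid must be strictly increasing")
  fits <- list(); scores <- list()
  for (j in seq_along(t_grid)) {
    fits[[j]] <- fit_bayes_shrunk(table, design, prior_spec(t_grid[j]),
                                  chains = chains, iters = iters,
                                  seed = derive_seed(seed, j, 3L, 3L))
    scores[[j]] <- score_model(fits[[j]], refit = refit)
  }
  elpd <- vapply(scores, `[[`, numeric(1), "elpd_loo")
  waic <- vapply(scores, `[[`, numeric(1), "waic")
  lt <- log(t_grid)
  m <- length(t_grid)
  curv <- rep(NA_real_, m)
  for (j in 2:(m - 1)) {
    h1 <- lt[j] - lt[j - 1]; h2 <- lt[j + 1] - lt[j]
    curv[j] <- 2 * (elpd[j - 1] / (h1 * (h1 + h2)) - elpd[j] / (h1 * h2) +
                      elpd[j + 1] / (h2 * (h1 + h2)))
  }
  j_star <- which.max(abs(curv))
  # MC error scale of elpd differences: per-point elpd variation between fits
  pw <- vapply(scores, function(s) s$pointwise$elpd_loo, scores[[1]]$pointwise$elpd_loo)
  diff_se <- stats::median(vapply(2:m, function(j)
    stats::sd(pw[, j] - pw[, j - 1]) * sqrt(nrow(pw)), numeric(1)))
  weak <- abs(curv[j_star]) < 2 * diff_se / max(diff(lt))
  structure(list(
    table = data.frame(t = t_grid, waic = waic, elpd_loo = elpd,
                       looic = -2 * elpd, curvature = curv),
    t_star = t_grid[j_star], curvature = curv[j_star],
    weak_inflection = weak, fits = fits), class = "sweep_result")
}
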