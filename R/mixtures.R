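## Weighted EM mixture models for Ks-age distributions.
##
## Node weights from the Ks engine enter as fractional observation counts, so
## the effective sample size n_eff = sum(weights) is used both in the weighted
## log-likelihood and in the BIC penalty, keeping the two consistent.

new_mixture_fit <- function(kind, k, pi, pars, loglik, n_eff, n_params, converged,
                            monotone = TRUE) {
  structure(list(kind = kind, k = k, pi = pi, pars = pars, loglik = loglik,
                 n_eff = n_eff, bic = -2 * loglik + n_params * log(n_eff),
                 n_params = n_params, converged = converged, monotone = monotone),
            class = "mixture_fit")
}

#' @export
print.mixture_fit <- function(x, ...) {
  cat(sprintf("mixture_fit [%s]: k = %d, loglik = %.3f, BIC = %.3f%s\n",
              x$kind, x$k, x$loglik, x$bic,
              if (x$converged) "" else " (not converged)"))
  invisible(x)
}

#' Back-transformed component peak locations (Ks scale)
#'
#' The peak of a log-normal component is reported as its median `exp(m)`
#' (median-invariance under the log transform), not its mean.
#'
#' @param fit a `mixture_fit`.
#' @return numeric vector of peak Ks values (lognormal components only).
#' @export
mixture_peaks <- function(fit) {
  if (fit$kind == "gmm_log") return(exp(fit$pars$mean))
  exp(fit$pars$meanlog)
}

weighted_em_gmm <- function(x, w, k, init_means, init_sds, init_pi,
                            tol = 1e-8, maxit = 500) {
  n_eff <- sum(w)
  fit <- wem_gmm_cpp(x, w, init_means, pmax(init_sds, 1e-3),
                     init_pi / sum(init_pi), tol, maxit)
  if (isTRUE(fit$collapsed)) {
    keep <- fit$wk >= 1e-8 * n_eff
    warn_wgdc("EM component collapsed and was pruned (k %d -> %d)", k, sum(keep))
    return(weighted_em_gmm(x, w, sum(keep), fit$m[keep], fit$s[keep],
                           fit$pi[keep], tol, maxit))
  }
  list(k = k, pi = fit$pi, mean = fit$m, sd = fit$s, loglik = fit$loglik,
       converged = fit$converged, monotone = fit$monotone)
}

#' Fit log-scale Gaussian mixtures to a Ks distribution, selecting k by BIC
#'
#' Ks values are transformed to the log scale and fitted with weighted-EM
#' Gaussian mixtures for k = 1..`k_max` components; the fit minimizing
#' `BIC = -2 loglik + params ln(n_eff)` is selected. Each k uses multiple
#' restarts (five k-means-initialized starts plus one quantile-spread start)
#' with restart seeds derived from `seed`; the EM log-likelihood is checked
#' for monotonicity at every iteration.
#'
#' @param dist a [ks_distribution()] (or data.frame with `ks` and `weight`).
#' @param k_max maximum number of components (default 8).
#' @param seed seed for the restart initializations.
#' @param min_points minimum number of retained pairs (default 50).
#' @return list with `fits` (all k) and `best` (min-BIC `mixture_fit`).
#' @export
fit_gmm_log <- function(dist, k_max = 8, seed = 1, min_points = 50) {
  w <- dist$weight %||% rep(1, nrow(dist))
  keep <- is.finite(dist$ks) & dist$ks > 0
  x <- log(dist$ks[keep]); w <- w[keep]
  assert_that(length(x) >= min_points,
              "too few points for mixture modelling (%d < %d)", length(x), min_points)
  fits <- vector("list", k_max)
  for (k in seq_len(k_max)) {
    best_run <- NULL
    for (r in seq_len(6)) {
      set.seed(derive_seeds(seed, k * 10 + r)[1])
      if (r <= 5 && k > 1) {
        km <- tryCatch(stats::kmeans(x, centers = k, nstart = 1), error = function(e) NULL)
        if (is.null(km)) next
        init_m <- as.numeric(km$centers)
        init_s <- rep(stats::sd(x) / k, k)
        init_p <- pmax(tabulate(km$cluster, k) / length(x), 1e-3)
      } else {
        qs <- stats::quantile(x, probs = (seq_len(k) - 0.5) / k, names = FALSE)
        init_m <- qs; init_s <- rep(stats::sd(x) / max(1, k - 1), k)
        if (k == 1) init_s <- stats::sd(x)
        init_p <- rep(1 / k, k)
      }
      run <- weighted_em_gmm(x, w, k, init_m, init_s, init_p)
      if (is.null(best_run) || run$loglik > best_run$loglik) best_run <- run
    }
    fits[[k]] <- new_mixture_fit("gmm_log", best_run$k,
                                 best_run$pi,
                                 list(mean = best_run$mean, sd = best_run$sd),
                                 best_run$loglik, sum(w),
                                 n_params = 3 * best_run$k - 1,
                                 converged = best_run$converged,
                                 monotone = best_run$monotone)
  }
  bics <- vapply(fits, `[[`, numeric(1), "bic")
  list(fits = fits, best = fits[[which.min(bics)]])
}

weighted_em_expln <- function(x, w, j, init, tol = 1e-8, maxit = 500) {
  fit <- wem_expln_cpp(x, log(x), w, init$rate, init$meanlog,
                       pmax(init$sdlog, 1e-3), init$pi / sum(init$pi),
                       tol, maxit)
  list(pi = fit$pi, rate = fit$rate, meanlog = fit$meanlog, sdlog = fit$sdlog,
       loglik = fit$loglik, converged = fit$converged, monotone = fit$monotone)
}

#' Fit the exponential-lognormal mixture to a Ks distribution
#'
#' One exponential component anchored at Ks = 0 models the L-shaped
#' small-scale-duplication background; one to `j_max` lognormal components
#' model candidate WGD peaks. The number of lognormal components is selected
#' by BIC.
#'
#' @inheritParams fit_gmm_log
#' @param j_max maximum number of lognormal components (default 5).
#' @return list with `fits` and `best`; the best fit's `pars` holds `rate`
#'   (exponential) and `meanlog`/`sdlog` vectors, `pi[1]` being the
#'   exponential weight.
#' @export
fit_exp_lognormal <- function(dist, j_max = 5, seed = 1, min_points = 50) {
  w <- dist$weight %||% rep(1, nrow(dist))
  keep <- is.finite(dist$ks) & dist$ks > 0
  x <- dist$ks[keep]; w <- w[keep]
  assert_that(length(x) >= min_points,
              "too few points for mixture modelling (%d < %d)", length(x), min_points)
  fits <- vector("list", j_max)
  lx <- log(x)
  for (j in seq_len(j_max)) {
    best_run <- NULL
    for (r in seq_len(6)) {
      set.seed(derive_seeds(seed, 100 + j * 10 + r)[1])
      if (r <= 5 && j > 1) {
        km <- tryCatch(stats::kmeans(lx, centers = j, nstart = 1), error = function(e) NULL)
        if (is.null(km)) next
        ml <- as.numeric(km$centers); sl <- rep(stats::sd(lx) / j, j)
      } else {
        ml <- stats::quantile(lx, probs = (seq_len(j) - 0.5) / j, names = FALSE)
        sl <- rep(stats::sd(lx) / max(1, j), j)
      }
      init <- list(rate = 1 / max(mean(x) / 2, 1e-3), meanlog = ml, sdlog = sl,
                   pi = rep(1 / (j + 1), j + 1))
      run <- weighted_em_expln(x, w, j, init)
      if (is.null(best_run) || run$loglik > best_run$loglik) best_run <- run
    }
    fits[[j]] <- new_mixture_fit("exp_lognormal", j, best_run$pi,
                                 list(rate = best_run$rate,
                                      meanlog = best_run$meanlog,
                                      sdlog = best_run$sdlog),
                                 best_run$loglik, sum(w),
                                 n_params = 3 * j + 1,
                                 converged = best_run$converged,
                                 monotone = best_run$monotone)
  }
  bics <- vapply(fits, `[[`, numeric(1), "bic")
  best <- fits[[which.min(bics)]]
  if (best$pi[1] < 1e-3) {
    warn_wgdc("exponential component weight ~ 0: no small-scale-duplication tail in the data")
  }
  list(fits = fits, best = best)
}
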