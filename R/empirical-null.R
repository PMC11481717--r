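#' Empirical-null estimation of bias and inflation
#'
#' Test statistics from epigenome-wide scans are frequently biased and/or
#' inflated by unmeasured confounding and correlation between probes.
#' Following the empirical-null idea, the bulk of the z statistics is
#' modelled as a three-component normal mixture — a dominant central null
#' component flanked by a negative- and a positive-mean component for truly
#' associated probes — fitted by a deterministic EM. The central
#' component's mean and standard deviation are the bias and inflation
#' estimates; corrected statistics are \code{(z - mu) / sigma}.
#'
#' The EM is initialized from the median and MAD of \code{z} with tail
#' components two null-SDs out, iterated to a relative log-likelihood
#' tolerance of 1e-6 (at most 1000 iterations), with the tail means
#' constrained to stay on their side of the null mean. On non-convergence a
#' warning is raised and median/MAD estimates are returned.
#'
#' @param z numeric vector of per-probe z statistics (>= 1000 in normal
#'   use; shorter vectors are accepted with a warning).
#' @param tol,maxIter EM stopping rule.
#' @return list with \code{mu}, \code{sigma}, \code{nullProportion},
#'   \code{converged}, \code{iterations}.
#' @examples
#' z <- qnorm(ppoints(5000))            # exact standard normal
#' fit <- estimateEmpiricalNull(z)
#' c(fit$mu, fit$sigma)
#' @export
estimateEmpiricalNull <- function(z, tol = 1e-6, maxIter = 1000L) {
  z <- z[is.finite(z)]
  if (length(z) < 10) stop("too few finite statistics")
  if (length(z) < 1000)
    warning("fewer than 1000 statistics; empirical-null estimates are noisy")
  mu0 <- stats::median(z)
  s0 <- max(stats::mad(z), 1e-3)
  mu <- c(mu0, mu0 - 2 * s0, mu0 + 2 * s0)
  sd <- c(s0, 2 * s0, 2 * s0)
  pi <- c(0.90, 0.05, 0.05)
  n <- length(z)
  ll <- -Inf
  converged <- FALSE
  iter <- 0L
  for (iter in seq_len(maxIter)) {
    dens <- vapply(1:3, function(k)
      pi[k] * stats::dnorm(z, mu[k], sd[k]), numeric(n))
    tot <- rowSums(dens)
    tot[tot < .Machine$double.xmin] <- .Machine$double.xmin
    llNew <- sum(log(tot))
    resp <- dens / tot
    nk <- colSums(resp)
    pi <- nk / n
    for (k in 1:3) {
      if (nk[k] < 1e-8) next
      mu[k] <- sum(resp[, k] * z) / nk[k]
      sd[k] <- sqrt(sum(resp[, k] * (z - mu[k])^2) / nk[k])
    }
    # keep the flanking components on their side of the null mean
    mu[2] <- min(mu[2], mu[1])
    mu[3] <- max(mu[3], mu[1])
    sd <- pmax(sd, 1e-3)
    if (is.finite(ll) && abs(llNew - ll) < tol * (abs(ll) + tol)) {
      converged <- TRUE
      ll <- llNew
      break
    }
    ll <- llNew
  }
  if (!converged) {
    warning("empirical-null EM did not converge; falling back to median/MAD")
    return(list(mu = stats::median(z), sigma = max(stats::mad(z), 1e-3),
                nullProportion = 1, converged = FALSE, iterations = iter))
  }
  list(mu = mu[1], sigma = sd[1], nullProportion = pi[1],
       converged = TRUE, iterations = iter)
}
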