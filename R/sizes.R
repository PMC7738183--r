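# Diameter summaries and 1D Gaussian mixture analysis.

#' Mean and standard deviation of a diameter sample
#'
#' @param diameters numeric vector, nm (n >= 2)
#' @return List with mean, sd, n.
#' @export
summarizeDiameters <- function(diameters) {
  if (length(diameters) < 2) stop("need at least 2 diameters")
  list(mean = mean(diameters), sd = sd(diameters), n = length(diameters))
}

# One EM run from a given mean initialisation. Returns NULL on a degenerate
# (collapsing-variance) path.
.emRun <- function(x, mu, maxIter, tol) {
  n <- length(x); k <- length(mu)
  s <- rep(sd(x) / 1.5, k); w <- rep(1 / k, k)
  ll0 <- -Inf; trace <- numeric(0)
  for (it in seq_len(maxIter)) {
    d <- vapply(seq_len(k), function(j) w[j] * dnorm(x, mu[j], s[j]),
                numeric(n))
    tot <- pmax(rowSums(d), 1e-300)
    ll <- sum(log(tot))
    trace <- c(trace, ll)
    g <- d / tot
    nk <- colSums(g)
    if (any(nk < 1e-8)) return(NULL)
    w <- nk / n
    mu <- colSums(g * x) / nk
    s <- sqrt(colSums(g * (x - rep(mu, each = n))^2) / nk)
    if (any(!is.finite(s)) || any(s < 1e-8 * sd(x))) return(NULL)
    if (abs(ll - ll0) < tol) break
    ll0 <- ll
  }
  list(ll = ll, mu = mu, s = s, w = w, trace = trace,
       posterior = g, converged = it < maxIter)
}

#' Fit a k-component Gaussian mixture to granule diameters
#'
#' Expectation-maximisation with seeded restarts (quantile split, k-means,
#' and random draws). Components are reported in ascending order of mean.
#' The fit is flagged non-separable when the component means are closer
#' than one pooled SD or either weight falls below 0.1 -- in that case the
#' component means are not reliably identified (see the methods vignette).
#'
#' @param diameters numeric vector, nm
#' @param k number of components (default 2; n >= 30 required for k >= 2)
#' @param nRestarts EM restarts
#' @param maxIter,tol EM iteration controls
#' @param seed integer seed for the random restarts
#' @return A \linkS4class{DiameterMixtureFit}. For k = 1 the estimates
#'   equal \code{\link{summarizeDiameters}} (sample SD).
#' @export
fitDiameterMixture <- function(diameters, k = 2, nRestarts = 10,
                               maxIter = 1000, tol = 1e-8, seed = 1L) {
  x <- as.numeric(diameters)
  if (k >= 2 && length(x) < 30) stop("need n >= 30 for k >= 2")
  if (k == 1) {
    sm <- summarizeDiameters(x)
    ll <- sum(dnorm(x, sm$mean, sm$sd, log = TRUE))
    return(new("DiameterMixtureFit", k = 1L, means = sm$mean, sds = sm$sd,
               weights = 1, logLik = ll, logLikTrace = ll,
               posterior = matrix(1, length(x), 1), separable = TRUE,
               converged = TRUE))
  }
  withr::local_seed(seed)
  inits <- list(as.numeric(quantile(x, probs = seq_len(k) / (k + 1))))
  km <- tryCatch(suppressWarnings(kmeans(x, k, nstart = 5)),
                 error = function(e) NULL)
  if (!is.null(km)) inits <- c(inits, list(sort(as.numeric(km$centers))))
  while (length(inits) < nRestarts) inits <- c(inits, list(sort(sample(x, k))))
  best <- NULL
  for (init in inits) {
    run <- .emRun(x, init, maxIter, tol)
    if (!is.null(run) && (is.null(best) || run$ll > best$ll)) best <- run
  }
  if (is.null(best))
    stop("all EM restarts degenerated; the sample does not support ", k,
         " components")
  o <- order(best$mu)
  sep <- TRUE
  if (k == 2) {
    pooled <- sqrt(mean(best$s^2))
    sep <- (diff(best$mu[o]) >= pooled) && all(best$w >= 0.1)
  }
  new("DiameterMixtureFit", k = as.integer(k), means = best$mu[o],
      sds = best$s[o], weights = best$w[o], logLik = best$ll,
      logLikTrace = best$trace, posterior = best$posterior[, o, drop = FALSE],
      separable = sep, converged = best$converged)
}
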