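# Calcium dose-response assembly, Hill mixture decomposition and model
# selection.

#' Wilson score confidence interval for a binomial proportion
#'
#' @param k successes
#' @param n trials
#' @param conf confidence level
#' @return Matrix with columns low, high.
#' @export
wilsonCI <- function(k, n, conf = 0.95) {
  z <- qnorm(1 - (1 - conf) / 2)
  p <- k / n
  den <- 1 + z^2 / n
  ctr <- (p + z^2 / (2 * n)) / den
  hw <- z * sqrt(p * (1 - p) / n + z^2 / (4 * n^2)) / den
  cbind(low = pmax(ctr - hw, 0), high = pmin(ctr + hw, 1))
}

#' Assemble a dose-response curve from fusion outcomes
#'
#' Accepts either the per-level outcome table (calcium, nDocked, nFused)
#' or the per-granule truth/event table (calcium, fused, onsetS), in which
#' case only fusions with onset within \code{windowS} count.
#'
#' @param x outcome or per-granule data.frame
#' @param windowS scoring window after calcium arrival, s
#' @return A \linkS4class{DoseResponseCurve} with Wilson 95\% intervals.
#' @export
assembleDoseResponse <- function(x, windowS = Inf) {
  if (all(c("nDocked", "nFused") %in% names(x))) {
    tab <- x
  } else if (all(c("calcium", "fused") %in% names(x))) {
    tab <- do.call(rbind, lapply(split(x, x$calcium), function(d)
      data.frame(calcium = d$calcium[1], nDocked = nrow(d),
                 nFused = sum(d$fused & (is.na(d$onsetS) |
                                           d$onsetS <= windowS)))))
  } else stop("x must have nDocked/nFused or calcium/fused columns")
  if (any(tab$nDocked <= 0)) stop("zero docked granules at a calcium level")
  tab <- tab[order(tab$calcium), ]
  ci <- wilsonCI(tab$nFused, tab$nDocked)
  new("DoseResponseCurve", calcium = tab$calcium, nDocked = tab$nDocked,
      nFused = tab$nFused, fraction = tab$nFused / tab$nDocked,
      ciLow = ci[, "low"], ciHigh = ci[, "high"])
}

.hillMix <- function(C, fMax, w, K, h) {
  out <- 0
  for (j in seq_along(K))
    out <- out + w[j] * C^h[j] / (C^h[j] + K[j]^h[j])
  fMax * out
}

.binomLogLik <- function(kS, n, p) {
  sum(dbinom(kS, n, pmin(pmax(p, 1e-12), 1 - 1e-12), log = TRUE))
}

# AICc on the binomial likelihood; the effective number of observations is
# the total number of Bernoulli trials (granules), not the number of
# grouped calcium levels.
.doseAicc <- function(logLik, nPar, nTrials) {
  -2 * logLik + 2 * nPar + 2 * nPar * (nPar + 1) / max(nTrials - nPar - 1, 1)
}

#' Fit a Hill (mixture) model to a dose-response curve
#'
#' Weighted least squares of
#' F(C) = fMax sum_j w_j C^h_j / (C^h_j + K_j^h_j), sum_j w_j = 1, with
#' binomial variance weights and multi-start Levenberg-Marquardt. For two
#' components the Hill coefficient is shared by default (both
#' synaptotagmins are C2-domain calcium sensors); set
#' \code{hillShared = FALSE} to free it per component. Bounds:
#' h in [0.5, 6] ([0.5, 8] when shared), K in [0.5, 500] uM.
#'
#' @param curve a \linkS4class{DoseResponseCurve} (>= 5 levels spanning the
#'   candidate K)
#' @param nComponents 1 or 2
#' @param hillShared share h across components (2-component fits)
#' @param weighted use binomial variance weights (TRUE) or plain least
#'   squares
#' @return A \linkS4class{HillFit}.
#' @export
fitDoseResponse <- function(curve, nComponents = 1, hillShared = TRUE,
                            weighted = TRUE) {
  stopifnot(is(curve, "DoseResponseCurve"), nComponents %in% 1:2)
  C <- curve@calcium; p <- curve@fraction; n <- curve@nDocked
  if (length(C) < 5) stop("need at least 5 calcium levels")
  q <- pmin(pmax(p, 1 / (2 * n)), 1 - 1 / (2 * n))
  wts <- if (weighted) n / (q * (1 - q)) else rep(1, length(C))
  fM0 <- max(p)
  best <- NULL
  if (nComponents == 1) {
    for (K0 in c(5, 10, 15, 25, 40, 100)) for (h0 in c(1, 2, 3, 5)) {
      fit <- tryCatch(
        nlsLM(p ~ .hillMix(C, fMax, 1, K, h),
              start = list(fMax = fM0, K = K0, h = h0),
              lower = c(0.01, 0.5, 0.5), upper = c(1, 500, 6),
              weights = wts,
              control = nls.lm.control(maxiter = 400, ftol = 1e-14)),
        error = function(e) NULL)
      if (!is.null(fit) && (is.null(best) || deviance(fit) < deviance(best)))
        best <- fit
    }
    if (is.null(best)) stop("1-component fit failed from every start")
    co <- coef(best)
    fitted <- .hillMix(C, co["fMax"], 1, co["K"], co["h"])
    ll <- .binomLogLik(curve@nFused, n, fitted)
    se <- tryCatch(sqrt(diag(vcov(best))), error = function(e)
      rep(NA_real_, 3))
    return(new("HillFit", nComponents = 1L, fMax = unname(co["fMax"]),
      weights = 1, kHalf = unname(co["K"]), hill = unname(co["h"]),
      se = list(fMax = unname(se[1]), kHalf = unname(se[2]),
                hill = unname(se[3])),
      rss = deviance(best), logLik = ll,
      aicc = .doseAicc(ll, 3, sum(n)), fitted = fitted, calcium = C,
      converged = TRUE))
  }
  starts <- expand.grid(K1 = c(6, 10, 14), K2 = c(30, 45, 80),
                        w1 = c(0.35, 0.5, 0.65))
  for (i in seq_len(nrow(starts))) {
    st <- starts[i, ]
    fit <- tryCatch(
      if (hillShared) {
        nlsLM(p ~ .hillMix(C, fMax, c(w1, 1 - w1), c(K1, K2), c(h, h)),
              start = list(fMax = fM0, w1 = st$w1, K1 = st$K1, K2 = st$K2,
                           h = 4),
              lower = c(0.01, 0.02, 0.5, 0.5, 0.5),
              upper = c(1, 0.98, 500, 500, 8), weights = wts,
              control = nls.lm.control(maxiter = 400, ftol = 1e-14))
      } else {
        nlsLM(p ~ .hillMix(C, fMax, c(w1, 1 - w1), c(K1, K2), c(h1, h2)),
              start = list(fMax = fM0, w1 = st$w1, K1 = st$K1, K2 = st$K2,
                           h1 = 3, h2 = 3),
              lower = c(0.01, 0.02, 0.5, 0.5, 0.5, 0.5),
              upper = c(1, 0.98, 500, 500, 6, 6), weights = wts,
              control = nls.lm.control(maxiter = 400, ftol = 1e-14))
      }, error = function(e) NULL)
    if (!is.null(fit) && (is.null(best) || deviance(fit) < deviance(best)))
      best <- fit
  }
  if (is.null(best)) stop("2-component fit failed from every start")
  co <- coef(best)
  w <- c(co["w1"], 1 - co["w1"])
  K <- c(co["K1"], co["K2"])
  h <- if (hillShared) rep(co["h"], 2) else c(co["h1"], co["h2"])
  o <- order(K)
  w <- w[o]; K <- K[o]; h <- h[o]
  fitted <- .hillMix(C, co["fMax"], w, K, h)
  ll <- .binomLogLik(curve@nFused, n, fitted)
  nPar <- length(co)
  se <- tryCatch(sqrt(diag(vcov(best))), error = function(e)
    rep(NA_real_, nPar))
  new("HillFit", nComponents = 2L, fMax = unname(co["fMax"]),
      weights = unname(w), kHalf = unname(K), hill = unname(h),
      se = list(all = se), rss = deviance(best), logLik = ll,
      aicc = .doseAicc(ll, nPar, sum(n)), fitted = fitted, calcium = C,
      converged = TRUE)
}

#' Choose between mono- and biphasic dose-response fits
#'
#' The two-component fit is chosen only when all three of the following
#' hold: its AICc improves on the one-component AICc by at least
#' \code{deltaAicc}; its minor component weight is at least
#' \code{minWeight}; and the ratio of its two K values is at least
#' \code{minKRatio}. Otherwise the one-component fit is returned.
#'
#' @param fit1,fit2 one- and two-component \linkS4class{HillFit}s of the
#'   same curve
#' @param deltaAicc,minWeight,minKRatio selection thresholds
#' @return List with \code{chosen} (a \linkS4class{HillFit}),
#'   \code{nComponents}, and \code{evidence}.
#' @export
selectDoseModel <- function(fit1, fit2, deltaAicc = 2, minWeight = 0.15,
                            minKRatio = 2) {
  stopifnot(is(fit1, "HillFit"), is(fit2, "HillFit"))
  kRatio <- max(fit2@kHalf) / min(fit2@kHalf)
  minW <- min(fit2@weights)
  takeTwo <- (aicc(fit2) <= aicc(fit1) - deltaAicc) &&
    minW >= minWeight && kRatio >= minKRatio
  list(chosen = if (takeTwo) fit2 else fit1,
       nComponents = if (takeTwo) 2L else 1L,
       evidence = list(aicc1 = aicc(fit1), aicc2 = aicc(fit2),
                       deltaAicc = aicc(fit1) - aicc(fit2),
                       minWeight = minW, kRatio = kRatio))
}

#' Compare selected dose-response fits across scenarios
#'
#' Classifies each fitted component as high-affinity (K below
#' \code{kBoundary}) or low-affinity and reports which affinity classes
#' each scenario lost or retained relative to the reference.
#'
#' @param fits named list of \linkS4class{HillFit}s (the selected model per
#'   scenario)
#' @param reference name of the reference scenario (must be present)
#' @param kBoundary uM boundary between high- and low-affinity components
#' @return data.frame with one row per scenario: nComponents, K values,
#'   weights, affinity flags, and a shift description vs the reference.
#' @export
compareScenarios <- function(fits, reference = "untreated", kBoundary = 25) {
  if (!reference %in% names(fits)) stop("missing reference scenario '",
                                        reference, "'")
  classify <- function(fit) {
    list(high = any(fit@kHalf < kBoundary), low = any(fit@kHalf >= kBoundary))
  }
  ref <- classify(fits[[reference]])
  rows <- lapply(names(fits), function(nm) {
    fit <- fits[[nm]]
    cl <- classify(fit)
    shift <- if (nm == reference) "reference" else {
      lost <- c(if (ref$high && !cl$high) "high-affinity component lost",
                if (ref$low && !cl$low) "low-affinity component lost")
      if (length(lost)) paste(lost, collapse = "; ") else "no shift"
    }
    data.frame(scenario = nm, nComponents = fit@nComponents,
      kHalf = paste(sprintf("%.1f", fit@kHalf), collapse = "/"),
      weights = paste(sprintf("%.2f", fit@weights), collapse = "/"),
      highAffinity = cl$high, lowAffinity = cl$low, shift = shift)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
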