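# Shared oracles and fixture builders, independent of the implementation
# paths they check.

# match detected centres to ground-truth positions within tol px
matchDetections <- function(centers, truth, tol = 1) {
  if (nrow(centers) == 0)
    return(list(recall = 0, precision = NA_real_))
  d2 <- outer(centers$x, truth$x, "-")^2 + outer(centers$y, truth$y, "-")^2
  list(recall = mean(apply(d2, 2, min) <= tol^2),
       precision = mean(apply(d2, 1, min) <= tol^2))
}

# textbook Welch t-test (unequal variances, Welch-Satterthwaite df)
welchOracle <- function(a, b) {
  na <- length(a); nb <- length(b)
  va <- var(a); vb <- var(b)
  t <- (mean(a) - mean(b)) / sqrt(va / na + vb / nb)
  df <- (va / na + vb / nb)^2 /
    ((va / na)^2 / (na - 1) + (vb / nb)^2 / (nb - 1))
  list(t = t, df = df, p = 2 * pt(-abs(t), df))
}

# brute-force single-Hill oracle: K on a 0.5 uM grid, h fixed, fMax
# profiled analytically per K (weighted least squares)
hillGridOracle <- function(calcium, fraction, weights, h,
                           kGrid = seq(0.5, 300, by = 0.5)) {
  best <- c(K = NA_real_, rss = Inf)
  for (K in kGrid) {
    g <- calcium^h / (calcium^h + K^h)
    fMax <- sum(weights * g * fraction) / sum(weights * g^2)
    rss <- sum(weights * (fraction - fMax * g)^2)
    if (rss < best["rss"]) best <- c(K = K, rss = rss)
  }
  best["K"]
}

# manual piecewise two-step trace (independent of simulateTrace):
# baseline iDock; exponential decay at kPore from onset; step of
# gain * pre-collapse value at collapse; decay at kPost
makeTwoStepTrace <- function(iDock, onset, collapse, kPore, gain, kPost,
                             dt = 0.05, n = 200) {
  j <- seq_len(n)
  v <- rep(iDock, n)
  mid <- j >= onset & j < collapse
  v[mid] <- iDock * exp(-kPore * (j[mid] - onset) * dt)
  iPre <- iDock * exp(-kPore * (collapse - onset) * dt)
  post <- j >= collapse
  v[post] <- iPre * (1 + gain) * exp(-kPost * (j[post] - collapse) * dt)
  new("IntensityTrace", values = v, frameInterval = dt,
      roiCenter = c(0, 0), roiHalfWidth = 2L)
}

# a large all-null lipid panel for type-I checks
nullLipidPanel <- function(nSpecies = 500) {
  data.frame(species = sprintf("PC %d:%d", 30 + seq_len(nSpecies) %% 18,
                               seq_len(nSpecies)),
             class = "PC")
}
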