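# TIRF stack photometry: temporal filtering, spot detection, ROI trace
# extraction, event segmentation, two-step release-model fitting, release
# mode classification and colocalization.

#' Temporal moving-average filter
#'
#' Per-pixel moving average over frames. Length is preserved; at the stack
#' edges the window shrinks to the available frames.
#'
#' @param stack height x width x frames array
#' @param window odd window length in frames (>= 1)
#' @return Filtered array of the same dimensions.
#' @export
preprocessStack <- function(stack, window = 5) {
  d <- dim(stack)
  if (window %% 2 != 1 || window < 1) stop("window must be odd and >= 1")
  if (window > d[3]) stop("window exceeds stack length")
  if (window == 1) return(stack)
  nf <- d[3]; h <- (window - 1) / 2
  m <- matrix(stack, ncol = nf)
  cs <- m
  for (j in 2:nf) cs[, j] <- cs[, j - 1] + m[, j]
  out <- matrix(0, nrow(m), nf)
  for (j in seq_len(nf)) {
    lo <- max(1, j - h); hi <- min(nf, j + h)
    lower <- if (lo > 1) cs[, lo - 1] else 0
    out[, j] <- (cs[, hi] - lower) / (hi - lo + 1)
  }
  array(out, dim = d)
}

.maxProject <- function(stack) {
  nf <- dim(stack)[3]
  m <- matrix(stack, ncol = nf)
  mp <- m[, 1]
  if (nf > 1) for (j in 2:nf) mp <- pmax(mp, m[, j])
  matrix(mp, dim(stack)[1], dim(stack)[2])
}

#' Detect granules on the maximum-intensity projection
#'
#' Projects the per-pixel maximum over the whole (preprocessed) stack,
#' keeps local maxima above background median + k MAD, merges maxima
#' closer than \code{minSep} px to the brighter one, and refines each
#' centre to sub-pixel precision by an intensity-weighted centroid in a
#' 5x5 window.
#'
#' @param stack height x width x frames array (preprocess first)
#' @param k robust threshold multiplier (median + k MAD)
#' @param minSep minimum spot separation, px
#' @return A \linkS4class{DetectionResult}; centres are 0-based with
#'   x = column.
#' @export
detectGranules <- function(stack, k = 6, minSep = 4) {
  if (length(dim(stack)) != 3 || any(dim(stack) == 0)) stop("empty stack")
  mp <- .maxProject(stack)
  bg <- median(mp)
  thr <- bg + k * mad(mp)
  ny <- nrow(mp); nx <- ncol(mp)
  inner <- mp[2:(ny - 1), 2:(nx - 1)]
  isMax <- inner > thr
  for (dy in -1:1) for (dx in -1:1) {
    if (dy == 0 && dx == 0) next
    isMax <- isMax & (inner >= mp[2:(ny - 1) + dy, 2:(nx - 1) + dx])
  }
  idx <- which(isMax, arr.ind = TRUE)
  if (nrow(idx) == 0)
    return(new("DetectionResult",
               centers = data.frame(x = numeric(0), y = numeric(0),
                                    peak = numeric(0)),
               threshold = thr, minSep = minSep))
  rows <- idx[, 1] + 1; cols <- idx[, 2] + 1
  peaks <- mp[cbind(rows, cols)]
  o <- order(peaks, decreasing = TRUE)
  rows <- rows[o]; cols <- cols[o]; peaks <- peaks[o]
  keep <- logical(length(rows))
  for (i in seq_along(rows)) {
    if (i == 1) { keep[1] <- TRUE; next }
    prev <- which(keep[seq_len(i - 1)])
    d2 <- (rows[prev] - rows[i])^2 + (cols[prev] - cols[i])^2
    keep[i] <- all(d2 >= minSep^2)
  }
  rows <- rows[keep]; cols <- cols[keep]; peaks <- peaks[keep]
  # sub-pixel refinement: intensity-weighted centroid, 5x5 window
  cx <- cy <- numeric(length(rows))
  for (i in seq_along(rows)) {
    r0 <- max(1, rows[i] - 2):min(ny, rows[i] + 2)
    c0 <- max(1, cols[i] - 2):min(nx, cols[i] + 2)
    wgt <- pmax(mp[r0, c0] - bg, 0)
    if (sum(wgt) == 0) wgt[] <- 1
    cy[i] <- sum(outer(r0, rep(1, length(c0))) * wgt) / sum(wgt) - 1
    cx[i] <- sum(outer(rep(1, length(r0)), c0) * wgt) / sum(wgt) - 1
  }
  new("DetectionResult",
      centers = data.frame(x = cx, y = cy, peak = peaks),
      threshold = thr, minSep = minSep)
}

#' Extract background-subtracted 5x5 ROI traces
#'
#' For each centre, sums a (2 halfWidth + 1)^2 pixel region per frame and
#' subtracts the ROI-area-scaled median of an annulus around the spot
#' (radii \code{annulusInner}..\code{annulusOuter} px) as local background.
#'
#' @param stack height x width x frames array
#' @param centers a \linkS4class{DetectionResult} or data.frame with x, y
#'   (0-based)
#' @param halfWidth ROI half-width (2 gives the 5x5 ROI)
#' @param annulusInner,annulusOuter background annulus radii, px
#' @param frameInterval s, stored in the traces
#' @return List of \linkS4class{IntensityTrace}.
#' @export
extractTraces <- function(stack, centers, halfWidth = 2L, annulusInner = 4,
                          annulusOuter = 7, frameInterval = 0.05) {
  if (is(centers, "DetectionResult")) centers <- detectedCenters(centers)
  d <- dim(stack); ny <- d[1]; nx <- d[2]; nf <- d[3]
  m <- matrix(stack, ncol = nf)
  lapply(seq_len(nrow(centers)), function(i) {
    col0 <- round(centers$x[i]) + 1  # 1-based
    row0 <- round(centers$y[i]) + 1
    if (col0 - halfWidth < 1 || col0 + halfWidth > nx ||
        row0 - halfWidth < 1 || row0 + halfWidth > ny)
      stop("ROI exceeds image bounds for centre ", i)
    rr <- (row0 - halfWidth):(row0 + halfWidth)
    cc <- (col0 - halfWidth):(col0 + halfWidth)
    roiIdx <- as.integer(outer(rr, (cc - 1) * ny, `+`))
    offs <- expand.grid(dy = -annulusOuter:annulusOuter,
                        dx = -annulusOuter:annulusOuter)
    rad2 <- offs$dx^2 + offs$dy^2
    offs <- offs[rad2 > annulusInner^2 & rad2 <= annulusOuter^2, ]
    ar <- row0 + offs$dy; ac <- col0 + offs$dx
    ok <- ar >= 1 & ar <= ny & ac >= 1 & ac <= nx
    annIdx <- as.integer(ar[ok] + (ac[ok] - 1) * ny)
    roi <- colSums(m[roiIdx, , drop = FALSE])
    bgMed <- apply(m[annIdx, , drop = FALSE], 2, median)
    new("IntensityTrace", values = roi - length(roiIdx) * bgMed,
        frameInterval = frameInterval,
        roiCenter = c(centers$x[i], centers$y[i]),
        roiHalfWidth = as.integer(halfWidth))
  })
}

.movavg <- function(v, w) {
  f <- as.numeric(stats::filter(v, rep(1 / w, w), sides = 2))
  f[is.na(f)] <- v[is.na(f)]
  f
}

#' Segment a fusion event in an intensity trace
#'
#' Finds the fusion onset and the end of content release. A sustained
#' departure of the smoothed trace from the docked baseline band marks the
#' event; the onset is then refined by a least-squares changepoint search
#' that jointly scans onset frame and initial decay rate over a fixed
#' scoring window. The end is the first frame after onset at which the
#' trace re-enters the post-release plateau band (within 2 noise SD) and
#' stays for \code{m} frames.
#'
#' Onset localisation is noise-limited for slow decays: when the per-frame
#' intensity change is small relative to the noise, onset and decay rate
#' trade off and the changepoint has an intrinsic uncertainty of a few
#' frames (see the methods vignette).
#'
#' @param trace an \linkS4class{IntensityTrace}
#' @param baselineFrames frames used to estimate the docked baseline
#' @param k departure threshold in units of smoothed noise SD
#' @param m frames the trace must stay out of (or in) a band
#' @param smoothWindow moving-average window for detection
#' @return List with \code{onset} and \code{end} (frame indices), or NULL
#'   when no departure is found.
#' @export
segmentEvent <- function(trace, baselineFrames = 40, k = 3, m = 5,
                         smoothWindow = 5) {
  stopifnot(is(trace, "IntensityTrace"))
  v <- trace@values
  n <- length(v); B <- baselineFrames
  if (n < B + m) stop("trace shorter than the baseline window")
  dt <- trace@frameInterval
  vs <- .movavg(v, smoothWindow)
  base <- median(v[1:B])
  sd0 <- mad(diff(v)) / sqrt(2)
  if (sd0 == 0) sd0 <- max(sd(v[1:B]), 1e-12)
  # the smoothed-baseline spread guards against traces that are already
  # temporally filtered (first differences underestimate their noise)
  sdS <- max(sd0 / sqrt(smoothWindow), mad(vs[1:B], center = base), 1e-12)
  dep <- NA_integer_
  # fusion opens with content loss, so the departure is one-sided (down)
  for (i in (B + 1):(n - m + 1))
    if (all(vs[i:(i + m - 1)] < base - k * sdS)) { dep <- i; break }
  if (is.na(dep)) return(NULL)
  # changepoint refinement: scan onset x decay rate on a fixed window that
  # stops short of the collapse peak
  hi <- min(dep + 60, n)
  pk <- which.max(vs[dep:hi])
  H <- min(max(pk - 3, 8), 45)
  os <- max(2, dep - 40):min(dep + 5, n - 5)
  rs <- exp(seq(log(0.05), log(6), length.out = 30))
  win <- max(1, dep - 60):min(dep + H, n)
  bestRss <- Inf; bestO <- dep; bestR <- 1
  for (pass in 1:2) {
    for (o in os) {
      for (r in rs) {
        pred <- ifelse(win < o, base, base * exp(-r * (win - o) * dt))
        rss <- sum((v[win] - pred)^2)
        if (rss < bestRss) { bestRss <- rss; bestO <- o; bestR <- r }
      }
    }
    rs <- bestR * exp(seq(-0.4, 0.4, length.out = 15))
  }
  onset <- bestO
  # event end: sustained re-entry into the post-release plateau band
  plateau <- median(tail(v, 10))
  end <- n
  start <- max(onset + 1, dep + pk - 1)
  if (start <= n - m + 1) {
    for (i in start:(n - m + 1))
      if (all(abs(v[i:(i + m - 1)] - plateau) <= 2 * sd0)) { end <- i; break }
  }
  list(onset = as.integer(onset), end = as.integer(end))
}

# Piecewise two-step model prediction for fixed (onset, collapse) frames.
.twoStepPred <- function(j, o, cf, iDock, kPore, dIc, kPost, dt) {
  v <- rep(iDock, length(j))
  pore <- j >= o & j < cf
  v[pore] <- iDock * exp(-kPore * (j[pore] - o) * dt)
  iPre <- iDock * exp(-kPore * (cf - o) * dt)
  post <- j >= cf
  v[post] <- (iPre + dIc) * exp(-kPost * (j[post] - cf) * dt)
  v
}

#' Fit the two-step content-release model to a trace
#'
#' Least-squares fit of the piecewise model (docked baseline; exponential
#' pore-phase loss; instantaneous step +delta-I_C at collapse; exponential
#' post-collapse decay). Onset and collapse frames are discrete and found
#' by candidate search (onset near the segmentation onset; collapse at the
#' largest positive intensity jumps after onset); the continuous
#' parameters are fitted by Levenberg-Marquardt for each candidate pair
#' and the pair with the lowest residual sum of squares wins.
#'
#' @param trace an \linkS4class{IntensityTrace}
#' @param bounds list(onset, end) from \code{\link{segmentEvent}}
#' @param maxCandidates collapse-frame candidates to try
#' @return One-row data.frame: onsetFrame, collapseFrame, iDock, poreRate,
#'   deltaIc, postRate, durationS, rss, converged, mode ("unclassified";
#'   see \code{\link{classifyModes}}).
#' @export
fitRelease <- function(trace, bounds, maxCandidates = 6) {
  stopifnot(is(trace, "IntensityTrace"))
  v <- trace@values; n <- length(v); dt <- trace@frameInterval
  o0 <- bounds$onset; endF <- min(bounds$end, n)
  iDock0 <- median(v[seq_len(max(o0 - 1, 2))])
  dj <- diff(v)
  cand <- integer(0)
  if (endF > o0 + 1) {
    jumps <- dj[(o0 + 1):(endF - 1)]
    ord <- order(jumps, decreasing = TRUE)
    ordIdx <- ord[seq_len(min(maxCandidates, length(ord)))]
    ordIdx <- ordIdx[jumps[ordIdx] > 0]
    cand <- o0 + 1 + ordIdx          # frame showing the raised intensity
  }
  span <- max(endF - o0, 4L)
  cand <- unique(c(cand, o0 + which.max(v[(o0 + 1):endF]),
                   o0 + pmax(1L, round(span * c(0.25, 0.5)))))
  cand <- cand[cand > o0 & cand < n]
  fitWin <- seq_len(min(n, endF + 20))
  best <- NULL
  for (o in unique(pmax(2, c(o0 - 1, o0, o0 + 1)))) {
    for (cf in unique(pmax(cand, o + 1))) {
      poreLen <- max(cf - o, 1)
      kp0 <- if (cf - o >= 3) {
        sl <- suppressWarnings(
          lm.fit(cbind(1, (o:(cf - 1)) * dt),
                 log(pmax(v[o:(cf - 1)], 1e-6)))$coefficients[2])
        max(min(-sl, 20), 0.01)
      } else 1
      dIc0 <- max(v[cf] - v[max(cf - 1, 1)], 1e-3)
      tailIdx <- cf:min(cf + 40, n)
      ks0 <- if (length(tailIdx) >= 4) {
        sl <- suppressWarnings(
          lm.fit(cbind(1, tailIdx * dt),
                 log(pmax(v[tailIdx], 1e-6)))$coefficients[2])
        max(min(-sl, 40), 0.05)
      } else 2
      fit <- tryCatch(
        nlsLM(v[fitWin] ~ .twoStepPred(fitWin, o, cf, iDock, kPore, dIc,
                                       kPost, dt),
              start = list(iDock = iDock0, kPore = kp0, dIc = dIc0,
                           kPost = ks0),
              lower = c(1e-6, 1e-4, 0, 1e-4),
              control = nls.lm.control(maxiter = 200, ftol = 1e-12,
                                       ptol = 1e-12)),
        error = function(e) NULL)
      if (!is.null(fit) &&
          (is.null(best) || deviance(fit) < best$rss)) {
        best <- list(fit = fit, o = o, cf = cf, rss = deviance(fit))
      }
    }
  }
  if (is.null(best)) {
    return(data.frame(onsetFrame = o0, collapseFrame = NA_integer_,
      iDock = iDock0, poreRate = NA_real_, deltaIc = NA_real_,
      postRate = NA_real_, durationS = (endF - o0) * dt, rss = NA_real_,
      converged = FALSE, mode = "unclassified"))
  }
  co <- coef(best$fit)
  data.frame(onsetFrame = best$o, collapseFrame = best$cf,
    iDock = unname(co["iDock"]), poreRate = unname(co["kPore"]),
    deltaIc = unname(co["dIc"]), postRate = unname(co["kPost"]),
    durationS = (endF - best$o) * dt, rss = best$rss, converged = TRUE,
    mode = "unclassified")
}

#' Classify release events into slow and fast modes
#'
#' Fits a two-component Gaussian mixture to the fitted delta-I_C values and
#' labels each event by posterior responsibility (the lower-mean component
#' is "slow"; posterior ties go to slow). If the mixture collapses (one
#' weight below \code{weightFloor}, means closer than \code{sepFactor}
#' pooled SD, or a one-component fit preferred by BIC) all events receive
#' the single label given by the surviving mean's position relative to
#' \code{referenceDeltaIc}.
#'
#' @param events data.frame from \code{\link{fitRelease}} rows
#' @param minEvents minimum number of events (default 20)
#' @param referenceDeltaIc counts separating slow from fast when only one
#'   mode is present
#' @param weightFloor,sepFactor mixture-collapse thresholds
#' @param seed integer seed for the mixture restarts
#' @return List with \code{events} (mode column filled) and \code{report}
#'   (mixture means, SDs, weights, collapsed flag).
#' @export
classifyModes <- function(events, minEvents = 20, referenceDeltaIc = 60,
                          weightFloor = 0.05, sepFactor = 0.5, seed = 1L) {
  ok <- is.finite(events$deltaIc)
  if (sum(ok) < minEvents)
    stop("need at least ", minEvents, " events with a fitted deltaIc")
  x <- events$deltaIc[ok]
  fit <- fitDiameterMixture(x, k = 2, seed = seed)
  fit1 <- fitDiameterMixture(x, k = 1)
  mu <- mixtureMeans(fit); sds <- mixtureSds(fit)
  w <- componentWeights(fit)
  pooled <- sqrt(mean(sds^2))
  nE <- length(x)
  bic2 <- -2 * fit@logLik + 5 * log(nE)
  bic1 <- -2 * fit1@logLik + 2 * log(nE)
  collapsed <- min(w) < weightFloor || diff(mu) < sepFactor * pooled ||
    bic1 <= bic2
  modes <- rep("unclassified", nrow(events))
  if (collapsed) {
    lab <- if (sum(w * mu) <= referenceDeltaIc) "slow" else "fast"
    modes[ok] <- lab
  } else {
    post <- fit@posterior
    modes[ok] <- ifelse(post[, 1] >= 0.5, "slow", "fast")
  }
  events$mode <- modes
  list(events = events,
       report = list(means = mu, sds = sds, weights = w,
                     collapsed = collapsed,
                     referenceDeltaIc = referenceDeltaIc))
}

#' Per-cell release durations
#'
#' @param events data.frame with columns cell and durationS (>= 1 event per
#'   cell)
#' @return List with \code{perCell} (cell, n, meanDuration, sdDuration) and
#'   \code{group} (mean and SD over cell means).
#' @export
releaseDurationsByCell <- function(events) {
  if (nrow(events) == 0) stop("no events")
  if (!all(c("cell", "durationS") %in% names(events)))
    stop("events must have 'cell' and 'durationS' columns")
  perCell <- do.call(rbind, lapply(split(events, events$cell), function(d)
    data.frame(cell = d$cell[1], n = nrow(d),
               meanDuration = mean(d$durationS),
               sdDuration = if (nrow(d) > 1) sd(d$durationS) else NA_real_)))
  rownames(perCell) <- NULL
  list(perCell = perCell,
       group = list(mean = mean(perCell$meanDuration),
                    sd = if (nrow(perCell) > 1) sd(perCell$meanDuration)
                         else NA_real_,
                    nCells = nrow(perCell)))
}

#' Relative docking
#'
#' @param count bound vesicles under the test condition
#' @param referenceCount bound vesicles under the reference condition (> 0)
#' @return count / referenceCount.
#' @export
normalizeDocking <- function(count, referenceCount) {
  if (any(referenceCount <= 0)) stop("referenceCount must be > 0")
  count / referenceCount
}

#' Otsu threshold of an intensity image
#'
#' Maximises between-class variance on a histogram of \code{nBins} equal
#' bins over the intensity range.
#'
#' @param x numeric vector or matrix of intensities
#' @param nBins histogram bins
#' @return Threshold on the intensity scale.
#' @export
otsuThreshold <- function(x, nBins = 256) {
  x <- as.numeric(x)
  r <- range(x)
  if (r[1] == r[2]) return(r[1])
  breaks <- seq(r[1], r[2], length.out = nBins + 1)
  h <- tabulate(findInterval(x, breaks, rightmost.closed = TRUE), nBins)
  p <- h / sum(h)
  mids <- (breaks[-1] + breaks[-(nBins + 1)]) / 2
  w0 <- cumsum(p)
  mu0 <- cumsum(p * mids)
  muT <- mu0[nBins]
  sb <- (muT * w0 - mu0)^2 / (w0 * (1 - w0))
  sb[!is.finite(sb)] <- 0
  mids[which.max(sb)]
}

#' Manders colocalization coefficients
#'
#' M1 is the fraction of channel-A intensity on pixels where channel B is
#' above its threshold; M2 is the symmetric quantity for channel B over
#' channel A. Thresholds default to per-channel Otsu.
#'
#' @param imgA,imgB same-shape numeric arrays
#' @param thrA,thrB channel thresholds (>= 0); NULL for Otsu
#' @return Named numeric c(M1, M2), both in [0, 1].
#' @export
mandersCoefficients <- function(imgA, imgB, thrA = NULL, thrB = NULL) {
  if (!identical(dim(imgA), dim(imgB)))
    stop("images must have the same shape")
  a <- as.numeric(imgA); b <- as.numeric(imgB)
  if (all(a == 0) || all(b == 0))
    stop("Manders coefficients are undefined for an all-zero channel")
  if (is.null(thrA)) thrA <- otsuThreshold(a)
  if (is.null(thrB)) thrB <- otsuThreshold(b)
  if (thrA < 0 || thrB < 0) stop("thresholds must be >= 0")
  c(M1 = sum(a[b > thrB]) / sum(a), M2 = sum(b[a > thrA]) / sum(b))
}

#' Centroid drift of a granule between two frame ranges
#'
#' Intensity-weighted centroid in a 7x7 window around the detected centre,
#' computed on the mean image of each frame range. Used to exclude mobile
#' granules from release-mode analysis (drift > 2 px by default).
#'
#' @param stack height x width x frames array
#' @param center c(x, y), 0-based
#' @param framesA,framesB frame index vectors to compare
#' @return Drift distance in px.
#' @export
granuleDrift <- function(stack, center, framesA, framesB) {
  ny <- dim(stack)[1]; nx <- dim(stack)[2]
  col0 <- round(center[1]) + 1; row0 <- round(center[2]) + 1
  rr <- max(1, row0 - 3):min(ny, row0 + 3)
  cc <- max(1, col0 - 3):min(nx, col0 + 3)
  centroid <- function(frames) {
    img <- apply(stack[rr, cc, frames, drop = FALSE], c(1, 2), mean)
    wgt <- pmax(img - median(img), 0)
    if (sum(wgt) == 0) wgt[] <- 1
    c(sum(outer(rep(1, length(rr)), cc) * wgt),
      sum(outer(rr, rep(1, length(cc))) * wgt)) / sum(wgt)
  }
  pa <- centroid(framesA); pb <- centroid(framesB)
  sqrt(sum((pa - pb)^2))
}
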