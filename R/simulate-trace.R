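# Single-event trace and TIRF image-stack generators.

# Noiseless two-step release profile evaluated at frame times.
# Frames are 1-based; onset and collapse are frame indices (events are
# aligned to the acquisition grid; sub-frame timing is out of scope).
.releaseProfile <- function(iDock, onsetFrame, collapseFrame, poreRate,
                            collapseGain, postRate, frameInterval, nFrames) {
  j <- seq_len(nFrames)
  v <- rep(iDock, nFrames)
  pore <- j >= onsetFrame & j < collapseFrame
  v[pore] <- iDock * exp(-poreRate * (j[pore] - onsetFrame) * frameInterval)
  iPre <- iDock * exp(-poreRate * (collapseFrame - onsetFrame) * frameInterval)
  post <- j >= collapseFrame
  v[post] <- iPre * (1 + collapseGain) *
    exp(-postRate * (j[post] - collapseFrame) * frameInterval)
  v
}

#' Simulate a single-granule content-release intensity trace
#'
#' Piecewise two-step model: constant docked intensity; exponential content
#' loss at \code{poreRate} from fusion onset; an instantaneous step of
#' +delta-I_C = \code{collapseGain} times the pre-collapse intensity when
#' the granule collapses; exponential decay at \code{postRate} thereafter.
#' The collapse occurs one pore-phase time constant (1/poreRate) after
#' onset, rounded to the frame grid.
#'
#' @param iDock docked intensity, counts
#' @param onsetFrame fusion onset frame (1-based); NA for an unfused granule
#' @param poreRate pre-collapse loss rate, 1/s
#' @param collapseGain fractional intensity jump at collapse
#' @param postRate post-collapse decay rate, 1/s
#' @param frameInterval s
#' @param nFrames trace length
#' @param noiseSd additive Gaussian noise SD, counts
#' @param seed integer seed (only used when noiseSd > 0)
#' @return List with \code{trace} (an \linkS4class{IntensityTrace}) and
#'   \code{truth} (onsetFrame, collapseFrame, deltaIc, iDock, poreRate,
#'   postRate, durationS). The true release duration is the pore phase plus
#'   three post-collapse time constants (97.5\% of the remaining content).
#' @export
simulateTrace <- function(iDock = 300, onsetFrame = 60, poreRate = 0.4,
                          collapseGain = 0.3, postRate = 1,
                          frameInterval = 0.05, nFrames = 200, noiseSd = 0,
                          seed = 1L) {
  if (frameInterval <= 0) stop("frameInterval must be > 0")
  if (noiseSd < 0) stop("noiseSd must be >= 0")
  if (!is.na(onsetFrame) && (onsetFrame < 1 || onsetFrame > nFrames))
    stop("onsetFrame outside the recording window")
  if (is.na(onsetFrame)) {
    v <- rep(iDock, nFrames)
    truth <- list(onsetFrame = NA_integer_, collapseFrame = NA_integer_,
                  deltaIc = NA_real_, iDock = iDock, poreRate = poreRate,
                  postRate = postRate, durationS = NA_real_)
  } else {
    collapseFrame <- onsetFrame +
      max(1L, as.integer(round((1 / poreRate) / frameInterval)))
    v <- .releaseProfile(iDock, onsetFrame, collapseFrame, poreRate,
                         collapseGain, postRate, frameInterval, nFrames)
    iPre <- iDock * exp(-poreRate * (collapseFrame - onsetFrame) * frameInterval)
    truth <- list(onsetFrame = as.integer(onsetFrame),
                  collapseFrame = as.integer(collapseFrame),
                  deltaIc = collapseGain * iPre, iDock = iDock,
                  poreRate = poreRate, postRate = postRate,
                  durationS = (collapseFrame - onsetFrame) * frameInterval +
                    3 / postRate)
  }
  if (noiseSd > 0) {
    withr::local_seed(seed)
    v <- v + rnorm(nFrames, 0, noiseSd)
  }
  trace <- new("IntensityTrace", values = v, frameInterval = frameInterval,
               roiCenter = c(NA_real_, NA_real_), roiHalfWidth = 2L)
  list(trace = trace, truth = truth)
}

#' Simulate a TIRF image stack of docked and fusing granules
#'
#' Granules are placed by rejection sampling (at least 3 psfSigma from the
#' edges, minimum separation 4 psfSigma) and rendered as 2D Gaussian spots
#' whose peak amplitude follows the noiseless two-step release profile of
#' their population. Pixel values are Poisson draws over a constant
#' background. Calcium arrives at \code{triggerFrame}; fused granules start
#' releasing after an exponential delay (truncated to the recording).
#'
#' @param config a \linkS4class{ScenarioConfig}
#' @param calcium triggering calcium concentration, uM
#' @param shape image height and width, px (>= 32)
#' @param nGranules granules to place
#' @param psfSigma Gaussian PSF sigma, px
#' @param background constant background, counts
#' @param frameInterval s
#' @param nFrames frames
#' @param triggerFrame frame at which calcium arrives
#' @param poissonNoise apply Poisson pixel noise (disable for noiseless
#'   renders in oracle checks)
#' @param seed integer seed
#' @return List with \code{stack} (height x width x frames array) and
#'   \code{truth} (per granule: x, y, population, fused, onsetFrame,
#'   collapseFrame, deltaIc, brightness). Coordinates are 0-based,
#'   x = column.
#' @export
simulateStack <- function(config, calcium = 100, shape = c(128, 128),
                          nGranules = 20, psfSigma = 1.2, background = 100,
                          frameInterval = 0.05, nFrames = 200,
                          triggerFrame = 40, poissonNoise = TRUE,
                          seed = config@seed) {
  stopifnot(is(config, "ScenarioConfig"))
  if (any(shape < 32)) stop("shape must be at least 32 x 32")
  withr::local_seed(seed)
  ny <- shape[1]; nx <- shape[2]
  margin <- 3 * psfSigma
  minSep <- 4 * psfSigma
  xs <- ys <- numeric(0)
  attempts <- 0
  while (length(xs) < nGranules) {
    attempts <- attempts + 1
    if (attempts > 1e4)
      stop("could not place ", nGranules,
           " granules at the minimum separation; reduce nGranules")
    x <- runif(1, margin, nx - 1 - margin)
    y <- runif(1, margin, ny - 1 - margin)
    if (length(xs) == 0 || all((xs - x)^2 + (ys - y)^2 >= minSep^2)) {
      xs <- c(xs, x); ys <- c(ys, y)
    }
  }
  w <- vapply(config@populations, function(p) p@weight, numeric(1))
  popIdx <- sample.int(length(w), nGranules, replace = TRUE, prob = w)
  stack <- array(background, dim = c(ny, nx, nFrames))
  truth <- vector("list", nGranules)
  half <- ceiling(4 * psfSigma)
  for (i in seq_len(nGranules)) {
    p <- config@populations[[popIdx[i]]]
    pFuse <- p@maxFuseProb * calcium^p@hill / (calcium^p@hill + p@kHalf^p@hill)
    # granules can only fuse if the trigger leaves room in the recording
    canFuse <- triggerFrame < nFrames - 6
    fused <- canFuse && runif(1) < pFuse
    onset <- NA_integer_
    if (fused) {
      repeat {
        onset <- triggerFrame +
          as.integer(round(rexp(1, 1 / p@delayMean) / frameInterval))
        if (onset < nFrames - 5) break
      }
      onset <- max(onset, triggerFrame + 1L)
    }
    sim <- simulateTrace(iDock = p@brightness, onsetFrame = onset,
                         poreRate = p@poreRate, collapseGain = p@collapseGain,
                         postRate = p@postRate, frameInterval = frameInterval,
                         nFrames = nFrames, noiseSd = 0)
    amp <- traceValues(sim$trace)
    cx <- xs[i]; cy <- ys[i]
    px <- max(0, floor(cx) - half):min(nx - 1, ceiling(cx) + half)
    py <- max(0, floor(cy) - half):min(ny - 1, ceiling(cy) + half)
    kern <- outer(exp(-(py - cy)^2 / (2 * psfSigma^2)),
                  exp(-(px - cx)^2 / (2 * psfSigma^2)))
    patch <- as.numeric(kern) %o% amp            # (pixels) x (frames)
    dim(patch) <- c(length(py), length(px), nFrames)
    stack[py + 1, px + 1, ] <- stack[py + 1, px + 1, ] + patch
    truth[[i]] <- data.frame(granule = i, x = cx, y = cy,
      population = p@label, fused = fused,
      onsetFrame = sim$truth$onsetFrame,
      collapseFrame = sim$truth$collapseFrame,
      deltaIc = sim$truth$deltaIc, brightness = p@brightness)
  }
  if (poissonNoise) stack[] <- rpois(length(stack), stack)
  list(stack = stack, truth = do.call(rbind, truth),
       psfSigma = psfSigma, background = background,
       frameInterval = frameInterval, triggerFrame = triggerFrame)
}

#' Write an image stack as 16-bit multi-page TIFF
#'
#' @param stack height x width x frames numeric array, values in
#'   [0, 65535]
#' @param path output file
#' @return Invisibly, \code{path}.
#' @export
writeStackTiff <- function(stack, path) {
  if (max(stack) > 65535 || min(stack) < 0)
    stop("stack values must fit unsigned 16-bit")
  frames <- lapply(seq_len(dim(stack)[3]), function(j)
    stack[, , j] / 65535)
  tiff::writeTIFF(frames, path, bits.per.sample = 16)
  invisible(path)
}

#' Read a multi-page TIFF stack written by \code{writeStackTiff}
#'
#' @param path TIFF file
#' @return height x width x frames array of counts.
#' @export
readStackTiff <- function(path) {
  frames <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(frames)) frames <- list(frames)
  arr <- array(0, dim = c(dim(frames[[1]])[1], dim(frames[[1]])[2],
                          length(frames)))
  for (j in seq_along(frames)) arr[, , j] <- round(frames[[j]] * 65535)
  arr
}
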