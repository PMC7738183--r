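# Tabular biochemistry statistics: lipidomics normalisation, volcano and
# class enrichment, immunodepletion fractions, secretion normalisations.

#' Normalise lipid peak areas to internal standard and protein
#'
#' Divides each sample's areas by its internal-standard area and protein
#' mass, adding a "normalized" assay.
#'
#' @param se SummarizedExperiment from \code{\link{simulateLipidTable}} (or
#'   with the same colData contract: standard, protein)
#' @return The SummarizedExperiment with a "normalized" assay.
#' @export
normalizeLipids <- function(se) {
  cd <- colData(se)
  if (!all(c("standard", "protein") %in% names(cd)))
    stop("colData must contain 'standard' and 'protein'")
  if (any(cd$standard == 0) || any(cd$protein == 0))
    stop("zero internal standard or protein mass")
  a <- assay(se, "area")
  assay(se, "normalized") <- sweep(a, 2,
                                   cd$standard * cd$protein, `/`)
  se
}

#' Lipid volcano statistics (syt9 over syt7)
#'
#' Per species: log2 of the ratio of group means (syt9/syt7) of normalised
#' areas and a two-tailed Welch t-test (unequal variances), with the
#' p-value reported as -log2(p). Species with p < 0.05 are flagged
#' significant.
#'
#' @param se normalised SummarizedExperiment (see
#'   \code{\link{normalizeLipids}}); >= 2 replicates per group
#' @param assayName assay to test
#' @param pAdjust "none" (default, the per-species rule) or a
#'   \code{\link[stats]{p.adjust}} method such as "BH"
#' @param logBase base for the p-value transform (2, matching the
#'   -log2(0.05) = 4.32 significance line; 10 optional)
#' @param logValues test log2-transformed values (default; the volcano
#'   works on log2 quantities and peak-area noise is multiplicative) or the
#'   raw normalised values
#' @return data.frame: species, class, log2Ratio, p, negLogP, significant.
#' @export
lipidVolcano <- function(se, assayName = "normalized", pAdjust = "none",
                         logBase = 2, logValues = TRUE) {
  x <- assay(se, assayName)
  grp <- colData(se)$group
  i7 <- grp == "syt7"; i9 <- grp == "syt9"
  if (sum(i7) < 2 || sum(i9) < 2) stop("need >= 2 replicates per group")
  m7 <- rowMeans(x[, i7, drop = FALSE])
  m9 <- rowMeans(x[, i9, drop = FALSE])
  if (any(m7 == 0) || any(m9 == 0)) stop("zero group mean for a species")
  xt <- if (logValues) log2(x) else x
  p <- vapply(seq_len(nrow(x)), function(i) {
    a <- xt[i, i9]; b <- xt[i, i7]
    if (sd(a) == 0 && sd(b) == 0)
      stop("zero variance in both groups for species ",
           rowData(se)$species[i])
    t.test(a, b, var.equal = FALSE)$p.value
  }, numeric(1))
  if (pAdjust != "none") p <- p.adjust(p, method = pAdjust)
  data.frame(species = rowData(se)$species, class = rowData(se)$class,
             log2Ratio = log2(m9 / m7), p = p,
             negLogP = -log(p, base = logBase), significant = p < 0.05,
             row.names = NULL)
}

#' Lipid class enrichment relative to syt7 granules
#'
#' Totals the normalised areas per class within each sample, divides by
#' the syt7 group mean of that class, and log2-transforms.
#'
#' @param se normalised SummarizedExperiment
#' @param assayName assay to total
#' @return List with \code{perSample} (long data.frame: class, sample,
#'   group, log2Fold) and \code{summary} (class x group mean log2 fold).
#' @export
classEnrichment <- function(se, assayName = "normalized") {
  x <- assay(se, assayName)
  cls <- rowData(se)$class
  grp <- colData(se)$group
  totals <- rowsum(x, cls)           # class x sample
  ref <- rowMeans(totals[, grp == "syt7", drop = FALSE])
  if (any(ref == 0)) stop("class absent from the syt7 group")
  lf <- log2(sweep(totals, 1, ref, `/`))
  perSample <- data.frame(
    class = rep(rownames(lf), ncol(lf)),
    sample = rep(colnames(x), each = nrow(lf)),
    group = rep(grp, each = nrow(lf)),
    log2Fold = as.numeric(lf), row.names = NULL)
  summary <- do.call(rbind, lapply(split(perSample,
                                         perSample[c("class", "group")]),
    function(d) data.frame(class = d$class[1], group = d$group[1],
                           meanLog2Fold = mean(d$log2Fold))))
  rownames(summary) <- NULL
  list(perSample = perSample, summary = summary)
}

#' Protein fractions from immunodepletion band intensities
#'
#' fractionSyt7 = (control - dep7)/control and fractionSyt9 =
#' (control - dep9)/control, where dep7/dep9 are the supernatant
#' intensities after depleting with anti-syt7/anti-syt9 beads. Raw
#' fractions are retained; reported fractions are clipped to [0, 1] and
#' renormalised to sum to one.
#'
#' @param control,dep7,dep9 band intensities (vectors are recycled to the
#'   longest; control > 0)
#' @param protein optional protein names
#' @return data.frame with raw and renormalised fractions per protein.
#' @export
depletionFractions <- function(control, dep7, dep9, protein = NULL) {
  if (any(control <= 0)) stop("control intensity must be > 0")
  nP <- max(length(control), length(dep7), length(dep9))
  control <- rep_len(control, nP); dep7 <- rep_len(dep7, nP)
  dep9 <- rep_len(dep9, nP)
  raw7 <- (control - dep7) / control
  raw9 <- (control - dep9) / control
  c7 <- pmin(pmax(raw7, 0), 1)
  c9 <- pmin(pmax(raw9, 0), 1)
  tot <- c7 + c9
  f7 <- ifelse(tot > 0, c7 / tot, 0.5)
  f9 <- ifelse(tot > 0, c9 / tot, 0.5)
  data.frame(protein = if (is.null(protein)) paste0("protein", seq_len(nP))
                       else protein,
             control = control, dep7 = dep7, dep9 = dep9,
             rawFractionSyt7 = raw7, rawFractionSyt9 = raw9,
             fractionSyt7 = f7, fractionSyt9 = f9, row.names = NULL)
}

#' Fractional secretion as percent of total
#'
#' 100 * secreted / (secreted + lysate): the percent of total reporter
#' fluorescence released under stimulation.
#'
#' @param secreted,lysate signals (>= 0, not both zero)
#' @return Percent secreted.
#' @export
fractionalSecretion <- function(secreted, lysate) {
  if (any(secreted + lysate == 0)) stop("secreted and lysate are both zero")
  100 * secreted / (secreted + lysate)
}

#' Secretion normalised to protein and to the reference condition
#'
#' Divides each sample's secreted signal by its protein mass, then by the
#' mean protein-normalised signal of the reference condition (untreated at
#' 90 mM KCl by default).
#'
#' @param measurements data.frame with scenario, stimulus, secreted,
#'   protein (e.g. rbind of \code{\link{simulateSecretion}} outputs)
#' @param referenceScenario,referenceStimulus the reference condition
#' @return The data.frame with perProtein and relative columns added.
#' @export
relativeSecretion <- function(measurements, referenceScenario = "untreated",
                              referenceStimulus = 90) {
  need <- c("scenario", "stimulus", "secreted", "protein")
  if (!all(need %in% names(measurements)))
    stop("missing column(s): ",
         paste(setdiff(need, names(measurements)), collapse = ", "))
  m <- measurements
  m$perProtein <- m$secreted / m$protein
  refIdx <- m$scenario == referenceScenario & m$stimulus == referenceStimulus
  if (!any(refIdx)) stop("reference condition (", referenceScenario, ", ",
                         referenceStimulus, " mM) not present")
  m$relative <- m$perProtein / mean(m$perProtein[refIdx])
  m
}

#' Normalised calcium-imaging response (F1 - F0 over positive control)
#'
#' (F - F0) / (Fcontrol - F0) with F0 the mean over the baseline window.
#'
#' @param f fluorescence trace
#' @param baselineWindow indices of the pre-stimulus baseline
#' @param control positive-control fluorescence (must exceed F0)
#' @return Normalised trace, 0 at baseline and 1 at the positive control.
#' @export
dffNormalize <- function(f, baselineWindow, control) {
  f0 <- mean(f[baselineWindow])
  if (control <= f0) stop("positive control must exceed the baseline")
  (f - f0) / (control - f0)
}
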