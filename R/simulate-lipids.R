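# Synthetic lipidomics peak-area tables.

.lipidClassSizes <- c(PC = 28, PE = 18, PS = 10, PI = 8, SM = 12, Cer = 8,
                      LPC = 8, DAG = 8)

.defaultSpecies <- function() {
  glycero <- c("32:1", "34:1", "34:2", "36:1", "36:2", "36:4", "38:4",
               "38:6", "40:6", "32:0", "33:1", "35:2", "38:3", "40:4",
               "30:1", "31:0", "37:4", "39:1", "28:0", "29:1", "36:3",
               "38:5", "40:5", "34:0", "36:0", "40:7", "38:2", "34:3")
  sphingo <- c("32:1", "34:1", "36:1", "38:1", "40:1", "41:1", "42:1",
               "42:2", "43:1", "44:1", "44:2", "46:1")
  sp <- unlist(lapply(names(.lipidClassSizes), function(cl) {
    tails <- if (cl %in% c("SM", "Cer")) sphingo else glycero
    paste(cl, tails[seq_len(.lipidClassSizes[[cl]])])
  }))
  data.frame(species = sp,
             class = rep(names(.lipidClassSizes), .lipidClassSizes))
}

#' Simulate a lipidomics peak-area table for syt7 vs syt9 granules
#'
#' Species peak areas are log-normal around species-specific base
#' abundances; non-enriched species have equal group means. Enriched
#' species are multiplied by their fold change in the \code{enrichedGroup}.
#' Each sample carries an internal-standard area and a protein mass so the
#' normalisation steps can be exercised; both also multiply the raw areas
#' (normalisation removes them again).
#'
#' @param nReps replicates per group
#' @param cv replicate coefficient of variation (log-normal)
#' @param enriched named numeric vector of linear fold changes, e.g.
#'   \code{c("SM 42:1" = 3)} (the default: the sphingomyelin species
#'   enriched threefold in syt7 granules)
#' @param enrichedGroup group carrying the enrichment ("syt7" or "syt9")
#' @param species data.frame with columns species, class; defaults to a
#'   100-species panel over 8 lipid classes including SM 42:1
#' @param seed integer seed
#' @return A \code{SummarizedExperiment}: assay "area"; rowData species,
#'   class, trueFold (fold in enrichedGroup over the other group); colData
#'   group, replicate, standard, protein.
#' @export
simulateLipidTable <- function(nReps = 4, cv = 0.15,
                               enriched = c("SM 42:1" = 3),
                               enrichedGroup = "syt7",
                               species = .defaultSpecies(), seed = 1L) {
  if (any(enriched <= 0)) stop("fold changes must be > 0")
  if (cv <= 0) stop("cv must be > 0")
  if (anyDuplicated(species$species)) stop("duplicate species names")
  if (length(enriched) && !all(names(enriched) %in% species$species))
    stop("enriched species not in the panel: ",
         paste(setdiff(names(enriched), species$species), collapse = ", "))
  withr::local_seed(seed)
  nS <- nrow(species)
  base <- 10^runif(nS, 4, 7)
  groups <- rep(c("syt7", "syt9"), each = nReps)
  standard <- exp(rnorm(2 * nReps, log(1e6), 0.05))
  protein <- pmax(rnorm(2 * nReps, 1, 0.05), 0.5)
  fold <- setNames(rep(1, nS), species$species)
  fold[names(enriched)] <- enriched
  sdl <- sqrt(log(1 + cv^2))
  areas <- matrix(0, nS, 2 * nReps,
                  dimnames = list(species$species,
                                  paste0(groups, "_", rep(seq_len(nReps), 2))))
  for (s in seq_len(2 * nReps)) {
    mu <- if (groups[s] == enrichedGroup) base * fold else base
    areas[, s] <- mu * standard[s] / 1e6 * protein[s] *
      exp(rnorm(nS, -sdl^2 / 2, sdl))
  }
  SummarizedExperiment(
    assays = list(area = areas),
    rowData = DataFrame(species = species$species, class = species$class,
                        trueFold = unname(fold)),
    colData = DataFrame(group = groups,
                        replicate = rep(seq_len(nReps), 2),
                        standard = standard, protein = protein,
                        row.names = colnames(areas)))
}
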