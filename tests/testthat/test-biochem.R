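test_that("lipid normalisation divides by internal standard and protein", {
  se <- simulateLipidTable(seed = 1)
  n <- normalizeLipids(se)
  a <- SummarizedExperiment::assay(n, "area")
  norm <- SummarizedExperiment::assay(n, "normalized")
  cd <- SummarizedExperiment::colData(n)
  expect_equal(norm[, 1], a[, 1] / (cd$standard[1] * cd$protein[1]))
  # doubling one sample's standard halves its normalised values
  cd2 <- cd; cd2$standard[2] <- 2 * cd$standard[2]
  se2 <- SummarizedExperiment::SummarizedExperiment(
    assays = list(area = a), rowData = SummarizedExperiment::rowData(n),
    colData = cd2)
  n2 <- normalizeLipids(se2)
  expect_equal(SummarizedExperiment::assay(n2, "normalized")[, 2],
               norm[, 2] / 2)
  # normalised values are proportional to the generating concentrations
  rd <- SummarizedExperiment::rowData(n)
  i7 <- cd$group == "syt7"
  m7 <- rowMeans(norm[, i7])
  m9 <- rowMeans(norm[, !i7])
  enr <- rd$trueFold > 1
  expect_equal(median(m7[!enr] / m9[!enr]), 1, tolerance = 0.1)
})

test_that("volcano statistics match their definitions", {
  se <- simulateLipidTable(seed = 2)
  n <- normalizeLipids(se)
  v <- lipidVolcano(n)
  expect_equal(-log2(0.05), 4.32, tolerance = 1e-3)
  expect_true(all(v$significant == (v$p < 0.05)))
  # identical groups give ratio 0 and p = 1
  a <- matrix(rep(c(1, 2, 3), 2), nrow = 1,
              dimnames = list("X", paste0("s", 1:6)))
  seId <- SummarizedExperiment::SummarizedExperiment(
    assays = list(area = a, normalized = a),
    rowData = S4Vectors::DataFrame(species = "X", class = "PC"),
    colData = S4Vectors::DataFrame(
      group = rep(c("syt7", "syt9"), each = 3),
      standard = rep(1, 6), protein = rep(1, 6),
      row.names = paste0("s", 1:6)))
  vId <- lipidVolcano(seId)
  expect_equal(vId$log2Ratio, 0)
  expect_equal(vId$p, 1)
})

test_that("Welch p-values match the textbook formula to 12 digits", {
  se <- normalizeLipids(simulateLipidTable(seed = 3))
  x <- log2(SummarizedExperiment::assay(se, "normalized"))
  grp <- SummarizedExperiment::colData(se)$group
  v <- lipidVolcano(se)
  for (i in c(1, 25, 60, 100)) {
    o <- welchOracle(x[i, grp == "syt9"], x[i, grp == "syt7"])
    expect_equal(v$p[i], o$p, tolerance = 1e-12)
  }
})

test_that("volcano type-I error is near nominal under the null", {
  hits <- vapply(1:10, function(s) {
    se <- normalizeLipids(simulateLipidTable(
      enriched = setNames(numeric(0), character(0)),
      species = nullLipidPanel(500), seed = s))
    mean(lipidVolcano(se)$significant)
  }, numeric(1))
  # Welch at n = 4 per group is slightly conservative; allow [0.03, 0.07]
  expect_lt(abs(mean(hits) - 0.05), 0.02)
})

test_that("class enrichment isolates the perturbed class", {
  se <- normalizeLipids(simulateLipidTable(seed = 4, cv = 0.05,
    enriched = c("SM 42:1" = 1)))
  # double every ceramide species in syt9 by editing the areas directly
  a <- SummarizedExperiment::assay(se, "normalized")
  rd <- SummarizedExperiment::rowData(se)
  grp <- SummarizedExperiment::colData(se)$group
  a[rd$class == "Cer", grp == "syt9"] <-
    2 * a[rd$class == "Cer", grp == "syt9"]
  SummarizedExperiment::assay(se, "normalized") <- a
  ce <- classEnrichment(se)
  s9 <- ce$summary[ce$summary$group == "syt9", ]
  expect_equal(s9$meanLog2Fold[s9$class == "Cer"], 1, tolerance = 0.15)
  expect_lt(max(abs(s9$meanLog2Fold[s9$class != "Cer"])), 0.15)
  # syt7 group mean log2 fold is 0 by construction of the reference
  s7 <- ce$perSample[ce$perSample$group == "syt7", ]
  perClass <- tapply(2^s7$log2Fold, s7$class, mean)
  expect_equal(as.numeric(perClass), rep(1, length(perClass)),
               tolerance = 1e-9)
})

test_that("noiseless enrichment is recovered exactly", {
  se <- normalizeLipids(simulateLipidTable(cv = 1e-8, seed = 5))
  n <- SummarizedExperiment::assay(se, "normalized")
  grp <- SummarizedExperiment::colData(se)$group
  i <- which(SummarizedExperiment::rowData(se)$species == "SM 42:1")
  fold <- mean(n[i, grp == "syt7"]) / mean(n[i, grp == "syt9"])
  expect_equal(fold, 3, tolerance = 1e-5)
})

test_that("depletion fractions follow the subtraction rule with clipping", {
  r <- depletionFractions(10, 2, 8)
  expect_equal(r$fractionSyt7, 0.8)
  expect_equal(r$fractionSyt9, 0.2)
  expect_equal(depletionFractions(10, 10, 0)$fractionSyt9, 1)
  expect_equal(depletionFractions(10, 5, 5)$fractionSyt7, 0.5)
  # scale invariance in the control intensity
  r2 <- depletionFractions(1000, 200, 800)
  expect_equal(r2$fractionSyt7, r$fractionSyt7)
  # noisy values outside [0, 1] are clipped but retained raw
  r3 <- depletionFractions(10, 11, 1)
  expect_equal(r3$rawFractionSyt7, -0.1)
  expect_equal(r3$fractionSyt7, 0)
  expect_error(depletionFractions(0, 1, 1), "> 0")
})

test_that("secretion normalisations match their worked examples", {
  expect_equal(fractionalSecretion(5, 95), 5)
  expect_equal(fractionalSecretion(0, 10), 0)
  expect_equal(fractionalSecretion(50, 50), 50)
  expect_error(fractionalSecretion(0, 0), "both zero")

  m <- data.frame(scenario = c("untreated", "untreated", "ffa"),
                  stimulus = c(90, 90, 90),
                  secreted = c(10, 10, 10),
                  protein = c(1, 1, 0.5))
  r <- relativeSecretion(m)
  expect_equal(r$relative[1], 1)
  expect_equal(r$perProtein[3], 2 * r$perProtein[1])
  expect_error(relativeSecretion(m[3, ]), "not present")
  # simulated high-KCl glutamate: ffa released far less than untreated
  ffa <- simulateSecretion(makeScenario("ffa"), 90, nReps = 10, seed = 6)
  un <- simulateSecretion(makeScenario("untreated"), 90, nReps = 10,
                          seed = 6)
  rel <- relativeSecretion(rbind(ffa, un))
  expect_lt(mean(rel$relative[rel$scenario == "ffa"]),
            0.8 * mean(rel$relative[rel$scenario == "untreated"]))
})

test_that("calcium-imaging normalisation spans 0 to 1", {
  f <- c(rep(100, 10), 150, 200)
  out <- dffNormalize(f, baselineWindow = 1:10, control = 200)
  expect_equal(out[1], 0)
  expect_equal(out[12], 1)
  expect_equal(out[11], 0.5)
  expect_error(dffNormalize(f, 1:10, control = 90), "exceed")
})
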