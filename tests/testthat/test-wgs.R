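test_that("taxonomy mapping walks up to family and averages phenotypes", {
  phen <- matrix(0L, 4, 6, dimnames = list(sprintf("g%d", 1:4),
                                           scfaPhenotypes()))
  phen[c("g1", "g2"), "butyrate"] <- 1L
  bpm <- makeBpm(phen,
                 phylum = "p1", class = "c1", order = "o1",
                 family = c("famA", "famA", "famA", "famB"),
                 genus = c("genA", "genA", "genA", "genB"),
                 species = c("spA", "spA", "spA", "spB"),
                 strain = sprintf("t%d", 1:4))
  taxa <- exampleTaxonomy(c("tx1", "tx2", "tx3"),
                          phylum = "p1", class = "c1", order = "o1")
  taxa["tx1", c("family", "genus", "species")] <- c("famA", "genA", "spA")
  taxa["tx2", "family"] <- "undefined"   # defined only to order level
  taxa["tx3", c("family", "genus", "species")] <- c("famZ", "genZ", "spZ")
  ab <- matrix(c(0.5, 0.3, 0.2), 1, dimnames = list("s1",
                                                    c("tx1", "tx2", "tx3")))
  res <- taxonomyMapCpi(ab, taxa, bpm)
  # tx1 matches species spA (3 strains, phenotypes 1,1,0) -> PI 2/3
  expect_equal(res$pi["tx1", "butyrate"], 2 / 3)
  # tx2 (order-level) and tx3 (unknown family) are discarded
  expect_false(res$mapped[["tx2"]])
  expect_false(res$mapped[["tx3"]])
  # only tx1 mapped: renormalized abundance 1 -> CPI = PI
  expect_equal(cpi(res$profile)["s1", "butyrate"], 2 / 3)
  # taxon defined at genus only still maps through the rank walk
  taxa2 <- taxa
  taxa2["tx1", "species"] <- "undefined"
  res2 <- taxonomyMapCpi(ab, taxa2, bpm)
  expect_equal(res2$pi["tx1", "butyrate"], 2 / 3)
  # all taxa unmapped: sample flagged
  ab3 <- ab[, "tx3", drop = FALSE]
  res3 <- taxonomyMapCpi(ab3, taxa, bpm)
  expect_false(res3$profile@retained[["s1"]])
  expect_true(all(is.na(cpi(res3$profile))))
  expect_error(taxonomyMapCpi(ab, taxa[, 1:3], bpm), "malformed")
})

test_that("taxonomy-mapped CPI equals the amplicon formulas on shared input", {
  spec <- fixtureSpec(13, nSamples = 5)
  ref <- generateReferenceCollection(spec)
  wgs <- generateWgsDataset(ref, spec)
  res <- taxonomyMapCpi(wgs$taxonAbundance, wgs$taxa, ref$bpm)
  # oracle: same abundances + same PI table through computeCpi directly
  direct <- computeCpi(wgs$taxonAbundance, res$pi)
  expect_equal(cpi(res$profile), direct, tolerance = 1e-12)
  # and both equal the generating composition-weighted phenotype fraction
  truth <- wgs$composition %*% phenotypeMatrix(ref$bpm)
  expect_equal(cpi(res$profile), truth, tolerance = 1e-9)
})

test_that("TMM factors: identity, scale invariance, edgeR cross-check", {
  set.seed(21)
  core <- sprintf("core%02d", 1:20)
  counts <- matrix(rpois(40, 500), 20, 2, dimnames = list(core, c("A", "B")))
  counts[, "B"] <- counts[, "A"]
  expect_equal(unname(tmmFactors(counts, core)), c(1, 1))
  # count-for-count doubling: factors 1 and identical normalized abundances
  counts2 <- cbind(A = counts[, "A"], B = 2L * counts[, "A"])
  f2 <- tmmFactors(counts2, core)
  expect_equal(unname(f2), c(1, 1), tolerance = 1e-9)
  n2 <- normalizeCounts(counts2, f2)
  expect_equal(n2[, "A"], n2[, "B"], tolerance = 1e-9)
  # scale invariance on a 4-sample table with pathway rows present
  extra <- matrix(rpois(12, 100), 3, 4,
                  dimnames = list(c("Thl", "Hbd", "Crt"), NULL))
  m <- rbind(matrix(rpois(80, 400), 20, 4, dimnames = list(core, NULL)),
             extra)
  colnames(m) <- paste0("s", 1:4)
  f <- tmmFactors(m, core)
  m2 <- m; m2[, 2] <- m2[, 2] * 7L
  n1 <- normalizeCounts(m, f)
  nScaled <- normalizeCounts(m2, tmmFactors(m2, core))
  expect_equal(n1, nScaled, tolerance = 1e-9)
  # independent implementation: edgeR on the core-only table
  skip_if_not_installed("edgeR")
  coreOnly <- m[core, ]
  ours <- tmmFactors(coreOnly, core)
  cpmCore <- sweep(coreOnly, 2, colSums(coreOnly), "/") * 1e6
  uq <- apply(cpmCore, 2, quantile, probs = 0.75)
  refIdx <- which.min(abs(uq - mean(uq)))
  theirs <- edgeR::calcNormFactors(coreOnly, method = "TMM",
                                   refColumn = refIdx)
  expect_equal(unname(ours), unname(theirs), tolerance = 0.02)
})

test_that("TMM trims an inflated core gene", {
  set.seed(22)
  ids <- c(sprintf("core%02d", 1:20), sprintf("gene%03d", 1:200))
  core <- ids[1:20]
  base <- rpois(220, 1000) + 1L
  counts <- cbind(A = base, B = base)
  rownames(counts) <- ids
  counts["core05", "B"] <- counts["core05", "B"] * 10L
  f <- tmmFactors(counts, core)
  expect_lt(abs(f[["B"]] - 1), 0.05)
  # with trimming disabled the inflated gene drags the factor away
  f0 <- tmmFactors(counts, core, trimM = 0, trimA = 0)
  expect_gt(abs(f0[["B"]] - 1), abs(f[["B"]] - 1))
})

test_that("TMM input validation", {
  core <- c("c1", "c2")
  m <- matrix(1:4, 2, 2, dimnames = list(core, c("A", "B")))
  expect_error(tmmFactors(m[, 1, drop = FALSE], core), "two samples")
  expect_error(tmmFactors(m, c("c1", "nope")), "absent")
  m0 <- m; m0[, 1] <- 0L
  expect_error(tmmFactors(m0, core), "zero total core")
  expect_error(tmmFactors(m, character()), "empty core")
})

test_that("count normalization to CPM", {
  m <- matrix(c(10, 10), 1, 2, dimnames = list("g", c("A", "B")))
  f <- c(A = 1, B = 2)
  n <- normalizeCounts(m, f, libSizes = c(A = 1e6, B = 1e6))
  expect_equal(n["g", "A"], 10)
  expect_equal(n["g", "B"], 5)    # factor 2 halves CPM
  expect_error(normalizeCounts(m, f, libSizes = c(A = 0, B = 1)), "zero")
  expect_error(normalizeCounts(m, c(A = 1)), "missing normalization factor")
})

test_that("pathway signatures are variant-specific and segments separate", {
  sig <- pathwaySignatures(loadPathwayDefinitions())
  expect_setequal(sig$butyrate$P1, c("Thl", "Hbd", "Crt"))
  expect_setequal(sig$butyrate$universal, "Bcd-EtfAB")
  expect_setequal(sig$butyrate$terminal, c("But", "CtfAB", "Ptb", "Buk"))
  # shared-segment roles never sit in a variant signature
  for (v in c("P1", "P2", "P3", "P4"))
    expect_length(intersect(sig$butyrate[[v]],
                            c("Bcd-EtfAB", "But", "CtfAB", "Ptb", "Buk")), 0L)
  # signatures of different variants of one product are disjoint
  for (p in names(sig)) {
    pooled <- unlist(sig[[p]])
    expect_false(anyDuplicated(pooled) > 0)
  }
})

test_that("pathway abundance sums signature roles", {
  sig <- list(butyrate = list(P1 = c("Thl", "Hbd", "Crt")))
  norm <- matrix(c(5, 3, 2, 100), 4, 1,
                 dimnames = list(c("Thl", "Hbd", "Crt", "core01"), "s1"))
  ab <- pathwayAbundance(norm, sig)
  expect_equal(ab["s1", "butyrate.P1"], 10)
  # zero rows give zero abundance
  norm0 <- norm; norm0[, 1] <- 0
  expect_equal(unname(pathwayAbundance(norm0, sig)[, 1]), 0)
  # absent signature role warns and contributes 0
  sig2 <- list(butyrate = list(P1 = c("Thl", "Hbd", "Crt", "Ghost")))
  expect_warning(ab2 <- pathwayAbundance(norm, sig2), "Ghost")
  expect_equal(ab2["s1", "butyrate.P1"], 10)
  expect_error(pathwayAbundance(norm, list(butyrate = list(P1 = character()))),
               "empty signature")
})

test_that("CPI vs pathway-abundance rank correlation", {
  x <- seq(0.1, 0.9, length.out = 10)
  cpim <- matrix(x, 10, 1, dimnames = list(sprintf("s%02d", 1:10),
                                           "butyrate"))
  ab <- matrix(exp(x), 10, 1, dimnames = list(rownames(cpim),
                                              "butyrate.P1"))
  expect_equal(cpiPathwayCorrelation(cpim, ab)$rho, 1)
  abRev <- ab; abRev[, 1] <- rev(ab[, 1])
  expect_equal(cpiPathwayCorrelation(cpim, abRev)$rho, -1)
  expect_error(cpiPathwayCorrelation(cpim[1:2, , drop = FALSE],
                                     ab[1:2, , drop = FALSE]), "3 shared")
})

test_that("carrier abundance drives both CPI and pathway abundance (simulation)", {
  set.seed(31)
  n <- 50
  carrier <- runif(n, 0.05, 0.9)             # variant-carrier cell fraction
  depthNoise <- rnorm(n, 0, 0.02)
  cpim <- matrix(carrier, n, 1,
                 dimnames = list(sprintf("s%02d", 1:n), "butyrate"))
  ab <- matrix(pmax(0, 3 * carrier + depthNoise), n, 1,
               dimnames = list(rownames(cpim), "butyrate.P1"))
  rho <- cpiPathwayCorrelation(cpim, ab)$rho
  expect_gt(rho, 0.9)
})

test_that("dominant generated variant is dominant in computed abundance", {
  spec <- fixtureSpec(17, nSamples = 12, wgsDepth = 2e5)
  ref <- generateReferenceCollection(spec)
  wgs <- generateWgsDataset(ref, spec)
  f <- tmmFactors(wgs$geneCounts, wgs$coreGenes)
  norm <- normalizeCounts(wgs$geneCounts, f)
  ab <- pathwayAbundance(norm, pathwaySignatures(loadPathwayDefinitions()))
  # compare within propionate variants (distinct per-variant signatures);
  # the P3* sub-label shares the P3 gene signature, so its carriage folds in
  carr <- wgs$carriage
  if ("propionate.P3*" %in% colnames(carr)) {
    if ("propionate.P3" %in% colnames(carr))
      carr[, "propionate.P3"] <- carr[, "propionate.P3"] +
        carr[, "propionate.P3*"]
    else colnames(carr)[colnames(carr) == "propionate.P3*"] <-
        "propionate.P3"
  }
  ents <- intersect(colnames(carr),
                    c("propionate.P1", "propionate.P2", "propionate.P3"))
  skip_if(length(ents) < 2)
  # a variant's summed gene abundance scales with the expected number of
  # variant-specific genes per carrier; divide it out before comparing
  ps <- loadPathwayDefinitions()
  sig <- pathwaySignatures(ps)$propionate
  perCarrier <- vapply(ents, function(e) {
    lab <- sub("^propionate\\.", "", e)
    def <- Filter(function(d) d$product == "propionate" && d$label == lab,
                  ps@definitions)[[1L]]
    own <- Filter(function(g)
      all(unlist(g$alternatives) %in% sig[[lab]]), def$groups)
    sum(vapply(own, function(g) mean(lengths(g$alternatives)), 0))
  }, 0)
  abAdj <- sweep(ab[, ents, drop = FALSE], 2L, perCarrier, "/")
  agree <- vapply(rownames(ab), function(s) {
    names(which.max(carr[s, ents])) == names(which.max(abAdj[s, ents]))
  }, NA)
  expect_gte(mean(agree), 0.95)
})
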