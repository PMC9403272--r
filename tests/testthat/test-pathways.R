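test_that("default config encodes the published variant inventory", {
  ps <- loadPathwayDefinitions()
  prods <- vapply(ps@definitions, `[[`, "", "product")
  expect_equal(sum(prods == "butyrate"), 4L)
  expect_equal(sum(prods == "propionate"), 3L)
  expect_equal(sum(prods %in% c("acetate", "formate",
                                "L-lactate", "D-lactate")), 4L)
  expect_setequal(pathwayProducts(ps), scfaPhenotypes())
  # butyrate variants all include the shared universal + terminal groups
  but <- Filter(function(d) d$product == "butyrate", ps@definitions)
  for (d in but)
    expect_true(any(vapply(d$groups, function(g)
      "Bcd-EtfAB" %in% unlist(g$alternatives), NA)))
})

test_that("config errors: empty, undeclared role, duplicate label", {
  empty <- withr::local_tempfile(fileext = ".yaml")
  writeLines("catalogue: []\npathways: {}", empty)
  expect_length(loadPathwayDefinitions(empty)@definitions, 0L)

  bad <- withr::local_tempfile(fileext = ".yaml")
  writeLines(c("catalogue:",
               "  - {role: Abc}",
               "pathways:",
               "  acetate:",
               "    variants:",
               "      A:",
               "        groups: [Abc, Xyz]"), bad)
  expect_error(loadPathwayDefinitions(bad), "Xyz")

  dup <- withr::local_tempfile(fileext = ".yaml")
  writeLines(c("catalogue:",
               "  - {role: Abc}",
               "pathways:",
               "  acetate:",
               "    variants:",
               "      A: {groups: [Abc]}",
               "      A: {groups: [Abc]}"), dup)
  expect_error(loadPathwayDefinitions(dup))

  # the same label under two different products is fine
  ok <- withr::local_tempfile(fileext = ".yaml")
  writeLines(c("catalogue:",
               "  - {role: Abc}",
               "pathways:",
               "  acetate:",
               "    variants:",
               "      A: {groups: [Abc]}",
               "  formate:",
               "    variants:",
               "      A: {groups: [Abc]}"), ok)
  expect_length(loadPathwayDefinitions(ok)@definitions, 2L)
})

test_that("variant calling follows the rule grammar", {
  ps <- loadPathwayDefinitions()
  expect_equal(
    callPathwayVariants(c("Thl", "Hbd", "Crt", "Bcd-EtfAB", "But"),
                        ps)$butyrate, "P1")
  expect_length(callPathwayVariants(c("Thl", "Hbd", "Crt"), ps)$butyrate, 0L)
  expect_equal(
    callPathwayVariants(c("PduC2", "PduD2", "PduP", "PduL", "PduW"),
                        ps)$propionate, "P3*")
  # with the B12-dependent dehydratase also present, the plain label wins
  expect_equal(
    callPathwayVariants(c("PduCDE", "PduC2", "PduD2", "PduP", "PduL",
                          "PduW"), ps)$propionate, "P3")
})

test_that("OR-group members are interchangeable", {
  ps <- loadPathwayDefinitions()
  base <- c("Thl", "Hbd", "Crt", "Bcd-EtfAB")
  terminals <- list("But", "CtfAB", c("Ptb", "Buk"))
  calls <- lapply(terminals, function(t)
    callPathwayVariants(c(base, t), ps))
  for (cl in calls) expect_equal(cl$butyrate, "P1")
  expect_equal(calls[[1]], calls[[2]])
  expect_equal(calls[[1]], calls[[3]])
})

test_that("calls are monotone in the role set and match the brute-force oracle", {
  ps <- loadPathwayDefinitions()
  allRoles <- ps@catalogue$role
  set.seed(101)
  for (rep in 1:40) {
    roles <- sample(allRoles, sample(0:12, 1))
    calls <- callPathwayVariants(roles, ps)
    # brute-force oracle agreement (sub-labels stripped on both sides)
    oracle <- bruteCallVariants(roles, ps)
    for (p in names(calls)) {
      expect_equal(stripSub(calls[[p]]),
                   stripSub(if (is.null(oracle[[p]])) character()
                            else oracle[[p]]))
    }
    # monotonicity: adding one role never removes a call
    extra <- sample(setdiff(allRoles, roles), 1)
    grown <- callPathwayVariants(c(roles, extra), ps)
    for (p in names(calls))
      expect_true(all(stripSub(calls[[p]]) %in% stripSub(grown[[p]])))
  }
})

test_that("relaxed mode waives the propionate CoA-transferase group", {
  roles <- c("MutAB", "Mce", "MmdABCDE")   # no PST, no AarC
  strict <- callPathwayVariants(roles, loadPathwayDefinitions())
  relaxed <- callPathwayVariants(roles,
                                 loadPathwayDefinitions(relaxed = TRUE))
  expect_length(strict$propionate, 0L)
  expect_equal(relaxed$propionate, "P1")
})

test_that("binary phenotypes derive from variant calls", {
  ps <- loadPathwayDefinitions()
  ph <- assignBinaryPhenotypes(callPathwayVariants(c("Pta", "AckA"), ps))
  expect_equal(unname(ph[scfaPhenotypes()]), c(0L, 0L, 1L, 0L, 0L, 0L))
  expect_true(all(assignBinaryPhenotypes(
    callPathwayVariants(character(), ps)) == 0L))
  expect_equal(assignBinaryPhenotypes(
    list(butyrate = c("P1", "P3")))[["butyrate"]], 1L)
})

test_that("buildBpm assembles canonical rows", {
  ps <- loadPathwayDefinitions()
  p1 <- rolesForVariant(ps, "butyrate", "P1")
  all4 <- unique(c(rolesForVariant(ps, "butyrate", "P1"),
                   rolesForVariant(ps, "butyrate", "P2"),
                   rolesForVariant(ps, "butyrate", "P3"),
                   rolesForVariant(ps, "butyrate", "P4")))
  frm <- makeFrm(list(gA = p1, gB = character(), gC = all4),
                 catalogueRoles = ps@catalogue$role)
  bpm <- buildBpm(frm, ps)
  expect_equal(variantCalls(bpm)["gA", "butyrate"], "P1")
  expect_true(all(phenotypeMatrix(bpm)["gB", ] == 0L))
  expect_equal(variantCalls(bpm)["gC", "butyrate"], "P1+P2+P3+P4")
  expect_true(all(phenotypeMatrix(bpm) %in% c(0L, 1L)))
  # binary closure: phenotype 1 <=> non-empty variant set, per row
  expect_identical(phenotypeMatrix(bpm) == 1L, variantCalls(bpm) != "")
  # duplicate genome ids refuse to build
  m <- roleMatrix(frm)
  rownames(m) <- c("gA", "gA", "gC")
  expect_error(FunctionalRoleMatrix(m, exampleTaxonomy(c("gA", "gB", "gC"))),
               "duplicate genome_id")
})

test_that("variant distribution summary partitions producers", {
  phen <- matrix(0L, 3, 6, dimnames = list(c("g1", "g2", "g3"),
                                           scfaPhenotypes()))
  phen[, "butyrate"] <- 1L
  v <- matrix("", 3, 6, dimnames = dimnames(phen))
  v[, "butyrate"] <- c("P1", "P1", "P1+P2")
  bpm <- new("BinaryPhenotypeMatrix", phenotypes = phen, variants = v,
             taxonomy = exampleTaxonomy(rownames(phen),
                                        species = c("s1", "s1", "undefined")))
  tab <- summarizeVariantDistribution(bpm, products = "butyrate")
  expect_equal(tab$n_genomes[tab$combination == "P1"], 2L)
  expect_equal(tab$n_genomes[tab$combination == "P1+P2"], 1L)
  expect_equal(tab$n_genomes[tab$combination == "Total"], 3L)
  # undefined species counts genomes but not species
  expect_equal(tab$n_species[tab$combination == "Total"], 1L)
  expect_equal(tab$n_species[tab$combination == "P1+P2"], 0L)
})

test_that("P3* is reported in calls but collapses in summaries", {
  ps <- loadPathwayDefinitions()
  frm <- makeFrm(list(g1 = c("PduC2", "PduD2", "PduP", "PduL", "PduW")),
                 catalogueRoles = ps@catalogue$role)
  bpm <- buildBpm(frm, ps)
  expect_equal(variantCalls(bpm)["g1", "propionate"], "P3*")
  expect_equal(variantCalls(bpm, collapseSub = TRUE)["g1", "propionate"],
               "P3")
  expect_equal(phenotypeMatrix(bpm)["g1", "propionate"], 1L)
  tab <- summarizeVariantDistribution(bpm, products = "propionate")
  expect_true("P3" %in% tab$combination)
  expect_false("P3*" %in% tab$combination)
})
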