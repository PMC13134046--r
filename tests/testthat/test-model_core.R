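# Model representation, GPR logic, I/O round trips and curation checks.

test_that("GPR parsing, deparsing and evaluation follow boolean semantics", {
  g <- parseGPR("(g1 and g2) or g3")
  expect_equal(g$op, "or")
  expect_equal(gprToString(g), "(g1 and g2) or g3")
  expect_setequal(gprGenes(g), c("g1", "g2", "g3"))

  expect_true(evaluateGPR(g, knockedOut = "g1"))          # g3 branch alive
  expect_false(evaluateGPR(parseGPR("g1 and g2"), "g2"))
  expect_true(evaluateGPR(NULL, "g1"))                    # no gene association
  expect_false(evaluateGPR(g, c("g1", "g3")))
  expect_false(evaluateGPR(g, c("g2", "g3")))

  # symbolic operators and case-insensitivity
  expect_equal(gprToString(parseGPR("a && (b || c)")), "a and (b or c)")
  expect_warning(evaluateGPR(parseGPR("gx"), genes = c("g1")),
                 "absent from the model")
  expect_error(parseGPR("g1 and (g2"), "missing")
})

test_that("GPR evaluation agrees with exhaustive truth-table enumeration", {
  set.seed(11)
  randomGPR <- function(genes, depth = 0) {
    if (depth > 2 || runif(1) < 0.4) return(sample(genes, 1))
    k <- sample(2:3, 1)
    list(op = sample(c("and", "or"), 1),
         args = replicate(k, randomGPR(genes, depth + 1), simplify = FALSE))
  }
  evalRef <- function(gpr, states) {   # independent recursive oracle over env
    if (is.character(gpr)) return(states[[gpr]])
    vals <- vapply(gpr$args, evalRef, NA, states = states)
    if (gpr$op == "and") all(vals) else any(vals)
  }
  for (trial in 1:25) {
    gs <- paste0("g", 1:sample(2:8, 1))
    gpr <- randomGPR(gs)
    used <- gprGenes(gpr)
    combos <- expand.grid(rep(list(c(TRUE, FALSE)), length(used)))
    names(combos) <- used
    for (i in seq_len(nrow(combos))) {
      states <- as.list(combos[i, , drop = FALSE])
      knocked <- used[!unlist(states)]
      expect_identical(evaluateGPR(gpr, knocked), evalRef(gpr, states))
    }
    # round trip through text form preserves semantics
    expect_identical(gprToString(parseGPR(gprToString(gpr))), gprToString(gpr))
  }
})

test_that("equation dialect parses exchanges, coefficients and directions", {
  m <- MetabolicModel("t", data.frame(
    id = c("EX_glc", "R1"),
    equation = c("glc_e <=> ", "A + 2 B -> C"), stringsAsFactors = FALSE))
  S <- stoichiometry(m)
  expect_equal(S["A", "R1"], -1)
  expect_equal(S["B", "R1"], -2)
  expect_equal(S["C", "R1"], 1)
  rxn <- reactions(m)
  expect_true(rxn$exchange[rxn$id == "EX_glc"])
  expect_equal(rxn$lb[rxn$id == "EX_glc"], -1000)   # reversible arrow
  expect_equal(rxn$lb[rxn$id == "R1"], 0)
  expect_error(MetabolicModel("t", data.frame(id = "R", equation = "A  B")),
               "no arrow")
  expect_error(MetabolicModel("t", data.frame(id = "R", equation = "0 A -> B")),
               "zero stoichiometric")
})

test_that("SBML round trip preserves the model field by field", {
  sc <- makeToyAnaerobe(1)
  path <- withr::local_tempfile(fileext = ".xml")
  writeSBMLModel(sc@model, path)
  m2 <- readSBMLModel(path)
  expect_identical(reactions(sc@model), reactions(m2))
  expect_identical(metabolites(sc@model), metabolites(m2))
  expect_identical(genes(sc@model), genes(m2))
  expect_identical(objectiveReaction(m2), "BIOMASS")
  expect_true(all(stoichiometry(sc@model) == stoichiometry(m2)))
  # GPR tree with OR root survives
  expect_equal(gprToString(gpr(m2, "AB3CL")), "gAB3CL1 or gAB3CL2")
  # bounds preserved exactly, including (-1000, 1000)
  expect_identical(reactions(m2)$lb, reactions(sc@model)$lb)
  # model with empty GPRs writes without gene-association blocks
  plain <- chainModel()
  p2 <- withr::local_tempfile(fileext = ".xml")
  writeSBMLModel(deactivateReactions(plain, character(0)), p2)
  expect_silent(readSBMLModel(p2))
  expect_error(readSBMLModel(withr::local_tempfile(fileext = ".xml")))
})

test_that("SBML reader tolerates FBC v1 and kineticLaw bound dialects", {
  v1 <- '<?xml version="1.0"?>
  <sbml xmlns="http://www.sbml.org/sbml/level3/version1/core"
        xmlns:fbc="http://www.sbml.org/sbml/level3/version1/fbc/version1"
        level="3" version="1">
   <model id="legacy">
    <listOfCompartments><compartment id="c" constant="true"/></listOfCompartments>
    <listOfSpecies><species id="A" compartment="c" constant="false"
      boundaryCondition="false" hasOnlySubstanceUnits="false"/></listOfSpecies>
    <fbc:listOfFluxBounds>
      <fbc:fluxBound fbc:reaction="R1" fbc:operation="greaterEqual" fbc:value="-7"/>
      <fbc:fluxBound fbc:reaction="R1" fbc:operation="lessEqual" fbc:value="4"/>
    </fbc:listOfFluxBounds>
    <listOfReactions>
     <reaction id="R1" reversible="true" fast="false">
      <listOfReactants>
        <speciesReference species="A" stoichiometry="1" constant="true"/>
      </listOfReactants>
     </reaction>
     <reaction id="R2" reversible="false" fast="false">
      <listOfProducts>
        <speciesReference species="A" stoichiometry="1" constant="true"/>
      </listOfProducts>
      <kineticLaw><math/>
        <listOfLocalParameters>
          <localParameter id="LOWER_BOUND" value="0"/>
          <localParameter id="UPPER_BOUND" value="123"/>
        </listOfLocalParameters>
      </kineticLaw>
     </reaction>
    </listOfReactions>
   </model></sbml>'
  path <- withr::local_tempfile(fileext = ".xml")
  writeLines(v1, path)
  m <- readSBMLModel(path)
  rxn <- reactions(m)
  expect_equal(rxn$lb[rxn$id == "R1"], -7)
  expect_equal(rxn$ub[rxn$id == "R1"], 4)
  expect_equal(rxn$ub[rxn$id == "R2"], 123)
})

test_that("TSV tables round trip and agree with the SBML path", {
  sc <- makeToyAnaerobe(1)
  dir <- withr::local_tempdir()
  writeModelTables(sc@model, dir)
  m3 <- readModelTables(dir)
  keep <- c("id", "lb", "ub", "gpr", "subsystem", "spontaneous", "exchange")
  expect_identical(reactions(sc@model)[keep], reactions(m3)[keep])
  expect_true(all(stoichiometry(sc@model)[metabolites(m3)$id, ] ==
                    stoichiometry(m3)))
  # cross-format: same model via SBML and TSV give identical structures
  xml <- withr::local_tempfile(fileext = ".xml")
  writeSBMLModel(sc@model, xml)
  m2 <- readSBMLModel(xml)
  expect_identical(reactions(m2)[keep], reactions(m3)[keep])
  expect_error(readModelTables(withr::local_tempdir()), "missing reactions.tsv")
})

test_that("mass/charge balance reports imbalances but not unverifiable reactions", {
  m <- MetabolicModel("bal", data.frame(
    id = c("EX_a", "OK", "BAD", "UNK"),
    equation = c("A_e <=>", "A -> B", "A -> C", "A -> D"),
    stringsAsFactors = FALSE),
    metabolites = data.frame(
      id = c("A_e", "A", "B", "C", "D"),
      compartment = c("e", "c", "c", "c", "c"),
      formula = c("CH4", "CH4", "CH4", "CH3", NA),
      charge = c(0, 0, 0, 1, NA)))
  rep <- checkMassChargeBalance(m)
  expect_named(rep$imbalanced, "BAD")
  expect_equal(rep$imbalanced$BAD[["H"]], -1)
  expect_equal(rep$imbalanced$BAD[["charge"]], 1)
  expect_equal(rep$unverifiable, "UNK")
  # exchange reactions are excluded by design
  expect_false("EX_a" %in% names(rep$imbalanced))
  # sums of balanced half-reactions stay balanced
  m2 <- MetabolicModel("bal2", data.frame(
    id = "SUM", equation = "2 A -> B + C2", stringsAsFactors = FALSE),
    metabolites = data.frame(id = c("A", "B", "C2"),
                             compartment = "c",
                             formula = c("CH4", "CH4", "CH4"),
                             charge = c(0, 0, 0)))
  expect_length(checkMassChargeBalance(m2)$imbalanced, 0)
  expect_error(checkMassChargeBalance(chainModel()), "no metabolite has a formula")
})

test_that("model summary counts reactions by subsystem and gene association", {
  sc <- makeToyAnaerobe(1)
  s <- modelSummary(sc@model)
  expect_equal(s$nReactions, nrow(reactions(sc@model)))
  expect_equal(s$nGenes, length(genes(sc@model)))
  sub <- s$subsystems
  tr <- sub[sub$subsystem == "Transport", ]
  # spontaneous transporters have no GPR and count as non-gene-associated
  expect_gt(tr$nonGeneAssociated, 0)
  expect_gt(tr$geneAssociated, 0)
  expect_equal(sum(sub$total), s$nReactions)
})

test_that("blocked reactions are found and invariant to reaction order", {
  sc <- makeToyAnaerobe(1)
  blocked <- findBlockedReactions(sc@model, sc@medium)
  expect_setequal(blocked, sc@groundTruth$blockedReactions)
  # dead-end metabolite path is blocked; producing chain is not
  m <- MetabolicModel("dead", data.frame(
    id = c("EX_a", "T1", "DEAD", "BIO"),
    equation = c("a_e <=>", "a_e -> a_c", "a_c -> x_c", "a_c ->"),
    stringsAsFactors = FALSE), objective = "BIO")
  med <- Medium(data.frame(exchange_id = "EX_a", lb = -10, ub = 1000))
  expect_setequal(findBlockedReactions(m, med), "DEAD")
  # relabeling reaction order leaves the blocked set unchanged
  tb <- data.frame(
    id = c("DEAD", "EX_a", "BIO", "T1"),
    equation = c("a_c -> x_c", "a_e <=>", "a_c ->", "a_e -> a_c"),
    stringsAsFactors = FALSE)
  m2 <- MetabolicModel("dead2", tb, objective = "BIO")
  expect_setequal(findBlockedReactions(m2, med), "DEAD")
})

test_that("model validity catches broken invariants", {
  expect_error(MetabolicModel("dup", data.frame(
    id = c("R1", "R1"), equation = c("A -> B", "A -> C"))), "duplicated")
  m <- chainModel()
  expect_error(setReactionBounds(m, "T1", lb = 5, ub = 1),
               "lower bound above upper")
  expect_error(setReactionBounds(m, "NOPE", lb = 0), "unknown reaction")
  expect_error({objectiveReaction(m) <- "NOPE"}, "objective")
})
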