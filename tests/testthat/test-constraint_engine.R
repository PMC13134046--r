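# FBA, parsimonious FBA, FVA and essentiality.

test_that("FBA solves bottleneck chains and reports status faithfully", {
  m <- chainModel()
  s <- fba(m, chainMedium(-10))
  expect_equal(solutionStatus(s), "optimal")
  expect_equal(objectiveValue(s), 10)
  expect_equal(unname(fluxes(s)[c("EX_a", "T1", "BIO")]), c(-10, 10, 10))
  # no carbon -> zero growth
  expect_equal(objectiveValue(fba(m, chainMedium(0))), 0)
  # steady state holds
  expect_lt(max(abs(as.vector(stoichiometry(m) %*% fluxes(s)))), 1e-6)
  # forced flux with no source -> infeasible, empty fluxes
  m2 <- setReactionBounds(m, "BIO", lb = 5)
  s2 <- fba(m2, chainMedium(0))
  expect_equal(solutionStatus(s2), "infeasible")
  expect_length(fluxes(s2), 0)
})

test_that("FBA picks the best of parallel routes (vertex oracle agrees)", {
  m <- parallelModel()
  med <- chainMedium(-10)
  s <- fba(m, med)
  expect_equal(objectiveValue(s), 10)    # yield-1 route wins
  lp <- gutGEM:::.lpData(applyMedium(m, med))
  or <- vertexOptimum(gutGEM:::.objVector(applyMedium(m, med), NULL),
                      lp$S, lp$lb, lp$ub)
  expect_equal(objectiveValue(s), or$objval, tolerance = 1e-12)
})

test_that("pFBA keeps the FBA optimum and minimizes total flux", {
  med <- chainMedium(-10)
  # equal-yield routes: total |v| equals the single-route minimum
  m <- equalRoutesModel()
  p <- pfba(m, med)
  expect_equal(objectiveValue(p), objectiveValue(fba(m, med)),
               tolerance = 1e-9)
  v <- fluxes(p)
  expect_equal(abs(v[["R1"]]) + abs(v[["R2"]]), 10)
  expect_equal(sum(abs(v)), 30)
  # feasible internal cycle carries zero flux under pFBA
  mc <- MetabolicModel("cyc", data.frame(
    id = c("EX_a", "T1", "C1", "C2", "BIO"),
    equation = c("a_e <=>", "a_e -> a_c", "a_c <=> x_c", "x_c <=> a_c",
                 "a_c ->"), stringsAsFactors = FALSE), objective = "BIO")
  pc <- pfba(mc, med)
  expect_equal(unname(abs(fluxes(pc)[c("C1", "C2")])), c(0, 0))
  # single-route chain: pFBA equals FBA
  s1 <- fba(chainModel(), med); p1 <- pfba(chainModel(), med)
  expect_equal(fluxes(p1), fluxes(s1))
})

test_that("FVA brackets the optimum and is monotone in the fraction", {
  m <- chainModel(); med <- chainMedium(-10)
  r1 <- fluxRanges(fva(m, med, fraction = 1))
  expect_equal(r1$min, r1$max, tolerance = 1e-9)   # unique flux at 100%
  r9 <- fluxRanges(fva(m, med, fraction = 0.9))
  expect_equal(r9[r9$reaction_id == "BIO", c("min", "max")],
               data.frame(min = 9, max = 10, row.names = 3L),
               tolerance = 1e-9)
  # lowering the fraction never narrows a range
  r5 <- fluxRanges(fva(m, med, fraction = 0.5))
  expect_true(all(r5$min <= r9$min + 1e-9 & r5$max >= r9$max - 1e-9))
  # parallel equal routes: each spans [0, full], sum constrained
  re <- fluxRanges(fva(equalRoutesModel(), med, fraction = 1))
  expect_equal(re[re$reaction_id %in% c("R1", "R2"), "min"], c(0, 0))
  expect_equal(re[re$reaction_id %in% c("R1", "R2"), "max"], c(10, 10))
  # pFBA fluxes lie inside FVA ranges at any fraction
  sc <- makeToyAnaerobe(1)
  v <- fluxes(pfba(sc@model, sc@medium))
  for (f in c(0.9, 1)) {
    rr <- fluxRanges(fva(sc@model, sc@medium, fraction = f))
    expect_true(all(v[rr$reaction_id] >= rr$min - 1e-6 &
                      v[rr$reaction_id] <= rr$max + 1e-6))
  }
  expect_error(fva(m, med, fraction = 0), "fraction > 0")
})

test_that("gene deletion essentiality follows the GPR truth table", {
  med <- chainMedium(-10)
  # sole path guarded by "g1 and g2": both essential
  d <- singleGeneDeletion(chainModel(), med)
  expect_true(all(d$essential))
  expect_equal(d$growth, c(0, 0))
  # "g1 or g2": neither essential alone
  mo <- MetabolicModel("or", data.frame(
    id = c("EX_a", "T1", "BIO"),
    equation = c("a_e <=>", "a_e -> a_c", "a_c ->"),
    gpr = c(NA, "g1 or g2", NA), stringsAsFactors = FALSE),
    objective = "BIO")
  do <- singleGeneDeletion(mo, med)
  expect_false(any(do$essential))
  # gene in no GPR: growth equals wild type
  mg <- MetabolicModel("free", data.frame(
    id = c("EX_a", "T1", "BIO"),
    equation = c("a_e <=>", "a_e -> a_c", "a_c ->"),
    gpr = c(NA, "g1", NA), stringsAsFactors = FALSE),
    genes = c("g1", "g_unused"), objective = "BIO")
  dg <- singleGeneDeletion(mg, med)
  expect_equal(dg$growth[dg$gene == "g_unused"], 10)
  expect_false(dg$essential[dg$gene == "g_unused"])
  # zero wild-type growth is an error
  expect_error(singleGeneDeletion(chainModel(), chainMedium(0)),
               "essentiality is undefined")
})

test_that("reaction deletion flags bottlenecks but not redundant or blocked steps", {
  med <- chainMedium(-10)
  d <- singleReactionDeletion(chainModel(), med)
  expect_true(d$essential[d$reaction_id == "T1"])
  de <- singleReactionDeletion(equalRoutesModel(), med)
  expect_false(de$essential[de$reaction_id == "R1"])   # parallel route
  # blocked reaction: non-essential, growth unchanged
  mb <- MetabolicModel("blk", data.frame(
    id = c("EX_a", "T1", "DEAD", "BIO"),
    equation = c("a_e <=>", "a_e -> a_c", "a_c -> x_c", "a_c ->"),
    stringsAsFactors = FALSE), objective = "BIO")
  db <- singleReactionDeletion(mb, med)
  expect_false(db$essential[db$reaction_id == "DEAD"])
  expect_equal(db$growth[db$reaction_id == "DEAD"], 10)
})

test_that("gene essentials cover reactions essential under single-gene GPRs", {
  sc <- makeToyAnaerobe(1)
  gd <- singleGeneDeletion(sc@model, sc@medium)
  rd <- singleReactionDeletion(sc@model, sc@medium)
  ess_rxn <- rd$reaction_id[rd$essential]
  for (r in ess_rxn) {
    g <- gpr(sc@model, r)
    if (!is.null(g) && is.character(g))     # single-gene GPR
      expect_true(gd$essential[gd$gene == g],
                  label = paste("gene", g, "for reaction", r))
  }
})

test_that("engine matches cobrapy on the toy anaerobe (independent implementation)", {
  # cobrapy + libsbml + GLPK are an entirely separate code path; agreement
  # validates both the SBML writer and the LP core
  sc <- makeToyAnaerobe(1)
  m <- applyMedium(sc@model, sc@medium)
  xml <- withr::local_tempfile(fileext = ".xml")
  out <- withr::local_tempfile(fileext = ".json")
  writeSBMLModel(m, xml)
  script <- sprintf('
import json, cobra, numpy as np
cobra.Configuration().solver = "glpk"
m = cobra.io.read_sbml_model("%s")
sol = m.optimize()
p = cobra.flux_analysis.pfba(m)
json.dump({"fba": sol.objective_value,
           "pfba_total": float(np.abs(p.fluxes).sum()),
           "n": len(m.reactions)}, open("%s", "w"))
', xml, out)
  py <- withr::local_tempfile(fileext = ".py")
  writeLines(script, py)
  res <- system2("python", py, stdout = TRUE, stderr = TRUE)
  expect_true(file.exists(out), info = paste(res, collapse = "\n"))
  ref <- jsonlite::fromJSON(out)
  expect_equal(ref$n, nrow(reactions(m)))
  expect_equal(objectiveValue(fba(m)), ref$fba, tolerance = 1e-6)
  expect_equal(sum(abs(fluxes(pfba(m)))), ref$pfba_total, tolerance = 1e-6)
})
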