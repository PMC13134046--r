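# Community assembly, abundance-weighted simulation, cross-feeding.

test_that("single-member community reproduces the monoculture optimum", {
  cm <- makeToyCommunity(1)
  one <- buildCommunity(cm@members["D"], 1)
  mono <- objectiveValue(suppressWarnings(fba(cm@members$D, cm@medium)))
  comm <- suppressWarnings(communityFBA(one, cm@medium))
  expect_equal(comm$communityGrowth, mono, tolerance = 1e-9)
  expect_equal(unname(comm$memberGrowth["D"]), mono, tolerance = 1e-9)
})

test_that("community assembly is block-diagonal with a shared pool", {
  cm <- makeToyCommunity(1)
  comm <- buildCommunity(cm@members, cm@abundances)
  merged <- mergedModel(comm)
  met <- metabolites(merged)
  # member internals are namespaced; only pool metabolites live in 'e'
  expect_true(all(grepl("__", met$id[met$compartment != "e"])))
  expect_false(any(grepl("__", met$id[met$compartment == "e"])))
  # no internal metabolite is shared across members
  internals <- met$id[met$compartment != "e"]
  expect_true(all(table(sub("__.*", "", internals)) > 0))
  # abundances must normalize; zero abundance is rejected
  expect_warning(buildCommunity(cm@members, c(1, 1, 2)), "normalizing")
  expect_error(buildCommunity(cm@members, c(0.5, 0.5, 0)), "positive")
  # pool mass balance: transfers plus community exchange close
  sol <- suppressWarnings(communityFBA(comm, cm@medium, parsimonious = TRUE))
  v <- fluxes(sol$solution)
  tr <- transferReactions(comm)
  for (met1 in unique(tr$metabolite)) {
    inflow <- sum(v[tr$reaction_id[tr$metabolite == met1]])
    outflow <- v[[paste0("EX_", met1)]]
    expect_equal(inflow, outflow, tolerance = 1e-6)
  }
})

test_that("two members with disjoint substrates add up; syntrophy needs both", {
  # disjoint substrates: community optimum = weighted sum of monocultures
  mA <- MetabolicModel("A", data.frame(
    id = c("EX_a_e", "Ta", "BIO"),
    equation = c("a_e <=>", "a_e -> x_c", "x_c ->"),
    stringsAsFactors = FALSE), objective = "BIO")
  mB <- MetabolicModel("B", data.frame(
    id = c("EX_b_e", "Tb", "BIO"),
    equation = c("b_e <=>", "b_e -> x_c", "x_c ->"),
    stringsAsFactors = FALSE), objective = "BIO")
  med <- Medium(data.frame(exchange_id = c("EX_a_e", "EX_b_e"),
                           lb = c(-10, -6), ub = 1000))
  comm <- buildCommunity(list(A = mA, B = mB), c(0.5, 0.5))
  res <- suppressWarnings(communityFBA(comm, med))
  monoA <- objectiveValue(suppressWarnings(fba(mA, med)))
  monoB <- objectiveValue(suppressWarnings(fba(mB, med)))
  # substrates limited by the shared medium: each member reaches its
  # monoculture optimum and the community objective is the weighted sum
  expect_equal(res$communityGrowth, 0.5 * monoA + 0.5 * monoB,
               tolerance = 1e-9)
  expect_equal(unname(res$memberGrowth), c(monoA, monoB), tolerance = 1e-9)
  # producer/consumer pair: B grows only on A's by-product
  pA <- MetabolicModel("P", data.frame(
    id = c("EX_a_e", "Ta", "FERM", "Wex", "EX_w_e", "BIO"),
    equation = c("a_e <=>", "a_e -> a_c", "a_c -> x_c + w_c", "w_c -> w_e",
                 "w_e <=>", "x_c ->"),
    lb = c(NA, NA, NA, NA, 0, NA), stringsAsFactors = FALSE),
    objective = "BIO")
  pB <- MetabolicModel("Q", data.frame(
    id = c("EX_w_e", "Tw", "BIO"),
    equation = c("w_e <=>", "w_e -> y_c", "y_c ->"),
    ub = c(0, NA, NA), stringsAsFactors = FALSE), objective = "BIO")
  medA <- Medium(data.frame(exchange_id = "EX_a_e", lb = -10, ub = 1000))
  expect_equal(objectiveValue(suppressWarnings(fba(pB, medA))), 0)   # starves alone
  duo <- buildCommunity(list(P = pA, Q = pB), c(0.5, 0.5))
  rduo <- suppressWarnings(communityFBA(duo, medA))
  expect_gt(unname(rduo$memberGrowth["Q"]), 0)     # fed by P in community
})

test_that("community FVA widens with lower fractions and respects scope", {
  cm <- makeToyCommunity(1)
  comm <- buildCommunity(cm@members, cm@abundances)
  r9 <- fluxRanges(suppressWarnings(communityFVA(comm, cm@medium, 0.9)))
  r1 <- fluxRanges(suppressWarnings(communityFVA(comm, cm@medium, 1.0)))
  both <- merge(r9, r1, by = "reaction_id", suffixes = c(".9", ".1"))
  expect_true(all(both$min.9 <= both$min.1 + 1e-9))
  expect_true(all(both$max.9 >= both$max.1 - 1e-9))
  # default scope is transfers + community exchanges
  expect_setequal(r9$reaction_id,
                  c(transferReactions(comm)$reaction_id, comm@exchanges))
  # obligate cross-feeding: near the optimum U must import acetaldehyde
  r99 <- fluxRanges(suppressWarnings(communityFVA(
    comm, cm@medium, 0.999, reactions = "U__EX_acald_e")))
  expect_lt(r99$max, 0)
})

test_that("cross-feeding inference recovers the engineered edges exactly", {
  cm <- makeToyCommunity(1)
  comm <- buildCommunity(cm@members, cm@abundances)
  edges <- suppressWarnings(
    inferCrossFeeding(comm, medium = cm@medium, fraction = 0.9))
  got <- edges[order(edges$species, edges$metabolite),
               c("species", "metabolite", "direction")]
  exp <- cm@groundTruth$edges[order(cm@groundTruth$edges$species,
                                    cm@groundTruth$edges$metabolite), ]
  rownames(got) <- rownames(exp) <- NULL
  expect_identical(got, exp)
  expect_setequal(attr(edges, "crossFed"), cm@groundTruth$crossFed)
  # direction invariants: production needs max > 0, consumption min < 0
  expect_true(all(edges$flux_max[edges$direction == "production"] > 1e-6))
  expect_true(all(edges$flux_min[edges$direction == "consumption"] < -1e-6))
  expect_true(all(edges$flux_min[edges$direction == "both"] < -1e-6 &
                    edges$flux_max[edges$direction == "both"] > 1e-6))
})

test_that("the community as a whole outgrows its members' solo efforts", {
  cm <- makeToyCommunity(1)
  comm <- buildCommunity(cm@members, cm@abundances)
  res <- suppressWarnings(communityFBA(comm, cm@medium, parsimonious = TRUE))
  expect_true(all(res$memberGrowth > 0))          # every guild grows
  expect_equal(objectiveValue(suppressWarnings(fba(cm@members$U, cm@medium))), 0)
  expect_equal(objectiveValue(suppressWarnings(fba(cm@members$S, cm@medium))), 0)
  # U and S are obligate community members; butyrate comes from U alone
  v <- fluxes(res$solution)
  expect_gt(v[["U__EX_but_e"]], 0)
  expect_equal(sum(grepl("EX_but", transferReactions(comm)$reaction_id[
    transferReactions(comm)$species != "U"])), 0)
  # near-degenerate abundance wipes out the minor members
  tiny <- buildCommunity(cm@members, c(0.98, 0.01, 0.01))
  rt <- suppressWarnings(communityFBA(tiny, cm@medium))
  expect_lt(unname(rt$memberGrowth["S"]), 0.1)
  expect_lt(unname(rt$memberGrowth["U"]), 0.1)
})

test_that("networks export as SIF and GraphML", {
  cm <- makeToyCommunity(1)
  comm <- buildCommunity(cm@members, cm@abundances)
  edges <- suppressWarnings(
    inferCrossFeeding(comm, medium = cm@medium, fraction = 0.9))
  sif <- withr::local_tempfile(fileext = ".sif")
  exportNetwork(edges, sif, "sif")
  lines <- readLines(sif)
  expect_length(lines, nrow(edges))
  expect_true(all(grepl("\t(production|consumption|both)\t", lines)))
  gml <- withr::local_tempfile(fileext = ".graphml")
  exportNetwork(edges, gml, "graphml")
  g <- igraph::read_graph(gml, format = "graphml")
  expect_equal(igraph::ecount(g), nrow(edges))
  expect_equal(igraph::vcount(g),
               length(unique(edges$species)) +
                 length(unique(edges$metabolite)))
  # empty edge set still writes valid files
  e0 <- edges[0, ]
  exportNetwork(e0, sif, "sif")
  expect_length(readLines(sif), 0)
  exportNetwork(e0, gml, "graphml")
  expect_equal(igraph::ecount(igraph::read_graph(gml, format = "graphml")), 0)
  expect_error(exportNetwork(edges, sif, "dot"), "should be one of")
})
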