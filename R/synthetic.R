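## Seeded generators for toy scenarios with known ground truth.
##
## The toy anaerobe emulates the fermentation logic of a butyrogenic gut
## bacterium: glucose is oxidized to acetyl-CoA, excess reducing
## equivalents must leave through butyrate production (a capped
## hydrogenase is the only alternative electron valve), and the terminal
## butyrate step can run either through a CoA transferase fed by
## acetoacetate (regenerating acetoacetyl-CoA, hence energetically cheap)
## or through a lumped kinase route that wastes the thioester bond.  An
## ATP-costing lysine-degradation branch and a methylmalonyl-CoA
## propionate branch are present but carry no flux under the default
## medium -- the lysine branch activates only when its ATP cost is removed
## and the acetoacetate-fed route is disabled.

#' Generate the toy anaerobe scenario
#'
#' Builds a ~35-reaction anaerobe with competing butyrate routes
#' (CoA-transferase vs kinase terminal steps), a five-reaction lysine
#' utilization branch (ids LYSAM, DH36M, DH35O, A53C, AB3CL), a
#' methylmalonyl-CoA propionate branch (SUCCT/MMM2/MME/MMCD/PPCST), GPRs
#' on all non-spontaneous reactions, a defined gut-like medium (amino-acid
#' uptake capped at 0.5 mmol/gDW/h, cellobiose closed), and a matching
#' Gibbs-energy table with round values.  Ground truth (preferred routes,
#' essential genes, blocked reactions) is recorded in the scenario.
#'
#' @param seed integer seed (recorded; the network itself is
#'   deterministic, the seed drives the companion expression generator).
#' @param includeLysineBranch include the lysine-to-butyrate branch.
#' @param includeEGC plant a two-reaction ATP-generating cycle
#'   (EGC1/EGC2) for testing the cycle screen.
#' @param lysineATPCost ATP stoichiometry of the lysine ABC transporter
#'   (default 1; 0 removes the energetic penalty).
#' @param hydCap upper bound of the hydrogenase electron valve
#'   (mmol/gDW/h, default 1).
#' @return a [ToyScenario-class].
#' @export
makeToyAnaerobe <- function(seed = 1L, includeLysineBranch = TRUE,
                            includeEGC = FALSE, lysineATPCost = 1,
                            hydCap = 1) {
  rx <- function(id, equation, gpr = NA, subsystem = "", spontaneous = FALSE,
                 lb = NA, ub = NA)
    data.frame(id = id, equation = equation, gpr = gpr, subsystem = subsystem,
               spontaneous = spontaneous, lb = lb, ub = ub,
               stringsAsFactors = FALSE)
  rows <- rbind(
    rx("EX_glc",  "glc_e <=>",  subsystem = "Exchange"),
    rx("EX_ac",   "ac_e <=>",   subsystem = "Exchange"),
    rx("EX_acac", "acac_e <=>", subsystem = "Exchange"),
    rx("EX_succ", "succ_e <=>", subsystem = "Exchange"),
    rx("EX_nh4",  "nh4_e <=>",  subsystem = "Exchange"),
    rx("EX_but",  "but_e <=>",  subsystem = "Exchange", lb = 0),
    rx("EX_ppa",  "ppa_e <=>",  subsystem = "Exchange", lb = 0),
    rx("EX_co2",  "co2_e <=>",  subsystem = "Exchange", lb = 0),
    rx("EX_h2",   "h2_e <=>",   subsystem = "Exchange", lb = 0),
    rx("EX_cellb","cellb_e <=>", subsystem = "Exchange"),
    rx("GLCt1",  "glc_e -> glc_c", "gGLCt1", "Transport"),
    rx("GLCt2",  "glc_e -> glc_c", "gGLCt2", "Transport"),
    rx("CELLBt", "cellb_e -> cellb_c", "gCELLBt", "Transport"),
    rx("CELLBH", "cellb_c -> 2 glc_c", "gCELLBH", "Carbohydrate metabolism"),
    rx("ACACt",  "acac_e -> acac_c", "gACACt", "Transport"),
    rx("ACt",    "ac_c <=> ac_e", spontaneous = TRUE, subsystem = "Transport"),
    rx("SUCt",   "succ_e <=> succ_c", spontaneous = TRUE, subsystem = "Transport"),
    rx("NH4t",   "nh4_e <=> nh4_c", spontaneous = TRUE, subsystem = "Transport"),
    rx("CO2t",   "co2_c -> co2_e", spontaneous = TRUE, subsystem = "Transport"),
    rx("H2t",    "h2_c -> h2_e", spontaneous = TRUE, subsystem = "Transport"),
    rx("BUTt",   "but_c -> but_e", "gBUTt", "Transport"),
    rx("PPAt",   "ppa_c -> ppa_e", "gPPAt", "Transport"),
    rx("GLYC",   "glc_c + 2 adp_c + 2 pi_c + 2 nad_c -> 2 pyr_c + 2 atp_c + 2 nadh_c",
       "gGLYC", "Glycolysis"),
    rx("PDH",    "pyr_c + coa_c + nad_c -> accoa_c + co2_c + nadh_c",
       "gPDH", "Pyruvate metabolism"),
    rx("ACKr",   "accoa_c + adp_c + pi_c <=> ac_c + atp_c + coa_c",
       "gACK", "Pyruvate metabolism"),
    rx("HYD",    "nadh_c -> nad_c + h2_c", "gHYD", "Energy metabolism",
       ub = hydCap),
    rx("ACACT",  "2 accoa_c -> aacoa_c + coa_c", "gACACT", "Butyrate synthesis"),
    rx("HBD",    "aacoa_c + nadh_c -> hbcoa_c + nad_c", "gHBD", "Butyrate synthesis"),
    rx("CRT",    "hbcoa_c -> crcoa_c", "gCRT", "Butyrate synthesis"),
    rx("BCD",    "crcoa_c + nadh_c -> btcoa_c + nad_c", "gBCD", "Butyrate synthesis"),
    rx("BUTCT2", "btcoa_c + acac_c -> but_c + aacoa_c",
       "gBUTCT2a and gBUTCT2b", "Butyrate synthesis"),
    rx("BUTKr",  "btcoa_c -> but_c + coa_c", "gBUTKr", "Butyrate synthesis"),
    rx("SUCCT",  "succ_c + accoa_c -> succoa_c + ac_c", "gSUCCT",
       "Propionate synthesis"),
    rx("MMM2",   "succoa_c -> mmcoa_R_c", "gMMM2", "Propionate synthesis"),
    rx("MME",    "mmcoa_R_c <=> mmcoa_S_c", "gMME", "Propionate synthesis"),
    rx("MMCD",   "mmcoa_S_c -> ppcoa_c + co2_c", "gMMCD", "Propionate synthesis"),
    rx("PPCST",  "ppcoa_c + succ_c -> ppa_c + succoa_c", "gPPCST",
       "Propionate synthesis"),
    rx("ATPM",   "atp_c -> adp_c + pi_c", subsystem = "Maintenance", lb = 0.5),
    rx("BIOMASS","3 accoa_c + 5 atp_c + 0.5 nh4_c -> 3 coa_c + 5 adp_c + 5 pi_c",
       subsystem = "Biomass")
  )
  if (includeLysineBranch) {
    lysEq <- if (lysineATPCost > 0)
      sprintf("lys_e + %s atp_c -> lys_c + %s adp_c + %s pi_c",
              lysineATPCost, lysineATPCost, lysineATPCost)
    else "lys_e -> lys_c"
    rows <- rbind(rows,
      rx("EX_lys", "lys_e <=>", subsystem = "Exchange"),
      rx("LYSt",  lysEq, "gLYSt", "Transport"),
      rx("LYSAM", "lys_c -> blys_c", "gLYSAM", "Lysine degradation"),
      rx("DH36M", "blys_c -> dahx_c", "gDH36Ma and gDH36Mb", "Lysine degradation"),
      rx("DH35O", "dahx_c + nad_c -> kahx_c + nadh_c + nh4_c", "gDH35O",
         "Lysine degradation"),
      rx("A53C",  "kahx_c + accoa_c -> abcoa_c + acac_c", "gA53C",
         "Lysine degradation"),
      rx("AB3CL", "abcoa_c -> crcoa_c + nh4_c", "gAB3CL1 or gAB3CL2",
         "Lysine degradation"))
  }
  if (includeEGC) {
    rows <- rbind(rows,
      rx("EGC1", "egcA_c + adp_c + pi_c -> egcB_c + atp_c", "gEGC1",
         "Artifact"),
      rx("EGC2", "egcB_c -> egcA_c", "gEGC2", "Artifact"))
  }
  model <- MetabolicModel("toy_anaerobe", rows, objective = "BIOMASS")

  capRows <- data.frame(
    exchange_id = c("EX_glc", "EX_acac", "EX_succ", "EX_nh4", "EX_ac",
                    "EX_cellb"),
    lb = c(-5, -15, -1, -5, 0, 0),
    ub = rep(1000, 6), stringsAsFactors = FALSE)
  if (includeLysineBranch)
    capRows <- rbind(capRows, data.frame(exchange_id = "EX_lys",
                                         lb = -0.5, ub = 1000))
  medium <- Medium(capRows, defaultUptakePolicy = "closed")

  dg <- c(GLYC = -80, PDH = -40, ACKr = 10, HYD = -20, ACACT = 20,
          HBD = -10, CRT = 0, BCD = -40, BUTCT2 = -10, BUTKr = -40,
          SUCCT = 10, MMM2 = 0, MME = 0, MMCD = -40, PPCST = -10,
          ATPM = -50, BUTt = -10, PPAt = -10)
  if (includeLysineBranch)
    dg <- c(dg, LYSAM = -10, DH36M = -10, DH35O = 20, A53C = -40, AB3CL = -40)
  thermo <- ThermoTable(dg)

  groundTruth <- list(
    activeReactions = c("GLYC", "PDH", "BUTCT2", "HBD", "BCD", "BUTt",
                        "ACKr", "BIOMASS"),
    zeroFluxReactions = c(
      if (includeLysineBranch) c("LYSt", "LYSAM", "DH36M", "DH35O",
                                 "A53C", "AB3CL"),
      c("SUCCT", "MMM2", "MME", "MMCD", "PPCST", "BUTKr",
        "CELLBt", "CELLBH")),
    lysineFeasibleInFVA = includeLysineBranch,
    essentialGenes = c("gGLYC", "gPDH", "gACK", "gACACt", "gHBD", "gCRT",
                       "gBCD", "gBUTCT2a", "gBUTCT2b", "gBUTt"),
    nonEssentialGenes = c("gGLCt1", "gGLCt2", "gHYD", "gBUTKr", "gACACT",
                          "gSUCCT",
                          "gMMM2", "gMME", "gMMCD", "gPPCST", "gPPAt",
                          "gCELLBt", "gCELLBH",
                          if (includeLysineBranch)
                            c("gLYSt", "gLYSAM", "gDH36Ma", "gDH36Mb",
                              "gDH35O", "gA53C", "gAB3CL1", "gAB3CL2")),
    ## SUCCT primes the catalytic methylmalonyl-CoA loop and cannot carry
    ## steady-state flux: the loop balances CoA internally
    blockedReactions = c("EX_cellb", "CELLBt", "CELLBH", "SUCCT"),
    egc = if (includeEGC) list(currency = "ATP", cycle = c("EGC1", "EGC2"))
          else NULL,
    lysineSwitch = if (includeLysineBranch) list(
      describe = paste("with lysineATPCost = 0, ACACT deactivated and",
                       "acetoacetate uptake closed, the lysine branch is",
                       "the only butyrate (electron-sink) route and",
                       "carries flux"),
      disable = "ACACT", closeUptake = "EX_acac") else NULL)

  new("ToyScenario", model = model, members = list(), abundances = numeric(0),
      medium = medium, thermo = thermo,
      expressionCounts = stats::setNames(numeric(0), character(0)),
      groundTruth = groundTruth, seed = as.integer(seed))
}

#' Generate expression counts for a scenario
#'
#' Produces raw read counts for every gene of the scenario's model such
#' that the designated low-expression genes fall below the
#' \code{percentile} CPM threshold and every other gene above it.
#' Deterministic per seed.
#'
#' @param scenario a [ToyScenario-class].
#' @param lowGenes character vector of genes to place below the threshold
#'   (must be a subset of the model's genes).
#' @param seed integer seed.
#' @param percentile the threshold percentile the separation must respect
#'   (default 70).
#' @return named numeric vector of counts.
#' @export
makeToyExpression <- function(scenario, lowGenes = character(0), seed = 1L,
                              percentile = 70) {
  g <- genes(scenario@model)
  bad <- setdiff(lowGenes, g)
  if (length(bad)) stop("lowGenes not in the model: ",
                        paste(bad, collapse = ", "))
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv())
  set.seed(seed)
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  ## highly expressed genes share one count so that, with no designated low
  ## genes, every score ties at the percentile threshold and the penalty
  ## vector is exactly zero; counts only need to straddle the threshold
  counts <- stats::setNames(rep(1000, length(g)), g)
  counts[lowGenes] <- round(stats::runif(length(lowGenes), 1, 10))
  cpm <- counts / sum(counts) * 1e6
  thr <- stats::quantile(cpm, percentile / 100)
  if (length(lowGenes) && any(cpm[lowGenes] >= thr))
    stop("cannot separate ", length(lowGenes), " low genes below the ",
         percentile, "th percentile of ", length(g), " genes")
  counts
}

#' Generate a concentration time course from a known flux
#'
#' Inverse of [estimateUptakeCap()]: \eqn{C_t = C_0 + v \Delta t X}, so
#' the estimator recovers \code{vTrue} exactly.
#'
#' @param vTrue true specific exchange flux (mmol/gDW/h; uptake negative).
#' @param X biomass density (gDW/L).
#' @param dt elapsed time (h).
#' @param C0 starting concentration (mmol/L).
#' @return list with elements C0, Ct, dt, X, vTrue.
#' @export
makeConcentrationSeries <- function(vTrue, X, dt, C0) {
  stopifnot(dt > 0, X > 0)
  Ct <- C0 + vTrue * dt * X
  if (Ct < 0) stop("unphysical scenario: Ct would be negative (", Ct, ")")
  list(C0 = C0, Ct = Ct, dt = dt, X = X, vTrue = vTrue)
}

#' Generate the three-species toy community
#'
#' A trophic chain mirroring the polysaccharide-degrader (D), intermediate
#' fermenter (S) and by-product utilizer (U) guilds of a minimal gut
#' community: D hydrolyzes an extracellular polymer into glucose (a public
#' good) and secretes acetate; S ferments glucose to acetate plus either
#' acetaldehyde or succinate; U grows only on the fermentation by-products
#' and is the sole butyrate producer.  Default abundances (D, S, U) =
#' (0.59, 0.26, 0.15).  The engineered cross-feeding edge list is recorded
#' as ground truth.
#'
#' @param seed integer seed (recorded).
#' @param abundances named or positional numeric of length 3 for (D, S, U).
#' @return a [ToyScenario-class] with the member models in \code{@members},
#'   the community medium in \code{@medium} and the expected edges in
#'   \code{@groundTruth$edges}.
#' @export
makeToyCommunity <- function(seed = 1L, abundances = c(D = 0.59, S = 0.26,
                                                       U = 0.15)) {
  rx <- function(id, equation, gpr = NA, spontaneous = FALSE, lb = NA, ub = NA)
    data.frame(id = id, equation = equation, gpr = gpr,
               spontaneous = spontaneous, lb = lb, ub = ub,
               stringsAsFactors = FALSE)
  D <- MetabolicModel("D", rbind(
    rx("EX_poly_e", "poly_e <=>"),
    rx("EX_glc_e","glc_e <=>", lb = 0),          # secretion only
    rx("EX_ac_e", "ac_e <=>", lb = 0),
    rx("POLYt",   "poly_e -> poly_c", "gD_POLYt"),
    rx("DEGR",    "poly_c -> 4 glc_c", "gD_DEGR"),
    rx("GLCex",   "glc_c -> glc_e", "gD_GLCex"),
    rx("GLYCD",   "glc_c + 2 adp_c + 2 pi_c -> 2 atp_c + 2 ac_c", "gD_GLYC",
       ub = 4),                       # saturable: surplus glucose spills over
    rx("ACex",    "ac_c -> ac_e", spontaneous = TRUE),
    rx("BIO",     "glc_c + 2 atp_c -> 2 adp_c + 2 pi_c")
  ), objective = "BIO")
  S <- MetabolicModel("S", rbind(
    rx("EX_glc_e", "glc_e <=>", ub = 0),         # uptake only
    rx("EX_ac_e",  "ac_e <=>", lb = 0),
    rx("EX_acald_e", "acald_e <=>", lb = 0),
    rx("EX_succ_e","succ_e <=>", lb = 0),
    rx("GLCt",     "glc_e -> glc_c", "gS_GLCt", ub = 6),
    rx("FERM1",    "glc_c + 2 adp_c + 2 pi_c -> 2 atp_c + ac_c + acald_c",
       "gS_FERM1"),
    rx("FERM2",    "glc_c + 2 adp_c + 2 pi_c -> 2 atp_c + ac_c + succ_c",
       "gS_FERM2"),
    rx("ACex",     "ac_c -> ac_e", spontaneous = TRUE),
    rx("ACALDex",  "acald_c -> acald_e", spontaneous = TRUE),
    rx("SUCex",    "succ_c -> succ_e", spontaneous = TRUE),
    rx("BIO",      "glc_c + 2 atp_c -> 2 adp_c + 2 pi_c")
  ), objective = "BIO")
  U <- MetabolicModel("U", rbind(
    rx("EX_ac_e",  "ac_e <=>", ub = 0),          # uptake only
    rx("EX_acald_e", "acald_e <=>", ub = 0),
    rx("EX_succ_e","succ_e <=>"),
    rx("EX_but_e", "but_e <=>", lb = 0),
    rx("ACt",      "ac_e -> ac_c", "gU_ACt"),
    rx("ACALDt",   "acald_e -> acald_c", "gU_ACALDt"),
    rx("SUCt",     "succ_e <=> succ_c", "gU_SUCt"),
    rx("USUC",     "succ_c <=> ac_c", "gU_SUC"),
    rx("UCAT",     "acald_c + ac_c + adp_c + pi_c -> but_c + atp_c", "gU_CAT"),
    rx("BUTex",    "but_c -> but_e", spontaneous = TRUE),
    rx("BIO",      "ac_c + 2 atp_c -> 2 adp_c + 2 pi_c")
  ), objective = "BIO")

  medium <- Medium(data.frame(
    exchange_id = "EX_poly_e", lb = -10, ub = 1000, stringsAsFactors = FALSE),
    defaultUptakePolicy = "closed")

  edges <- data.frame(
    species    = c("D", "D", "D", "S", "S", "S", "S", "U", "U", "U", "U"),
    metabolite = c("poly_e", "glc_e", "ac_e",
                   "glc_e", "ac_e", "acald_e", "succ_e",
                   "ac_e", "acald_e", "but_e", "succ_e"),
    direction  = c("consumption", "production", "production",
                   "consumption", "production", "production", "production",
                   "consumption", "consumption", "production", "both"),
    stringsAsFactors = FALSE)

  new("ToyScenario", model = D, members = list(D = D, S = S, U = U),
      abundances = as.numeric(abundances),
      medium = medium, thermo = ThermoTable(),
      expressionCounts = stats::setNames(numeric(0), character(0)),
      groundTruth = list(
        edges = edges,
        crossFed = c("glc_e", "acald_e", "ac_e", "succ_e"),
        soleButyrateProducer = "U",
        obligateCommunityMember = "U"),
      seed = as.integer(seed))
}

setMethod("show", "ToyScenario", function(object) {
  cat("ToyScenario (seed ", object@seed, "): ", sep = "")
  if (length(object@members))
    cat(length(object@members), "member community\n")
  else cat("monoculture model '", object@model@id, "'\n", sep = "")
})
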