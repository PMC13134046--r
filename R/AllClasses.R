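#' @import methods
NULL

#' MetabolicModel: a stoichiometric metabolic network
#'
#' Container for a constraint-based metabolic model: metabolites, reactions
#' with flux bounds (mmol/gDW/h) and GPR rules, a sparse stoichiometric
#' matrix, the gene set, compartments and a biomass objective reaction.
#'
#' @slot id model identifier.
#' @slot S sparse stoichiometric matrix (metabolites x reactions).
#' @slot metabolites data.frame with columns id, name, compartment,
#'   formula (NA when unannotated), charge (NA when unannotated).
#' @slot reactions data.frame with columns id, name, lb, ub, subsystem,
#'   spontaneous (logical), exchange (logical).
#' @slot gprs list of GPR expression trees, parallel to reactions
#'   (NULL elements mean no gene association).
#' @slot genes character vector of gene ids.
#' @slot compartments character vector of compartment ids.
#' @slot extracellular id of the extracellular compartment.
#' @slot objective id of the objective (biomass) reaction.
#' @export
setClass("MetabolicModel",
  representation(
    id = "character",
    S = "dgCMatrix",
    metabolites = "data.frame",
    reactions = "data.frame",
    gprs = "list",
    genes = "character",
    compartments = "character",
    extracellular = "character",
    objective = "character"
  )
)

setValidity("MetabolicModel", function(object) {
  msg <- character(0)
  met <- object@metabolites; rxn <- object@reactions
  if (anyDuplicated(met$id)) msg <- c(msg, "duplicated metabolite ids")
  if (anyDuplicated(rxn$id)) msg <- c(msg, "duplicated reaction ids")
  if (!identical(rownames(object@S), met$id))
    msg <- c(msg, "rownames of S do not match metabolite ids")
  if (!identical(colnames(object@S), rxn$id))
    msg <- c(msg, "colnames of S do not match reaction ids")
  if (!all(met$compartment %in% object@compartments))
    msg <- c(msg, "metabolite compartment not declared in the model")
  if (any(rxn$lb > rxn$ub + 1e-12))
    msg <- c(msg, "reaction with lower bound above upper bound")
  if (length(object@gprs) != nrow(rxn))
    msg <- c(msg, "gprs list not parallel to reactions")
  gg <- unique(unlist(lapply(object@gprs, gprGenes)))
  if (!all(gg %in% object@genes))
    msg <- c(msg, "GPR references gene absent from gene set")
  if (length(object@objective) == 1L && !is.na(object@objective) &&
      !(object@objective %in% rxn$id))
    msg <- c(msg, "objective does not resolve to a reaction")
  ## flagged exchanges must touch exactly one extracellular metabolite
  if (nrow(rxn)) {
    ex <- which(rxn$exchange)
    for (j in ex) {
      mets <- met$compartment[which(object@S[, j] != 0)]
      if (!(length(mets) == 1L && mets == object@extracellular)) {
        msg <- c(msg, paste0("exchange reaction '", rxn$id[j],
                             "' does not touch exactly one extracellular metabolite"))
        break
      }
    }
  }
  if (length(msg)) msg else TRUE
})

#' Medium: growth-medium exchange constraints
#'
#' Exchange-reaction flux caps in mmol/gDW/h with the COBRA sign
#' convention: uptake is negative, secretion is positive.
#'
#' @slot caps data.frame with columns exchange_id, lb, ub.
#' @slot defaultUptakePolicy what happens to exchanges not listed:
#'   "closed" (no uptake, secretion open) or "open" (uptake allowed).
#' @export
setClass("Medium",
  representation(caps = "data.frame", defaultUptakePolicy = "character"))

setValidity("Medium", function(object) {
  msg <- character(0)
  if (!all(c("exchange_id", "lb", "ub") %in% names(object@caps)))
    msg <- c(msg, "caps needs columns exchange_id, lb, ub")
  else {
    if (anyDuplicated(object@caps$exchange_id))
      msg <- c(msg, "duplicated exchange ids in medium")
    if (any(object@caps$lb > object@caps$ub))
      msg <- c(msg, "medium cap with lb > ub")
  }
  if (!object@defaultUptakePolicy %in% c("closed", "open"))
    msg <- c(msg, "defaultUptakePolicy must be 'closed' or 'open'")
  if (length(msg)) msg else TRUE
})

#' FluxSolution: one flux distribution
#'
#' @slot objectiveValue optimal objective (1/h for a biomass objective).
#' @slot fluxes named numeric vector of reaction fluxes (mmol/gDW/h).
#' @slot status "optimal", "infeasible" or "unbounded".
#' @slot method "fba" or "pfba".
#' @slot metadata free-form list (e.g. degeneracy note for plain FBA).
#' @export
setClass("FluxSolution",
  representation(objectiveValue = "numeric", fluxes = "numeric",
                 status = "character", method = "character",
                 metadata = "list"))

#' FluxRange: flux variability intervals
#'
#' @slot ranges data.frame with columns reaction_id, min, max.
#' @slot objectiveFraction fraction of the optimum enforced during FVA.
#' @export
setClass("FluxRange",
  representation(ranges = "data.frame", objectiveFraction = "numeric"))

setValidity("FluxRange", function(object) {
  if (any(object@ranges$min > object@ranges$max + 1e-9))
    "range with min > max" else TRUE
})

#' ThermoTable: transformed reaction Gibbs energies
#'
#' @slot entries named numeric vector, reaction id -> Gibbs energy (kJ/mol)
#'   of the reaction as written.
#' @slot conditions list recording pH, temperature (K) and ionic
#'   strength (M) for provenance.
#' @export
setClass("ThermoTable",
  representation(entries = "numeric", conditions = "list"))

#' ExpressionProfile: CPM-normalized gene expression
#'
#' @slot cpm named numeric vector of counts per million.
#' @slot librarySize total mapped counts.
#' @slot percentile percentile used for the high-expression threshold.
#' @slot threshold CPM value at that percentile.
#' @export
setClass("ExpressionProfile",
  representation(cpm = "numeric", librarySize = "numeric",
                 percentile = "numeric", threshold = "numeric"))

#' ReactionScores: expression scores mapped onto reactions
#'
#' @slot scores named numeric vector on the CPM scale; NA marks reactions
#'   without gene association ("unscored").
#' @slot threshold the expression threshold the scores are compared to.
#' @export
setClass("ReactionScores",
  representation(scores = "numeric", threshold = "numeric"))

#' CommunityModel: multi-species model with a shared extracellular pool
#'
#' Member models are embedded block-diagonally; member exchange reactions
#' become transfer reactions into a shared extracellular pool which has its
#' own community-level exchange reactions.  The community objective is the
#' abundance-weighted sum of member biomass fluxes.
#'
#' @slot model the merged MetabolicModel.
#' @slot members data.frame with columns id, abundance, biomass (namespaced
#'   biomass reaction id).
#' @slot transfers data.frame with columns reaction_id, species, metabolite.
#' @slot exchanges character vector of community exchange reaction ids.
#' @slot objectiveWeights named numeric: biomass reaction id -> abundance.
#' @export
setClass("CommunityModel",
  representation(model = "MetabolicModel", members = "data.frame",
                 transfers = "data.frame", exchanges = "character",
                 objectiveWeights = "numeric"))

setValidity("CommunityModel", function(object) {
  msg <- character(0)
  if (abs(sum(object@members$abundance) - 1) > 1e-9)
    msg <- c(msg, "abundances must sum to 1")
  if (!all(object@members$biomass %in% object@model@reactions$id))
    msg <- c(msg, "member biomass reaction missing from merged model")
  if (length(msg)) msg else TRUE
})

#' ToyScenario: a generated test world with known ground truth
#'
#' @slot model monoculture model (for community scenarios, the first member).
#' @slot members list of member MetabolicModels (community scenarios).
#' @slot abundances numeric abundances parallel to members.
#' @slot medium Medium the scenario is stated under.
#' @slot thermo ThermoTable for the scenario's reactions.
#' @slot expressionCounts named numeric of raw read counts.
#' @slot groundTruth list of expected outcomes (active branches, essential
#'   genes, planted cycles, cross-feeding edges).
#' @slot seed integer seed the scenario was generated from.
#' @export
setClass("ToyScenario",
  representation(model = "MetabolicModel", members = "list",
                 abundances = "numeric", medium = "Medium",
                 thermo = "ThermoTable", expressionCounts = "numeric",
                 groundTruth = "list", seed = "integer"))
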