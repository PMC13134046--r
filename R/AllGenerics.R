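#' @rdname MetabolicModel-accessors
#' @export
setGeneric("modelID", function(object) standardGeneric("modelID"))

#' @rdname MetabolicModel-accessors
#' @export
setGeneric("reactions", function(object) standardGeneric("reactions"))

#' @rdname MetabolicModel-accessors
#' @export
setGeneric("metabolites", function(object) standardGeneric("metabolites"))

#' @rdname MetabolicModel-accessors
#' @export
setGeneric("genes", function(object) standardGeneric("genes"))

#' @rdname MetabolicModel-accessors
#' @export
setGeneric("stoichiometry", function(object) standardGeneric("stoichiometry"))

#' @rdname MetabolicModel-accessors
#' @export
setGeneric("objectiveReaction", function(object) standardGeneric("objectiveReaction"))

#' @rdname MetabolicModel-accessors
#' @export
setGeneric("objectiveReaction<-", function(object, value) standardGeneric("objectiveReaction<-"))

#' @rdname MetabolicModel-accessors
#' @export
setGeneric("exchangeReactions", function(object) standardGeneric("exchangeReactions"))

#' @rdname MetabolicModel-accessors
#' @export
setGeneric("gpr", function(object, id) standardGeneric("gpr"))

#' @rdname FluxSolution-accessors
#' @export
setGeneric("fluxes", function(object) standardGeneric("fluxes"))

#' @rdname FluxSolution-accessors
#' @export
setGeneric("objectiveValue", function(object) standardGeneric("objectiveValue"))

#' @rdname FluxSolution-accessors
#' @export
setGeneric("solutionStatus", function(object) standardGeneric("solutionStatus"))

#' @rdname FluxRange-class
#' @export
setGeneric("fluxRanges", function(object) standardGeneric("fluxRanges"))

#' @rdname CommunityModel-accessors
#' @export
setGeneric("members", function(object) standardGeneric("members"))

#' @rdname CommunityModel-accessors
#' @export
setGeneric("transferReactions", function(object) standardGeneric("transferReactions"))

#' @rdname CommunityModel-accessors
#' @export
setGeneric("mergedModel", function(object) standardGeneric("mergedModel"))
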