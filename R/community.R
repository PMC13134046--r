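## Multi-species community modeling: block-diagonal assembly with a shared
## extracellular pool, abundance-weighted community objective, community
## FBA/FVA and cross-feeding inference.

.renameGPR <- function(gpr, prefix) {
  if (is.null(gpr)) return(NULL)
  if (.gprIsLeaf(gpr)) return(paste0(prefix, gpr))
  list(op = gpr$op, args = lapply(gpr$args, .renameGPR, prefix = prefix))
}

#' Assemble a community model
#'
#' Embeds member models block-diagonally: member reaction, metabolite and
#' gene ids are namespaced as \code{"<species>__<id>"}, member exchange
#' reactions are rewired into transfer reactions between the member's own
#' extracellular metabolite and a shared community pool metabolite, and
#' community-level exchange reactions are created for every pool
#' metabolite.  All member flux bounds are scaled by the member's
#' abundance so fluxes are per gram community dry weight, and the
#' community objective is the abundance-weighted sum of member biomass
#' fluxes.
#'
#' Pool identity defaults to the member's extracellular metabolite id
#' (same-id fallback: members sharing \code{glc_e} share glucose); supply
#' \code{idMap} to map differing namespaces explicitly.
#'
#' @param models named list of [MetabolicModel-class] members (names are
#'   the species ids).
#' @param abundances numeric vector parallel to \code{models}; normalized
#'   to sum to 1 with a warning if needed.
#' @param idMap optional data.frame with columns species, metabolite
#'   (member extracellular metabolite id) and shared_id.
#' @return a [CommunityModel-class].
#' @export
buildCommunity <- function(models, abundances, idMap = NULL) {
  stopifnot(length(models) >= 1L, length(abundances) == length(models))
  if (is.null(names(models)) || !all(nzchar(names(models))))
    stop("models must be a named list (names are species ids)")
  if (any(abundances <= 0)) stop("abundances must be positive")
  if (abs(sum(abundances) - 1) > 1e-9) {
    warning("abundances do not sum to 1; normalizing")
    abundances <- abundances / sum(abundances)
  }
  sids <- names(models)

  sharedId <- function(sid, met) {
    if (!is.null(idMap)) {
      hit <- which(idMap$species == sid & idMap$metabolite == met)
      if (length(hit)) return(idMap$shared_id[hit[1L]])
    }
    met
  }

  rxnRows <- list(); metRows <- list(); transfers <- list()
  comps <- "e"; genesAll <- character(0)
  biomass <- character(length(models)); names(biomass) <- sids
  poolMets <- character(0)

  for (k in seq_along(models)) {
    sid <- sids[k]; mm <- models[[k]]; a <- abundances[k]
    if (is.na(mm@objective))
      stop("member '", sid, "' has no objective reaction")
    p <- paste0(sid, "__")
    tb <- .modelToTables(mm)
    met <- tb$metabolites
    met$id <- paste0(p, met$id)
    met$compartment <- paste0(p, met$compartment)
    comps <- union(comps, met$compartment)
    metRows[[sid]] <- met

    rxn <- tb$reactions
    exch <- rxn$exchange
    rows <- data.frame(id = paste0(p, rxn$id), name = rxn$name,
                       equation = NA_character_,
                       lb = rxn$lb * a, ub = rxn$ub * a,
                       gpr = NA_character_, subsystem = rxn$subsystem,
                       spontaneous = rxn$spontaneous,
                       exchange = FALSE, stringsAsFactors = FALSE)
    gprsNew <- lapply(mm@gprs, .renameGPR, prefix = p)
    rows$gpr <- vapply(gprsNew, gprToString, "")
    genesAll <- union(genesAll, paste0(p, mm@genes))
    for (j in seq_len(nrow(rxn))) {
      st <- mm@S[, j]; st <- st[st != 0]
      names(st) <- paste0(p, names(st))
      if (exch[j]) {
        ## rewire into a transfer to the community pool
        metLocal <- names(st)
        shared <- sharedId(sid, sub(paste0("^", p), "", metLocal))
        poolMets <- union(poolMets, shared)
        st[shared] <- -st[[metLocal]]
        transfers[[length(transfers) + 1L]] <- data.frame(
          reaction_id = rows$id[j], species = sid, metabolite = shared,
          stringsAsFactors = FALSE)
      }
      rows$equation[j] <- .equationString(st, rxn$lb[j] < 0)
    }
    rxnRows[[sid]] <- rows
    biomass[sid] <- paste0(p, mm@objective)
  }

  poolDF <- data.frame(id = poolMets, name = poolMets, compartment = "e",
                       formula = NA_character_, charge = NA_integer_,
                       stringsAsFactors = FALSE)
  exRows <- data.frame(id = paste0("EX_", poolMets),
                       name = paste0("community exchange of ", poolMets),
                       equation = paste(poolMets, "<=>"),
                       lb = 0, ub = 1000, gpr = "", subsystem = "Exchange",
                       spontaneous = FALSE, exchange = TRUE,
                       stringsAsFactors = FALSE)
  allRxn <- do.call(rbind, c(rxnRows, list(exRows)))
  allMet <- rbind(do.call(rbind, metRows), poolDF)

  merged <- MetabolicModel(paste0("community_", paste(sids, collapse = "_")),
                           allRxn, metabolites = allMet, genes = genesAll,
                           objective = NA_character_, extracellular = "e",
                           compartments = comps)
  weights <- stats::setNames(as.numeric(abundances), unname(biomass))
  new("CommunityModel", model = merged,
      members = data.frame(id = sids, abundance = as.numeric(abundances),
                           biomass = unname(biomass),
                           stringsAsFactors = FALSE),
      transfers = do.call(rbind, transfers),
      exchanges = exRows$id, objectiveWeights = weights)
}

#' @rdname CommunityModel-accessors
#' @name CommunityModel-accessors
#' @param object a CommunityModel.
#' @export
setMethod("members", "CommunityModel", function(object) object@members)

#' @rdname CommunityModel-accessors
#' @export
setMethod("transferReactions", "CommunityModel", function(object) object@transfers)

#' @rdname CommunityModel-accessors
#' @export
setMethod("mergedModel", "CommunityModel", function(object) object@model)

setMethod("show", "CommunityModel", function(object) {
  cat("CommunityModel with", nrow(object@members), "members:\n")
  for (i in seq_len(nrow(object@members)))
    cat("  ", object@members$id[i], " (abundance ",
        object@members$abundance[i], ")\n", sep = "")
  cat("  shared pool:", length(object@exchanges), "metabolites;",
      nrow(object@transfers), "transfer reactions\n")
})

#' Community FBA
#'
#' Maximizes the abundance-weighted sum of member biomass fluxes on the
#' merged model; species abundances are fixed input parameters.
#'
#' @param cm a [CommunityModel-class].
#' @param medium optional [Medium-class] on the community exchange
#'   reactions.
#' @param parsimonious also minimize total flux at the community optimum
#'   (pFBA; recommended for reporting point fluxes, which are otherwise
#'   representative but possibly degenerate).
#' @return list with \code{solution} (a [FluxSolution-class]),
#'   \code{communityGrowth} and \code{memberGrowth} (named per-species
#'   biomass fluxes).
#' @export
communityFBA <- function(cm, medium = NULL, parsimonious = FALSE) {
  fun <- if (parsimonious) pfba else fba
  sol <- fun(cm@model, medium, objective = cm@objectiveWeights)
  mg <- stats::setNames(rep(NA_real_, nrow(cm@members)), cm@members$id)
  if (solutionStatus(sol) == "optimal")
    mg[] <- fluxes(sol)[cm@members$biomass]
  list(solution = sol,
       communityGrowth = objectiveValue(sol),
       memberGrowth = mg)
}

#' Community FVA
#'
#' Flux variability at a fraction of the maximal community objective,
#' scanning by default the transfer and community exchange reactions (the
#' reactions cross-feeding is read from).
#'
#' @inheritParams communityFBA
#' @param fraction fraction of the community optimum (default 0.9).
#' @param reactions reaction ids to scan; default transfers + community
#'   exchanges.
#' @return a [FluxRange-class].
#' @export
communityFVA <- function(cm, medium = NULL, fraction = 0.9, reactions = NULL) {
  if (is.null(reactions))
    reactions <- c(cm@transfers$reaction_id, cm@exchanges)
  fva(cm@model, medium, fraction = fraction, reactions = reactions,
      objective = cm@objectiveWeights)
}

#' Infer cross-feeding interactions from community FVA
#'
#' Classifies each species x pool-metabolite transfer by the sign of its
#' feasible flux range: a maximum above \code{tol} means the species can
#' produce the metabolite into the pool, a minimum below \code{-tol} that
#' it can consume it; both signs give direction "both".  A metabolite
#' produced by one species and consumed by another within the same
#' solution space is a potential cross-feeding interaction.
#'
#' @param cm a [CommunityModel-class].
#' @param ranges a [FluxRange-class] from [communityFVA()]; computed on
#'   the fly when NULL.
#' @param medium,fraction used only when \code{ranges} is NULL.
#' @param tol flux tolerance for calling an edge (default 1e-6).
#' @param lowFluxCutoff edges whose largest absolute flux stays below this
#'   are flagged \code{low_flux} (default 0.01 mmol/gDW/h).
#' @return data.frame of edges (species, metabolite, direction, flux_min,
#'   flux_max, low_flux) with attribute \code{crossFed}: the pool
#'   metabolites produced by one species and consumed by another.
#' @export
inferCrossFeeding <- function(cm, ranges = NULL, medium = NULL,
                              fraction = 0.9, tol = 1e-6,
                              lowFluxCutoff = 0.01) {
  if (is.null(ranges))
    ranges <- communityFVA(cm, medium, fraction = fraction)
  rg <- fluxRanges(ranges)
  tr <- cm@transfers
  rg <- rg[rg$reaction_id %in% tr$reaction_id, , drop = FALSE]
  k <- match(rg$reaction_id, tr$reaction_id)
  prod <- rg$max > tol; cons <- rg$min < -tol
  keep <- prod | cons
  edges <- data.frame(
    species = tr$species[k][keep],
    metabolite = tr$metabolite[k][keep],
    direction = ifelse(prod[keep] & cons[keep], "both",
                       ifelse(prod[keep], "production", "consumption")),
    flux_min = rg$min[keep], flux_max = rg$max[keep],
    stringsAsFactors = FALSE)
  edges$low_flux <- pmax(abs(edges$flux_min), abs(edges$flux_max)) < lowFluxCutoff
  ## cross-fed: some species can produce it and a *different* one consume it
  crossFed <- vapply(unique(edges$metabolite), function(m) {
    e <- edges[edges$metabolite == m, ]
    producers <- e$species[e$direction %in% c("production", "both")]
    consumers <- e$species[e$direction %in% c("consumption", "both")]
    length(producers) > 0 && length(consumers) > 0 &&
      length(union(producers, consumers)) > 1
  }, NA)
  attr(edges, "crossFed") <- unique(edges$metabolite)[crossFed]
  rownames(edges) <- NULL
  edges
}

#' Export a cross-feeding network
#'
#' Writes the bipartite species-metabolite interaction graph as SIF
#' (\code{species <direction> metabolite}, one edge per line) or GraphML
#' (with direction and flux range as edge attributes).
#'
#' @param edges edge data.frame from [inferCrossFeeding()].
#' @param path output file.
#' @param format "sif" or "graphml".
#' @return the path, invisibly.
#' @export
exportNetwork <- function(edges, path, format = c("sif", "graphml")) {
  format <- match.arg(format)
  if (format == "sif") {
    lines <- if (nrow(edges))
      paste(edges$species, edges$direction, edges$metabolite, sep = "\t")
    else character(0)
    writeLines(lines, path)
  } else {
    nodes <- data.frame(
      name = c(unique(edges$species), unique(edges$metabolite)),
      type = c(rep("species", length(unique(edges$species))),
               rep("metabolite", length(unique(edges$metabolite)))),
      stringsAsFactors = FALSE)
    g <- igraph::graph_from_data_frame(
      if (nrow(edges)) edges[c("species", "metabolite", "direction",
                               "flux_min", "flux_max")]
      else data.frame(from = character(0), to = character(0)),
      directed = FALSE, vertices = nodes)
    igraph::write_graph(g, path, format = "graphml")
  }
  invisible(path)
}
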