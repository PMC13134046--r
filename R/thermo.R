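## Thermodynamic curation: directionality from transformed Gibbs energies,
## energy-generating-cycle (EGC) screening, and ranked gap-reaction
## integration.

#' Construct a ThermoTable
#'
#' @param entries named numeric vector: reaction id -> transformed reaction
#'   Gibbs energy (kJ/mol), signed for the reaction as written.
#' @param pH,temperature,ionicStrength conditions recorded for provenance
#'   (defaults: gut-like pH 6, 310 K, 0.25 M).
#' @return a [ThermoTable-class].
#' @export
ThermoTable <- function(entries = numeric(0), pH = 6, temperature = 310,
                        ionicStrength = 0.25) {
  new("ThermoTable", entries = entries,
      conditions = list(pH = pH, temperature = temperature,
                        ionicStrength = ionicStrength))
}

#' Read a thermodynamics TSV
#'
#' Columns \code{reaction_id}, \code{delta_rG_prime_kJ_per_mol}; header
#' comment lines (\code{# pH: ...}, \code{# T_K: ...}, \code{# I_M: ...})
#' record the conditions.
#'
#' @param path file path.
#' @return a [ThermoTable-class].
#' @export
readThermoTable <- function(path) {
  lines <- readLines(path)
  hdr <- grep("^#", lines, value = TRUE)
  getc <- function(key, default) {
    hit <- grep(paste0("^#\\s*", key, ":"), hdr, value = TRUE)
    if (length(hit)) as.numeric(sub(paste0("^#\\s*", key, ":"), "", hit[1L]))
    else default
  }
  tb <- utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
  ThermoTable(stats::setNames(tb$delta_rG_prime_kJ_per_mol, tb$reaction_id),
              pH = getc("pH", 6), temperature = getc("T_K", 310),
              ionicStrength = getc("I_M", 0.25))
}

#' Assign reaction directionality from Gibbs energies
#'
#' Applies the directionality rule: reactions with
#' \eqn{\Delta_r G' < -threshold} are constrained to the forward direction
#' (lower bound clamped to 0), reactions with
#' \eqn{\Delta_r G' > +threshold} to the reverse direction (upper bound
#' clamped to 0), and reactions within the band (boundary included) are
#' left reversible.  Exchange reactions and reactions absent from the
#' table are never touched.  A clamp that would make lb > ub is reported
#' and skipped with a warning.
#'
#' @param model a [MetabolicModel-class].
#' @param thermo a [ThermoTable-class].
#' @param threshold band half-width in kJ/mol (default 30).
#' @param exemptTransporters ids of transport reactions to exempt even if
#'   present in the table (default none).
#' @return the model with updated bounds.
#' @export
assignDirectionality <- function(model, thermo, threshold = 30,
                                 exemptTransporters = character(0)) {
  stopifnot(threshold > 0)
  rxn <- model@reactions
  ids <- intersect(names(thermo@entries), rxn$id)
  ids <- setdiff(ids, c(rxn$id[rxn$exchange], exemptTransporters))
  for (id in ids) {
    dg <- thermo@entries[[id]]
    j <- match(id, rxn$id)
    lb <- model@reactions$lb[j]; ub <- model@reactions$ub[j]
    if (dg < -threshold) {
      if (ub < 0) {
        warning("directionality conflict for '", id,
                "': forward clamp would give lb > ub; left unchanged")
        next
      }
      model@reactions$lb[j] <- max(lb, 0)
    } else if (dg > threshold) {
      if (lb > 0) {
        warning("directionality conflict for '", id,
                "': reverse clamp would give lb > ub; left unchanged")
        next
      }
      model@reactions$ub[j] <- min(ub, 0)
    }
  }
  model
}

.defaultEnergyCurrencies <- function() list(
  ATP   = c(atp_c = -1, h2o_c = -1, adp_c = 1, pi_c = 1, h_c = 1),
  GTP   = c(gtp_c = -1, h2o_c = -1, gdp_c = 1, pi_c = 1, h_c = 1),
  NADH  = c(nadh_c = -1, nad_c = 1, h_c = 1),
  NADPH = c(nadph_c = -1, nadp_c = 1, h_c = 1),
  FADH2 = c(fadh2_c = -1, fad_c = 1, h_c = 2),
  PMF   = c(h_e = -1, h_c = 1)
)

#' Detect energy-generating cycles
#'
#' With every exchange closed, a dissipation reaction is added for each
#' energy currency (e.g. ATP + H2O -> ADP + Pi + H) and its flux
#' maximized.  Any positive maximum reveals an internal cycle generating
#' the currency from nothing -- a thermodynamically impossible artifact.
#' The reactions active in a parsimonious dissipating flux distribution
#' are reported as the cycle.
#'
#' @param model a [MetabolicModel-class].
#' @param energyCurrencies named list of dissipation stoichiometries
#'   (metabolite id -> coefficient); defaults cover ATP, GTP, NADH, NADPH,
#'   FADH2 and the proton-motive force.
#' @param tol flux tolerance (default 1e-6).
#' @return data.frame with columns currency, maxDissipation, cycle (list
#'   column of active reaction ids); zero rows when the model is clean.
#' @export
detectEGCs <- function(model, energyCurrencies = .defaultEnergyCurrencies(),
                       tol = 1e-6) {
  stopifnot(length(energyCurrencies) > 0)
  exch <- model@reactions$id[model@reactions$exchange]
  closed <- if (length(exch))
    setReactionBounds(model, exch, lb = 0, ub = 0) else model
  ## forced internal fluxes (e.g. a maintenance lower bound) are relaxed so
  ## the screen reports only the cycle itself, not reactions the forcing
  ## drags along
  rxn <- closed@reactions
  forced <- rxn$id[!rxn$exchange & (rxn$lb > 0 | rxn$ub < 0)]
  if (length(forced)) {
    j <- match(forced, rxn$id)
    closed@reactions$lb[j] <- pmin(rxn$lb[j], 0)
    closed@reactions$ub[j] <- pmax(rxn$ub[j], 0)
  }
  out <- data.frame(currency = character(0), maxDissipation = numeric(0))
  out$cycle <- list()
  ## water/protons are dropped from a dissipation stoichiometry when the
  ## model does not track them (lumped toy models); the core currency
  ## metabolites must be present or the currency is skipped
  droppable <- c("h_c", "h_e", "h2o_c", "h2o_e")
  for (cur in names(energyCurrencies)) {
    st <- energyCurrencies[[cur]]
    absent <- setdiff(names(st), closed@metabolites$id)
    st <- st[!(names(st) %in% intersect(absent, droppable))]
    missing <- setdiff(names(st), closed@metabolites$id)
    if (length(missing) || !length(st)) {
      message("EGC screen: currency ", cur, " skipped (metabolites absent: ",
              paste(missing, collapse = ", "), ")")
      next
    }
    dissId <- paste0("EGC_DISS_", cur)
    eq <- .equationString(st, FALSE)
    probe <- addReactions(closed,
      data.frame(id = dissId, equation = eq, lb = 0, ub = 1000,
                 stringsAsFactors = FALSE))
    sol <- fba(probe, objective = dissId)
    mx <- if (solutionStatus(sol) == "optimal") objectiveValue(sol) else
      if (solutionStatus(sol) == "unbounded") Inf else 0
    if (mx > tol) {
      ## parsimonious flux at the dissipation maximum isolates the cycle
      psol <- pfba(probe, objective = dissId)
      v <- fluxes(psol)
      active <- setdiff(names(v)[abs(v) > tol], dissId)
      out <- rbind(out, data.frame(currency = cur, maxDissipation = mx,
                                   cycle = I(list(active))))
    }
  }
  rownames(out) <- NULL
  out
}

#' Add reactions from a curation table
#'
#' Thin wrapper around [addReactions()] for manually curated reaction rows
#' (id, equation, gpr, name, subsystem ...), e.g. a literature-supported
#' pathway with its GPR rules.  New genes are registered automatically.
#'
#' @param model a [MetabolicModel-class].
#' @param table reaction data.frame in the TSV dialect.
#' @param replace allow replacing existing reactions.
#' @return the extended model.
#' @export
addReactionsFromTable <- function(model, table, replace = FALSE)
  addReactions(model, table, replace = replace)

#' Integrate top-ranked candidate gap reactions
#'
#' Adds the top \code{n} reactions from a ranked candidate list
#' (deduplicating against existing reaction ids), re-applies the
#' thermodynamic directionality rule, then screens for energy-generating
#' cycles; added reactions participating in a detected cycle are removed
#' greedily, lowest-ranked first, until the model is clean.  Reactions of
#' the original model are never removed.
#'
#' @param model a [MetabolicModel-class].
#' @param candidates data.frame with columns rank, id, equation and
#'   optionally gpr, score.
#' @param n how many top-ranked candidates to integrate (0 = none).
#' @param thermo optional [ThermoTable-class] re-applied after addition.
#' @param medium optional [Medium-class]; when given, the report includes
#'   growth before and after integration.
#' @param threshold directionality threshold passed on (kJ/mol).
#' @return list with elements \code{model} and \code{report} (added,
#'   skipped, removed, growthBefore, growthAfter, inflation).
#' @export
integrateCandidates <- function(model, candidates, n, thermo = NULL,
                                medium = NULL, threshold = 30) {
  stopifnot(n >= 0, n <= nrow(candidates))
  if (anyDuplicated(candidates$rank))
    stop("candidate ranks must be unique")
  cand <- candidates[order(candidates$rank), , drop = FALSE][seq_len(n), , drop = FALSE]
  skipped <- intersect(cand$id, model@reactions$id)
  cand <- cand[!(cand$id %in% skipped), , drop = FALSE]
  growth0 <- if (!is.null(medium)) {
    s <- fba(model, medium)
    if (solutionStatus(s) == "optimal") objectiveValue(s) else 0
  } else NA_real_
  out <- model
  if (nrow(cand)) {
    newmets <- setdiff(
      unique(unlist(lapply(cand$equation, function(e) names(.parseEquation(e)$stoich)))),
      model@metabolites$id)
    out <- withCallingHandlers(
      addReactions(model, cand),
      warning = function(w) {
        if (grepl("auto-created metabolites", conditionMessage(w)))
          invokeRestart("muffleWarning")
      })
    if (length(newmets))
      warning("candidates introduced new metabolites (unverifiable for balance): ",
              paste(newmets, collapse = ", "))
  }
  if (!is.null(thermo))
    out <- assignDirectionality(out, thermo, threshold = threshold)
  removed <- character(0)
  addedLeft <- cand$id
  repeat {
    egcs <- detectEGCs(out)
    if (!nrow(egcs)) break
    involved <- intersect(addedLeft, unique(unlist(egcs$cycle)))
    if (!length(involved)) {
      warning("EGCs persist but involve no added reaction; original model ",
              "reactions are never auto-removed")
      break
    }
    ## lowest-ranked (largest rank number) first
    rk <- cand$rank[match(involved, cand$id)]
    drop1 <- involved[which.max(rk)]
    tb <- .modelToTables(out)
    keep <- tb$reactions[tb$reactions$id != drop1, , drop = FALSE]
    out <- MetabolicModel(out@id, keep, metabolites = tb$metabolites,
                          genes = out@genes, objective = out@objective,
                          extracellular = out@extracellular,
                          compartments = out@compartments)
    removed <- c(removed, drop1)
    addedLeft <- setdiff(addedLeft, drop1)
  }
  growth1 <- if (!is.null(medium)) {
    s <- fba(out, medium)
    if (solutionStatus(s) == "optimal") objectiveValue(s) else 0
  } else NA_real_
  list(model = out,
       report = list(added = setdiff(cand$id, removed), skipped = skipped,
                     removed = removed, growthBefore = growth0,
                     growthAfter = growth1,
                     inflation = if (!is.na(growth0) && growth0 > 0)
                       growth1 / growth0 else NA_real_))
}
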