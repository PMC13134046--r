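## Model construction from reaction tables and equation strings.

## Parse one reaction equation in the TSV dialect:
##   "A + 2 B -> C", "glc_e <=>", "X <- Y".
## Returns list(stoich = named numeric, reversible, backward).
.parseEquation <- function(eq, context = "") {
  eq <- trimws(eq)
  arrow <- regmatches(eq, regexpr("<=>|<->|=>|->|<=|<-", eq))
  if (!length(arrow))
    stop("cannot parse reaction equation", context, ": '", eq, "' (no arrow)")
  arrow <- arrow[[1L]]
  sides <- strsplit(eq, "<=>|<->|=>|->|<=|<-", fixed = FALSE)[[1L]]
  lhs <- if (length(sides) >= 1L) sides[1L] else ""
  rhs <- if (length(sides) >= 2L) sides[2L] else ""
  parseSide <- function(s, sign) {
    s <- trimws(s)
    if (!nzchar(s)) return(numeric(0))
    terms <- strsplit(s, "\\+")[[1L]]
    out <- numeric(0)
    for (tm in terms) {
      tm <- trimws(tm)
      if (!nzchar(tm)) next
      bits <- strsplit(tm, "[[:space:]]+")[[1L]]
      coef <- suppressWarnings(as.numeric(bits[1L]))
      if (length(bits) > 1L && !is.na(coef)) {
        met <- paste(bits[-1L], collapse = "_")
      } else {
        coef <- 1
        met <- paste(bits, collapse = "_")
      }
      if (coef == 0)
        stop("zero stoichiometric coefficient", context, " in '", eq, "'")
      out[met] <- (if (is.na(out[met])) 0 else out[met]) + sign * coef
    }
    out
  }
  st <- numeric(0)
  for (term in list(list(lhs, -1), list(rhs, +1))) {
    side <- parseSide(term[[1L]], term[[2L]])
    for (m in names(side)) st[m] <- (if (m %in% names(st)) st[m] else 0) + side[m]
  }
  st <- st[st != 0]
  list(stoich = st,
       reversible = arrow %in% c("<=>", "<->"),
       backward = arrow %in% c("<-", "<="))
}

## Reaction equation string from a stoichiometry vector.
.equationString <- function(stoich, reversible) {
  fmt <- function(v, ids) {
    if (!length(ids)) return("")
    paste(mapply(function(c0, m) if (abs(c0 - 1) < 1e-12) m else paste(format(c0), m),
                 v, ids), collapse = " + ")
  }
  neg <- stoich < 0; pos <- stoich > 0
  paste(fmt(-stoich[neg], names(stoich)[neg]),
        if (reversible) "<=>" else "->",
        fmt(stoich[pos], names(stoich)[pos]))
}

.metCompartment <- function(id, compartments) {
  suf <- sub(".*_", "", id)
  if (suf %in% compartments && suf != id) suf else NA_character_
}

#' Construct a MetabolicModel from a reaction table
#'
#' The workhorse constructor.  Reactions are given as a data.frame with at
#' least columns \code{id} and \code{equation} (dialect
#' \code{"A + 2 B -> C"}; \code{"<=>"} marks a reversible reaction and an
#' empty product side an exchange, e.g. \code{"glc_e <=>"}).  Optional
#' columns: \code{name}, \code{lb}, \code{ub} (mmol/gDW/h; default derived
#' from the arrow and \code{defaultBound}), \code{gpr} (rule string),
#' \code{subsystem}, \code{spontaneous} (logical) and \code{exchange}
#' (logical override of the automatic single-extracellular-metabolite
#' detection).
#'
#' Metabolites referenced by equations but absent from \code{metabolites}
#' are created with the compartment inferred from an id suffix
#' (\code{"_e"}, \code{"_c"}, ...) and no formula (they then count as
#' unverifiable in the mass/charge balance check).
#'
#' @param id model id.
#' @param reactions reaction data.frame (see Details).
#' @param metabolites optional data.frame with columns id and any of name,
#'   compartment, formula, charge.
#' @param genes optional character vector; GPR genes are added
#'   automatically.
#' @param objective id of the objective (biomass) reaction.
#' @param extracellular id of the extracellular compartment (default "e").
#' @param compartments optional character vector of compartment ids.
#' @param defaultBound magnitude used for unspecified bounds (default 1000).
#' @return A [MetabolicModel-class] object.
#' @examples
#' rxn <- data.frame(id = c("EX_a", "R1", "BIO"),
#'                   equation = c("a_e <=>", "a_e -> a_c", "a_c ->"))
#' m <- MetabolicModel("toy", rxn, objective = "BIO")
#' @export
MetabolicModel <- function(id, reactions, metabolites = NULL, genes = NULL,
                           objective = NA_character_, extracellular = "e",
                           compartments = NULL, defaultBound = 1000) {
  stopifnot(is.data.frame(reactions), all(c("id", "equation") %in% names(reactions)))
  rxn <- reactions
  n <- nrow(rxn)
  if (anyDuplicated(rxn$id))
    stop("duplicated reaction ids: ",
         paste(unique(rxn$id[duplicated(rxn$id)]), collapse = ", "))
  parsed <- lapply(seq_len(n), function(i)
    .parseEquation(rxn$equation[i], paste0(" (reaction '", rxn$id[i], "')")))

  getcol <- function(col, default) {
    if (col %in% names(rxn)) {
      v <- rxn[[col]]
      v[is.na(v)] <- default[is.na(v)]
      v
    } else default
  }
  lb0 <- vapply(parsed, function(p)
    if (p$reversible || p$backward) -defaultBound else 0, 0)
  ub0 <- vapply(parsed, function(p)
    if (p$backward) 0 else defaultBound, 0)
  lb <- as.numeric(getcol("lb", lb0))
  ub <- as.numeric(getcol("ub", ub0))
  name <- as.character(getcol("name", rxn$id))
  subsystem <- as.character(getcol("subsystem", rep("", n)))
  spont <- as.logical(getcol("spontaneous", rep(FALSE, n)))
  gprs <- if ("gpr" %in% names(rxn)) lapply(rxn$gpr, parseGPR)
          else rep(list(NULL), n)

  metIDs <- unique(unlist(lapply(parsed, function(p) names(p$stoich))))
  metDF <- data.frame(id = metIDs, name = metIDs,
                      compartment = NA_character_,
                      formula = NA_character_, charge = NA_integer_,
                      stringsAsFactors = FALSE)
  if (!is.null(metabolites)) {
    stopifnot("id" %in% names(metabolites))
    idx <- match(metDF$id, metabolites$id)
    for (col in intersect(c("name", "compartment", "formula", "charge"),
                          names(metabolites))) {
      hit <- !is.na(idx)
      metDF[[col]][hit] <- metabolites[[col]][idx[hit]]
    }
    extra <- setdiff(metabolites$id, metDF$id)
    if (length(extra))
      warning("metabolites never used by any reaction are dropped: ",
              paste(extra, collapse = ", "))
  }
  comps <- unique(c(compartments, "c", extracellular,
                    metDF$compartment[!is.na(metDF$compartment)]))
  infer <- is.na(metDF$compartment)
  metDF$compartment[infer] <- vapply(metDF$id[infer], function(m) {
    cc <- .metCompartment(m, comps)
    if (is.na(cc)) "c" else cc
  }, "")

  trip_i <- integer(0); trip_j <- integer(0); trip_x <- numeric(0)
  for (j in seq_len(n)) {
    st <- parsed[[j]]$stoich
    trip_i <- c(trip_i, match(names(st), metDF$id))
    trip_j <- c(trip_j, rep(j, length(st)))
    trip_x <- c(trip_x, unname(st))
  }
  S <- Matrix::sparseMatrix(i = trip_i, j = trip_j, x = trip_x,
                            dims = c(nrow(metDF), n),
                            dimnames = list(metDF$id, rxn$id))

  ## exchange detection: exactly one metabolite, in the extracellular space
  auto <- vapply(seq_len(n), function(j) {
    nz <- which(S[, j] != 0)
    length(nz) == 1L && metDF$compartment[nz] == extracellular
  }, NA)
  exch <- if ("exchange" %in% names(rxn)) {
    ifelse(is.na(rxn$exchange), auto, as.logical(rxn$exchange))
  } else auto

  rxnDF <- data.frame(id = as.character(rxn$id), name = name, lb = lb, ub = ub,
                      subsystem = subsystem, spontaneous = spont,
                      exchange = exch, stringsAsFactors = FALSE)
  genes <- sort(unique(c(genes, unlist(lapply(gprs, gprGenes)))))
  names(gprs) <- rxnDF$id
  new("MetabolicModel", id = id, S = methods::as(S, "CsparseMatrix"),
      metabolites = metDF, reactions = rxnDF, gprs = gprs,
      genes = as.character(genes), compartments = comps,
      extracellular = extracellular, objective = as.character(objective))
}

## Rebuild the reaction table (with equation strings) from a model; the
## editing helpers round-trip through this so there is one construction path.
.modelToTables <- function(model) {
  rxn <- model@reactions
  S <- model@S
  eqs <- vapply(seq_len(nrow(rxn)), function(j) {
    st <- S[, j]
    st <- st[st != 0]
    .equationString(st, rxn$lb[j] < 0)
  }, "")
  rxn$equation <- eqs
  rxn$gpr <- vapply(model@gprs, gprToString, "")
  list(reactions = rxn, metabolites = model@metabolites)
}

#' Add reactions to a model
#'
#' Appends reactions given in the table dialect of [MetabolicModel()].
#' Unknown metabolites are created with a warning (and remain unverifiable
#' for the balance check); new GPR genes are registered.
#'
#' @param model a [MetabolicModel-class].
#' @param table reaction data.frame (columns as in [MetabolicModel()]).
#' @param replace replace existing reactions with clashing ids instead of
#'   raising an error.
#' @return the extended model.
#' @export
addReactions <- function(model, table, replace = FALSE) {
  if (!nrow(table)) return(model)
  tb <- .modelToTables(model)
  dup <- intersect(table$id, tb$reactions$id)
  if (length(dup) && !replace)
    stop("reaction ids already present (use replace = TRUE): ",
         paste(dup, collapse = ", "))
  old <- tb$reactions[!(tb$reactions$id %in% dup), , drop = FALSE]
  cols <- union(names(old), names(table))
  for (cc in setdiff(cols, names(table))) table[[cc]] <- NA
  for (cc in setdiff(cols, names(old))) old[[cc]] <- NA
  allr <- rbind(old[cols], table[cols])
  known <- unique(unlist(lapply(allr$equation, function(e) names(.parseEquation(e)$stoich))))
  newmets <- setdiff(known, tb$metabolites$id)
  if (length(newmets))
    warning("auto-created metabolites (no formula; unverifiable in balance checks): ",
            paste(newmets, collapse = ", "))
  MetabolicModel(model@id, allr, metabolites = tb$metabolites,
                 genes = model@genes, objective = model@objective,
                 extracellular = model@extracellular,
                 compartments = model@compartments)
}

#' Set flux bounds on reactions
#'
#' @param model a [MetabolicModel-class].
#' @param ids reaction ids.
#' @param lb,ub new bounds, recycled along \code{ids}; NA leaves the
#'   existing bound untouched.
#' @return the model with updated bounds.
#' @export
setReactionBounds <- function(model, ids, lb = NA, ub = NA) {
  j <- match(ids, model@reactions$id)
  if (anyNA(j)) stop("unknown reaction ids: ",
                     paste(ids[is.na(j)], collapse = ", "))
  lb <- rep_len(lb, length(j)); ub <- rep_len(ub, length(j))
  keep <- !is.na(lb); model@reactions$lb[j[keep]] <- lb[keep]
  keep <- !is.na(ub); model@reactions$ub[j[keep]] <- ub[keep]
  validObject(model)
  model
}

#' Deactivate reactions by closing their bounds
#'
#' Sets bounds to (0, 0); the reaction stays in the model structure.
#'
#' @param model a [MetabolicModel-class].
#' @param ids reaction ids to switch off.
#' @return the model with the reactions deactivated.
#' @export
deactivateReactions <- function(model, ids)
  setReactionBounds(model, ids, lb = 0, ub = 0)

#' Knock out genes
#'
#' Evaluates every GPR with the given genes absent and deactivates the
#' reactions whose rules evaluate FALSE.
#'
#' @param model a [MetabolicModel-class].
#' @param genes gene ids to knock out.
#' @return the model with all disabled reactions deactivated.
#' @export
knockoutGenes <- function(model, genes) {
  off <- .disabledReactions(model, genes)
  if (length(off)) deactivateReactions(model, off) else model
}

## reactions whose GPR evaluates FALSE when `genes` are knocked out
.disabledReactions <- function(model, genes) {
  hit <- vapply(model@gprs, function(g)
    !is.null(g) && any(gprGenes(g) %in% genes) && !.evalGPR(g, genes), NA)
  model@reactions$id[hit]
}
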