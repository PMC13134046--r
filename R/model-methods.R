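#' Accessors for MetabolicModel
#'
#' @param object a [MetabolicModel-class].
#' @param id a reaction id (for \code{gpr}).
#' @param value replacement value.
#' @name MetabolicModel-accessors
NULL

#' @rdname MetabolicModel-accessors
#' @export
setMethod("modelID", "MetabolicModel", function(object) object@id)

#' @rdname MetabolicModel-accessors
#' @export
setMethod("reactions", "MetabolicModel", function(object) {
  df <- object@reactions
  df$gpr <- vapply(object@gprs, gprToString, "")
  df
})

#' @rdname MetabolicModel-accessors
#' @export
setMethod("metabolites", "MetabolicModel", function(object) object@metabolites)

#' @rdname MetabolicModel-accessors
#' @export
setMethod("genes", "MetabolicModel", function(object) object@genes)

#' @rdname MetabolicModel-accessors
#' @export
setMethod("stoichiometry", "MetabolicModel", function(object) object@S)

#' @rdname MetabolicModel-accessors
#' @export
setMethod("objectiveReaction", "MetabolicModel", function(object) object@objective)

#' @rdname MetabolicModel-accessors
#' @export
setReplaceMethod("objectiveReaction", "MetabolicModel", function(object, value) {
  object@objective <- value
  validObject(object)
  object
})

#' @rdname MetabolicModel-accessors
#' @export
setMethod("exchangeReactions", "MetabolicModel", function(object)
  object@reactions$id[object@reactions$exchange])

#' @rdname MetabolicModel-accessors
#' @export
setMethod("gpr", "MetabolicModel", function(object, id) {
  if (!id %in% object@reactions$id) stop("unknown reaction: ", id)
  object@gprs[[id]]
})

setMethod("show", "MetabolicModel", function(object) {
  cat("MetabolicModel '", object@id, "'\n", sep = "")
  cat("  ", nrow(object@metabolites), " metabolites, ",
      nrow(object@reactions), " reactions, ",
      length(object@genes), " genes\n", sep = "")
  cat("  compartments: ", paste(object@compartments, collapse = ", "),
      " (extracellular: '", object@extracellular, "')\n", sep = "")
  cat("  exchanges: ", sum(object@reactions$exchange),
      "; objective: ", object@objective, "\n", sep = "")
})

setMethod("show", "FluxSolution", function(object) {
  cat("FluxSolution (", object@method, "): status ", object@status, sep = "")
  if (object@status == "optimal")
    cat(", objective ", format(object@objectiveValue, digits = 6), sep = "")
  cat("\n  ", length(object@fluxes), " fluxes",
      if (isTRUE(object@metadata$degenerate))
        "; point solution is representative, possibly degenerate" else "",
      "\n", sep = "")
})

#' @rdname FluxSolution-accessors
#' @name FluxSolution-accessors
#' @param object a FluxSolution.
#' @export
setMethod("fluxes", "FluxSolution", function(object) object@fluxes)

#' @rdname FluxSolution-accessors
#' @export
setMethod("objectiveValue", "FluxSolution", function(object) object@objectiveValue)

#' @rdname FluxSolution-accessors
#' @export
setMethod("solutionStatus", "FluxSolution", function(object) object@status)

#' @rdname FluxRange-class
#' @param object a FluxRange.
#' @export
setMethod("fluxRanges", "FluxRange", function(object) object@ranges)

setMethod("show", "FluxRange", function(object) {
  cat("FluxRange over ", nrow(object@ranges), " reactions at objective fraction ",
      object@objectiveFraction, "\n", sep = "")
})

setMethod("show", "Medium", function(object) {
  cat("Medium with ", nrow(object@caps), " exchange caps; unlisted exchanges: ",
      object@defaultUptakePolicy, "\n", sep = "")
})

#' Summarise a model
#'
#' Counts of metabolites, reactions and genes, plus the per-subsystem
#' reaction distribution split into gene-associated and
#' non-gene-associated reactions.
#'
#' @param model a [MetabolicModel-class].
#' @return list with elements \code{nMetabolites}, \code{nReactions},
#'   \code{nGenes} and \code{subsystems} (data.frame with columns
#'   subsystem, geneAssociated, nonGeneAssociated, total).
#' @export
modelSummary <- function(model) {
  rxn <- model@reactions
  ga <- !vapply(model@gprs, is.null, NA)
  sub <- ifelse(nzchar(rxn$subsystem), rxn$subsystem, "(none)")
  lev <- sort(unique(sub))
  df <- data.frame(
    subsystem = lev,
    geneAssociated = vapply(lev, function(s) sum(sub == s & ga), 0L),
    nonGeneAssociated = vapply(lev, function(s) sum(sub == s & !ga), 0L),
    row.names = NULL)
  df$total <- df$geneAssociated + df$nonGeneAssociated
  list(nMetabolites = nrow(model@metabolites),
       nReactions = nrow(rxn),
       nGenes = length(model@genes),
       subsystems = df)
}

## "C6H12O6" -> c(C = 6, H = 12, O = 6); NA formula -> NULL
.parseFormula <- function(f) {
  if (is.na(f) || !nzchar(f)) return(NULL)
  m <- gregexpr("([A-Z][a-z]?)([0-9]*)", f)[[1L]]
  toks <- regmatches(f, gregexpr("([A-Z][a-z]?)([0-9]*)", f))[[1L]]
  if (!length(toks) || sum(nchar(toks)) != nchar(f))
    stop("cannot parse chemical formula: '", f, "'")
  out <- numeric(0)
  for (t in toks) {
    el <- sub("[0-9]*$", "", t)
    cnt <- sub("^[A-Za-z]+", "", t)
    cnt <- if (nzchar(cnt)) as.numeric(cnt) else 1
    out[el] <- (if (el %in% names(out)) out[el] else 0) + cnt
  }
  out
}

#' Check elemental and charge balance of all reactions
#'
#' Non-exchange reactions whose net elemental composition or net charge is
#' nonzero are reported as imbalanced.  Reactions involving a metabolite
#' without a formula cannot be verified and are reported separately, not as
#' imbalanced.  Exchange reactions are unbalanced by design and skipped.
#'
#' @param model a [MetabolicModel-class].
#' @return list with \code{imbalanced} (named list: reaction id -> named
#'   vector of net element/charge totals) and \code{unverifiable}
#'   (character vector of reaction ids).
#' @export
checkMassChargeBalance <- function(model) {
  met <- model@metabolites
  if (all(is.na(met$formula)))
    stop("no metabolite has a formula; balance checking is impossible")
  formulas <- lapply(met$formula, .parseFormula)
  rxn <- model@reactions
  imb <- list(); unver <- character(0)
  for (j in seq_len(nrow(rxn))) {
    if (rxn$exchange[j]) next
    st <- model@S[, j]
    nz <- which(st != 0)
    if (any(vapply(formulas[nz], is.null, NA))) {
      unver <- c(unver, rxn$id[j])
      next
    }
    tot <- numeric(0)
    chg <- 0
    for (k in nz) {
      fo <- formulas[[k]] * st[k]
      for (el in names(fo))
        tot[el] <- (if (el %in% names(tot)) tot[el] else 0) + fo[el]
      ch <- met$charge[k]
      chg <- chg + (if (is.na(ch)) 0 else ch) * unname(st[k])
    }
    tot <- c(tot, charge = chg)
    tot <- tot[abs(tot) > 1e-9]
    if (length(tot)) imb[[rxn$id[j]]] <- tot
  }
  list(imbalanced = imb, unverifiable = unver)
}
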