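## SBML Level 3 I/O with FBC-style bounds, objective and GPRs.
##
## No libsbml binding exists for R, so a pragmatic subset is implemented on
## xml2.  The writer emits Level 3 Version 1 + fbc version 2
## (bounds-as-parameters).  The reader is dialect-tolerant: it resolves
## bounds from fbc v2 parameter references, fbc v1 listOfFluxBounds, or
## COBRA-style kineticLaw LOCAL parameters, falling back to the
## `reversible` attribute; all lookups are by local name so namespace
## prefixes do not matter.

.SBML_CORE <- "http://www.sbml.org/sbml/level3/version1/core"
.SBML_FBC2 <- "http://www.sbml.org/sbml/level3/version1/fbc/version2"

.checkSId <- function(ids, what) {
  bad <- ids[!grepl("^[A-Za-z_][A-Za-z0-9_]*$", ids)]
  if (length(bad))
    stop("invalid SBML identifiers for ", what, ": ",
         paste(bad, collapse = ", "))
  ids
}

#' Write a model as SBML
#'
#' Emits SBML Level 3 Version 1 with the fbc (version 2) flux-bound,
#' objective and gene-product-association extensions.  Subsystem and
#' spontaneity annotations are carried in COBRA-style notes.
#'
#' @param model a [MetabolicModel-class].
#' @param path output file path.
#' @return the path, invisibly.
#' @export
writeSBMLModel <- function(model, path) {
  met <- model@metabolites; rxn <- model@reactions
  .checkSId(met$id, "metabolites"); .checkSId(rxn$id, "reactions")
  .checkSId(model@genes, "genes")
  esc <- function(x) {
    x <- gsub("&", "&amp;", x); x <- gsub("<", "&lt;", x)
    x <- gsub(">", "&gt;", x); gsub("\"", "&quot;", x)
  }
  out <- c(
    "<?xml version=\"1.0\" encoding=\"UTF-8\"?>",
    paste0("<sbml xmlns=\"", .SBML_CORE, "\" xmlns:fbc=\"", .SBML_FBC2,
           "\" level=\"3\" version=\"1\" fbc:required=\"false\">"),
    paste0("  <model id=\"", esc(model@id), "\" fbc:strict=\"true\">"),
    "    <listOfCompartments>",
    paste0("      <compartment id=\"", esc(model@compartments),
           "\" constant=\"true\"/>"),
    "    </listOfCompartments>",
    "    <listOfSpecies>")
  for (i in seq_len(nrow(met))) {
    extra <- ""
    if (!is.na(met$formula[i]))
      extra <- paste0(extra, " fbc:chemicalFormula=\"", esc(met$formula[i]), "\"")
    if (!is.na(met$charge[i]))
      extra <- paste0(extra, " fbc:charge=\"", met$charge[i], "\"")
    out <- c(out, paste0(
      "      <species id=\"", met$id[i], "\" name=\"", esc(met$name[i]),
      "\" compartment=\"", met$compartment[i],
      "\" hasOnlySubstanceUnits=\"false\" boundaryCondition=\"false\"",
      " constant=\"false\"", extra, "/>"))
  }
  out <- c(out, "    </listOfSpecies>", "    <listOfParameters>")
  for (i in seq_len(nrow(rxn))) {
    out <- c(out,
      paste0("      <parameter id=\"", rxn$id[i], "_lower\" value=\"",
             rxn$lb[i], "\" constant=\"true\"/>"),
      paste0("      <parameter id=\"", rxn$id[i], "_upper\" value=\"",
             rxn$ub[i], "\" constant=\"true\"/>"))
  }
  out <- c(out, "    </listOfParameters>")
  if (length(model@genes)) {
    out <- c(out, "    <fbc:listOfGeneProducts>",
      paste0("      <fbc:geneProduct fbc:id=\"G_", model@genes,
             "\" fbc:label=\"", esc(model@genes), "\"/>"),
      "    </fbc:listOfGeneProducts>")
  }
  gprXML <- function(g, indent) {
    pad <- strrep(" ", indent)
    if (.gprIsLeaf(g))
      return(paste0(pad, "<fbc:geneProductRef fbc:geneProduct=\"G_", g, "\"/>"))
    tag <- paste0("fbc:", g$op)
    c(paste0(pad, "<", tag, ">"),
      unlist(lapply(g$args, gprXML, indent = indent + 2L)),
      paste0(pad, "</", tag, ">"))
  }
  out <- c(out, "    <listOfReactions>")
  for (i in seq_len(nrow(rxn))) {
    st <- model@S[, i]
    nz <- which(st != 0)
    out <- c(out, paste0(
      "      <reaction id=\"", rxn$id[i], "\" name=\"", esc(rxn$name[i]),
      "\" reversible=\"", tolower(rxn$lb[i] < 0), "\" fast=\"false\"",
      " fbc:lowerFluxBound=\"", rxn$id[i], "_lower\"",
      " fbc:upperFluxBound=\"", rxn$id[i], "_upper\">"))
    notes <- character(0)
    if (nzchar(rxn$subsystem[i]))
      notes <- c(notes, paste0("<p>SUBSYSTEM: ", esc(rxn$subsystem[i]), "</p>"))
    if (rxn$spontaneous[i])
      notes <- c(notes, "<p>SPONTANEOUS: true</p>")
    if (length(notes))
      out <- c(out,
        "        <notes><body xmlns=\"http://www.w3.org/1999/xhtml\">",
        paste0("          ", notes),
        "        </body></notes>")
    g <- model@gprs[[i]]
    if (!is.null(g))
      out <- c(out, "        <fbc:geneProductAssociation>",
               gprXML(g, 10L), "        </fbc:geneProductAssociation>")
    rct <- nz[st[nz] < 0]; prd <- nz[st[nz] > 0]
    if (length(rct)) out <- c(out, "        <listOfReactants>",
      paste0("          <speciesReference species=\"", met$id[rct],
             "\" stoichiometry=\"", -st[rct], "\" constant=\"true\"/>"),
      "        </listOfReactants>")
    if (length(prd)) out <- c(out, "        <listOfProducts>",
      paste0("          <speciesReference species=\"", met$id[prd],
             "\" stoichiometry=\"", st[prd], "\" constant=\"true\"/>"),
      "        </listOfProducts>")
    out <- c(out, "      </reaction>")
  }
  out <- c(out, "    </listOfReactions>")
  if (length(model@objective) == 1L && !is.na(model@objective)) {
    out <- c(out,
      "    <fbc:listOfObjectives fbc:activeObjective=\"obj\">",
      "      <fbc:objective fbc:id=\"obj\" fbc:type=\"maximize\">",
      "        <fbc:listOfFluxObjectives>",
      paste0("          <fbc:fluxObjective fbc:reaction=\"", model@objective,
             "\" fbc:coefficient=\"1\"/>"),
      "        </fbc:listOfFluxObjectives>",
      "      </fbc:objective>",
      "    </fbc:listOfObjectives>")
  }
  out <- c(out, "  </model>", "</sbml>")
  writeLines(out, path)
  invisible(path)
}

## attribute lookup ignoring namespace prefixes
.xattr <- function(node, local) {
  at <- xml2::xml_attrs(node)
  hit <- which(sub("^.*:", "", names(at)) == local)
  if (length(hit)) unname(at[hit[1L]]) else NA_character_
}

.xfind <- function(node, local)
  xml2::xml_find_all(node, paste0(".//*[local-name()='", local, "']"))

#' Read a model from SBML
#'
#' Parses SBML Level 3 with FBC-style annotations (see
#' [writeSBMLModel()] for the dialects tolerated).  Exchange reactions are
#' auto-detected by the single-extracellular-metabolite rule.
#'
#' @param path SBML file path.
#' @param extracellular id of the extracellular compartment (default "e").
#' @param defaultBound bound magnitude used when a file gives none.
#' @return a [MetabolicModel-class].
#' @export
readSBMLModel <- function(path, extracellular = "e", defaultBound = 1000) {
  doc <- tryCatch(xml2::read_xml(path), error = function(e)
    stop("malformed SBML XML in '", path, "': ", conditionMessage(e)))
  modelNode <- .xfind(doc, "model")
  if (!length(modelNode)) stop("no <model> element in '", path, "'")
  modelNode <- modelNode[[1L]]
  mid <- .xattr(modelNode, "id"); if (is.na(mid)) mid <- "model"

  comps <- vapply(.xfind(modelNode, "compartment"), .xattr, "", local = "id")

  spNodes <- .xfind(modelNode, "species")
  met <- data.frame(
    id = vapply(spNodes, .xattr, "", local = "id"),
    name = vapply(spNodes, function(n) {
      v <- .xattr(n, "name"); if (is.na(v)) .xattr(n, "id") else v }, ""),
    compartment = vapply(spNodes, .xattr, "", local = "compartment"),
    formula = vapply(spNodes, .xattr, "", local = "chemicalFormula"),
    charge = suppressWarnings(as.integer(
      vapply(spNodes, .xattr, "", local = "charge"))),
    stringsAsFactors = FALSE)

  params <- .xfind(modelNode, "parameter")
  pval <- suppressWarnings(as.numeric(vapply(params, .xattr, "", local = "value")))
  names(pval) <- vapply(params, .xattr, "", local = "id")

  ## fbc v1 global flux bounds: reaction/operation/value triples
  fb1 <- .xfind(modelNode, "fluxBound")
  fb1tab <- if (length(fb1)) data.frame(
    reaction = vapply(fb1, .xattr, "", local = "reaction"),
    operation = vapply(fb1, .xattr, "", local = "operation"),
    value = as.numeric(vapply(fb1, .xattr, "", local = "value")),
    stringsAsFactors = FALSE) else NULL

  gpNodes <- .xfind(modelNode, "geneProduct")
  gpLabel <- vapply(gpNodes, function(n) {
    v <- .xattr(n, "label"); if (is.na(v)) sub("^G_", "", .xattr(n, "id")) else v
  }, "")
  names(gpLabel) <- vapply(gpNodes, .xattr, "", local = "id")

  parseAssoc <- function(node) {
    nm <- xml2::xml_name(node)
    if (nm == "geneProductRef") {
      ref <- .xattr(node, "geneProduct")
      if (ref %in% names(gpLabel)) return(unname(gpLabel[ref]))
      return(sub("^G_", "", ref))
    }
    if (nm %in% c("and", "or")) {
      kids <- xml2::xml_children(node)
      return(list(op = nm, args = lapply(kids, parseAssoc)))
    }
    kids <- xml2::xml_children(node)
    if (length(kids) == 1L) return(parseAssoc(kids[[1L]]))
    stop("cannot parse gene association element <", nm, ">")
  }

  rxNodes <- xml2::xml_find_all(modelNode,
    ".//*[local-name()='listOfReactions']/*[local-name()='reaction']")
  n <- length(rxNodes)
  ids <- vapply(rxNodes, .xattr, "", local = "id")
  lb <- ub <- rep(NA_real_, n)
  eqs <- character(n); gprstr <- character(n)
  subsys <- character(n); spont <- logical(n)
  for (i in seq_len(n)) {
    node <- rxNodes[[i]]
    refs <- function(kind) {
      side <- xml2::xml_find_all(node,
        paste0("./*[local-name()='", kind, "']/*[local-name()='speciesReference']"))
      if (!length(side)) return(numeric(0))
      sp <- vapply(side, .xattr, "", local = "species")
      sto <- suppressWarnings(as.numeric(
        vapply(side, .xattr, "", local = "stoichiometry")))
      sto[is.na(sto)] <- 1
      stats::setNames(sto, sp)
    }
    rct <- refs("listOfReactants"); prd <- refs("listOfProducts")
    missing <- setdiff(c(names(rct), names(prd)), met$id)
    if (length(missing))
      stop("reaction '", ids[i], "' references unknown metabolites: ",
           paste(missing, collapse = ", "))
    ## bounds: fbc v2 parameter refs, then fbc v1, then kineticLaw locals
    lref <- .xattr(node, "lowerFluxBound"); uref <- .xattr(node, "upperFluxBound")
    if (!is.na(lref) && lref %in% names(pval)) lb[i] <- pval[lref]
    if (!is.na(uref) && uref %in% names(pval)) ub[i] <- pval[uref]
    if (!is.null(fb1tab)) {
      rows <- fb1tab[fb1tab$reaction == ids[i], , drop = FALSE]
      for (k in seq_len(nrow(rows))) {
        op <- rows$operation[k]
        if (op %in% c("greaterEqual", "greater")) lb[i] <- rows$value[k]
        if (op %in% c("lessEqual", "less")) ub[i] <- rows$value[k]
        if (op == "equal") { lb[i] <- rows$value[k]; ub[i] <- rows$value[k] }
      }
    }
    locals <- xml2::xml_find_all(node,
      ".//*[local-name()='kineticLaw']//*[local-name()='localParameter' or local-name()='parameter']")
    for (lp in locals) {
      pid <- .xattr(lp, "id")
      pv <- suppressWarnings(as.numeric(.xattr(lp, "value")))
      if (identical(pid, "LOWER_BOUND")) lb[i] <- pv
      if (identical(pid, "UPPER_BOUND")) ub[i] <- pv
    }
    rev <- identical(tolower(.xattr(node, "reversible")), "true")
    if (is.na(lb[i])) lb[i] <- if (rev) -defaultBound else 0
    if (is.na(ub[i])) ub[i] <- defaultBound

    st <- numeric(0)
    for (m2 in names(rct)) st[m2] <- (if (m2 %in% names(st)) st[m2] else 0) - rct[m2]
    for (m2 in names(prd)) st[m2] <- (if (m2 %in% names(st)) st[m2] else 0) + prd[m2]
    st <- st[st != 0]
    eqs[i] <- .equationString(st, lb[i] < 0)

    assoc <- xml2::xml_find_first(node,
      "./*[local-name()='geneProductAssociation']")
    gprstr[i] <- if (inherits(assoc, "xml_missing")) "" else
      gprToString(parseAssoc(xml2::xml_children(assoc)[[1L]]))

    for (p in xml2::xml_find_all(node, ".//*[local-name()='p']")) {
      txt <- trimws(xml2::xml_text(p))
      if (grepl("^SUBSYSTEM:", txt)) subsys[i] <- trimws(sub("^SUBSYSTEM:", "", txt))
      if (grepl("^SPONTANEOUS:", txt))
        spont[i] <- tolower(trimws(sub("^SPONTANEOUS:", "", txt))) == "true"
    }
  }

  obj <- NA_character_
  fo <- .xfind(modelNode, "fluxObjective")
  if (length(fo)) obj <- .xattr(fo[[1L]], "reaction")

  names <- vapply(rxNodes, function(nd) {
    v <- .xattr(nd, "name"); if (is.na(v)) .xattr(nd, "id") else v }, "")
  rxn <- data.frame(id = ids, name = names, equation = eqs, lb = lb, ub = ub,
                    gpr = gprstr, subsystem = subsys, spontaneous = spont,
                    stringsAsFactors = FALSE)
  met$formula[met$formula == ""] <- NA_character_
  MetabolicModel(mid, rxn, metabolites = met, objective = obj,
                 extracellular = extracellular, compartments = comps)
}
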