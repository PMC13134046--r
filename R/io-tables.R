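## TSV model dialect: reactions.tsv / metabolites.tsv / genes.tsv in one
## directory.  Tab-separated, UTF-8, "#" starts a comment line.

#' Read a model from a TSV directory
#'
#' Expects \code{reactions.tsv} with columns id, equation, lb, ub, gpr,
#' subsystem (plus optional name, spontaneous, objective flag column) and
#' optionally \code{metabolites.tsv} (id, name, compartment, formula,
#' charge) and \code{genes.tsv} (id).  Equations use the
#' \code{"A + 2 B -> C"} dialect with \code{"<=>"} for reversible
#' reactions.
#'
#' @param dir directory containing the tables.
#' @param extracellular extracellular compartment id (default "e").
#' @return a [MetabolicModel-class].
#' @export
readModelTables <- function(dir, extracellular = "e") {
  rpath <- file.path(dir, "reactions.tsv")
  if (!file.exists(rpath)) stop("missing reactions.tsv in '", dir, "'")
  rxn <- utils::read.delim(rpath, comment.char = "#", stringsAsFactors = FALSE)
  need <- c("id", "equation")
  miss <- setdiff(need, names(rxn))
  if (length(miss))
    stop("reactions.tsv lacks required columns: ", paste(miss, collapse = ", "))
  for (i in seq_len(nrow(rxn)))
    tryCatch(.parseEquation(rxn$equation[i]),
             error = function(e) stop("reactions.tsv line ", i + 1L, ": ",
                                      conditionMessage(e)))
  met <- NULL
  mpath <- file.path(dir, "metabolites.tsv")
  if (file.exists(mpath))
    met <- utils::read.delim(mpath, comment.char = "#", stringsAsFactors = FALSE)
  genes <- NULL
  gpath <- file.path(dir, "genes.tsv")
  if (file.exists(gpath))
    genes <- utils::read.delim(gpath, comment.char = "#",
                               stringsAsFactors = FALSE)$id
  obj <- NA_character_
  if ("objective" %in% names(rxn)) {
    flag <- which(as.logical(rxn$objective) %in% TRUE)
    if (length(flag)) obj <- rxn$id[flag[1L]]
  }
  mid <- basename(normalizePath(dir, mustWork = FALSE))
  MetabolicModel(mid, rxn, metabolites = met, genes = genes, objective = obj,
                 extracellular = extracellular)
}

#' Write a model as TSV tables
#'
#' Inverse of [readModelTables()]: writes reactions.tsv, metabolites.tsv
#' and genes.tsv into \code{dir}.
#'
#' @param model a [MetabolicModel-class].
#' @param dir output directory (created if needed).
#' @return the directory, invisibly.
#' @export
writeModelTables <- function(model, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  tb <- .modelToTables(model)
  rxn <- tb$reactions
  rxn$objective <- rxn$id == model@objective
  cols <- c("id", "name", "equation", "lb", "ub", "gpr", "subsystem",
            "spontaneous", "exchange", "objective")
  utils::write.table(rxn[cols], file.path(dir, "reactions.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(tb$metabolites, file.path(dir, "metabolites.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(data.frame(id = model@genes),
                     file.path(dir, "genes.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(dir)
}
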