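## Growth media: construction, flux-cap estimation, application to models.

#' Construct a Medium
#'
#' @param caps data.frame with columns exchange_id, lb, ub (mmol/gDW/h;
#'   uptake negative, secretion positive).  May be empty.
#' @param defaultUptakePolicy bounds for exchanges not listed: "closed"
#'   (lb 0, ub +1000 -- no uptake, free secretion) or "open" (lb -1000,
#'   ub +1000).
#' @return a [Medium-class] object.
#' @export
Medium <- function(caps = data.frame(exchange_id = character(0),
                                     lb = numeric(0), ub = numeric(0)),
                   defaultUptakePolicy = "closed") {
  caps$exchange_id <- as.character(caps$exchange_id)
  new("Medium", caps = caps[c("exchange_id", "lb", "ub")],
      defaultUptakePolicy = defaultUptakePolicy)
}

#' Estimate an exchange-flux cap from two concentration measurements
#'
#' Computes the average specific exchange flux
#' \deqn{v = (C_t - C_0) / (\Delta t \cdot X)}
#' from metabolite concentrations at two time points and the biomass
#' density, in mmol/gDW/h.  A falling concentration gives a negative value
#' (uptake), a rising one a positive value (secretion); the result is used
#' as a conservative cap on the matching exchange reaction (lower bound
#' when negative, upper bound when positive).
#'
#' @param C0 concentration at the first time point (mmol/L).
#' @param Ct concentration at the second time point (mmol/L).
#' @param dt elapsed time (h); must be > 0.
#' @param X biomass density (gDW/L); must be > 0.
#' @return signed flux in mmol/gDW/h.
#' @examples
#' estimateUptakeCap(C0 = 10, Ct = 4, dt = 3, X = 0.5)  # -4
#' @export
estimateUptakeCap <- function(C0, Ct, dt, X) {
  if (any(dt <= 0)) stop("dt must be positive (hours)")
  if (any(X <= 0)) stop("biomass density X must be positive (gDW/L)")
  (Ct - C0) / (dt * X)
}

#' Build a Medium from a mixed cap/concentration table
#'
#' Each row either gives a direct cap (columns \code{lb}/\code{ub}, with
#' the literal string \code{"amino_acid_default"} in \code{lb} standing for
#' the bulk amino-acid uptake rate), or a concentration pair (columns
#' \code{C0}, \code{Ct}, \code{dt_h}, \code{X_gDW_per_L}) from which the
#' cap is estimated with [estimateUptakeCap()].
#'
#' @param table data.frame with column \code{exchange_id} plus cap or
#'   concentration columns.
#' @param aaDefault bulk amino-acid uptake rate in mmol/gDW/h (default
#'   0.5); applied as a cap of (-aaDefault, 1000).
#' @param defaultBound secretion bound used when only an uptake cap is
#'   derived.
#' @param defaultUptakePolicy passed to [Medium()].
#' @return a [Medium-class].
#' @export
buildMedium <- function(table, aaDefault = 0.5, defaultBound = 1000,
                        defaultUptakePolicy = "closed") {
  if (!nrow(table))
    return(Medium(defaultUptakePolicy = defaultUptakePolicy))
  stopifnot("exchange_id" %in% names(table))
  if (anyDuplicated(table$exchange_id)) {
    dup <- unique(table$exchange_id[duplicated(table$exchange_id)])
    stop("conflicting duplicate medium rows for: ", paste(dup, collapse = ", "))
  }
  n <- nrow(table)
  lb <- rep(NA_real_, n); ub <- rep(NA_real_, n)
  hasConc <- all(c("C0", "Ct", "dt_h", "X_gDW_per_L") %in% names(table))
  for (i in seq_len(n)) {
    if (hasConc && !is.na(table$C0[i]) && !is.na(table$Ct[i])) {
      v <- estimateUptakeCap(table$C0[i], table$Ct[i],
                             table$dt_h[i], table$X_gDW_per_L[i])
      if (v < 0) { lb[i] <- v; ub[i] <- defaultBound }
      else { lb[i] <- 0; ub[i] <- max(v, 0) }
    } else if ("lb" %in% names(table) && !is.na(table$lb[i])) {
      if (identical(as.character(table$lb[i]), "amino_acid_default")) {
        lb[i] <- -aaDefault; ub[i] <- defaultBound
      } else {
        lb[i] <- as.numeric(as.character(table$lb[i]))
        ub[i] <- if ("ub" %in% names(table) && !is.na(table$ub[i]))
          as.numeric(as.character(table$ub[i])) else defaultBound
      }
    } else {
      stop("medium row for '", table$exchange_id[i],
           "' has neither a cap nor a concentration pair")
    }
  }
  Medium(data.frame(exchange_id = as.character(table$exchange_id),
                    lb = lb, ub = ub, stringsAsFactors = FALSE),
         defaultUptakePolicy = defaultUptakePolicy)
}

#' Apply a medium to a model
#'
#' Sets the bounds of every exchange reaction from the medium: listed
#' exchanges get their caps, unlisted ones follow the medium's default
#' uptake policy, and \code{overrides} are applied last (e.g. closing the
#' cellobiose uptake with \code{list(EX_cellb = c(0, 1000))}).  Medium caps
#' that reference unknown reactions produce a warning; overrides naming a
#' non-exchange reaction are an error.
#'
#' @param model a [MetabolicModel-class].
#' @param medium a [Medium-class].
#' @param overrides named list: exchange id -> c(lb, ub).
#' @param defaultBound magnitude used by the default policy.
#' @return the model with exchange bounds set.
#' @export
applyMedium <- function(model, medium, overrides = list(), defaultBound = 1000) {
  rxn <- model@reactions
  exch <- rxn$id[rxn$exchange]
  caps <- medium@caps
  unknown <- setdiff(caps$exchange_id, rxn$id)
  if (length(unknown))
    warning("medium caps for reactions not in the model: ",
            paste(unknown, collapse = ", "))
  notexch <- setdiff(intersect(caps$exchange_id, rxn$id), exch)
  if (length(notexch))
    warning("medium caps for non-exchange reactions are ignored: ",
            paste(notexch, collapse = ", "))
  ## default policy first
  lb <- if (medium@defaultUptakePolicy == "closed") 0 else -defaultBound
  model <- setReactionBounds(model, exch, lb = lb, ub = defaultBound)
  listed <- intersect(caps$exchange_id, exch)
  if (length(listed)) {
    k <- match(listed, caps$exchange_id)
    model <- setReactionBounds(model, listed, lb = caps$lb[k], ub = caps$ub[k])
  }
  if (length(overrides)) {
    bad <- setdiff(names(overrides), exch)
    if (length(bad))
      stop("overrides must name exchange reactions; not exchanges: ",
           paste(bad, collapse = ", "))
    for (id in names(overrides)) {
      b <- overrides[[id]]
      model <- setReactionBounds(model, id, lb = b[1], ub = b[2])
    }
  }
  model
}

#' Read / write a medium TSV
#'
#' Tab-separated with columns \code{exchange_id}, \code{lower_bound},
#' \code{upper_bound}; the extended dialect may instead carry
#' \code{C0}, \code{Ct}, \code{dt_h}, \code{X_gDW_per_L} columns which
#' trigger the concentration-based estimator.  Lines starting with
#' \code{#} are comments.
#'
#' @param path file path.
#' @param ... passed to [buildMedium()].
#' @return [readMediumTable()] returns a [Medium-class].
#' @export
readMediumTable <- function(path, ...) {
  tb <- utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
  nm <- names(tb)
  nm[nm == "lower_bound"] <- "lb"
  nm[nm == "upper_bound"] <- "ub"
  names(tb) <- nm
  buildMedium(tb, ...)
}

#' @rdname readMediumTable
#' @param medium a [Medium-class] to write.
#' @export
writeMediumTable <- function(medium, path) {
  df <- medium@caps
  names(df) <- c("exchange_id", "lower_bound", "upper_bound")
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
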