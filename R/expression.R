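## Transcriptome contextualization: CPM normalization, expression-to-
## reaction mapping, GIMME and pruning of inactive reactions.

#' CPM-normalize raw read counts
#'
#' Counts per million: \eqn{CPM_g = count_g / \sum count \times 10^6}.
#' The high-expression threshold is the given percentile of the CPM
#' distribution -- computed over the genes present in the model when one is
#' supplied (the recommended usage), otherwise over all profiled genes.
#'
#' @param counts named numeric vector of raw read counts per gene.
#' @param model optional [MetabolicModel-class] restricting the genes over
#'   which the percentile is taken.
#' @param percentile percentile in (0, 100) defining "highly expressed"
#'   (default 70: genes above the 70th percentile).
#' @return an [ExpressionProfile-class].
#' @export
cpmNormalize <- function(counts, model = NULL, percentile = 70) {
  stopifnot(percentile > 0, percentile < 100)
  if (is.null(names(counts)) || !all(nzchar(names(counts))))
    stop("counts must be named by gene id")
  total <- sum(counts)
  if (total <= 0) stop("all-zero counts: cannot normalize")
  cpm <- counts / total * 1e6
  ref <- if (!is.null(model)) cpm[names(cpm) %in% genes(model)] else cpm
  if (!length(ref))
    stop("no profiled gene matches the model gene set")
  thr <- unname(stats::quantile(ref, percentile / 100))
  new("ExpressionProfile", cpm = cpm, librarySize = total,
      percentile = percentile, threshold = thr)
}

setMethod("show", "ExpressionProfile", function(object) {
  cat("ExpressionProfile: ", length(object@cpm), " genes, library size ",
      object@librarySize, "\n  threshold: ", format(object@threshold),
      " CPM (", object@percentile, "th percentile)\n", sep = "")
})

#' Map gene expression onto reactions
#'
#' Aggregates gene CPM values through each reaction's GPR: AND nodes take
#' the minimum of their children (a complex is limited by its scarcest
#' subunit), OR nodes the maximum (isoenzymes add up to the best one).
#' Genes missing from the profile score 0 with a warning; reactions
#' without gene association stay unscored (NA).
#'
#' @param model a [MetabolicModel-class].
#' @param profile an [ExpressionProfile-class].
#' @return a [ReactionScores-class].
#' @export
mapExpressionToReactions <- function(model, profile) {
  missing <- setdiff(genes(model), names(profile@cpm))
  if (length(missing))
    warning("model genes absent from the expression profile score 0: ",
            paste(missing, collapse = ", "))
  sc <- vapply(model@gprs, .gprScore, 0, scores = profile@cpm)
  names(sc) <- model@reactions$id
  new("ReactionScores", scores = sc, threshold = profile@threshold)
}

setMethod("show", "ReactionScores", function(object) {
  cat("ReactionScores: ", sum(!is.na(object@scores)), " scored / ",
      length(object@scores), " reactions; threshold ",
      format(object@threshold), " CPM\n", sep = "")
})

#' GIMME context-specific flux prediction
#'
#' Minimizes flux through low-expression reactions while enforcing a
#' minimum growth rate: solves
#' \deqn{\min \sum_i c_i |v_i| \quad s.t.\ S v = 0,\ bounds,\
#'       v_{biomass} \ge f \cdot v^{opt}}
#' with penalties \eqn{c_i = \max(0, t - score_i)} on gene-associated,
#' non-blocked reactions scoring below the threshold \eqn{t}.  Blocked
#' reactions (infeasible regardless of expression) and reactions without
#' gene association are never penalized.
#'
#' @param model a [MetabolicModel-class].
#' @param medium optional [Medium-class].
#' @param scores a [ReactionScores-class] from
#'   [mapExpressionToReactions()].
#' @param growthFraction required fraction of optimal growth (default 0.9).
#' @param tol zero-flux tolerance.
#' @return list with \code{solution} (a [FluxSolution-class]),
#'   \code{penalty} (optimal penalty objective), \code{penalized}
#'   (penalized reaction ids) and \code{inactive} (penalized reactions
#'   carrying zero flux -- the candidates for pruning).
#' @export
gimme <- function(model, medium = NULL, scores, growthFraction = 0.9,
                  tol = 1e-6) {
  stopifnot(is(scores, "ReactionScores"))
  if (!is.null(medium)) model <- applyMedium(model, medium)
  cvec <- .objVector(model, NULL)
  lp <- .lpData(model)
  wt <- .solveModelLP(lp, cvec, maximize = TRUE)
  if (wt$status != "optimal" || wt$objval <= 1e-9)
    stop("GIMME needs positive wild-type growth (status: ", wt$status, ")")
  blocked <- findBlockedReactions(model)
  sc <- scores@scores[lp$ids]
  pen <- pmax(0, scores@threshold - sc)
  pen[is.na(pen)] <- 0                       # unscored: no gene association
  pen[lp$ids %in% blocked] <- 0
  res <- .minWeightedFlux(lp, weights = unname(pen),
    fixRows = list(list(coef = cvec, rhs = growthFraction * wt$objval,
                        sense = ">=")))
  if (res$status != "optimal")
    stop("GIMME LP ", res$status, " at growth fraction ", growthFraction,
         "; try a lower fraction")
  v <- res$v
  names(v) <- lp$ids
  sol <- new("FluxSolution", objectiveValue = sum(cvec * v), fluxes = v,
             status = "optimal", method = "pfba",
             metadata = list(gimmePenalty = res$total))
  penalized <- lp$ids[pen > 0]
  list(solution = sol, penalty = res$total, penalized = penalized,
       inactive = penalized[abs(v[penalized]) < tol])
}

#' Prune inactive reactions after contextualization
#'
#' Knocks out (bounds to zero, never structural deletion) the reactions
#' that carry no flux in the contextualized solution and are
#' gene-associated, non-spontaneous and not essential.
#'
#' @param model a [MetabolicModel-class].
#' @param solution a [FluxSolution-class] (e.g. \code{gimme(...)$solution}).
#' @param essentials reaction ids protected from pruning (typically from
#'   [singleReactionDeletion()]).
#' @param tol zero-flux tolerance.
#' @return list with \code{model} (pruned) and \code{knockedOut}
#'   (character vector of deactivated reaction ids).
#' @export
pruneInactive <- function(model, solution, essentials = character(0),
                          tol = 1e-6) {
  stopifnot(is(solution, "FluxSolution"))
  if (solutionStatus(solution) != "optimal")
    stop("pruneInactive needs an optimal solution")
  v <- fluxes(solution)
  rxn <- model@reactions
  ga <- !vapply(model@gprs, is.null, NA)
  idle <- rxn$id %in% names(v)[abs(v) < tol]
  cand <- rxn$id[idle & ga & !rxn$spontaneous & !(rxn$id %in% essentials)]
  out <- if (length(cand)) deactivateReactions(model, cand) else model
  list(model = out, knockedOut = cand)
}

#' One-call transcriptome contextualization
#'
#' Convenience pipeline: CPM-normalize counts, map them to reactions, run
#' GIMME, protect essential reactions, and prune the inactive ones.
#'
#' @param model a [MetabolicModel-class].
#' @param medium a [Medium-class].
#' @param counts named numeric raw counts.
#' @param percentile high-expression percentile (default 70).
#' @param growthFraction minimum growth fraction (default 0.9).
#' @param fEss essentiality threshold protecting reactions from pruning.
#' @return list with \code{model}, \code{solution}, \code{profile},
#'   \code{scores}, \code{knockedOut}, \code{penalty}.
#' @export
contextualizeModel <- function(model, medium, counts, percentile = 70,
                               growthFraction = 0.9, fEss = 0.9) {
  profile <- cpmNormalize(counts, model = model, percentile = percentile)
  scores <- mapExpressionToReactions(model, profile)
  g <- gimme(model, medium, scores, growthFraction = growthFraction)
  ess <- singleReactionDeletion(model, medium, fEss = fEss)
  pruned <- pruneInactive(if (is.null(medium)) model else
                            applyMedium(model, medium),
                          g$solution,
                          essentials = ess$reaction_id[ess$essential])
  list(model = pruned$model, solution = g$solution, profile = profile,
       scores = scores, knockedOut = pruned$knockedOut, penalty = g$penalty)
}
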