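## Constraint engine: FBA, parsimonious FBA, FVA, essentiality.
##
## All operations reduce to the internal LP interface .solveModelLP(), which
## augments the steady-state system S v = 0 with optional extra linear rows
## (objective-fixing constraints) via slack columns and hands the problem to
## the simplex core in lp-simplex.R.

.lpData <- function(model) {
  list(S = as.matrix(model@S),
       lb = model@reactions$lb,
       ub = model@reactions$ub,
       ids = model@reactions$id)
}

## objective spec -> coefficient vector over reactions
.objVector <- function(model, objective = NULL) {
  ids <- model@reactions$id
  if (is.null(objective)) objective <- model@objective
  if (is.numeric(objective) && !is.null(names(objective))) {
    bad <- setdiff(names(objective), ids)
    if (length(bad)) stop("objective references unknown reactions: ",
                          paste(bad, collapse = ", "))
    cv <- numeric(length(ids)); names(cv) <- ids
    cv[names(objective)] <- objective
    return(unname(cv))
  }
  if (is.na(objective) || !objective %in% ids)
    stop("objective reaction not found: ", objective)
  as.numeric(ids == objective)
}

## extraRows: list of list(coef, rhs, sense in c("=", ">=", "<="))
.solveModelLP <- function(lp, cvec, maximize = TRUE, extraRows = list()) {
  n <- ncol(lp$S)
  A <- lp$S
  b <- rep(0, nrow(A))
  lb <- lp$lb; ub <- lp$ub
  obj <- cvec
  for (row in extraRows) {
    slack <- switch(row$sense, "=" = NULL, ">=" = -1, "<=" = 1)
    newrow <- c(row$coef, rep(0, ncol(A) - n))
    A <- rbind(A, newrow)
    b <- c(b, row$rhs)
    if (!is.null(slack)) {
      A <- cbind(A, c(rep(0, nrow(A) - 1L), slack))
      lb <- c(lb, 0); ub <- c(ub, Inf); obj <- c(obj, 0)
    }
  }
  res <- .lpSolve(obj, A, b, lb, ub, maximize = maximize)
  if (res$status == "optimal") res$x <- res$x[seq_len(n)]
  res
}

.fluxSolution <- function(res, lp, cvec, method, metadata = list()) {
  if (res$status != "optimal")
    return(new("FluxSolution", objectiveValue = NA_real_,
               fluxes = stats::setNames(numeric(0), character(0)),
               status = res$status, method = method, metadata = metadata))
  v <- res$x
  names(v) <- lp$ids
  new("FluxSolution", objectiveValue = sum(cvec * res$x), fluxes = v,
      status = "optimal", method = method, metadata = metadata)
}

#' Flux balance analysis
#'
#' Maximizes the objective reaction flux subject to steady state
#' (\eqn{S v = 0}) and flux bounds.  If a medium is given, it is applied to
#' the exchange bounds first ([applyMedium()]).
#'
#' @param model a [MetabolicModel-class].
#' @param medium optional [Medium-class]; NULL uses the model bounds as
#'   they stand.
#' @param objective a reaction id, or a named numeric vector of objective
#'   coefficients (used for community objectives); default the model's
#'   objective reaction.
#' @return a [FluxSolution-class]; status "infeasible" or "unbounded" is
#'   reported faithfully with empty fluxes.
#' @export
fba <- function(model, medium = NULL, objective = NULL) {
  if (!is.null(medium)) model <- applyMedium(model, medium)
  cvec <- .objVector(model, objective)
  lp <- .lpData(model)
  res <- .solveModelLP(lp, cvec, maximize = TRUE)
  .fluxSolution(res, lp, cvec, "fba", metadata = list(degenerate = TRUE,
    note = "representative, possibly degenerate optimum"))
}

#' Parsimonious FBA
#'
#' Two-stage LP: the objective is first maximized (plain FBA), then fixed
#' at its optimum while the total absolute flux \eqn{\sum_i |v_i|} is
#' minimized (reversible reactions split into forward/backward parts with
#' unit weights).
#'
#' @inheritParams fba
#' @return a [FluxSolution-class] with method "pfba"; the objective value
#'   equals the FBA optimum (to 1e-9 relative).
#' @export
pfba <- function(model, medium = NULL, objective = NULL) {
  if (!is.null(medium)) model <- applyMedium(model, medium)
  cvec <- .objVector(model, objective)
  lp <- .lpData(model)
  stage1 <- .solveModelLP(lp, cvec, maximize = TRUE)
  if (stage1$status != "optimal")
    return(.fluxSolution(stage1, lp, cvec, "pfba"))
  opt <- stage1$objval
  res <- .minWeightedFlux(lp, weights = rep(1, ncol(lp$S)),
                          fixRows = list(list(coef = cvec, rhs = opt, sense = "=")))
  if (res$status != "optimal")
    return(.fluxSolution(res, lp, cvec, "pfba"))
  v <- res$v
  names(v) <- lp$ids
  new("FluxSolution", objectiveValue = sum(cvec * v), fluxes = v,
      status = "optimal", method = "pfba",
      metadata = list(totalFlux = res$total))
}

## minimize sum_i w_i |v_i| subject to S v = 0, bounds and fixRows, via the
## standard forward/backward split.  Weights may be zero.  Returns
## list(status, v, total = sum w|v|).
.minWeightedFlux <- function(lp, weights, fixRows = list()) {
  S <- lp$S; lb <- lp$lb; ub <- lp$ub
  n <- ncol(S)
  lbp <- pmax(lb, 0); ubp <- pmax(ub, 0)
  lbn <- pmax(-ub, 0); ubn <- pmax(-lb, 0)
  A <- cbind(S, -S)
  b <- rep(0, nrow(S))
  obj <- c(weights, weights)
  lbs <- c(lbp, lbn); ubs <- c(ubp, ubn)
  for (row in fixRows) {
    newrow <- c(row$coef, -row$coef, rep(0, ncol(A) - 2L * n))
    slack <- switch(row$sense, "=" = NULL, ">=" = -1, "<=" = 1)
    A <- rbind(A, newrow)
    b <- c(b, row$rhs)
    if (!is.null(slack)) {
      A <- cbind(A, c(rep(0, nrow(A) - 1L), slack))
      lbs <- c(lbs, 0); ubs <- c(ubs, Inf); obj <- c(obj, 0)
    }
  }
  res <- .lpSolve(obj, A, b, lbs, ubs, maximize = FALSE)
  if (res$status != "optimal") return(list(status = res$status))
  vp <- res$x[seq_len(n)]; vn <- res$x[n + seq_len(n)]
  list(status = "optimal", v = vp - vn, total = res$objval)
}

#' Flux variability analysis
#'
#' For each reaction, the minimum and maximum flux compatible with the
#' objective reaching at least \code{fraction} of its optimum.
#'
#' @inheritParams fba
#' @param fraction required fraction of the optimal objective, in (0, 1]
#'   (default 0.9).
#' @param reactions optional reaction ids to scan (default: all).
#' @return a [FluxRange-class].
#' @export
fva <- function(model, medium = NULL, fraction = 0.9, reactions = NULL,
                objective = NULL) {
  stopifnot(fraction > 0, fraction <= 1)
  if (!is.null(medium)) model <- applyMedium(model, medium)
  cvec <- .objVector(model, objective)
  lp <- .lpData(model)
  stage1 <- .solveModelLP(lp, cvec, maximize = TRUE)
  if (stage1$status != "optimal")
    stop("FVA requires a feasible, bounded model (FBA status: ",
         stage1$status, ")")
  opt <- stage1$objval
  rows <- list(list(coef = cvec, rhs = fraction * opt, sense = ">="))
  if (is.null(reactions)) reactions <- lp$ids
  j <- match(reactions, lp$ids)
  if (anyNA(j)) stop("unknown reactions: ",
                     paste(reactions[is.na(j)], collapse = ", "))
  mins <- maxs <- numeric(length(j))
  for (k in seq_along(j)) {
    e <- numeric(ncol(lp$S)); e[j[k]] <- 1
    lo <- .solveModelLP(lp, e, maximize = FALSE, extraRows = rows)
    hi <- .solveModelLP(lp, e, maximize = TRUE, extraRows = rows)
    if (lo$status != "optimal" || hi$status != "optimal")
      stop("FVA subproblem for '", reactions[k], "' returned ",
           lo$status, "/", hi$status,
           " -- consider a slightly lower fraction (numerical tolerance)")
    mins[k] <- lo$objval; maxs[k] <- hi$objval
  }
  ## guard against solver noise producing min > max on degenerate ranges
  flip <- mins > maxs
  if (any(flip)) {
    tmp <- mins[flip]; mins[flip] <- maxs[flip]; maxs[flip] <- tmp
  }
  new("FluxRange",
      ranges = data.frame(reaction_id = reactions, min = mins, max = maxs,
                          stringsAsFactors = FALSE),
      objectiveFraction = fraction)
}

#' Find blocked reactions
#'
#' Reactions that cannot carry flux in any feasible steady state under the
#' given medium (their flux minimum and maximum are both zero, with no
#' constraint on the objective).
#'
#' @inheritParams fba
#' @param tol zero-flux tolerance in mmol/gDW/h (default 1e-6).
#' @return character vector of blocked reaction ids.
#' @export
findBlockedReactions <- function(model, medium = NULL, tol = 1e-6) {
  if (!is.null(medium)) model <- applyMedium(model, medium)
  lp <- .lpData(model)
  feas <- .solveModelLP(lp, rep(0, ncol(lp$S)), maximize = TRUE)
  if (feas$status != "optimal")
    stop("model is infeasible under the given medium")
  blocked <- character(0)
  for (k in seq_along(lp$ids)) {
    e <- numeric(ncol(lp$S)); e[k] <- 1
    hi <- .solveModelLP(lp, e, maximize = TRUE)
    if (hi$status != "optimal" || abs(hi$objval) > tol) next
    lo <- .solveModelLP(lp, e, maximize = FALSE)
    if (lo$status == "optimal" && abs(lo$objval) < tol)
      blocked <- c(blocked, lp$ids[k])
  }
  blocked
}

.deletionGrowth <- function(lp, cvec, off) {
  if (length(off)) {
    j <- match(off, lp$ids)
    lp$lb[j] <- 0; lp$ub[j] <- 0
  }
  res <- .solveModelLP(lp, cvec, maximize = TRUE)
  if (res$status == "optimal") res$objval else 0
}

#' Single-gene deletion essentiality
#'
#' Each gene is knocked out in turn: reactions whose GPR evaluates FALSE
#' without the gene are constrained to zero flux and growth re-optimized by
#' plain FBA.  A gene is essential when the knockout prevents reaching
#' \code{fEss} of the wild-type optimum.
#'
#' @inheritParams fba
#' @param fEss essentiality threshold as a fraction of wild-type growth
#'   (default 0.9).
#' @return data.frame with columns gene, growth, essential.
#' @export
singleGeneDeletion <- function(model, medium = NULL, fEss = 0.9,
                               objective = NULL) {
  if (!is.null(medium)) model <- applyMedium(model, medium)
  cvec <- .objVector(model, objective)
  lp <- .lpData(model)
  wt <- .solveModelLP(lp, cvec, maximize = TRUE)
  if (wt$status != "optimal" || wt$objval <= 1e-9)
    stop("wild-type growth is zero or infeasible; essentiality is undefined")
  growth <- vapply(model@genes, function(g) {
    off <- .disabledReactions(model, g)
    if (!length(off)) wt$objval else .deletionGrowth(lp, cvec, off)
  }, 0)
  data.frame(gene = model@genes, growth = unname(growth),
             essential = unname(growth) < fEss * wt$objval - 1e-9,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Single-reaction deletion essentiality
#'
#' @inheritParams singleGeneDeletion
#' @return data.frame with columns reaction_id, growth, essential.
#' @export
singleReactionDeletion <- function(model, medium = NULL, fEss = 0.9,
                                   objective = NULL) {
  if (!is.null(medium)) model <- applyMedium(model, medium)
  cvec <- .objVector(model, objective)
  lp <- .lpData(model)
  wt <- .solveModelLP(lp, cvec, maximize = TRUE)
  if (wt$status != "optimal" || wt$objval <= 1e-9)
    stop("wild-type growth is zero or infeasible; essentiality is undefined")
  growth <- vapply(lp$ids, function(r) .deletionGrowth(lp, cvec, r), 0)
  data.frame(reaction_id = lp$ids, growth = unname(growth),
             essential = unname(growth) < fEss * wt$objval - 1e-9,
             row.names = NULL, stringsAsFactors = FALSE)
}
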