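# Independent brute-force LP oracle: enumerates the vertices of
# {v : S v = 0, lb <= v <= ub} by fixing (n - rank) variables at bounds and
# solving for the rest.  Deliberately shares no code with the simplex core.

vertexEnumerate <- function(S, lb, ub, b = NULL) {
  S <- as.matrix(S)
  n <- ncol(S)
  if (is.null(b)) b <- rep(0, nrow(S))
  r <- qr(S)$rank
  nf <- n - r
  subs <- if (nf == 0) list(integer(0)) else utils::combn(n, nf, simplify = FALSE)
  verts <- list()
  for (Fv in subs) {
    Bv <- setdiff(seq_len(n), Fv)
    if (qr(S[, Bv, drop = FALSE])$rank < r) next
    picks <- if (length(Fv)) expand.grid(rep(list(1:2), length(Fv))) else
      data.frame(x = 1)[, 0, drop = FALSE]
    for (k in seq_len(max(1, nrow(picks)))) {
      xF <- if (length(Fv))
        ifelse(as.numeric(picks[k, ]) == 1, lb[Fv], ub[Fv]) else numeric(0)
      if (any(!is.finite(xF))) next
      rhs <- b - (if (length(Fv)) drop(S[, Fv, drop = FALSE] %*% xF) else 0)
      xB <- tryCatch(qr.solve(S[, Bv, drop = FALSE], rhs),
                     error = function(e) NULL)
      if (is.null(xB)) next
      if (max(abs(drop(S[, Bv, drop = FALSE] %*% xB) - rhs)) > 1e-7) next
      x <- numeric(n); x[Fv] <- xF; x[Bv] <- xB
      if (any(x < lb - 1e-7) || any(x > ub + 1e-7)) next
      verts[[length(verts) + 1L]] <- x
    }
  }
  verts
}

# maximum of obj'v over the enumerated vertices; NULL if infeasible
vertexOptimum <- function(obj, S, lb, ub) {
  verts <- vertexEnumerate(S, lb, ub)
  if (!length(verts)) return(NULL)
  vals <- vapply(verts, function(v) sum(obj * v), 0)
  list(objval = max(vals), vertices = verts, values = vals)
}

# random small flux polytope (a "toy model" in matrix form) for
# oracle-equivalence testing; all bounds finite and containing zero
randomToyLP <- function(n = NULL, m = NULL) {
  if (is.null(n)) n <- sample(4:8, 1)
  if (is.null(m)) m <- sample(2:min(4, n - 1), 1)
  S <- matrix(0, m, n)
  for (j in seq_len(n)) {
    k <- sample(1:min(2, m), 1)
    S[sample(m, k), j] <- sample(c(-2, -1, 1, 2), k, replace = TRUE)
  }
  rev <- runif(n) < 0.5
  lb <- ifelse(rev, -10, 0)
  ub <- rep(10, n)
  obj <- numeric(n); obj[sample(n, 1)] <- 1
  list(S = S, lb = lb, ub = ub, obj = obj)
}

# matrix-form wrappers of the package engine, for oracle comparisons
engineFBA <- function(lp) {
  rxn <- data.frame(id = paste0("R", seq_along(lp$lb)),
                    equation = "x ->", lb = lp$lb, ub = lp$ub)
  # build the model directly from the stoichiometric matrix
  eqs <- vapply(seq_len(ncol(lp$S)), function(j) {
    st <- lp$S[, j]; names(st) <- paste0("M", seq_len(nrow(lp$S)))
    st <- st[st != 0]
    if (!length(st)) return("orphan_met ->")
    gutGEM:::.equationString(st, lp$lb[j] < 0)
  }, "")
  rxn$equation <- eqs
  m <- MetabolicModel("oracle_toy", rxn, objective = rxn$id[which(lp$obj != 0)])
  m
}
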