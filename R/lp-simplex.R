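## Internal linear-programming core.
##
## The package needs many small dense LPs (FBA and friends); no LP solver
## package is available as a dependency, so a self-contained bounded-variable
## two-phase primal simplex lives here, behind the minimal interface
## .lpSolve().  Problems are dense and small (tens to a few hundred
## variables), so a dense tableau-free revised simplex with an explicit basis
## inverse, eta updates and periodic refactorisation is adequate and easy to
## keep numerically honest.

## Solve  max (or min)  obj'x   s.t.  A x = b,  lb <= x <= ub.
## Bounds may be +-Inf.  Returns list(status, x, objval) with status one of
## "optimal", "infeasible", "unbounded", "maxit", "singular".
.lpSolve <- function(obj, A, b, lb, ub, maximize = TRUE,
                     tol = 1e-9, maxit = NULL) {
  A <- as.matrix(A)
  m <- nrow(A); n <- ncol(A)
  stopifnot(length(obj) == n, length(b) == m, length(lb) == n, length(ub) == n)
  if (any(lb > ub + 1e-12))
    return(list(status = "infeasible", x = rep(NA_real_, n), objval = NA_real_))
  cvec <- if (maximize) as.numeric(obj) else -as.numeric(obj)
  if (is.null(maxit)) maxit <- 200L * (n + m + 10L)

  ## initial point: each structural variable at its "cheapest" finite bound
  x0 <- numeric(n)
  st0 <- integer(n)                      # 1 at lower, 2 at upper, 3 free at 0
  for (j in seq_len(n)) {
    lf <- is.finite(lb[j]); uf <- is.finite(ub[j])
    if (lf && (!uf || abs(lb[j]) <= abs(ub[j]))) { x0[j] <- lb[j]; st0[j] <- 1L }
    else if (uf)                                 { x0[j] <- ub[j]; st0[j] <- 2L }
    else                                         { x0[j] <- 0;     st0[j] <- 3L }
  }

  ## artificial columns give a trivially feasible starting basis
  r <- b - drop(A %*% x0)
  sgn <- ifelse(r >= 0, 1, -1)
  Aext <- cbind(A, diag(sgn, nrow = m))
  N <- n + m
  lbe <- c(lb, rep(0, m)); ube <- c(ub, rep(Inf, m))
  x <- c(x0, abs(r))
  stat <- c(st0, rep(0L, m))
  basis <- (n + 1L):N
  Binv <- diag(sgn, nrow = m)            # inverse of the artificial basis

  ## phase 1: drive artificials to zero
  c1 <- c(rep(0, n), rep(-1, m))
  ph1 <- .simplexCore(Aext, b, c1, lbe, ube, basis, stat, x, Binv, tol, maxit)
  if (ph1$status == "singular" || ph1$status == "maxit")
    return(list(status = ph1$status, x = rep(NA_real_, n), objval = NA_real_))
  art <- ph1$x[(n + 1L):N]
  feastol <- 1e-7 * (1 + max(abs(b)))
  if (sum(art) > feastol)
    return(list(status = "infeasible", x = rep(NA_real_, n), objval = NA_real_))

  ## phase 2: artificials pinned at zero, optimise the real objective
  ube[(n + 1L):N] <- 0
  ph1$x[(n + 1L):N] <- pmax(0, pmin(ph1$x[(n + 1L):N], 0)) + 0
  c2 <- c(cvec, rep(0, m))
  ph2 <- .simplexCore(Aext, b, c2, lbe, ube, ph1$basis, ph1$stat, ph1$x,
                      ph1$Binv, tol, maxit)
  if (ph2$status %in% c("singular", "maxit", "unbounded"))
    return(list(status = ph2$status, x = rep(NA_real_, n), objval = NA_real_))
  xs <- ph2$x[seq_len(n)]
  ## snap to bounds within tolerance
  snap <- is.finite(lb) & abs(xs - lb) < 1e-9; xs[snap] <- lb[snap]
  snap <- is.finite(ub) & abs(xs - ub) < 1e-9; xs[snap] <- ub[snap]
  objval <- sum(obj * xs)
  list(status = "optimal", x = xs, objval = objval)
}

## One run of the bounded-variable primal simplex (maximisation).
## Dantzig pricing with a switch to Bland's rule after a stretch of
## degenerate iterations; refactorises the basis inverse periodically.
.simplexCore <- function(A, b, cvec, lb, ub, basis, stat, x, Binv,
                         tol, maxit) {
  m <- nrow(A); N <- ncol(A)
  fixed <- (ub - lb) < 1e-12
  refactor_every <- 60L
  bland <- FALSE
  stall <- 0L
  lastobj <- -Inf
  epspiv <- 1e-10

  for (it in seq_len(maxit)) {
    if (it %% refactor_every == 0L) {
      Bmat <- A[, basis, drop = FALSE]
      Binv <- tryCatch(solve(Bmat), error = function(e) NULL)
      if (is.null(Binv))
        return(list(status = "singular"))
      nb <- setdiff(seq_len(N), basis)
      x[basis] <- drop(Binv %*% (b - A[, nb, drop = FALSE] %*% x[nb]))
    }

    cB <- cvec[basis]
    y <- drop(crossprod(Binv, cB))
    d <- cvec - drop(crossprod(A, y))
    nonbasic <- stat != 0L
    elig <- nonbasic & !fixed &
      ((stat == 1L & d > tol) | (stat == 2L & d < -tol) |
       (stat == 3L & abs(d) > tol))
    if (!any(elig)) {
      return(list(status = "optimal", basis = basis, stat = stat,
                  x = x, Binv = Binv))
    }
    idx <- which(elig)
    q <- if (bland) idx[1L] else idx[which.max(abs(d[idx]))]
    sigma <- if (stat[q] == 2L) -1 else if (stat[q] == 3L) sign(d[q]) else 1

    w <- drop(Binv %*% A[, q])
    ## ratio test
    tmax <- if (is.finite(lb[q]) && is.finite(ub[q])) ub[q] - lb[q] else Inf
    leave <- 0L                          # 0 means bound flip of q itself
    delta <- sigma * w
    for (i in seq_len(m)) {
      bi <- basis[i]
      if (delta[i] > epspiv) {
        if (is.finite(lb[bi])) {
          ti <- (x[bi] - lb[bi]) / delta[i]
          if (ti < tmax - 1e-12 || (ti < tmax + 1e-12 && leave > 0L &&
                                    abs(w[i]) > abs(w[leave]))) {
            tmax <- min(tmax, ti); leave <- i
          }
        }
      } else if (delta[i] < -epspiv) {
        if (is.finite(ub[bi])) {
          ti <- (x[bi] - ub[bi]) / delta[i]
          if (ti < tmax - 1e-12 || (ti < tmax + 1e-12 && leave > 0L &&
                                    abs(w[i]) > abs(w[leave]))) {
            tmax <- min(tmax, ti); leave <- i
          }
        }
      }
    }
    if (!is.finite(tmax))
      return(list(status = "unbounded"))
    tmax <- max(tmax, 0)

    ## objective progress bookkeeping for anti-cycling
    if (tmax * abs(d[q]) < 1e-12) stall <- stall + 1L else stall <- 0L
    if (stall > 3L * (m + 1L)) bland <- TRUE

    x[q] <- x[q] + sigma * tmax
    x[basis] <- x[basis] - tmax * delta

    if (leave == 0L) {
      ## q flipped from one of its bounds to the other
      stat[q] <- if (sigma > 0) 2L else 1L
      x[q] <- if (stat[q] == 2L) ub[q] else lb[q]
    } else {
      out <- basis[leave]
      hit_lower <- delta[leave] > 0
      stat[out] <- if (hit_lower) 1L else 2L
      x[out] <- if (hit_lower) lb[out] else ub[out]
      basis[leave] <- q
      stat[q] <- 0L
      ## eta update of the basis inverse
      piv <- w[leave]
      if (abs(piv) < 1e-11) {
        Bmat <- A[, basis, drop = FALSE]
        Binv <- tryCatch(solve(Bmat), error = function(e) NULL)
        if (is.null(Binv)) return(list(status = "singular"))
      } else {
        Binv[leave, ] <- Binv[leave, ] / piv
        adj <- w; adj[leave] <- 0
        Binv <- Binv - outer(adj, Binv[leave, ])
      }
    }
    lastobj <- sum(cvec * x)
  }
  list(status = "maxit")
}
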