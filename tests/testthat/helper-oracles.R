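## Independent brute-force oracles. These deliberately share no code with
## the package internals: plain triple loops and exhaustive searches that
## are only feasible on tiny instances.

loopReconstruct <- function(A, B, C, lambda = rep(1, ncol(A))) {
  I <- nrow(A); J <- nrow(B); K <- nrow(C)
  out <- array(0, c(I, J, K))
  for (i in seq_len(I)) for (j in seq_len(J)) for (k in seq_len(K))
    for (f in seq_len(ncol(A)))
      out[i, j, k] <- out[i, j, k] + lambda[f] * A[i, f] * B[j, f] * C[k, f]
  out
}

loopMaskedObjective <- function(X, W, A, B, C, lambda = rep(1, ncol(A))) {
  R <- loopReconstruct(A, B, C, lambda)
  s <- 0
  for (i in seq_len(dim(X)[1])) for (j in seq_len(dim(X)[2]))
    for (k in seq_len(dim(X)[3]))
      s <- s + W[i, j, k] * (X[i, j, k] - R[i, j, k])^2
  s
}

loopAggregate <- function(X, ks) {
  I <- dim(X)[1]
  M <- matrix(0, I, I)
  for (i in seq_len(I)) for (j in seq_len(I)) {
    if (i == j) next
    for (k in ks) M[i, j] <- M[i, j] + X[i, j, k]
  }
  M
}

## Dense grid search for the masked rank-1 nonnegative least-squares
## optimum on a 2 x 2 x K (K <= 2) tensor. Unit-norm nonnegative factors
## are parameterized by their first component t via (t, sqrt(1 - t^2));
## the free scale has a closed form. The stated base resolution (0.01) is
## followed by successive local refinements around the incumbent so the
## returned objective certifies the optimum to ~1e-10.
gridRank1Objective <- function(X, W, step = 0.01, refinements = 6L) {
  stopifnot(dim(X)[1] == 2, dim(X)[2] == 2, dim(X)[3] <= 2)
  K <- dim(X)[3]
  cells <- which(W == 1)
  sub <- arrayInd(cells, dim(X))
  x <- X[cells]
  evalObj <- function(ta, tb, tc) {
    g <- expand.grid(ta = ta, tb = tb, tc = tc)
    av <- cbind(g$ta, sqrt(pmax(0, 1 - g$ta^2)))
    bv <- cbind(g$tb, sqrt(pmax(0, 1 - g$tb^2)))
    cv <- cbind(g$tc, sqrt(pmax(0, 1 - g$tc^2)))
    sxy <- 0; syy <- 0
    for (r in seq_along(cells)) {
      m <- av[, sub[r, 1]] * bv[, sub[r, 2]] *
        (if (K == 1) 1 else cv[, sub[r, 3]])
      sxy <- sxy + x[r] * m
      syy <- syy + m * m
    }
    lam <- pmax(0, sxy / pmax(syy, 1e-300))
    obj <- sum(x^2) - 2 * lam * sxy + lam^2 * syy
    best <- which.min(obj)
    list(obj = obj[best], ta = g$ta[best], tb = g$tb[best], tc = g$tc[best])
  }
  clampGrid <- function(centre, h) {
    g <- seq(centre - h, centre + h, by = h / 10)
    g[g >= 0 & g <= 1]
  }
  grid0 <- seq(0, 1, by = step)
  cur <- evalObj(grid0, grid0, if (K == 2) grid0 else 0)
  h <- step
  for (r in seq_len(refinements)) {
    cur <- evalObj(clampGrid(cur$ta, h), clampGrid(cur$tb, h),
                   if (K == 2) clampGrid(cur$tc, h) else 0)
    h <- h / 10
  }
  cur$obj
}

## Exhaustive-permutation factor match score (recursive enumeration),
## feasible for F <= 4.
exhaustiveFMS <- function(Ae, Be, Ce, At, Bt, Ct) {
  cosAbs <- function(u, v) {
    nu <- sqrt(sum(u^2)); nv <- sqrt(sum(v^2))
    if (nu == 0 || nv == 0) 0 else abs(sum(u * v)) / (nu * nv)
  }
  F <- ncol(Ae)
  stopifnot(ncol(At) == F, F <= 4)
  perms <- function(v) {
    if (length(v) <= 1) return(list(v))
    out <- list()
    for (i in seq_along(v))
      for (p in perms(v[-i])) out[[length(out) + 1]] <- c(v[i], p)
    out
  }
  best <- 0
  for (p in perms(seq_len(F))) {
    s <- mean(vapply(seq_len(F), function(f) {
      cosAbs(Ae[, f], At[, p[f]]) * cosAbs(Be[, f], Bt[, p[f]]) *
        cosAbs(Ce[, f], Ct[, p[f]])
    }, numeric(1)))
    if (s > best) best <- s
  }
  best
}

## Non-increasing check with the floating-point noise floor of evaluating
## the objective (~ eps^2 * initial scale) for traces that hit machine zero.
expectMonotoneTrace <- function(tr) {
  if (length(tr) < 2) return(invisible(TRUE))
  slack <- pmax(1e-10 * tr[-length(tr)], 100 * .Machine$double.eps^2 * max(tr))
  expect_true(all(diff(tr) <= slack))
}

## Small planted configuration used across tests (kept light).
smallSpec <- function(noise = "none", ...) {
  plantedSpec(I = 12L, K = 6L, nSystems = 2L, supportSize = 3L,
              noise = noise, ...)
}
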