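#' Fit a diagonal-masked nonnegative CP decomposition
#'
#' Solves
#' \deqn{\min_{A,B,C \ge 0} \| W \circledast (X - \sum_f a_f \circ b_f
#'   \circ c_f) \|_F^2}
#' where \eqn{W} is the tensor's binary mask (zero on every diagonal cell,
#' and on any declared-missing cell). The solver alternates an EM-style
#' imputation step -- masked-out cells are filled with the current
#' reconstruction -- with one round of HALS (hierarchical alternating least
#' squares) columnwise nonnegative updates of \code{A}, \code{B} and
#' \code{C} on the completed tensor. Both steps are exact coordinate
#' minimizations, so the masked objective is non-increasing across outer
#' iterations.
#'
#' Factors are initialized uniform at random on \code{[0, 1]}; of
#' \code{restarts} independent runs (seeded \code{seed}, \code{seed + 1},
#' ...) the one with the lowest final objective is returned, ties going to
#' the earlier restart. A factor column that collapses to zero during the
#' fit is re-seeded once at epsilon scale; if it collapses again the
#' component is dropped with a warning.
#'
#' @param x a \code{\linkS4class{FlowTensor}}.
#' @param rank number of components \code{F} (the number of migration
#'   systems). A warning is issued when \code{rank} exceeds the number of
#'   geographies.
#' @param maxIter maximum outer iterations per restart (default 500).
#' @param tol stop when the relative objective decrease falls below this
#'   (default 1e-8).
#' @param restarts number of random restarts (default 10).
#' @param seed integer RNG seed; the fit is deterministic given
#'   \code{(seed, opts)} and the caller's RNG state is left untouched.
#' @return A normalized \code{\linkS4class{CPModel}} with the winning
#'   restart's objective trace.
#' @examples
#' sim <- generatePlanted(plantedSpec(I = 10, K = 6, nSystems = 1,
#'                                    supportSize = 3, noise = "none"))
#' fit <- fitNCPD(sim$tensor, rank = 1, restarts = 2, seed = 1)
#' factorMatchScore(fit, sim$truth)
#' @seealso \code{\link{rankScan}} for choosing \code{rank},
#'   \code{\link{extractSystem}} for interpreting components.
#' @export
fitNCPD <- function(x, rank, maxIter = 500L, tol = 1e-8, restarts = 10L,
                    seed = 1L) {
  stopifnot(is(x, "FlowTensor"))
  rank <- as.integer(rank)
  if (length(rank) != 1L || is.na(rank) || rank < 1L)
    stop("rank must be a positive integer")
  if (rank > length(x@geo))
    warning("rank exceeds the number of geographies; fit may be degenerate")
  X <- x@values
  W <- x@mask
  if (any(!is.finite(X))) stop("tensor contains non-finite values")
  if (sum(W * X^2) == 0)
    stop("nothing to fit: all masked-in entries are zero")
  restarts <- max(1L, as.integer(restarts))
  best <- NULL
  for (r in seq_len(restarts)) {
    res <- withSeed(as.integer(seed) + r - 1L,
                    .ncpdSingle(X, W, rank, maxIter, tol))
    if (is.null(best) || res$objective < best$objective) best <- res
  }
  CPModel(best$A, best$B, best$C, geo = x@geo, periods = x@periods,
          objectiveTrace = best$trace, seed = seed, restarts = restarts,
          converged = best$converged)
}

## One EM + HALS run from a random start, using the current RNG stream.
.ncpdSingle <- function(X, W, F, maxIter, tol) {
  dm <- dim(X); I <- dm[1]; J <- dm[2]; K <- dm[3]
  Xw <- X * W
  Wc <- 1 - W
  epsScale <- 1e-8 * (max(Xw) + 1)
  A <- matrix(stats::runif(I * F), I, F)
  B <- matrix(stats::runif(J * F), J, F)
  C <- matrix(stats::runif(K * F), K, F)
  reseeded <- rep(FALSE, F)
  trace <- numeric(0)
  prev <- Inf
  converged <- FALSE
  for (it in seq_len(maxIter)) {
    ## E-step: complete the tensor with the current reconstruction
    Xc <- Xw + .cpRecon(A, B, C) * Wc
    drop <- rep(FALSE, ncol(A))
    ## M-step: one HALS sweep per mode on the completed tensor
    upd <- .halsSweep(matrix(Xc, I, J * K), A, B, C, reseeded, epsScale)
    A <- upd$M; reseeded <- upd$reseeded; drop <- drop | upd$drop
    upd <- .halsSweep(matrix(aperm(Xc, c(2, 1, 3)), J, I * K), B, A, C,
                      reseeded, epsScale)
    B <- upd$M; reseeded <- upd$reseeded; drop <- drop | upd$drop
    upd <- .halsSweep(matrix(aperm(Xc, c(3, 1, 2)), K, I * J), C, A, B,
                      reseeded, epsScale)
    C <- upd$M; reseeded <- upd$reseeded; drop <- drop | upd$drop
    if (any(drop)) {
      warning(sprintf("dropping %d component(s) that repeatedly collapsed",
                      sum(drop)))
      keep <- !drop
      if (!any(keep)) stop("all components collapsed during the fit")
      A <- A[, keep, drop = FALSE]; B <- B[, keep, drop = FALSE]
      C <- C[, keep, drop = FALSE]
      reseeded <- reseeded[keep]
    }
    obj <- sum((Xw - W * .cpRecon(A, B, C))^2)
    trace <- c(trace, obj)
    if (is.finite(prev) &&
        (prev - obj) <= tol * max(prev, .Machine$double.xmin)) {
      converged <- TRUE
      break
    }
    prev <- obj
  }
  list(A = A, B = B, C = C, objective = obj, trace = trace,
       converged = converged)
}

## One HALS pass updating the factor M of the unfolded tensor Xu, with the
## other two factors U (larger khatri-rao index) and V held fixed.
## Update for column f: m_f <- max(0, m_f + (P[,f] - M G[,f]) / G[f,f])
## with G = (U'U) * (V'V) and P = Xu (U kr V). A column that lands on zero
## is re-seeded once at epsilon scale, then flagged for dropping.
.halsSweep <- function(Xu, M, V, U, reseeded, epsScale) {
  G <- crossprod(V) * crossprod(U)
  P <- Xu %*% khatriRao(U, V)
  drop <- rep(FALSE, ncol(M))
  for (f in seq_len(ncol(M))) {
    gff <- G[f, f]
    if (gff <= .Machine$double.eps) {
      m <- rep(0, nrow(M))
    } else {
      m <- pmax(0, M[, f] + (P[, f] - M %*% G[, f]) / gff)
    }
    if (max(m) == 0) {
      if (!reseeded[f]) {
        m <- stats::runif(nrow(M)) * epsScale
        reseeded[f] <- TRUE
      } else {
        drop[f] <- TRUE
        m <- M[, f]  # keep until the joint drop at the end of the iteration
      }
    }
    M[, f] <- m
  }
  list(M = M, reseeded = reseeded, drop = drop)
}
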