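#' @import methods
NULL

#' FlowTensor: an origin x destination x time flow count tensor
#'
#' The central data container: a nonnegative \code{I x I x K} array of
#' movement counts between \code{I} geographies over \code{K} periods,
#' together with a binary weight (mask) tensor of the same shape. Diagonal
#' cells \code{(i, i, k)} carry no between-unit movement information and are
#' always masked out of any model fit; further cells (e.g. suppressed small
#' flows in administrative extracts) can be masked via \code{missingCells}
#' in \code{\link{buildFlowTensor}}.
#'
#' @slot values nonnegative \code{I x I x K} array of counts.
#' @slot mask \code{I x I x K} array in \{0, 1\}; 0 on every diagonal cell.
#' @slot geo character vector of \code{I} unique geography labels.
#' @slot periods character vector of \code{K} unique, ordered period labels.
#'
#' @seealso \code{\link{buildFlowTensor}}, \code{\link{fitNCPD}}
#' @exportClass FlowTensor
setClass("FlowTensor",
  slots = c(values = "array", mask = "array",
            geo = "character", periods = "character"),
  validity = function(object) {
    msg <- character(0)
    dv <- dim(object@values)
    dm <- dim(object@mask)
    if (length(dv) != 3L) msg <- c(msg, "values must be a 3-way array")
    if (!identical(dv, dm)) msg <- c(msg, "values and mask must share shape")
    if (length(dv) == 3L) {
      if (dv[1] != dv[2]) msg <- c(msg, "first two modes must have equal length")
      if (dv[1] != length(object@geo))
        msg <- c(msg, "geo length must match mode-1 extent")
      if (dv[3] != length(object@periods))
        msg <- c(msg, "periods length must match mode-3 extent")
      if (anyDuplicated(object@geo)) msg <- c(msg, "geo labels must be unique")
      if (anyDuplicated(object@periods))
        msg <- c(msg, "period labels must be unique")
      if (any(!is.finite(object@values)))
        msg <- c(msg, "values must be finite")
      if (any(object@values < 0)) msg <- c(msg, "values must be nonnegative")
      if (!all(object@mask %in% c(0, 1)))
        msg <- c(msg, "mask entries must be 0 or 1")
      if (identical(dv[1], dv[2]) &&
          any(object@mask[.diagIndex(dv[1], dv[3])] != 0))
        msg <- c(msg, "mask must be zero on all diagonal cells")
    }
    if (length(msg)) msg else TRUE
  })

#' CPModel: a normalized nonnegative CP decomposition
#'
#' Holds the factor matrices of a fitted (or planted) nonnegative canonical
#' polyadic model of a \code{\link{FlowTensor}}. Columns of \code{A} (origin
#' memberships), \code{B} (destination memberships) and \code{C} (temporal
#' intensities) have unit Euclidean norm; the absorbed scale of component
#' \code{f} is \code{lambda[f]} and components are sorted by \code{lambda}
#' in non-increasing order, which is the importance ranking of the
#' discovered migration systems.
#'
#' @slot A,B nonnegative \code{I x F} matrices of origin/destination
#'   memberships, unit-norm columns, rows named by geography.
#' @slot C nonnegative \code{K x F} matrix of temporal intensities,
#'   unit-norm columns, rows named by period.
#' @slot lambda length-\code{F} nonnegative scales, non-increasing.
#' @slot geo,periods label vectors (as in \code{FlowTensor}).
#' @slot objectiveTrace masked objective value after each outer solver
#'   iteration (non-increasing); empty for hand-built models.
#' @slot seed,restarts integers recording how the fit was produced.
#' @slot converged logical; \code{NA} for hand-built models.
#'
#' @seealso \code{\link{CPModel}}, \code{\link{fitNCPD}}
#' @exportClass CPModel
setClass("CPModel",
  slots = c(A = "matrix", B = "matrix", C = "matrix", lambda = "numeric",
            geo = "character", periods = "character",
            objectiveTrace = "numeric", seed = "integer",
            restarts = "integer", converged = "logical"),
  validity = function(object) {
    msg <- character(0)
    Fn <- ncol(object@A)
    if (ncol(object@B) != Fn || ncol(object@C) != Fn || length(object@lambda) != Fn)
      msg <- c(msg, "A, B, C and lambda must agree on the number of components")
    if (nrow(object@A) != length(object@geo) ||
        nrow(object@B) != length(object@geo))
      msg <- c(msg, "A and B must have one row per geography")
    if (nrow(object@C) != length(object@periods))
      msg <- c(msg, "C must have one row per period")
    for (nm in c("A", "B", "C")) {
      M <- slot(object, nm)
      if (any(M < -1e-12)) msg <- c(msg, paste(nm, "must be nonnegative"))
      if (ncol(M) > 0 && any(abs(.colNorms(M) - 1) > 1e-6))
        msg <- c(msg, paste("columns of", nm, "must have unit Euclidean norm"))
    }
    if (any(object@lambda < 0)) msg <- c(msg, "lambda must be nonnegative")
    if (Fn > 1 && any(diff(object@lambda) > 1e-12 * max(object@lambda, 1)))
      msg <- c(msg, "lambda must be sorted non-increasing")
    tr <- object@objectiveTrace
    if (length(tr) > 1) {
      ## 1e-10 relative, plus the floating-point noise floor of evaluating
      ## the objective itself (~ eps^2 * initial scale) for traces that
      ## decay to machine zero
      slack <- pmax(1e-10 * tr[-length(tr)],
                    100 * .Machine$double.eps^2 * max(tr))
      if (any(diff(tr) > slack))
        msg <- c(msg, "objectiveTrace must be non-increasing")
    }
    if (length(msg)) msg else TRUE
  })

#' PlantedTruth: ground-truth factors of a synthetic flow tensor
#'
#' A \code{\linkS4class{CPModel}} carrying, in addition, the planted shock
#' period of each system (\code{NA} for systems without one) and the
#' generator settings that produced it.
#'
#' @slot shockPeriods integer vector, one entry per component: the 1-based
#'   period index of the planted temporal spike, or \code{NA}.
#' @slot spec the \code{\link{plantedSpec}} list used by the generator.
#'
#' @seealso \code{\link{generatePlanted}}, \code{\link{factorMatchScore}}
#' @exportClass PlantedTruth
setClass("PlantedTruth", contains = "CPModel",
  slots = c(shockPeriods = "integer", spec = "list"),
  validity = function(object) {
    if (length(object@shockPeriods) != ncol(object@A))
      "shockPeriods must have one entry per component" else TRUE
  })

#' MigrationSystem: one ranked, interpretable component
#'
#' The per-component view produced by \code{\link{extractSystem}}: unit-norm
#' origin/destination membership vectors, their within-system L1
#' normalizations (read as the probability of a geography belonging to the
#' system), the temporal intensity profile, and the top-k member lists.
#'
#' @slot index component index in the parent model (1 = most important).
#' @slot lambda the component scale.
#' @slot originMembership,destMembership named nonnegative unit-norm vectors.
#' @slot originProb,destProb named vectors summing to 1.
#' @slot temporal named temporal intensity vector (one entry per period).
#' @slot topOrigins,topDests labels of the largest memberships, descending,
#'   ties broken by label order.
#'
#' @exportClass MigrationSystem
setClass("MigrationSystem",
  slots = c(index = "integer", lambda = "numeric",
            originMembership = "numeric", destMembership = "numeric",
            originProb = "numeric", destProb = "numeric",
            temporal = "numeric",
            topOrigins = "character", topDests = "character"),
  validity = function(object) {
    msg <- character(0)
    for (nm in c("originProb", "destProb")) {
      p <- slot(object, nm)
      if (any(p < 0) || abs(sum(p) - 1) > 1e-12)
        msg <- c(msg, paste(nm, "must be nonnegative and sum to 1"))
    }
    if (length(msg)) msg else TRUE
  })

#' Construct a FlowTensor from a dense array
#'
#' Low-level constructor. Most users build tensors from long-format records
#' with \code{\link{buildFlowTensor}}. The diagonal of any supplied mask is
#' forced to zero.
#'
#' @param values nonnegative \code{I x I x K} array.
#' @param geo geography labels (default: dimnames or \code{G01, G02, ...}).
#' @param periods period labels (default: dimnames or \code{1, 2, ...}).
#' @param mask optional \{0,1\} array; default masks only the diagonal.
#' @return A \code{\linkS4class{FlowTensor}}.
#' @examples
#' x <- FlowTensor(array(rpois(2 * 2 * 3, 5), c(2, 2, 3)))
#' flowMask(x)[1, 1, ]
#' @export
FlowTensor <- function(values, geo = NULL, periods = NULL, mask = NULL) {
  stopifnot(is.array(values), length(dim(values)) == 3L)
  dv <- dim(values)
  if (dv[1] != dv[2])
    stop("flow tensor must be square in its first two modes")
  if (is.null(geo)) {
    geo <- dimnames(values)[[1]]
    if (is.null(geo)) geo <- sprintf("G%02d", seq_len(dv[1]))
  }
  if (is.null(periods)) {
    periods <- dimnames(values)[[3]]
    if (is.null(periods)) periods <- as.character(seq_len(dv[3]))
  }
  geo <- as.character(geo)
  periods <- as.character(periods)
  if (is.null(mask)) {
    mask <- array(1, dv)
  } else {
    mask <- array(as.numeric(mask), dv)
  }
  mask[.diagIndex(dv[1], dv[3])] <- 0
  dimnames(values) <- dimnames(mask) <- list(geo, geo, periods)
  new("FlowTensor", values = values, mask = mask,
      geo = geo, periods = periods)
}

#' Construct (and normalize) a CPModel from raw factor matrices
#'
#' Takes arbitrary nonnegative factor matrices, drops all-zero components
#' with a warning, rescales every remaining column to unit Euclidean norm,
#' absorbs the scales into \code{lambda[f] =
#' ||a_f|| * ||b_f|| * ||c_f||}, and sorts components by \code{lambda}
#' non-increasing (stable, so ties keep their input order). The
#' reconstruction is unchanged by this normalization.
#'
#' @param A,B nonnegative \code{I x F} origin/destination factor matrices.
#' @param C nonnegative \code{K x F} temporal factor matrix.
#' @param geo,periods optional labels (defaults derived from row names or
#'   generated).
#' @param objectiveTrace,seed,restarts,converged fit metadata (optional).
#' @return A \code{\linkS4class{CPModel}}.
#' @examples
#' m <- CPModel(A = cbind(c(3, 4, 0)), B = cbind(c(0, 0, 1)),
#'              C = cbind(c(2, 0)))
#' systemScales(m)   # 5 * 1 * 2 = 10
#' @export
CPModel <- function(A, B, C, geo = NULL, periods = NULL,
                    objectiveTrace = numeric(0), seed = NA_integer_,
                    restarts = NA_integer_, converged = NA) {
  A <- as.matrix(A); B <- as.matrix(B); C <- as.matrix(C)
  if (ncol(A) != ncol(B) || ncol(A) != ncol(C))
    stop("A, B and C must have the same number of columns")
  if (nrow(A) != nrow(B))
    stop("A and B must have the same number of rows")
  if (any(A < 0) || any(B < 0) || any(C < 0))
    stop("factor matrices must be nonnegative")
  na <- .colNorms(A); nb <- .colNorms(B); nc <- .colNorms(C)
  keep <- na > 0 & nb > 0 & nc > 0
  if (!any(keep)) stop("all components are zero; nothing to normalize")
  if (!all(keep)) {
    warning(sprintf("dropping %d all-zero component(s)", sum(!keep)))
    A <- A[, keep, drop = FALSE]; B <- B[, keep, drop = FALSE]
    C <- C[, keep, drop = FALSE]
    na <- na[keep]; nb <- nb[keep]; nc <- nc[keep]
  }
  lambda <- na * nb * nc
  A <- sweep(A, 2L, na, "/")
  B <- sweep(B, 2L, nb, "/")
  C <- sweep(C, 2L, nc, "/")
  ord <- order(lambda, decreasing = TRUE)
  A <- A[, ord, drop = FALSE]; B <- B[, ord, drop = FALSE]
  C <- C[, ord, drop = FALSE]; lambda <- lambda[ord]
  if (is.null(geo)) {
    geo <- rownames(A)
    if (is.null(geo)) geo <- sprintf("G%02d", seq_len(nrow(A)))
  }
  if (is.null(periods)) {
    periods <- rownames(C)
    if (is.null(periods)) periods <- as.character(seq_len(nrow(C)))
  }
  cn <- sprintf("S%d", seq_along(lambda))
  dimnames(A) <- list(geo, cn); dimnames(B) <- list(geo, cn)
  dimnames(C) <- list(periods, cn)
  names(lambda) <- cn
  ## initialize() rather than new(): an argument named "C" would partially
  ## match new()'s formal `Class`
  obj <- initialize(new("CPModel"), A = A, B = B, C = C, lambda = lambda,
                    geo = as.character(geo),
                    periods = as.character(periods),
                    objectiveTrace = as.numeric(objectiveTrace),
                    seed = as.integer(seed), restarts = as.integer(restarts),
                    converged = as.logical(converged))
  validObject(obj)
  obj
}

setMethod("show", "FlowTensor", function(object) {
  dv <- dim(object@values)
  cat(sprintf("FlowTensor: %d geographies x %d periods (%s..%s)\n",
              dv[1], dv[3], object@periods[1], object@periods[dv[3]]))
  cat(sprintf("  masked-in cells: %d of %d; total off-diagonal flow: %g\n",
              sum(object@mask == 1), length(object@mask),
              sum(object@values * object@mask)))
})

setMethod("show", "CPModel", function(object) {
  cat(sprintf("CPModel: %d migration system(s), %d geographies x %d periods\n",
              ncol(object@A), length(object@geo), length(object@periods)))
  cat("  lambda:", paste(signif(object@lambda, 4), collapse = ", "), "\n")
  if (length(object@objectiveTrace))
    cat(sprintf("  final masked objective: %.6g after %d outer iteration(s)%s\n",
                utils::tail(object@objectiveTrace, 1),
                length(object@objectiveTrace),
                if (isTRUE(object@converged)) " (converged)" else ""))
})

setMethod("show", "MigrationSystem", function(object) {
  cat(sprintf("MigrationSystem %d (lambda = %.4g)\n",
              object@index, object@lambda))
  cat("  top origins:     ", paste(object@topOrigins, collapse = ", "), "\n")
  cat("  top destinations:", paste(object@topDests, collapse = ", "), "\n")
})
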