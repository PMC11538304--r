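#' Residual scan over candidate ranks
#'
#' Fits the masked nonnegative CP model independently at each candidate
#' rank and records the relative masked residual
#' \code{sqrt(masked SSE) / sqrt(masked sum(X^2))}. The number of migration
#' systems is chosen by reading this curve: the residual drops sharply
#' while genuine systems remain unexplained and flattens once the rank
#' exceeds their number.
#'
#' @param x a \code{\linkS4class{FlowTensor}}.
#' @param ranks strictly increasing vector of candidate ranks.
#' @param ... fit options passed to \code{\link{fitNCPD}} (\code{maxIter},
#'   \code{tol}, \code{restarts}, \code{seed}).
#' @param keepModels retain the fitted models as an attribute?
#' @return A data frame with columns \code{rank} and \code{relResidual}
#'   (values in \code{[0, 1]}); when \code{keepModels = TRUE} the fits are
#'   attached as \code{attr(, "models")}.
#' @seealso \code{\link{elbowRank}} for the drop-ratio heuristic.
#' @export
rankScan <- function(x, ranks, ..., keepModels = FALSE) {
  ranks <- as.integer(ranks)
  if (length(ranks) < 1L || any(diff(ranks) <= 0))
    stop("ranks must be strictly increasing")
  denom <- sqrt(sum(x@mask * x@values^2))
  models <- vector("list", length(ranks))
  rel <- numeric(length(ranks))
  for (p in seq_along(ranks)) {
    fit <- fitNCPD(x, rank = ranks[p], ...)
    rel[p] <- sqrt(maskedObjective(x, fit)) / denom
    if (keepModels) models[[p]] <- fit
  }
  out <- data.frame(rank = ranks, relResidual = rel)
  if (keepModels) attr(out, "models") <- models
  out
}

#' Elbow detection on a rank scan by the drop-ratio heuristic
#'
#' For each interior rank \code{F} of a consecutive scan, compares the
#' residual drop achieved by adding the \code{F}th component with the drop
#' achieved by the next one:
#' \code{ratio(F) = (r(F-1) - r(F)) / (r(F) - r(F+1))}, using the virtual
#' zero-component residual \code{r(0) = 1}. The elbow is the rank with the
#' largest ratio, reported only when that ratio reaches \code{minRatio};
#' rank choice remains a user decision and this is a diagnostic, never
#' silently automatic.
#'
#' @param scan data frame from \code{\link{rankScan}} over consecutive
#'   ranks starting at 1.
#' @param minRatio smallest drop-ratio accepted as an elbow (default 2).
#' @return The elbow rank as an integer, with the ratio profile attached as
#'   \code{attr(, "ratios")}; \code{NA} when no rank qualifies.
#' @export
elbowRank <- function(scan, minRatio = 2) {
  stopifnot(is.data.frame(scan), all(c("rank", "relResidual") %in% names(scan)))
  if (scan$rank[1] != 1L || any(diff(scan$rank) != 1L))
    stop("elbowRank expects a consecutive scan starting at rank 1")
  res <- c(1, scan$relResidual)               # r(0) = 1 by definition
  drops <- -diff(res)                         # drop achieved by rank F
  eps <- 1e-12
  ratios <- drops[-length(drops)] / pmax(drops[-1], eps)
  names(ratios) <- scan$rank[-nrow(scan)]
  best <- which.max(ratios)
  out <- if (ratios[best] >= minRatio) scan$rank[best] else NA_integer_
  attr(out, "ratios") <- ratios
  out
}

#' Cross-model component congruence scores
#'
#' For each component of \code{model}, the best-matching congruence against
#' the components of \code{reference}: the product of absolute cosine
#' similarities of the origin, destination and temporal factors, maximized
#' over reference components. 1 means a component reappears unchanged.
#'
#' @param model,reference \code{\linkS4class{CPModel}} objects on the same
#'   labels.
#' @return Numeric vector of length \code{nComponents(model)}, values in
#'   \code{[0, 1]}.
#' @export
congruenceScores <- function(model, reference) {
  S <- .cosineAbs(model@A, reference@A) *
       .cosineAbs(model@B, reference@B) *
       .cosineAbs(model@C, reference@C)
  apply(S, 1, max)
}

#' Stability of a rank-F solution against a higher-rank refit
#'
#' Refits the tensor at \code{rank} and at \code{rankPlus > rank} and
#' reports, for each component of the rank-\code{rank} fit, its best
#' congruence among the components of the larger model. Scores near 1 for
#' all components indicate that raising the rank leaves the leading
#' migration systems essentially unchanged -- the robustness property that
#' justifies reporting a fixed number of systems.
#'
#' @param x a \code{\linkS4class{FlowTensor}}.
#' @param rank,rankPlus the two ranks to compare (\code{rankPlus > rank}).
#' @param ... fit options passed to \code{\link{fitNCPD}}.
#' @return Numeric vector of \code{rank} congruence scores.
#' @export
stabilityCheck <- function(x, rank, rankPlus, ...) {
  if (rankPlus <= rank) stop("rankPlus must exceed rank")
  base <- fitNCPD(x, rank = rank, ...)
  plus <- fitNCPD(x, rank = rankPlus, ...)
  congruenceScores(base, plus)
}
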