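#' Settings for the planted-system flow generator
#'
#' Describes a synthetic flow tensor built as a sum of sparse nonnegative
#' rank-one migration systems plus count noise, emulating the structure of
#' administrative origin-destination extracts: a few systems, each with a
#' small origin support and a small destination support, memberships drawn
#' uniform on \code{[0.5, 1]} over the support (sparse, nonnegative,
#' non-orthogonal), smooth or spiked temporal intensities, Poisson-like
#' noise, and uninformative diagonal cells.
#'
#' The defaults mirror a county-scale study shrunk to desk size: 30
#' geographies, 29 yearly periods labeled 1990..2018, 3 systems of support
#' size 5 with disjoint supports, the last system carrying a temporal spike
#' in 2005 (period 16) of 8x baseline -- a hurricane-displacement analogue
#' -- and Poisson counts with mean signal level 50 on masked-in cells.
#'
#' @param I number of geographies.
#' @param K number of periods; labels are \code{1990, 1991, ...} so that
#'   the default spike falls in 2005.
#' @param nSystems number of planted systems (true rank).
#' @param supportSize members per system, on each of the origin and
#'   destination sides.
#' @param overlap members shared between consecutive systems' supports
#'   (default 0: well-separated).
#' @param temporalShape list with one entry per system, each either
#'   \code{list(type = "trend")}, \code{list(type = "constant")} or
#'   \code{list(type = "spike", period = <1-based index>, magnitude = m)};
#'   \code{NULL} gives the default (trends plus one spike at period
#'   \code{floor(K/2) + 2}).
#' @param meanSignal target mean of the noiseless signal over its nonzero
#'   masked-in cells; sets the component scales unless \code{scales} is
#'   given.
#' @param scales optional explicit per-system scales (overrides
#'   \code{meanSignal} calibration).
#' @param noise \code{"poisson"} (counts with the noiseless tensor as
#'   mean), \code{"gaussian"} (additive, clipped at 0) or \code{"none"}.
#' @param noiseSD standard deviation for Gaussian noise.
#' @param seed generator seed.
#' @param noiseSeed optional separate seed for the noise draw only: the
#'   planted truth stays fixed by \code{seed} while the noise varies, for
#'   replicated-noise designs.
#' @return A \code{plantedSpec} list, validated.
#' @export
plantedSpec <- function(I = 30L, K = 29L, nSystems = 3L, supportSize = 5L,
                        overlap = 0L, temporalShape = NULL, meanSignal = 50,
                        scales = NULL,
                        noise = c("poisson", "none", "gaussian"),
                        noiseSD = 5, seed = 1L, noiseSeed = NULL) {
  noise <- match.arg(noise)
  spec <- list(I = as.integer(I), K = as.integer(K),
               nSystems = as.integer(nSystems),
               supportSize = as.integer(supportSize),
               overlap = as.integer(overlap),
               temporalShape = temporalShape, meanSignal = meanSignal,
               scales = scales, noise = noise, noiseSD = noiseSD,
               seed = as.integer(seed), noiseSeed = noiseSeed)
  if (is.null(spec$temporalShape)) {
    shapes <- rep(list(list(type = "trend")), spec$nSystems)
    shapes[[spec$nSystems]] <- list(type = "spike",
                                    period = min(spec$K, spec$K %/% 2 + 2L),
                                    magnitude = 8)
    spec$temporalShape <- shapes
  }
  .validatePlantedSpec(spec)
  class(spec) <- c("plantedSpec", "list")
  spec
}

.validatePlantedSpec <- function(spec) {
  if (spec$supportSize > spec$I)
    stop("supportSize must not exceed I")
  if (spec$overlap >= spec$supportSize && spec$nSystems > 1L)
    stop("overlap must be smaller than supportSize")
  needed <- spec$nSystems * spec$supportSize -
    (spec$nSystems - 1L) * spec$overlap
  if (needed > spec$I)
    stop("infeasible supports: nSystems * supportSize - overlaps exceeds I")
  if (length(spec$temporalShape) != spec$nSystems)
    stop("temporalShape must have one entry per system")
  for (sh in spec$temporalShape) {
    if (!sh$type %in% c("trend", "constant", "spike"))
      stop("unknown temporal shape: ", sh$type)
    if (sh$type == "spike") {
      if (sh$period < 1L || sh$period > spec$K)
        stop("spike period out of range")
      if (sh$magnitude <= 1) stop("spike magnitude must exceed 1")
    }
  }
  if (!is.null(spec$scales) &&
      (length(spec$scales) != spec$nSystems || any(spec$scales <= 0)))
    stop("scales must be positive, one per system")
  invisible(spec)
}

#' Generate a flow tensor with planted migration systems
#'
#' Draws ground-truth factors per \code{spec}, forms the noiseless signal
#' \code{sum_f lambda_f a_f o b_f o c_f}, applies the requested count
#' noise, fills the diagonal cells with arbitrary large values (they are
#' masked, so they must never influence a fit), and returns both the
#' observable tensor and the truth. Deterministic given \code{spec$seed};
#' the caller's RNG state is untouched.
#'
#' @param spec a \code{\link{plantedSpec}}.
#' @return A list with elements \code{tensor}
#'   (\code{\linkS4class{FlowTensor}}) and \code{truth}
#'   (\code{\linkS4class{PlantedTruth}}).
#' @examples
#' sim <- generatePlanted(plantedSpec(I = 12, K = 6, nSystems = 2,
#'                                    supportSize = 3, noise = "none"))
#' sim$tensor
#' @export
generatePlanted <- function(spec) {
  .validatePlantedSpec(spec)
  withSeed(spec$seed, .generatePlanted(spec))
}

.generatePlanted <- function(spec) {
  I <- spec$I; K <- spec$K; Fn <- spec$nSystems
  drawSupports <- function() {
    pool <- sample.int(I)
    used <- 0L
    supports <- vector("list", Fn)
    for (f in seq_len(Fn)) {
      fresh <- spec$supportSize -
        if (f > 1L) spec$overlap else 0L
      idx <- pool[used + seq_len(fresh)]
      used <- used + fresh
      if (f > 1L && spec$overlap > 0L)
        idx <- c(sample(supports[[f - 1L]], spec$overlap), idx)
      supports[[f]] <- sort(idx)
    }
    supports
  }
  sparseFactor <- function(supports) {
    M <- matrix(0, I, Fn)
    for (f in seq_len(Fn))
      M[supports[[f]], f] <- stats::runif(spec$supportSize, 0.5, 1)
    M
  }
  A <- sparseFactor(drawSupports())
  B <- sparseFactor(drawSupports())
  C <- matrix(0, K, Fn)
  shockAt <- rep(NA_integer_, Fn)
  for (f in seq_len(Fn)) {
    sh <- spec$temporalShape[[f]]
    C[, f] <- switch(sh$type,
      constant = rep(1, K),
      trend = {
        ends <- stats::runif(2, 0.5, 1.5)
        seq(ends[1], ends[2], length.out = K)
      },
      spike = {
        cc <- rep(1, K)
        cc[sh$period] <- sh$magnitude
        shockAt[f] <- as.integer(sh$period)
        cc
      })
  }
  ## normalize columns, then calibrate scales to the target signal level
  A <- sweep(A, 2L, .colNorms(A), "/")
  B <- sweep(B, 2L, .colNorms(B), "/")
  C <- sweep(C, 2L, .colNorms(C), "/")
  geo <- sprintf("G%02d", seq_len(I))
  periods <- as.character(seq(1990L, length.out = K))
  if (!is.null(spec$scales)) {
    lambda <- as.numeric(spec$scales)
  } else {
    lambda <- vapply(seq_len(Fn), function(f) {
      comp <- .cpRecon(A[, f, drop = FALSE], B[, f, drop = FALSE],
                       C[, f, drop = FALSE])
      comp[.diagIndex(I, K)] <- 0
      spec$meanSignal / mean(comp[comp > 0])
    }, numeric(1))
  }
  ord <- order(lambda, decreasing = TRUE)
  A <- A[, ord, drop = FALSE]; B <- B[, ord, drop = FALSE]
  C <- C[, ord, drop = FALSE]
  lambda <- lambda[ord]; shockAt <- shockAt[ord]
  signal <- .cpRecon(A, B, C, lambda)
  applyNoise <- function() switch(spec$noise,
    none = signal,
    gaussian = pmax(signal + stats::rnorm(length(signal),
                                          sd = spec$noiseSD), 0),
    poisson = array(stats::rpois(length(signal), signal), dim(signal)))
  ## an explicit noiseSeed redraws the noise while keeping the planted
  ## truth fixed (replicated-noise designs)
  values <- if (!is.null(spec$noiseSeed)) {
    withSeed(spec$noiseSeed, applyNoise())
  } else {
    applyNoise()
  }
  ## diagonal cells carry no information: plant arbitrary large values
  ## there so any leakage through the mask is loud
  di <- .diagIndex(I, K)
  values[di] <- stats::runif(nrow(di), 0.5, 1.5) * 100 * (max(signal) + 1)
  tensor <- FlowTensor(values, geo = geo, periods = periods)
  base <- CPModel(sweep(A, 2L, lambda, "*"), B, C,
                  geo = geo, periods = periods, seed = spec$seed)
  ## CPModel() sorts by lambda (stable); order already matches
  truth <- new("PlantedTruth", base, shockPeriods = shockAt,
               spec = unclass(spec))
  list(tensor = tensor, truth = truth)
}

#' Factor match score between an estimate and the planted truth
#'
#' The standard recovery metric for CP benchmarks: cosine similarities are
#' computed per mode between estimated and true components, multiplied
#' across modes, and averaged over components under the best component
#' matching. The matching is exhaustive over permutations when both models
#' have the same number of components and at most 8; otherwise a greedy
#' best-pair matching over the \code{min(F)} components is used. The score
#' is invariant to component permutation and to positive rescaling of the
#' estimated factors.
#'
#' @param est a \code{\linkS4class{CPModel}} (the estimate).
#' @param truth a \code{\linkS4class{CPModel}} or
#'   \code{\linkS4class{PlantedTruth}}.
#' @return A score in \code{[0, 1]}; 1 means perfect recovery.
#' @export
factorMatchScore <- function(est, truth) {
  S <- .cosineAbs(est@A, truth@A) *
       .cosineAbs(est@B, truth@B) *
       .cosineAbs(est@C, truth@C)
  Fe <- nrow(S); Ft <- ncol(S)
  if (Fe == Ft && Fe <= 8L) {
    perms <- .permutations(Fe)
    best <- 0
    for (p in seq_len(nrow(perms))) {
      sc <- mean(S[cbind(seq_len(Fe), perms[p, ])])
      if (sc > best) best <- sc
    }
    best
  } else {
    m <- min(Fe, Ft)
    total <- 0
    Sw <- S
    for (step in seq_len(m)) {
      ij <- arrayInd(which.max(Sw), dim(Sw))
      total <- total + Sw[ij]
      Sw[ij[1], ] <- -Inf
      Sw[, ij[2]] <- -Inf
    }
    total / m
  }
}

#' Recovery benchmark over seeded replicates
#'
#' Runs \code{generate -> fit -> score} \code{nReplicates} times with
#' per-replicate seeds derived from \code{seed}, recording the factor
#' match score, the relative masked residual, and -- for every planted
#' temporal spike -- whether \code{\link{shockScan}} on the best-matching
#' estimated component flags the planted period first.
#'
#' @param spec a \code{\link{plantedSpec}}; its own seed is overridden per
#'   replicate.
#' @param rank fit rank (default: the spec's number of systems).
#' @param nReplicates number of replicates (default 20).
#' @param seed base seed for the replicate stream.
#' @param fitOpts list of options for \code{\link{fitNCPD}}
#'   (\code{maxIter}, \code{tol}, \code{restarts}).
#' @param minRatio shock-flagging threshold.
#' @return A list with \code{replicates} (one row per replicate: fms,
#'   relResidual, shockHit) and \code{summary} (medians, IQRs, shock hit
#'   rate). Deterministic given \code{seed}.
#' @export
benchmarkRecovery <- function(spec, rank = NULL, nReplicates = 20L,
                              seed = 1L, fitOpts = list(), minRatio = 3) {
  if (nReplicates < 1L) stop("nReplicates must be at least 1")
  if (is.null(rank)) rank <- spec$nSystems
  rows <- vector("list", nReplicates)
  for (i in seq_len(nReplicates)) {
    specI <- spec
    specI$seed <- as.integer(seed + 1000L + i)
    sim <- generatePlanted(specI)
    fit <- do.call(fitNCPD,
                   c(list(x = sim$tensor, rank = rank,
                          seed = as.integer(seed + 2000L + i)), fitOpts))
    fms <- factorMatchScore(fit, sim$truth)
    relRes <- sqrt(maskedObjective(sim$tensor, fit)) /
      sqrt(sum(flowMask(sim$tensor) * flowValues(sim$tensor)^2))
    shockHit <- NA
    planted <- which(!is.na(sim$truth@shockPeriods))
    if (length(planted)) {
      hits <- vapply(planted, function(tf) {
        S <- .cosineAbs(fit@A, sim$truth@A[, tf, drop = FALSE]) *
             .cosineAbs(fit@B, sim$truth@B[, tf, drop = FALSE]) *
             .cosineAbs(fit@C, sim$truth@C[, tf, drop = FALSE])
        g <- which.max(S[, 1])
        sc <- shockScan(extractSystem(fit, g, kTop = spec$supportSize),
                        minRatio = minRatio)
        nrow(sc) > 0 && sc$index[1] == sim$truth@shockPeriods[tf]
      }, logical(1))
      shockHit <- all(hits)
    }
    rows[[i]] <- data.frame(replicate = i, fms = fms,
                            relResidual = relRes, shockHit = shockHit)
  }
  replicates <- do.call(rbind, rows)
  summary <- data.frame(
    fmsMedian = stats::median(replicates$fms),
    fmsIQR = stats::IQR(replicates$fms),
    relResidualMedian = stats::median(replicates$relResidual),
    shockHitRate = if (all(is.na(replicates$shockHit))) NA_real_
                   else mean(replicates$shockHit, na.rm = TRUE))
  list(replicates = replicates, summary = summary)
}

#' Export a tensor back to long-format flow records
#'
#' Emits one record per nonzero cell (including the masked diagonal cells,
#' so a write/build round trip reproduces the stored tensor exactly).
#'
#' @param x a \code{\linkS4class{FlowTensor}}.
#' @param includeZeros also emit cells whose value is 0?
#' @return A record data frame with columns \code{origin}, \code{dest},
#'   \code{period}, \code{count}.
#' @export
flowRecordsFromTensor <- function(x, includeZeros = FALSE) {
  stopifnot(is(x, "FlowTensor"))
  idx <- if (includeZeros) which(x@values >= 0) else which(x@values != 0)
  sub <- arrayInd(idx, dim(x@values))
  out <- data.frame(origin = x@geo[sub[, 1]],
                    dest = x@geo[sub[, 2]],
                    period = x@periods[sub[, 3]],
                    count = x@values[idx],
                    stringsAsFactors = FALSE)
  out <- out[order(sub[, 3], sub[, 1], sub[, 2]), , drop = FALSE]
  rownames(out) <- NULL
  out
}
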