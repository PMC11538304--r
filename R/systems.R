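#' Extract one migration system from a fitted model
#'
#' Turns component \code{f} of a \code{\linkS4class{CPModel}} into an
#' interpretable \code{\linkS4class{MigrationSystem}}: the unit-norm origin
#' and destination membership vectors, their within-component L1
#' normalizations (the probability of each geography belonging to the
#' system), the temporal intensity profile, and the top-k member lists
#' (largest memberships first, ties broken by label order; the list is
#' shorter than \code{kTop} when fewer memberships are nonzero).
#'
#' @param model a \code{\linkS4class{CPModel}}.
#' @param f component index, \code{1 <= f <= nComponents(model)}.
#' @param kTop how many top origins/destinations to list (default 10).
#' @return A \code{\linkS4class{MigrationSystem}}.
#' @export
extractSystem <- function(model, f, kTop = 10L) {
  stopifnot(is(model, "CPModel"))
  f <- as.integer(f)
  if (f < 1L || f > ncol(model@A)) stop("component index out of range")
  kTop <- as.integer(kTop)
  if (kTop < 1L) stop("kTop must be at least 1")
  a <- stats::setNames(model@A[, f], model@geo)
  b <- stats::setNames(model@B[, f], model@geo)
  cc <- stats::setNames(model@C[, f], model@periods)
  if (sum(a) == 0 || sum(b) == 0)
    stop("zero membership vector: cannot normalize component ", f)
  topK <- function(v) {
    nz <- sum(v > 0)
    ord <- order(-v, names(v), method = "radix")
    names(v)[ord][seq_len(min(kTop, nz))]
  }
  new("MigrationSystem", index = f, lambda = unname(model@lambda[f]),
      originMembership = a, destMembership = b,
      originProb = a / sum(a), destProb = b / sum(b),
      temporal = cc, topOrigins = topK(a), topDests = topK(b))
}

#' Top-k spatial association matrix of a system
#'
#' The rank-one matrix whose \code{(i, j)} entry is the product of the
#' \code{i}th strongest origin membership and the \code{j}th strongest
#' destination membership -- who sends to whom within the system, at the
#' resolution of its top-k members. Every 2x2 minor is zero by
#' construction.
#'
#' @param system a \code{\linkS4class{MigrationSystem}}.
#' @param k how many top origins/destinations to cross (default 10; capped
#'   at the number of nonzero memberships).
#' @return A \code{k x k} (or smaller) nonnegative matrix with origin
#'   labels as rows and destination labels as columns.
#' @export
associationMatrix <- function(system, k = 10L) {
  stopifnot(is(system, "MigrationSystem"))
  k <- as.integer(k)
  pick <- function(v) {
    nz <- sum(v > 0)
    ord <- order(-v, names(v), method = "radix")
    v[ord][seq_len(min(k, nz))]
  }
  a <- pick(system@originMembership)
  b <- pick(system@destMembership)
  outer(a, b)
}

#' Flag temporal shocks in a system's intensity profile
#'
#' A period is flagged when its intensity reaches \code{minRatio} times the
#' median intensity of all other periods -- a spike-versus-baseline rule
#' capturing displacement events such as a hurricane landfall year.
#'
#' @param system a \code{\linkS4class{MigrationSystem}} with at least 3
#'   periods.
#' @param minRatio smallest intensity-to-median ratio flagged (default 3).
#' @return A data frame with columns \code{period}, \code{index} (1-based
#'   period position) and \code{score} (the ratio), sorted by score
#'   descending; zero rows when no period qualifies.
#' @export
shockScan <- function(system, minRatio = 3) {
  stopifnot(is(system, "MigrationSystem"))
  cc <- system@temporal
  K <- length(cc)
  if (K < 3L) stop("shock scan needs at least 3 periods")
  score <- vapply(seq_len(K), function(k) {
    med <- stats::median(cc[-k])
    if (med == 0) {
      if (cc[k] > 0) Inf else 0
    } else cc[k] / med
  }, numeric(1))
  hit <- which(score >= minRatio)
  out <- data.frame(period = names(cc)[hit], index = hit,
                    score = score[hit], stringsAsFactors = FALSE)
  out <- out[order(-out$score, out$index), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Classify every geography into one of the leading systems
#'
#' Assigns each geography an origin-side and a destination-side system
#' label using the first \code{nSystems} columns of the membership
#' matrices. \code{"argmax"} takes the component with the largest
#' membership. \code{"knn"} first declares seeds -- geographies whose
#' largest membership reaches half of that component's column maximum --
#' and labels the remaining geographies by majority vote of their
#' \code{knnK} nearest seeds in membership-row space (Euclidean distance;
#' vote ties go to the smaller component index). Geographies with all-zero
#' memberships are labeled \code{"unassigned"} under either method.
#'
#' @param model a \code{\linkS4class{CPModel}}.
#' @param nSystems number of leading components to classify into
#'   (\code{<= nComponents(model)}).
#' @param method \code{"argmax"} or \code{"knn"}.
#' @param knnK number of nearest seeds consulted (default 5).
#' @return A data frame with columns \code{geography}, \code{origin},
#'   \code{dest}; labels are component indices as character, or
#'   \code{"unassigned"}.
#' @export
classifyGeographies <- function(model, nSystems, method = c("argmax", "knn"),
                                knnK = 5L) {
  stopifnot(is(model, "CPModel"))
  method <- match.arg(method)
  nSystems <- as.integer(nSystems)
  if (nSystems < 1L || nSystems > ncol(model@A))
    stop("nSystems must be between 1 and nComponents(model)")
  data.frame(
    geography = model@geo,
    origin = .classifyRows(model@A[, seq_len(nSystems), drop = FALSE],
                           method, knnK),
    dest = .classifyRows(model@B[, seq_len(nSystems), drop = FALSE],
                         method, knnK),
    stringsAsFactors = FALSE)
}

.classifyRows <- function(M, method, knnK) {
  n <- nrow(M)
  lab <- rep(NA_character_, n)
  zero <- rowSums(M) == 0
  lab[zero] <- "unassigned"
  live <- which(!zero)
  if (!length(live)) return(lab)
  arg <- max.col(M[live, , drop = FALSE], ties.method = "first")
  if (method == "argmax") {
    lab[live] <- as.character(arg)
    return(lab)
  }
  colMax <- apply(M, 2, max)
  topVal <- M[cbind(live, arg)]
  isSeed <- topVal >= 0.5 * colMax[arg]
  seeds <- live[isSeed]
  seedLab <- arg[isSeed]
  lab[seeds] <- as.character(seedLab)
  rest <- live[!isSeed]
  if (length(rest)) {
    k <- min(as.integer(knnK), length(seeds))
    for (i in rest) {
      d <- sqrt(colSums((t(M[seeds, , drop = FALSE]) - M[i, ])^2))
      nn <- seedLab[order(d)][seq_len(k)]
      votes <- table(factor(nn, levels = sort(unique(seedLab))))
      lab[i] <- names(votes)[which.max(votes)]
    }
  }
  lab
}

#' Full per-system report of a fitted model
#'
#' Bundles, for every component in importance order, the extracted system,
#' its top-k association matrix, and its flagged temporal shocks, as a
#' plain nested list ready for JSON serialization.
#'
#' @param model a \code{\linkS4class{CPModel}}.
#' @param kTop top-k size for member lists and association matrices.
#' @param minRatio shock-flagging threshold passed to
#'   \code{\link{shockScan}}.
#' @return A list with elements \code{kTop}, \code{lambda} and
#'   \code{systems}; each system entry carries index, scale, top lists,
#'   probability vectors, temporal profile, association matrix and shock
#'   table.
#' @seealso \code{\link{writeSystemsReport}}, \code{\link{readSystemsReport}}
#' @export
systemsReport <- function(model, kTop = 10L, minRatio = 3) {
  stopifnot(is(model, "CPModel"))
  systems <- lapply(seq_len(ncol(model@A)), function(f) {
    s <- extractSystem(model, f, kTop = kTop)
    assoc <- associationMatrix(s, k = kTop)
    shocks <- shockScan(s, minRatio = minRatio)
    list(index = f,
         lambda = s@lambda,
         topOrigins = s@topOrigins,
         topDests = s@topDests,
         originProb = as.list(s@originProb),
         destProb = as.list(s@destProb),
         temporal = as.list(s@temporal),
         association = list(rows = rownames(assoc), cols = colnames(assoc),
                            values = lapply(seq_len(nrow(assoc)),
                                            function(r) as.list(unname(assoc[r, ])))),
         shocks = list(period = shocks$period, index = shocks$index,
                       score = shocks$score))
  })
  list(kTop = as.integer(kTop), minRatio = minRatio,
       lambda = unname(model@lambda), systems = systems)
}

#' Write / read a systems report as JSON
#'
#' @param report a list from \code{\link{systemsReport}}.
#' @param path JSON file path.
#' @return \code{writeSystemsReport} returns \code{path} invisibly;
#'   \code{readSystemsReport} returns the report list (numeric values
#'   preserved to full double precision).
#' @export
writeSystemsReport <- function(report, path) {
  jsonlite::write_json(report, path, auto_unbox = TRUE, digits = NA,
                       null = "null", na = "null", pretty = TRUE)
  invisible(path)
}

#' @rdname writeSystemsReport
#' @export
readSystemsReport <- function(path) {
  if (!file.exists(path)) stop("report file not found: ", path)
  jsonlite::read_json(path, simplifyVector = FALSE)
}
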