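#' Read long-format flow records from a delimited text file
#'
#' Parses a CSV/TSV of origin-destination-period flow counts. Column names
#' are configurable through \code{columns}, so files with headers like
#' \code{y1_statefips, y2_statefips, year, n} map onto the canonical record
#' fields without preprocessing.
#'
#' @param path path to a delimited text file with a header row.
#' @param columns named character vector mapping the canonical fields
#'   \code{origin}, \code{dest}, \code{period}, \code{count} to column names
#'   in the file.
#' @param sep field separator (default comma).
#' @return A data frame with columns \code{origin}, \code{dest} (character),
#'   \code{period} (as read) and \code{count} (numeric), one row per input
#'   row in file order.
#' @details Rows with a missing or negative count are rejected with an error
#'   naming the offending line; counts are never imputed.
#' @examples
#' f <- tempfile(fileext = ".csv")
#' writeLines(c("origin,dest,period,count", "A,B,2000,5", "B,A,2000,2"), f)
#' readFlowRecords(f)
#' @export
readFlowRecords <- function(path,
                            columns = c(origin = "origin", dest = "dest",
                                        period = "period", count = "count"),
                            sep = ",") {
  if (!file.exists(path)) stop("input file not found: ", path)
  need <- c("origin", "dest", "period", "count")
  if (!all(need %in% names(columns)))
    stop("`columns` must name all of: ", paste(need, collapse = ", "))
  df <- utils::read.csv(path, sep = sep, stringsAsFactors = FALSE,
                        check.names = FALSE)
  missing <- setdiff(unname(columns[need]), names(df))
  if (length(missing))
    stop("column(s) not found in ", path, ": ",
         paste(missing, collapse = ", "))
  count <- df[[columns["count"]]]
  if (!is.numeric(count)) count <- suppressWarnings(as.numeric(count))
  bad <- which(is.na(count) | count < 0)
  if (length(bad))
    stop("invalid count (missing or negative) at line(s) ",
         paste(bad + 1L, collapse = ", "), " of ", path)
  data.frame(origin = as.character(df[[columns["origin"]]]),
             dest = as.character(df[[columns["dest"]]]),
             period = df[[columns["period"]]],
             count = count,
             stringsAsFactors = FALSE)
}

## Order period labels: numerically when all labels parse as numbers,
## lexicographically (C locale) otherwise.
.orderPeriods <- function(p) {
  u <- unique(as.character(p))
  num <- suppressWarnings(as.numeric(u))
  if (!anyNA(num)) u[order(num)] else sort(u, method = "radix")
}

#' Build a FlowTensor from long-format records
#'
#' Places each record's count at cell \code{(origin, dest, period)} of a
#' dense \code{I x I x K} array; cells with no record are 0. The mask is 1
#' everywhere off-diagonal and 0 on the diagonal; additional cells can be
#' masked (declared missing) via \code{missingCells}.
#'
#' Self-loop records (\code{origin == dest}) are stored in \code{values} so
#' the tensor matches the source file, but their cells are masked and never
#' enter any objective; a warning reports how many there were.
#'
#' @param records data frame as returned by \code{\link{readFlowRecords}}.
#' @param geo geography labels, or \code{"infer"} to use the lexicographically
#'   sorted union of origins and destinations.
#' @param periods period labels in order, or \code{"infer"} to sort the
#'   observed periods ascending (numerically when possible).
#' @param duplicates what to do with repeated \code{(origin, dest, period)}
#'   keys: \code{"sum"} (default) or \code{"error"}.
#' @param missingCells optional data frame with columns \code{origin},
#'   \code{dest}, \code{period} naming cells whose mask is set to 0.
#' @return A \code{\linkS4class{FlowTensor}}.
#' @examples
#' rec <- data.frame(origin = c("A", "B"), dest = c("B", "A"),
#'                   period = 2000, count = c(5, 2))
#' flowValues(buildFlowTensor(rec))[, , 1]
#' @export
buildFlowTensor <- function(records, geo = "infer", periods = "infer",
                            duplicates = c("sum", "error"),
                            missingCells = NULL) {
  duplicates <- match.arg(duplicates)
  stopifnot(is.data.frame(records),
            all(c("origin", "dest", "period", "count") %in% names(records)))
  if (any(records$count < 0)) stop("counts must be nonnegative")
  orig <- as.character(records$origin)
  dest <- as.character(records$dest)
  per <- as.character(records$period)
  if (identical(geo, "infer")) {
    geo <- sort(unique(c(orig, dest)), method = "radix")
  } else {
    unknown <- setdiff(unique(c(orig, dest)), geo)
    if (length(unknown))
      stop("geography label(s) not in `geo`: ",
           paste(unknown, collapse = ", "))
  }
  if (identical(periods, "infer")) {
    periods <- .orderPeriods(per)
  } else {
    periods <- as.character(periods)
    unknown <- setdiff(unique(per), periods)
    if (length(unknown))
      stop("period label(s) not in `periods`: ",
           paste(unknown, collapse = ", "))
  }
  I <- length(geo); K <- length(periods)
  i <- match(orig, geo); j <- match(dest, geo); k <- match(per, periods)
  key <- paste(i, j, k)
  if (duplicates == "error" && anyDuplicated(key))
    stop("duplicate (origin, dest, period) records found (policy = error)")
  nSelf <- sum(i == j)
  if (nSelf > 0)
    warning(sprintf(
      "%d self-loop record(s) stored in values but masked from the objective",
      nSelf))
  values <- array(0, c(I, I, K))
  lin <- i + (j - 1L) * I + (k - 1L) * I * I
  sums <- rowsum(records$count, lin)
  values[as.integer(rownames(sums))] <- sums[, 1]
  mask <- NULL
  if (!is.null(missingCells)) {
    mask <- array(1, c(I, I, K))
    mi <- match(as.character(missingCells$origin), geo)
    mj <- match(as.character(missingCells$dest), geo)
    mk <- match(as.character(missingCells$period), periods)
    if (anyNA(mi) || anyNA(mj) || anyNA(mk))
      stop("missingCells refers to unknown labels")
    mask[cbind(mi, mj, mk)] <- 0
  }
  FlowTensor(values, geo = geo, periods = periods, mask = mask)
}

#' Collapse geographies outside a focal set into one aggregate node
#'
#' Relabels every record whose origin (resp. destination) lies outside
#' \code{internal} to the aggregate \code{label} and merges the relabeled
#' records by summation; records internal on both ends pass through
#' unchanged. Records external on both ends would become self-loops of the
#' aggregate node and are dropped (a message reports how many). This mirrors
#' the common "state plus rest-of-country" analysis design.
#'
#' @param records long-format record data frame.
#' @param internal character vector of geography ids to keep distinct.
#' @param label label for the aggregate node (must not be in
#'   \code{internal}).
#' @return A record data frame over \code{internal} plus \code{label}.
#' @export
addExternalNode <- function(records, internal, label = "EXT") {
  if (label %in% internal)
    stop("aggregate label must not be one of the internal geographies")
  orig <- as.character(records$origin)
  dest <- as.character(records$dest)
  oin <- orig %in% internal
  din <- dest %in% internal
  nDrop <- sum(!oin & !din)
  if (nDrop > 0)
    message(sprintf("addExternalNode: dropped %d record(s) external on both ends",
                    nDrop))
  keep <- oin | din
  passthrough <- records[oin & din, , drop = FALSE]
  rel <- records[keep & !(oin & din), , drop = FALSE]
  if (nrow(rel)) {
    ro <- as.character(rel$origin); rd <- as.character(rel$dest)
    ro[!(ro %in% internal)] <- label
    rd[!(rd %in% internal)] <- label
    rel <- stats::aggregate(
      list(count = rel$count),
      by = list(origin = ro, dest = rd, period = rel$period),
      FUN = sum)
    rel <- rel[, c("origin", "dest", "period", "count")]
  }
  out <- rbind(passthrough[, c("origin", "dest", "period", "count")], rel)
  rownames(out) <- NULL
  out
}

#' Aggregate a window of periods into one weight matrix
#'
#' Sums the tensor slabs over an inclusive period window and zeroes the
#' diagonal, giving the aggregated weight matrix used for pre/post event
#' comparisons (e.g. migration networks before and after a disaster).
#'
#' @param x a \code{\linkS4class{FlowTensor}}.
#' @param start,end period labels bounding the window (inclusive); both must
#'   be in \code{periodLabels(x)} with \code{start} not after \code{end}.
#' @return An \code{I x I} matrix with zero diagonal, dimnames from
#'   \code{geoLabels(x)} and a \code{"window"} attribute
#'   \code{c(start, end)}.
#' @export
aggregateWindow <- function(x, start, end) {
  stopifnot(is(x, "FlowTensor"))
  ks <- match(as.character(start), x@periods)
  ke <- match(as.character(end), x@periods)
  if (is.na(ks) || is.na(ke)) stop("window bounds must be known period labels")
  if (ks > ke) stop("empty window: start is after end")
  M <- apply(x@values[, , ks:ke, drop = FALSE], c(1, 2), sum)
  diag(M) <- 0
  dimnames(M) <- list(x@geo, x@geo)
  attr(M, "window") <- c(x@periods[ks], x@periods[ke])
  M
}

#' Serialize / restore a fitted CP model
#'
#' \code{writeCPModel} writes the factor matrices as labeled CSV files
#' (\code{A.csv}, \code{B.csv}, \code{C.csv}) and all remaining metadata
#' (scales, labels, objective trace, seed, restarts, convergence flag; for
#' \code{\linkS4class{PlantedTruth}} also shock periods and generator
#' settings) as \code{metadata.json}. \code{readCPModel} restores the
#' object; the round trip preserves factors to better than 1e-12.
#'
#' @param model a \code{\linkS4class{CPModel}} (or
#'   \code{\linkS4class{PlantedTruth}}).
#' @param dir directory to write into (created if needed).
#' @return \code{writeCPModel} returns \code{dir} invisibly;
#'   \code{readCPModel} returns the restored model.
#' @export
writeCPModel <- function(model, dir) {
  stopifnot(is(model, "CPModel"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  writeFactor <- function(M, labels, file) {
    df <- data.frame(label = labels,
                     signif(M, 17) * 1,  # keep full double precision
                     check.names = FALSE, stringsAsFactors = FALSE)
    utils::write.csv(format(df, digits = 17, trim = TRUE, scientific = NA),
                     file, row.names = FALSE, quote = FALSE)
  }
  writeFactor(model@A, model@geo, file.path(dir, "A.csv"))
  writeFactor(model@B, model@geo, file.path(dir, "B.csv"))
  writeFactor(model@C, model@periods, file.path(dir, "C.csv"))
  meta <- list(class = class(model)[1],
               nComponents = ncol(model@A),
               lambda = unname(model@lambda),
               geo = model@geo, periods = model@periods,
               objectiveTrace = model@objectiveTrace,
               seed = model@seed, restarts = model@restarts,
               converged = model@converged)
  if (is(model, "PlantedTruth")) {
    meta$shockPeriods <- model@shockPeriods
    meta$spec <- model@spec
  }
  jsonlite::write_json(meta, file.path(dir, "metadata.json"),
                       auto_unbox = TRUE, digits = NA, null = "null",
                       na = "null", pretty = TRUE)
  invisible(dir)
}

#' @rdname writeCPModel
#' @export
readCPModel <- function(dir) {
  files <- file.path(dir, c("A.csv", "B.csv", "C.csv", "metadata.json"))
  if (!all(file.exists(files)))
    stop("not a model directory (missing files): ", dir)
  meta <- jsonlite::read_json(files[4], simplifyVector = TRUE)
  readFactor <- function(file) {
    df <- utils::read.csv(file, check.names = FALSE,
                          stringsAsFactors = FALSE)
    as.matrix(df[, -1, drop = FALSE])
  }
  A <- readFactor(files[1]); B <- readFactor(files[2])
  C <- readFactor(files[3])
  ## stored factors are unit-norm; re-absorb lambda so the constructor
  ## recovers the stored scales exactly
  A <- sweep(A, 2L, meta$lambda, "*")
  model <- CPModel(A, B, C, geo = meta$geo, periods = meta$periods,
                   objectiveTrace = meta$objectiveTrace %||% numeric(0),
                   seed = meta$seed %||% NA_integer_,
                   restarts = meta$restarts %||% NA_integer_,
                   converged = meta$converged %||% NA)
  if (identical(meta$class, "PlantedTruth")) {
    model <- new("PlantedTruth", model,
                 shockPeriods = as.integer(meta$shockPeriods),
                 spec = as.list(meta$spec))
  }
  model
}

`%||%` <- function(a, b) if (is.null(a)) b else a
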