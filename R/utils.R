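## Internal numeric helpers shared by the solver, diagnostics and the
## synthetic generator. None of these are exported.

## Column-wise Khatri-Rao product: column f is kron(U[, f], V[, f]).
khatriRao <- function(U, V) {
  stopifnot(ncol(U) == ncol(V))
  out <- matrix(0, nrow(U) * nrow(V), ncol(U))
  for (f in seq_len(ncol(U))) out[, f] <- kronecker(U[, f], V[, f])
  out
}

## CP reconstruction sum_f lambda_f a_f o b_f o c_f as a dense I x J x K array.
.cpRecon <- function(A, B, C, lambda = NULL) {
  if (!is.null(lambda)) A <- sweep(A, 2L, lambda, "*")
  array(A %*% t(khatriRao(C, B)), dim = c(nrow(A), nrow(B), nrow(C)))
}

.colNorms <- function(M) sqrt(colSums(M^2))

## |cosine| between every column pair of U and V; all-zero columns score 0.
.cosineAbs <- function(U, V) {
  nu <- .colNorms(U)
  nv <- .colNorms(V)
  nu[nu == 0] <- Inf
  nv[nv == 0] <- Inf
  abs(crossprod(U, V)) / outer(nu, nv)
}

## (i, i, k) index matrix for the diagonal fibres of an I x I x K array.
.diagIndex <- function(I, K) {
  cbind(rep(seq_len(I), times = K),
        rep(seq_len(I), times = K),
        rep(seq_len(K), each = I))
}

## Evaluate expr under a fixed RNG seed, restoring the caller's RNG state.
withSeed <- function(seed, expr) {
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    stats::runif(1)
  }
  old <- get(".Random.seed", envir = globalenv(), inherits = FALSE)
  on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  set.seed(seed)
  expr
}

## All permutations of 1..n as rows; used for exhaustive component matching.
.permutations <- function(n) {
  if (n == 1L) return(matrix(1L, 1L, 1L))
  sub <- .permutations(n - 1L)
  do.call(rbind, lapply(seq_len(n), function(i) {
    rest <- setdiff(seq_len(n), i)
    cbind(i, matrix(rest[sub], nrow = nrow(sub)))
  }))
}
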