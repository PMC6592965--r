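# Internal numerical helpers shared across the package.

`%||%` <- function(a, b) if (is.null(a)) b else a

## log-determinant of a symmetric positive-definite matrix via Cholesky
logdet <- function(M) {
  if (length(M) == 1L) return(log(as.numeric(M)))
  2 * sum(log(diag(chol(M))))
}

## force exact symmetry (guards against round-off drift in precision algebra)
symm <- function(M) (M + t(M)) / 2

## robust inverse of a symmetric matrix; adds minimal jitter if needed
inv_sym <- function(M, jitter = 0) {
  if (length(M) == 1L) return(matrix(1 / (as.numeric(M) + jitter), 1, 1))
  M <- symm(M)
  if (jitter > 0) M <- M + diag(jitter, nrow(M))
  out <- tryCatch(chol2inv(chol(M)), error = function(e) NULL)
  if (is.null(out)) out <- solve(M + diag(1e-10 * max(1, mean(diag(M))), nrow(M)))
  symm(out)
}

is_finite_all <- function(x) all(is.finite(x))

## deterministic child seeds derived from one integer seed (kept < 2^31)
child_seed <- function(seed, index) {
  as.integer((as.numeric(seed) * 48271 + index * 1299721) %% 2147483647)
}

stop_dcm <- function(fmt, ..., class = "dcm_error") {
  stop(errorCondition(sprintf(fmt, ...), class = c(class, "error", "condition")))
}
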