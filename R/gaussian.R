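#' Gaussian density over named parameters
#'
#' Container used throughout the package for priors, posteriors and reduced
#' priors: an ordered set of parameter names, a mean vector and a symmetric
#' positive semidefinite covariance matrix.
#'
#' @param mean Numeric vector of means. Names are taken from `names(mean)`
#'   unless `names` is given.
#' @param cov Covariance matrix (or a single variance, or a vector of
#'   variances, which is expanded to a diagonal matrix).
#' @param names Optional character vector of parameter labels.
#' @return An object of class `gaussian_density` with fields `names`, `mean`
#'   and `cov`.
#' @examples
#' gaussian_density(c(a = 0, b = 1), diag(2))
#' @export
gaussian_density <- function(mean, cov, names = NULL) {
  mean <- unlist(mean)
  if (is.null(names)) names <- names(mean)
  mean <- as.numeric(mean)
  p <- length(mean)
  if (is.null(names)) names <- paste0("p", seq_len(p))
  if (length(names) != p) stop_dcm("length(names) != length(mean)")
  if (!is.matrix(cov)) {
    cov <- if (length(cov) == 1L) diag(rep(as.numeric(cov), p), p) else diag(as.numeric(cov), p)
  }
  if (!all(dim(cov) == c(p, p))) stop_dcm("covariance dimensions do not match mean")
  cov <- symm(cov)
  ev <- eigen(cov, symmetric = TRUE, only.values = TRUE)$values
  if (any(ev < -1e-8 * max(abs(ev), 1))) {
    stop_dcm("covariance is not positive semidefinite")
  }
  structure(list(names = as.character(names), mean = setNames(mean, names), cov = cov),
            class = "gaussian_density")
}

#' @export
print.gaussian_density <- function(x, ...) {
  cat("Gaussian density over", length(x$mean), "parameters\n")
  sds <- sqrt(pmax(diag(x$cov), 0))
  df <- data.frame(mean = x$mean, sd = sds, row.names = x$names)
  print(head(df, 20))
  if (length(x$mean) > 20) cat("... (", length(x$mean) - 20, " more)\n", sep = "")
  invisible(x)
}

## KL divergence KL[q || p] between two Gaussians over the same names
kl_gaussian <- function(q, p) {
  stopifnot(identical(q$names, p$names))
  Pp <- inv_sym(p$cov)
  d <- q$mean - p$mean
  0.5 * (sum(Pp * q$cov) + sum(d * (Pp %*% d)) - length(d) +
           logdet(p$cov) - logdet(q$cov))
}

## align a density to a given name ordering
align_density <- function(d, names) {
  if (identical(d$names, names)) return(d)
  idx <- match(names, d$names)
  if (anyNA(idx)) stop_dcm("density is missing parameters: %s",
                           paste(names[is.na(idx)], collapse = ", "))
  gaussian_density(d$mean[idx], d$cov[idx, idx, drop = FALSE], names = names)
}
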