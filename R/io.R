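# Plain-text interchange formats: cross-spectra, depth LFPs, design matrices.

#' Write cross-spectral data to a delimited text file
#'
#' The format is one row per (frequency, channel pair) with columns
#' `frequency_hz, channel_i, channel_j, real, imag`, channel indices 0-based
#' with `i <= j` (the lower triangle is implied by Hermitian symmetry).
#' Header lines prefixed `#` carry the channel labels and units.
#'
#' @param x A `spectral_data` object.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_spectra <- function(x, path) {
  stopifnot(inherits(x, "spectral_data"))
  n <- length(x$channels)
  rows <- list()
  for (i in seq_len(n)) for (j in i:n) {
    z <- x$csd[, i, j]
    rows[[length(rows) + 1L]] <- data.frame(
      frequency_hz = x$freqs, channel_i = i - 1L, channel_j = j - 1L,
      real = Re(z), imag = if (i == j) 0 else Im(z))
  }
  tab <- do.call(rbind, rows)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(paste("# channels:", paste(x$channels, collapse = ",")),
               "# units: frequency_hz=Hz csd=a.u.",
               paste(colnames(tab), collapse = "\t")), con)
  writeLines(sprintf("%.17g\t%d\t%d\t%.17g\t%.17g", tab$frequency_hz,
                     tab$channel_i, tab$channel_j, tab$real, tab$imag), con)
  invisible(path)
}

#' Read cross-spectral data from a delimited text file
#'
#' Parses the format written by [write_spectra()], validates that every
#' `(frequency, i, j)` pair with `i <= j` appears exactly once and that
#' auto-spectra have zero imaginary part, and fills the lower triangle by
#' conjugation.
#'
#' @param path Input file path.
#' @return A `spectral_data` object.
#' @export
read_spectra <- function(path) {
  if (!file.exists(path)) stop_dcm("file not found: %s", path)
  lines <- readLines(path)
  hdr <- grep("^#", lines, value = TRUE)
  channels <- NULL
  chl <- grep("^# channels:", hdr, value = TRUE)
  if (length(chl)) channels <- trimws(strsplit(sub("^# channels:", "", chl[1]), ",")[[1]])
  body_idx <- which(!grepl("^#", lines) & nzchar(trimws(lines)))
  if (!length(body_idx)) stop_dcm("no data rows in %s", path)
  header_row <- lines[body_idx[1]]
  cols <- strsplit(header_row, "\t")[[1]]
  need <- c("frequency_hz", "channel_i", "channel_j", "real", "imag")
  if (!identical(cols, need)) stop_dcm("expected columns %s", paste(need, collapse = ", "))
  data_idx <- body_idx[-1]
  fields <- strsplit(lines[data_idx], "\t", fixed = TRUE)
  bad_len <- which(lengths(fields) != 5L)
  if (length(bad_len)) stop_dcm("malformed row at line %d", data_idx[bad_len[1]])
  M <- matrix(suppressWarnings(as.numeric(unlist(fields))), ncol = 5, byrow = TRUE)
  if (anyNA(M)) {
    bad <- which(apply(M, 1, anyNA))[1]
    stop_dcm("non-numeric field at line %d", data_idx[bad])
  }
  freqs <- sort(unique(M[, 1]))
  ci <- as.integer(M[, 2]); cj <- as.integer(M[, 3])
  if (any(ci > cj)) {
    bad <- which(ci > cj)[1]
    stop_dcm("lower-triangle row (%g Hz, %d, %d): store i <= j only",
             M[bad, 1], ci[bad], cj[bad])
  }
  n <- max(cj) + 1L
  if (is.null(channels)) channels <- paste0("ch", seq_len(n))
  if (length(channels) != n) stop_dcm("channel labels do not match channel indices")
  key <- paste(M[, 1], ci, cj)
  dup <- key[duplicated(key)]
  if (length(dup)) stop_dcm("duplicate entry for (frequency, i, j) = (%s)", dup[1])
  expect <- as.vector(outer(freqs, unlist(lapply(0:(n - 1), function(i)
    paste(i, i:(n - 1)))), paste))
  missing <- setdiff(expect, key)
  if (length(missing)) stop_dcm("missing entry for (frequency, i, j) = (%s)", missing[1])
  auto <- ci == cj & M[, 5] != 0
  if (any(auto)) {
    bad <- which(auto)[1]
    stop_dcm("auto-spectrum at (%g Hz, %d, %d) has nonzero imaginary part",
             M[bad, 1], ci[bad], cj[bad])
  }
  csd <- array(0 + 0i, c(length(freqs), n, n))
  fi <- match(M[, 1], freqs)
  for (row in seq_len(nrow(M))) {
    z <- complex(real = M[row, 4], imaginary = M[row, 5])
    csd[fi[row], ci[row] + 1L, cj[row] + 1L] <- z
    csd[fi[row], cj[row] + 1L, ci[row] + 1L] <- Conj(z)
  }
  spectral_data(freqs, csd, channels)
}

#' Depth-resolved LFP container
#'
#' Local field potentials from a laminar probe: a matrix of voltages over
#' equally spaced contacts (ordered superficial to deep) by time.
#'
#' @param times Time points (ms).
#' @param depths Contact positions (micrometres), equally spaced, at least 3.
#' @param v Voltage matrix, contacts x time (mV).
#' @return An object of class `depth_lfp`.
#' @export
depth_lfp <- function(times, depths, v) {
  times <- as.numeric(times); depths <- as.numeric(depths)
  v <- as.matrix(v)
  if (length(depths) < 3) stop_dcm("depth LFP needs at least 3 contacts")
  dz <- diff(depths)
  if (any(abs(dz - mean(dz)) > 0.01 * abs(mean(dz)))) {
    stop_dcm("contact spacing must be uniform within 1%%")
  }
  if (!all(dim(v) == c(length(depths), length(times)))) {
    stop_dcm("v must be contacts x time")
  }
  structure(list(times = times, depths = depths, v = v), class = "depth_lfp")
}

#' @export
print.depth_lfp <- function(x, ...) {
  cat(sprintf("Depth LFP: %d contacts (spacing %.4g um), %d samples (%.4g-%.4g ms)\n",
              length(x$depths), mean(diff(x$depths)), length(x$times),
              min(x$times), max(x$times)))
  invisible(x)
}

#' Write / read depth-resolved LFPs as delimited text
#'
#' First column is time (ms); remaining columns are contacts ordered
#' superficial to deep. The contact spacing (micrometres) is carried in a
#' `#` header comment.
#'
#' @param x A `depth_lfp` object.
#' @param path File path.
#' @return `write_depth_lfp` returns `path` invisibly; `read_depth_lfp`
#'   returns a `depth_lfp`.
#' @export
write_depth_lfp <- function(x, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(sprintf("# depths_um: %s", paste(format(x$depths, trim = TRUE), collapse = ",")),
               paste(c("time_ms", paste0("contact", seq_along(x$depths))), collapse = "\t")),
             con)
  tab <- cbind(x$times, t(x$v))
  write.table(format(tab, digits = 17, trim = TRUE), con, sep = "\t",
              quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @rdname write_depth_lfp
#' @export
read_depth_lfp <- function(path) {
  if (!file.exists(path)) stop_dcm("file not found: %s", path)
  lines <- readLines(path)
  dl <- grep("^# depths_um:", lines, value = TRUE)
  if (!length(dl)) stop_dcm("missing '# depths_um:' header in %s", path)
  depths <- as.numeric(strsplit(sub("^# depths_um:", "", dl[1]), ",")[[1]])
  tab <- read.table(path, header = TRUE, sep = "\t", comment.char = "#")
  depth_lfp(times = tab[[1]], depths = depths,
            v = unname(t(as.matrix(tab[, -1]))))
}

#' Read a between-subject design matrix from delimited text
#'
#' Expects a header row of covariate names and one row per subject. A
#' constant column named `const` is prepended if absent, and all other
#' covariates are mean-centred so the constant encodes the group mean.
#'
#' @param path File path (tab- or comma-delimited).
#' @param center Mean-centre non-constant covariates (default `TRUE`).
#' @return Numeric design matrix with column names.
#' @export
read_design <- function(path, center = TRUE) {
  if (!file.exists(path)) stop_dcm("file not found: %s", path)
  sep <- if (grepl(",", readLines(path, n = 1))) "," else "\t"
  tab <- read.table(path, header = TRUE, sep = sep, comment.char = "#")
  X <- as.matrix(tab)
  if (!is.numeric(X)) stop_dcm("design matrix must be numeric")
  make_design(X, center = center)
}

## normalise a design matrix: ensure leading constant, centre covariates
make_design <- function(X, center = TRUE) {
  X <- as.matrix(X)
  if (is.null(colnames(X))) colnames(X) <- paste0("x", seq_len(ncol(X)))
  if (!any(apply(X, 2, function(col) all(col == col[1]) && col[1] != 0))) {
    X <- cbind(const = 1, X)
  } else {
    const_col <- which(apply(X, 2, function(col) all(col == col[1]) && col[1] != 0))[1]
    X <- cbind(const = X[, const_col] / X[1, const_col],
               X[, -const_col, drop = FALSE])
  }
  if (center && ncol(X) > 1) {
    X[, -1] <- sweep(X[, -1, drop = FALSE], 2, colMeans(X[, -1, drop = FALSE]))
  }
  X
}
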