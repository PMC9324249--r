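#' Remove per-column mean and linear trend
#'
#' Least-squares removal of an intercept and a linear time trend from
#' every column of a timeseries matrix.
#'
#' @param ts T x N numeric matrix (rows = timepoints).
#' @return matrix of the same shape with zero column means and zero
#'   least-squares linear slopes.
#' @export
detrend <- function(ts) {
  ts <- as.matrix(ts)
  if (nrow(ts) < 3) stop("detrending needs at least 3 timepoints",
                         call. = FALSE)
  tt <- seq_len(nrow(ts))
  X <- cbind(1, tt - mean(tt))
  qr.resid(qr(X), ts)
}

#' Regress nuisance confounds out of a timeseries
#'
#' Projects every column of `ts` onto the orthogonal complement of the
#' span of the confound regressors (an intercept is always included),
#' the standard treatment of CSF/white-matter nuisance signals at the
#' ROI level.
#'
#' @param ts T x N numeric matrix.
#' @param regressors T x k numeric matrix of confound timecourses.
#' @return residual T x N matrix, orthogonal to the regressor span.
#' @export
regress_confounds <- function(ts, regressors) {
  ts <- as.matrix(ts)
  regressors <- as.matrix(regressors)
  if (nrow(regressors) != nrow(ts)) {
    stop("`regressors` must have the same number of rows as `ts`",
         call. = FALSE)
  }
  if (ncol(regressors) >= nrow(ts)) {
    stop("more regressors than timepoints", call. = FALSE)
  }
  X <- cbind(1, regressors)
  qx <- qr(X)
  if (qx$rank < ncol(X)) {
    stop("confound regressors are rank deficient", call. = FALSE)
  }
  qr.resid(qx, ts)
}

#' Band-pass filter a timeseries in the frequency domain
#'
#' Hard frequency-domain masking: Fourier components with frequency `f`
#' satisfying `low_hz <= f <= high_hz` are retained, all others
#' (including the DC component when `low_hz > 0`) are zeroed.  The
#' default band 0.01-0.1 Hz is the standard resting-state BOLD band.
#'
#' @param ts T x N numeric matrix.
#' @param TR repetition time in seconds (sampling interval).
#' @param low_hz,high_hz band edges in Hz; must satisfy
#'   `0 <= low_hz < high_hz <= 1/(2*TR)`.
#' @return filtered real-valued matrix of the same shape.
#' @export
bandpass <- function(ts, TR, low_hz = 0.01, high_hz = 0.1) {
  ts <- as.matrix(ts)
  n <- nrow(ts)
  nyquist <- 1 / (2 * TR)
  if (low_hz < 0 || low_hz >= high_hz || high_hz > nyquist + 1e-12 ||
      high_hz <= 0) {
    stop(sprintf("band [%g, %g] Hz must satisfy 0 <= low < high <= Nyquist = %g",
                 low_hz, high_hz, nyquist), call. = FALSE)
  }
  k <- 0:(n - 1)
  freq <- pmin(k, n - k) / (n * TR)
  keep <- freq >= low_hz - 1e-12 & freq <= high_hz + 1e-12
  if (low_hz > 0) keep[1] <- FALSE
  ft <- mvfft(ts)
  ft[!keep, ] <- 0
  Re(mvfft(ft, inverse = TRUE)) / n
}

#' Fisher-z connectivity matrix of a subject
#'
#' Pearson correlations between all ROI pairs, clipped to
#' `+/-(1 - 1e-7)` and Fisher-transformed (`atanh`).  The diagonal is
#' stored as 0 and excluded from all downstream computation.  A column
#' with zero variance gets its whole row/column zeroed with a warning.
#'
#' @param ts T x N numeric matrix of (denoised) ROI timeseries.
#' @param subject_id optional subject label carried along.
#' @param T_effective timepoints that contribute to each correlation;
#'   defaults to `nrow(ts)`.
#' @return object of class `conn_matrix`: list with elements `z`
#'   (N x N symmetric matrix), `T_effective`, `subject_id`.
#' @export
correlation_matrix <- function(ts, subject_id = NA_character_,
                               T_effective = nrow(ts)) {
  ts <- as.matrix(ts)
  if (nrow(ts) < 5) stop("need at least 5 timepoints for correlation",
                         call. = FALSE)
  v <- apply(ts, 2, var)
  bad <- v < .Machine$double.eps
  n_roi <- ncol(ts)
  z <- matrix(0, n_roi, n_roi)
  if (any(bad)) {
    warning(sprintf("%d zero-variance column(s); their connectivity set to 0",
                    sum(bad)), call. = FALSE)
  }
  good <- which(!bad)
  if (length(good) >= 2) {
    r <- cor(ts[, good, drop = FALSE])
    r <- pmin(pmax(r, -(1 - 1e-7)), 1 - 1e-7)
    z[good, good] <- atanh(r)
  }
  diag(z) <- 0
  z <- (z + t(z)) / 2
  structure(list(z = z, T_effective = as.integer(T_effective),
                 subject_id = subject_id),
            class = "conn_matrix")
}

#' Full ROI-level denoising and connectivity pipeline
#'
#' Applies, in order: detrending, optional confound regression,
#' band-pass filtering, and Fisher-z correlation.
#'
#' @param ts T x N ROI timeseries matrix.
#' @param TR repetition time in seconds.
#' @param low_hz,high_hz band-pass edges in Hz.
#' @param confounds optional T x k confound matrix.
#' @param do_detrend,do_bandpass stage switches.
#' @inheritParams correlation_matrix
#' @return `conn_matrix` object.
#' @export
connectivity_pipeline <- function(ts, TR = 2.5, low_hz = 0.01,
                                  high_hz = 0.1, confounds = NULL,
                                  do_detrend = TRUE, do_bandpass = TRUE,
                                  subject_id = NA_character_) {
  x <- as.matrix(ts)
  if (do_detrend) x <- detrend(x)
  if (!is.null(confounds)) x <- regress_confounds(x, confounds)
  if (do_bandpass) x <- bandpass(x, TR, low_hz, high_hz)
  correlation_matrix(x, subject_id = subject_id, T_effective = nrow(x))
}

#' Write / read a connectivity matrix as TSV
#'
#' The TSV has a `roi_id` header row and first column.
#'
#' @param conn `conn_matrix` object.
#' @param path file path.
#' @param roi_ids 0-based ROI ids for the header (defaults to
#'   `0:(N-1)`).
#' @return `read_conn_matrix` returns a `conn_matrix`; `T_effective`
#'   is restored from the `# T_effective:` comment line.
#' @export
write_conn_matrix <- function(conn, path, roi_ids = NULL) {
  stopifnot(inherits(conn, "conn_matrix"))
  n <- nrow(conn$z)
  roi_ids <- roi_ids %||% (seq_len(n) - 1L)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# T_effective: %d", conn$T_effective), con)
  df <- data.frame(roi_id = roi_ids, conn$z, check.names = FALSE)
  names(df) <- c("roi_id", roi_ids)
  write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_conn_matrix
#' @export
read_conn_matrix <- function(path) {
  first <- readLines(path, n = 1)
  t_eff <- as.integer(sub("# T_effective: *", "", first))
  df <- read.delim(path, sep = "\t", skip = 1, check.names = FALSE)
  z <- as.matrix(df[, -1])
  dimnames(z) <- NULL
  structure(list(z = z, T_effective = t_eff,
                 subject_id = sub("\\.tsv$", "", basename(path))),
            class = "conn_matrix")
}
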