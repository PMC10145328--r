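#' Read a single-channel record from CSV
#'
#' Two layouts are accepted.  A two-column file (`time_s`, `value`)
#' carries its own clock: the sampling frequency is inferred from the
#' median time step, and timestamps whose steps vary by more than 1%
#' are rejected as nonuniform.  A one-column file of bare samples needs
#' an explicit `fs`.  A header row is tolerated in both layouts.
#'
#' @param path Path to the CSV file.
#' @param fs Sampling frequency in Hz, required for one-column files;
#'   if given for a two-column file it overrides the inferred value
#'   after the uniformity check.
#' @param label Optional label; defaults to the file name.
#' @return A [signal_record()].
#' @export
read_signal_csv <- function(path, fs = NULL, label = NULL) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.csv(path, header = guess_header(path))
  if (is.null(label)) label <- basename(path)
  bad <- function(col) !is.numeric(df[[col]]) || anyNA(df[[col]]) ||
    !all(is.finite(df[[col]]))
  if (ncol(df) >= 2L) {
    if (bad(1L) || bad(2L))
      stop("non-numeric or non-finite entries in ", path, call. = FALSE)
    dt <- diff(df[[1L]])
    if (any(dt <= 0)) stop("time column must be strictly increasing",
                           call. = FALSE)
    step <- stats::median(dt)
    if (max(abs(dt - step)) > 0.01 * step)
      stop("nonuniform sampling: time steps vary by more than 1%",
           call. = FALSE)
    fs_inf <- 1 / step
    signal_record(df[[2L]], fs = if (is.null(fs)) fs_inf else fs,
                  label = label)
  } else {
    if (is.null(fs))
      stop("one-column CSV requires an explicit 'fs'", call. = FALSE)
    if (bad(1L))
      stop("non-numeric or non-finite entries in ", path, call. = FALSE)
    signal_record(df[[1L]], fs = fs, label = label)
  }
}

# header iff the first comma-field of line 1 is not parseable as a number
guess_header <- function(path) {
  first <- readLines(path, n = 1L)
  fields <- strsplit(first, ",", fixed = TRUE)[[1L]]
  suppressWarnings(any(is.na(as.numeric(fields))))
}

#' Write a record to CSV
#'
#' Writes `time_s,value` rows (full double precision) with a mandatory
#' header; [read_signal_csv()] round-trips the result losslessly.
#'
#' @param x A [signal_record()].
#' @param path Output path.
#' @param time_column Include the time column (default `TRUE`); with
#'   `FALSE` a one-column file is written and `fs` must travel
#'   separately.
#' @return `path`, invisibly.
#' @export
write_signal_csv <- function(x, path, time_column = TRUE) {
  stopifnot(inherits(x, "signal_record"))
  df <- if (time_column) as.data.frame(x) else
    data.frame(value = x$samples)
  utils::write.csv(format(df, digits = 17, trim = TRUE, scientific = FALSE),
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write a decomposition to CSV
#'
#' Columns `imf_1 ... imf_P, residual`, one row per sample.
#'
#' @param x A `gafd_decomposition`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_decomposition_csv <- function(x, path) {
  stopifnot(inherits(x, "gafd_decomposition"))
  utils::write.csv(as.data.frame(x), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Resample a record to a target rate
#'
#' Fourier-method resampling: the record's spectrum is truncated (ideal
#' brickwall anti-aliasing) or zero-padded to the target bandwidth and
#' inverted on the new grid — exact for band-limited content, the
#' standard preprocessing step that unifies heterogeneous acquisition
#' rates (e.g. 500 Hz bedside monitors, 5000 Hz DAQ systems) to a
#' common 100 Hz before analysis.  Duration is preserved to within one
#' output sample.
#'
#' @param x A [signal_record()].
#' @param fs_target Target sampling frequency in Hz (default 100).
#' @return A [signal_record()] at `fs_target`.
#' @export
resample_to <- function(x, fs_target = 100) {
  stopifnot(inherits(x, "signal_record"))
  if (!is.numeric(fs_target) || length(fs_target) != 1L || fs_target <= 0)
    stop("'fs_target' must be a positive scalar", call. = FALSE)
  if (fs_target == x$fs) return(x)
  if (fs_target > 10 * x$fs)
    warning("upsampling by more than 10x: interpolation only, no new information")
  N <- length(x$samples)
  n_out <- round(N * fs_target / x$fs)
  X <- stats::fft(x$samples)
  Y <- complex(n_out)
  # strictly-positive-frequency bins shared by both grids (excl. DC/Nyquist)
  keep <- min(ceiling(N / 2), ceiling(n_out / 2)) - 1L
  Y[1L] <- X[1L]
  if (keep >= 1L) {
    Y[1L + seq_len(keep)] <- X[1L + seq_len(keep)]
    Y[n_out + 1L - seq_len(keep)] <- X[N + 1L - seq_len(keep)]
  }
  if (n_out < N && n_out %% 2L == 0L) {
    # new Nyquist bin: fold the old grid's +/- fs_target/2 bins together
    Y[n_out / 2L + 1L] <- X[n_out / 2L + 1L] + X[N - n_out / 2L + 1L]
  } else if (n_out > N && N %% 2L == 0L) {
    # old Nyquist bin: split it across the new grid's +/- fs/2 bins
    Y[N / 2L + 1L] <- X[N / 2L + 1L] / 2
    Y[n_out - N / 2L + 1L] <- X[N / 2L + 1L] / 2
  }
  y <- Re(stats::fft(Y, inverse = TRUE)) / N
  signal_record(y, fs = fs_target, label = x$label)
}
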