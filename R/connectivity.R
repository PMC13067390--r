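#' Construct an ROI time-series object
#'
#' Container for one subject's parcellated resting-state signal: a
#' frames x ROIs matrix with the repetition time (TR) needed to convert
#' window counts into seconds.
#'
#' @param data numeric frames x ROIs matrix, no missing values.
#' @param tr_seconds repetition time in seconds.
#' @param subject_id subject identifier.
#' @param roi_names optional ROI names (defaults to column names or ROI01...).
#' @return object of class `roi_ts`.
#' @export
roi_ts <- function(data, tr_seconds, subject_id = "subject",
                   roi_names = NULL) {
  data <- as.matrix(data)
  stopifnot(is.numeric(data), !anyNA(data), tr_seconds > 0, nrow(data) >= 2)
  if (is.null(roi_names)) {
    roi_names <- colnames(data)
    if (is.null(roi_names)) roi_names <- sprintf("ROI%02d", seq_len(ncol(data)))
  }
  stopifnot(length(roi_names) == ncol(data))
  colnames(data) <- roi_names
  structure(
    list(subject_id = subject_id, tr_seconds = tr_seconds,
         data = data, roi_names = roi_names),
    class = "roi_ts"
  )
}

## Pearson r -> Fisher z with clipping so z stays finite even for
## numerically perfect (anti)correlations in degenerate synthetic input.
fisher_z <- function(r, clip = 1 - 1e-7) {
  atanh(pmin(pmax(r, -clip), clip))
}

check_nonconstant <- function(x, roi_names) {
  v <- apply(x, 2, stats::var)
  bad <- which(v == 0)
  if (length(bad)) {
    stop("constant ROI column(s): ", paste(roi_names[bad], collapse = ", "))
  }
}

#' Static functional connectivity
#'
#' Pairwise Pearson correlation over all frames, Fisher z-transformed
#' (`atanh`) with correlations clipped to `+/-(1 - 1e-7)` so the transform is
#' finite everywhere. The diagonal (self-connection) is set to 0.
#'
#' @param ts a [roi_ts()] or a frames x ROIs numeric matrix.
#' @return symmetric ROIs x ROIs matrix of Fisher-z values, zero diagonal.
#' @export
static_fc <- function(ts) {
  x <- if (inherits(ts, "roi_ts")) ts$data else as.matrix(ts)
  roi_names <- colnames(x)
  check_nonconstant(x, roi_names)
  z <- fisher_z(stats::cor(x))
  z <- (z + t(z)) / 2  # enforce exact symmetry against fp asymmetry
  diag(z) <- 0
  z
}

#' Sliding-window functional connectivity
#'
#' Computes one Fisher-z connectivity matrix per contiguous window
#' `[t, t + window_trs)` of the time series, stepped one TR at a time
#' (rectangular window, no taper), giving `n_frames - window_trs + 1`
#' windows.
#'
#' @param ts a [roi_ts()] or frames x ROIs matrix.
#' @param window_trs window length in TRs; must not exceed the series length.
#' @param tr_seconds TR override when `ts` is a bare matrix.
#' @return object of class `windowed_fc`: list with `matrices` (list of
#'   z-matrices), `vectors` (windows x edges matrix of upper-triangle
#'   vectorizations), `window_starts`, `window_trs`, `tr_seconds`,
#'   `subject_id`.
#' @export
sliding_window_fc <- function(ts, window_trs, tr_seconds = NULL) {
  x <- if (inherits(ts, "roi_ts")) ts$data else as.matrix(ts)
  tr <- if (inherits(ts, "roi_ts")) ts$tr_seconds else tr_seconds
  sid <- if (inherits(ts, "roi_ts")) ts$subject_id else "subject"
  stopifnot(window_trs >= 2)
  n <- nrow(x)
  if (window_trs > n) {
    stop(sprintf("window (%d TRs) longer than series (%d frames)",
                 window_trs, n))
  }
  check_nonconstant(x, colnames(x))
  n_win <- n - window_trs + 1
  p <- ncol(x)
  mats <- vector("list", n_win)
  vecs <- matrix(0, n_win, p * (p - 1) / 2)
  for (w in seq_len(n_win)) {
    seg <- x[w:(w + window_trs - 1), , drop = FALSE]
    r <- suppressWarnings(stats::cor(seg))
    r[is.na(r)] <- 0  # window-constant column: undefined r treated as 0
    z <- fisher_z(r)
    z <- (z + t(z)) / 2
    diag(z) <- 0
    mats[[w]] <- z
    vecs[w, ] <- z[upper.tri(z)]
  }
  structure(
    list(matrices = mats, vectors = vecs,
         window_starts = seq_len(n_win), window_trs = as.integer(window_trs),
         tr_seconds = tr, subject_id = sid, n_rois = p),
    class = "windowed_fc"
  )
}

#' Window duration in seconds
#'
#' @param window_trs window length in TRs.
#' @param tr_seconds repetition time in seconds.
#' @return window length in seconds, rounded to 2 decimals (e.g. 55 TRs at
#'   TR 0.720 s -> 39.60 s).
#' @export
window_seconds <- function(window_trs, tr_seconds) {
  stopifnot(window_trs > 0, tr_seconds > 0)
  round(window_trs * tr_seconds, 2)
}

#' Framewise-displacement quality control
#'
#' A participant fails QC when the fraction of frames with FD at or above
#' `fd_threshold_mm` strictly exceeds `max_fraction` (the "more than 7.5% of
#' frames at >= 0.5 mm" exclusion rule). The subject's median FD is also
#' returned for group motion comparisons.
#'
#' @param fd_series nonnegative numeric vector of per-frame FD in mm.
#' @param fd_threshold_mm spike threshold (default 0.5 mm).
#' @param max_fraction maximum tolerated spike fraction (default 0.075).
#' @return list with `pass` (logical), `fraction` of frames at/above
#'   threshold, and `median_fd`.
#' @export
qc_fd <- function(fd_series, fd_threshold_mm = 0.5, max_fraction = 0.075) {
  if (length(fd_series) == 0) stop("empty FD series")
  stopifnot(all(fd_series >= 0))
  frac <- mean(fd_series >= fd_threshold_mm)
  list(pass = frac <= max_fraction, fraction = frac,
       median_fd = stats::median(fd_series))
}
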