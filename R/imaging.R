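#' Movie stack container
#'
#' @param frames 3-D numeric array, rows x cols x frames.
#' @param frame_rate_hz Frame rate, Hz.
#' @return An object of class `movie_stack`.
#' @export
movie_stack <- function(frames, frame_rate_hz) {
  stopifnot(is.array(frames), length(dim(frames)) == 3)
  if (dim(frames)[3] < 1) abort_config("movie needs at least one frame")
  check_number(frame_rate_hz, "frame_rate_hz", min = 0, strict_min = TRUE)
  structure(list(frames = frames, frame_rate_hz = frame_rate_hz),
            class = "movie_stack")
}

#' @export
print.movie_stack <- function(x, ...) {
  d <- dim(x$frames)
  cat(sprintf("<movie_stack> %d x %d px, %d frames @ %g Hz\n",
              d[1], d[2], d[3], x$frame_rate_hz))
  invisible(x)
}

#' ROI mask set
#'
#' @param label_image Integer matrix, one label per pixel (0 = background);
#'   labels must be contiguous 1..N and every ROI non-empty.
#' @param centroids Optional N x 2 matrix (row, col); computed from the mask
#'   when `NULL`.
#' @return An object of class `roi_mask_set`.
#' @export
roi_mask_set <- function(label_image, centroids = NULL) {
  stopifnot(is.matrix(label_image))
  label_image <- matrix(as.integer(label_image), nrow(label_image),
                        ncol(label_image))
  n <- max(0L, max(label_image))
  present <- sort(unique(label_image[label_image > 0]))
  if (n > 0 && !identical(present, seq_len(n)))
    stop("ROI labels must be contiguous 1..N with every ROI non-empty",
         call. = FALSE)
  if (is.null(centroids)) {
    centroids <- matrix(NA_real_, n, 2, dimnames = list(NULL, c("row", "col")))
    for (i in seq_len(n)) {
      px <- which(label_image == i, arr.ind = TRUE)
      centroids[i, ] <- colMeans(px)
    }
  }
  structure(list(label_image = label_image, centroids = centroids,
                 n_rois = n),
            class = "roi_mask_set")
}

# signed circular shift of a 2-D cross-correlation peak index
signed_shift <- function(idx, n) {
  s <- idx - 1L
  if (s > n %/% 2) s <- s - n
  s
}

# translate a matrix by (dy, dx), filling exposed pixels with `fill`
translate_frame <- function(frame, dy, dx, fill) {
  h <- nrow(frame); w <- ncol(frame)
  out <- matrix(fill, h, w)
  src_r <- seq_len(h) - dy
  src_c <- seq_len(w) - dx
  ok_r <- src_r >= 1 & src_r <= h
  ok_c <- src_c >= 1 & src_c <= w
  out[ok_r, ok_c] <- frame[src_r[ok_r], src_c[ok_c]]
  out
}

#' Rigid motion correction by integer-pixel cross-correlation
#'
#' Estimates a rigid integer translation for every frame by locating the
#' peak of the FFT cross-correlation against a reference image (the mean
#' frame or the first frame), then applies the correcting shift, filling
#' exposed pixels with the frame median. This deliberately simple rigid
#' registration replaces heavier motion-correction machinery; its quality is
#' verified by exact recovery of planted integer shifts.
#'
#' @param movie A [movie_stack()] with at least 2 frames.
#' @param reference `"mean_frame"` or `"first_frame"`.
#' @return A list: `movie` (corrected [movie_stack()]) and `shifts` — an
#'   n_frames x 2 matrix of applied corrections (`dy`, `dx`); a planted
#'   content shift of (+a, +b) is corrected by (-a, -b).
#' @export
register_movie <- function(movie, reference = c("mean_frame", "first_frame")) {
  stopifnot(inherits(movie, "movie_stack"))
  reference <- match.arg(reference)
  fr <- movie$frames
  d <- dim(fr)
  if (d[3] < 2) stop("need at least 2 frames to register", call. = FALSE)
  ref <- if (reference == "mean_frame") apply(fr, c(1, 2), mean) else
    fr[, , 1]
  if (all(fr == 0)) {
    warning("registration degenerate: all-zero movie; zero shifts")
    return(list(movie = movie,
                shifts = matrix(0L, d[3], 2,
                                dimnames = list(NULL, c("dy", "dx")))))
  }
  ref_c <- ref - mean(ref)
  F_ref <- fft(ref_c)
  shifts <- matrix(0L, d[3], 2, dimnames = list(NULL, c("dy", "dx")))
  out <- fr
  for (k in seq_len(d[3])) {
    frame <- fr[, , k]
    if (sd(frame) == 0) next  # featureless frame: leave unshifted
    cc <- Re(fft(F_ref * Conj(fft(frame - mean(frame))), inverse = TRUE))
    peak <- which(cc == max(cc), arr.ind = TRUE)[1, ]
    # the correlation peak sits at minus the content displacement, which is
    # exactly the correcting shift
    dy <- signed_shift(peak[1], d[1])
    dx <- signed_shift(peak[2], d[2])
    shifts[k, ] <- c(dy, dx)
    if (dy != 0 || dx != 0)
      out[, , k] <- translate_frame(frame, dy, dx, stats::median(frame))
  }
  list(movie = movie_stack(out, movie$frame_rate_hz), shifts = shifts)
}

#' Extract per-ROI mean fluorescence traces
#'
#' `trace[i, t]` is the mean intensity over ROI i's pixels in frame t.
#'
#' @param movie A [movie_stack()].
#' @param rois A [roi_mask_set()] whose mask matches the frame shape.
#' @return A [trace_matrix()], rows in ROI label order.
#' @export
extract_traces <- function(movie, rois) {
  stopifnot(inherits(movie, "movie_stack"), inherits(rois, "roi_mask_set"))
  d <- dim(movie$frames)
  if (!all(dim(rois$label_image) == d[1:2]))
    stop("mask shape does not match frame shape", call. = FALSE)
  n <- rois$n_rois
  lab <- as.vector(rois$label_image)
  inroi <- lab > 0
  counts <- tabulate(lab[inroi], nbins = n)
  if (any(counts == 0))
    stop("empty ROI(s): ", paste(which(counts == 0), collapse = ", "),
         call. = FALSE)
  flat <- matrix(movie$frames, d[1] * d[2], d[3])
  sums <- rowsum(flat[inroi, , drop = FALSE], group = lab[inroi])
  m <- sums / counts
  dimnames(m) <- NULL
  trace_matrix(m, movie$frame_rate_hz)
}

#' Normalize fluorescence traces
#'
#' `percentile_baseline`: per-neuron dF/F, `(F - F0)/F0` with `F0` a
#' per-neuron percentile of the whole session (default 10th).
#' `first_bin`: each neuron's trace divided by its mean over the session's
#' first time bin (default 180 s), the convention used by the tonic
#' within-session analysis.
#'
#' @param traces A [trace_matrix()].
#' @param method `"percentile_baseline"` or `"first_bin"`.
#' @param percentile Baseline percentile (0-100) for `percentile_baseline`.
#' @param bin_s First-bin length in seconds for `first_bin`.
#' @return A normalized [trace_matrix()] of identical shape.
#' @export
deltaf_normalize <- function(traces,
                             method = c("percentile_baseline", "first_bin"),
                             percentile = 10, bin_s = 180) {
  method <- match.arg(method)
  fr <- frame_rate(traces)
  m <- unclass(traces)
  f0 <- switch(method,
    percentile_baseline = apply(m, 1, quantile, probs = percentile / 100,
                                names = FALSE),
    first_bin = {
      nb <- min(ncol(m), max(1L, round(bin_s * fr)))
      rowMeans(m[, seq_len(nb), drop = FALSE])
    })
  bad <- which(f0 <= 0)
  if (length(bad))
    stop("non-positive baseline for neuron(s): ",
         paste(bad, collapse = ", "), call. = FALSE)
  out <- if (method == "percentile_baseline") (m - f0) / f0 else m / f0
  trace_matrix(out, fr)
}
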