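# Motion correction by whole-frame cross-correlation.

# Integer shift (dy, dx) maximizing the whole-frame cross-correlation of
# `frame` with `ref`, searched over |dy|,|dx| <= max_shift via FFT.
# Convention: frame(y, x) ~ scene(y - dy, x - dx), i.e. a positive dy means
# the content moved down by dy rows relative to the reference.
xcorr_shift <- function(ref, frame, max_shift = 15L) {
  d <- dim(ref)
  a <- ref - mean(ref)
  b <- frame - mean(frame)
  cc <- Re(stats::fft(stats::fft(b) * Conj(stats::fft(a)), inverse = TRUE))
  # cc[i, j] corresponds to shift (i-1, j-1) modulo frame size
  sy <- c(0:max_shift, -(max_shift:1))
  idx_y <- (sy %% d[1L]) + 1L
  idx_x <- (sy %% d[2L]) + 1L
  sub <- cc[idx_y, idx_x, drop = FALSE]
  best <- arrayInd(which.max(sub), dim(sub))
  c(dy = sy[best[1L]], dx = sy[best[2L]])
}

# Translate a frame by (dy, dx) integer pixels, padding exposed edges with
# the frame median (wrap-free).
translate_frame <- function(frame, dy, dx, fill = stats::median(frame)) {
  d <- dim(frame)
  out <- matrix(fill, d[1L], d[2L])
  ys <- seq_len(d[1L]); xs <- seq_len(d[2L])
  ys_dst <- ys + dy; xs_dst <- xs + dx
  ok_y <- ys_dst >= 1L & ys_dst <= d[1L]
  ok_x <- xs_dst >= 1L & xs_dst <= d[2L]
  out[ys_dst[ok_y], xs_dst[ok_x]] <- frame[ys[ok_y], xs[ok_x]]
  out
}

#' Register a frame stack to a reference image
#'
#' Corrects horizontal and vertical drift by translating each frame by the
#' integer shift that maximizes its whole-frame cross-correlation with a
#' reference image. The reference is the mean of the contiguous window of
#' frames (default 67 frames, about 2.2 s at 30 Hz) with minimal mean
#' frame-to-frame displacement, i.e. the lowest-motion epoch of the movie.
#'
#' @param movie numeric array `[ny x nx x n_frames]`.
#' @param max_shift largest shift searched, pixels.
#' @param ref_window reference window length in frames (clipped to the movie
#'   length).
#' @return list with `shifts` (`n_frames x 2` matrix of (dy, dx) of each frame
#'   relative to the reference), `registered` (the shifted stack) and
#'   `reference` (the reference image).
#' @export
register_frames <- function(movie, max_shift = 15L, ref_window = 67L) {
  stopifnot(is.array(movie), length(dim(movie)) == 3L)
  nf <- dim(movie)[3L]
  if (nf < 2L) stop("movie must have at least 2 frames")
  w <- min(ref_window, nf)
  # frame-to-frame displacement magnitudes
  step <- vapply(seq_len(nf - 1L), function(i) {
    s <- xcorr_shift(movie[, , i], movie[, , i + 1L], max_shift)
    sqrt(sum(s^2))
  }, numeric(1))
  if (nf == w) {
    start <- 1L
  } else {
    win_mean <- vapply(seq_len(nf - w + 1L), function(i) {
      mean(step[i:(i + w - 2L)])
    }, numeric(1))
    start <- which.min(win_mean)
  }
  reference <- apply(movie[, , start:(start + w - 1L), drop = FALSE],
                     c(1L, 2L), mean)
  shifts <- matrix(0L, nf, 2L, dimnames = list(NULL, c("dy", "dx")))
  registered <- movie
  for (i in seq_len(nf)) {
    s <- xcorr_shift(reference, movie[, , i], max_shift)
    shifts[i, ] <- s
    registered[, , i] <- translate_frame(movie[, , i], -s[1L], -s[2L])
  }
  list(shifts = shifts, registered = registered, reference = reference)
}

#' Extract an ROI fluorescence trace from a movie
#'
#' Per-frame mean of the pixels inside a binary mask; each mask should cover
#' a single dendrite.
#'
#' @param movie numeric array `[ny x nx x n_frames]`.
#' @param mask logical matrix `[ny x nx]`, at least one `TRUE` pixel.
#' @return numeric vector of length `n_frames`.
#' @export
extract_roi_trace <- function(movie, mask) {
  stopifnot(is.array(movie), length(dim(movie)) == 3L)
  mask <- as.logical(mask)
  if (length(mask) != prod(dim(movie)[1:2]))
    stop("mask dimensions do not match the movie frames")
  if (!any(mask)) stop("empty ROI mask")
  nf <- dim(movie)[3L]
  vapply(seq_len(nf), function(i) mean(movie[, , i][mask]), numeric(1))
}
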