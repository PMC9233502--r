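# Readers and writers. CSV long format is the interchange dialect for ROI
# trial data; configs and summaries are JSON. All writes are atomic
# (temporary file in the destination directory, then rename) and every JSON
# output embeds a schema version.

SCHEMA_VERSION <- "1.0"

atomic_write <- function(write_fn, path) {
  tmp <- tempfile(tmpdir = dirname(path), fileext = ".tmp")
  on.exit(if (file.exists(tmp)) unlink(tmp), add = TRUE)
  write_fn(tmp)
  if (!file.rename(tmp, path))
    stop(sprintf("could not move temporary file into place at %s", path))
  invisible(path)
}

#' Write a JSON summary atomically
#' @param x a list (converted with `auto_unbox`).
#' @param path destination file.
#' @return the path, invisibly.
#' @export
write_json_summary <- function(x, path) {
  x$schema_version <- SCHEMA_VERSION
  atomic_write(function(tmp)
    jsonlite::write_json(x, tmp, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE), path)
}

#' Read a JSON configuration file
#' @param path file path.
#' @return a list.
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stop(sprintf("config file not found: %s", path))
  jsonlite::read_json(path, simplifyVector = TRUE)
}

#' Write ROI trial blocks as a long-format CSV table
#'
#' Columns: `roi_id`, `neuron_id`, `compartment`, `trial`, `frame`, `value`
#' (raw fluorescence). Frame rate and protocol are recorded in a JSON
#' sidecar (`<path>.meta.json`) so a read round-trips losslessly.
#'
#' @param blocks list of [roi_block()]s.
#' @param path destination CSV path.
#' @return the path, invisibly.
#' @export
write_roi_table <- function(blocks, path) {
  stopifnot(length(blocks) >= 1L)
  tabs <- lapply(blocks, function(b) {
    nt <- nrow(b$trials); nf <- ncol(b$trials)
    data.frame(roi_id = b$roi_id, neuron_id = b$neuron_id,
               compartment = b$compartment,
               trial = rep(seq_len(nt), each = nf),
               frame = rep(seq_len(nf), nt),
               value = as.vector(t(b$trials)), stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, tabs)
  atomic_write(function(tmp)
    utils::write.csv(tab, tmp, row.names = FALSE), path)
  b1 <- blocks[[1L]]
  meta <- list(frame_rate = b1$frame_rate, units = b1$units,
               protocol = unclass(b1$protocol)[c(
                 "condition_label", "n_tones", "tone_duration", "isi",
                 "n_trials", "pre_stimulus_window")])
  write_json_summary(meta, paste0(path, ".meta.json"))
  invisible(path)
}

#' Read ROI trial blocks from a long-format CSV table
#'
#' Expects the layout written by [write_roi_table()]. Required columns:
#' `roi_id`, `compartment`, `trial`, `frame`, `value` (plus optional
#' `neuron_id`). Missing columns are reported by name; rows with missing
#' values and ROIs with inconsistent frame counts across trials are
#' reported with their positions.
#'
#' @param path CSV path (the `<path>.meta.json` sidecar supplies frame rate
#'   and protocol; `frame_rate` / `protocol` arguments override).
#' @param frame_rate,protocol,units metadata overrides.
#' @return list of [roi_block()]s.
#' @export
read_roi_table <- function(path, frame_rate = NULL, protocol = NULL,
                           units = NULL) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path))
  meta_path <- paste0(path, ".meta.json")
  if (file.exists(meta_path)) {
    meta <- jsonlite::read_json(meta_path, simplifyVector = TRUE)
    if (is.null(frame_rate)) frame_rate <- meta$frame_rate
    if (is.null(units)) units <- meta$units
    if (is.null(protocol))
      protocol <- do.call(make_protocol, as.list(meta$protocol))
  }
  if (is.null(frame_rate) || is.null(protocol))
    stop("frame_rate and protocol are required (no metadata sidecar found)")
  if (is.null(units)) units <- "F"
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  required <- c("roi_id", "compartment", "trial", "frame", "value")
  miss <- setdiff(required, names(tab))
  if (length(miss) > 0L)
    stop(sprintf("missing required column(s): %s",
                 paste(miss, collapse = ", ")))
  bad <- which(!stats::complete.cases(tab[required]))
  if (length(bad) > 0L)
    stop(sprintf("malformed rows (missing values) at lines: %s",
                 paste(utils::head(bad + 1L, 10L), collapse = ", ")))
  if (!"neuron_id" %in% names(tab)) tab$neuron_id <- NA_character_
  blocks <- lapply(split(tab, tab$roi_id), function(d) {
    counts <- table(d$trial)
    if (length(unique(counts)) != 1L)
      stop(sprintf("ROI %s: inconsistent frame counts across trials",
                   d$roi_id[1L]))
    nt <- length(counts); nf <- unique(counts)[[1L]]
    d <- d[order(d$trial, d$frame), ]
    roi_block(matrix(d$value, nrow = nt, ncol = nf, byrow = TRUE),
              frame_rate, protocol, compartment = d$compartment[1L],
              roi_id = d$roi_id[1L], neuron_id = d$neuron_id[1L],
              units = units)
  })
  unname(blocks[order(vapply(blocks, function(b) b$roi_id, character(1)))])
}

#' Write a movie as a multi-page TIFF stack
#' @param movie numeric array `[ny x nx x n_frames]`, values rescaled to
#'   `[0, 1]` on write.
#' @param path destination file.
#' @return the path, invisibly.
#' @export
write_movie_tiff <- function(movie, path) {
  rng <- range(movie)
  sc <- if (diff(rng) > 0) (movie - rng[1L]) / diff(rng) else movie * 0
  frames <- lapply(seq_len(dim(movie)[3L]), function(i) sc[, , i])
  atomic_write(function(tmp)
    tiff::writeTIFF(frames, tmp, bits.per.sample = 16L), path)
}

#' Read a multi-page TIFF stack as a movie array
#' @param path TIFF file.
#' @return numeric array `[ny x nx x n_frames]`.
#' @export
read_movie_tiff <- function(path) {
  frames <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(frames)) frames <- list(frames)
  array(unlist(frames), c(dim(frames[[1L]]), length(frames)))
}
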