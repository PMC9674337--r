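# Disk formats: movies as multi-frame TIFF (16-bit) + JSON sidecar,
# event trains as CSV, stimulus/channel configs as YAML.

#' Write / read a movie as multi-frame TIFF with a JSON sidecar
#'
#' Luminance (or fluorescence counts) are scaled to 16 bit; the sidecar
#' (`<path>.json`) records the frame rate, pixel pitch/size, scale, and
#' timeline so the movie round-trips.
#'
#' @param movie A `stimulus_movie` or `fluor_movie`.
#' @param path Output `.tif` path.
#' @return `write_movie_tiff` returns `path` invisibly;
#'   `read_movie_tiff` returns the reconstructed object.
#' @export
write_movie_tiff <- function(movie, path) {
  d <- dim(movie$frames)
  mx <- max(movie$frames, 1e-12)
  frames <- lapply(seq_len(d[1]), function(i) movie$frames[i, , ] / mx)
  tiff::writeTIFF(frames, path, bits.per.sample = 16L)
  side <- list(
    class = class(movie)[1], scale_max = mx,
    frame_rate = movie$frame_rate,
    pixel_pitch = movie$pixel_pitch %||% NULL,
    pixel_size_um = movie$pixel_size_um %||% NULL,
    times = movie$times, timeline = movie$timeline %||% NULL,
    coarse = movie$coarse %||% NULL
  )
  jsonlite::write_json(side[!vapply(side, is.null, logical(1))],
                       paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname write_movie_tiff
#' @export
read_movie_tiff <- function(path) {
  frames <- tiff::readTIFF(path, all = TRUE)
  side <- jsonlite::read_json(paste0(path, ".json"),
                              simplifyVector = TRUE)
  arr <- array(0, dim = c(length(frames), dim(frames[[1]])[1:2]))
  for (i in seq_along(frames)) arr[i, , ] <- frames[[i]] * side$scale_max
  if (identical(side$class, "fluor_movie")) {
    fluor_movie(arr, side$frame_rate, side$pixel_size_um,
                timeline = as.list(side$timeline))
  } else {
    m <- .new_stimulus_movie(arr, side$frame_rate, side$pixel_pitch,
                             side$times,
                             coarse = isTRUE(side$coarse))
    m
  }
}

#' Write / read a synaptic event train as CSV
#'
#' Columns `time_s`, `polarity`, `class`, `facet_id`, `source`.
#'
#' @param train A `SynapticEventTrain` tibble.
#' @param path CSV path.
#' @export
write_events_csv <- function(train, path) {
  utils::write.csv(
    train[, c("time_s", "polarity", "class", "facet_id", "source")],
    path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_events_csv
#' @export
read_events_csv <- function(path) {
  as_tibble(utils::read.csv(path, stringsAsFactors = FALSE)) |>
    dplyr::mutate(facet_id = as.integer(.data$facet_id)) |>
    dplyr::arrange(.data$time_s)
}
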