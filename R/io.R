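# Interchange with the formats used around curtain experiments: kymographs
# as multi-page TIFF (for image software) or plain CSV matrices (lossless),
# track tables as flat CSV, run configuration as YAML.

#' Write a kymograph as a multi-page TIFF
#'
#' One page per frame per channel, channel-major (all green frames, then
#' blue, then magenta). TIFF stores values in `[0, 1]`, so intensities are
#' scaled by the maximum across channels; the scale factor is returned (and
#' needed to recover absolute intensities).
#'
#' @param kymo A [render_kymograph()] object.
#' @param path Output file.
#' @param bits_per_sample TIFF bit depth (16 by default).
#' @returns Invisibly, the intensity scale factor.
#' @export
write_kymograph_tiff <- function(kymo, path, bits_per_sample = 16) {
  stopifnot(inherits(kymo, "kymograph"))
  scale <- max(kymo$green, kymo$blue, kymo$magenta, 1e-12)
  pages <- list()
  for (ch in c("green", "blue", "magenta")) {
    m <- kymo[[ch]] / scale
    pages <- c(pages, lapply(seq_len(nrow(m)), function(f) {
      matrix(m[f, ], nrow = 1)
    }))
  }
  tiff::writeTIFF(pages, path, bits.per.sample = bits_per_sample)
  invisible(scale)
}

#' Read a multi-page kymograph TIFF
#'
#' @param path File written by [write_kymograph_tiff()].
#' @param scale Intensity scale factor returned by the writer.
#' @returns A list with `green`, `blue`, `magenta` matrices.
#' @export
read_kymograph_tiff <- function(path, scale = 1) {
  pages <- tiff::readTIFF(path, all = TRUE)
  n <- length(pages) / 3L
  if (n != floor(n)) {
    abort("TIFF page count is not divisible by 3 channels.",
          class = "curtainr_invalid_input")
  }
  grab <- function(k) {
    do.call(rbind, pages[((k - 1L) * n + 1L):(k * n)]) * scale
  }
  list(green = grab(1), blue = grab(2), magenta = grab(3))
}

#' Write a kymograph's channels as plain CSV matrices
#'
#' Writes `<prefix>_green.csv`, `<prefix>_blue.csv`, `<prefix>_magenta.csv`,
#' each a headerless frames-by-pixels numeric matrix (lossless).
#'
#' @param kymo A [render_kymograph()] object.
#' @param prefix Path prefix for the three files.
#' @returns Invisibly, the three file paths.
#' @export
write_kymograph_csv <- function(kymo, prefix) {
  stopifnot(inherits(kymo, "kymograph"))
  paths <- vapply(c("green", "blue", "magenta"), function(ch) {
    p <- paste0(prefix, "_", ch, ".csv")
    readr::write_csv(as.data.frame(kymo[[ch]]), p, col_names = FALSE)
    p
  }, character(1))
  invisible(paths)
}

#' Read kymograph channels from CSV matrices
#'
#' @param prefix Prefix used by [write_kymograph_csv()].
#' @returns A list with `green`, `blue`, `magenta` matrices.
#' @export
read_kymograph_csv <- function(prefix) {
  grab <- function(ch) {
    as.matrix(readr::read_csv(paste0(prefix, "_", ch, ".csv"),
                              col_names = FALSE, show_col_types = FALSE,
                              col_types = readr::cols(.default = "d")))
  }
  out <- lapply(c("green", "blue", "magenta"), grab)
  out <- lapply(out, function(m) {
    dimnames(m) <- NULL
    m
  })
  names(out) <- c("green", "blue", "magenta")
  out
}

#' Write a track table to CSV
#'
#' Flattens the list-columns: per-frame positions are joined with
#' semicolons; pause intervals as `start:len` pairs.
#'
#' @param tracks A ground-truth or segmented track tibble.
#' @param path Output file.
#' @returns Invisibly, `path`.
#' @export
write_tracks_csv <- function(tracks, path) {
  flat <- tracks
  squash <- function(v) paste(v, collapse = ";")
  for (col in names(flat)) {
    if (is.list(flat[[col]])) {
      flat[[col]] <- vapply(flat[[col]], function(x) {
        if (is.data.frame(x)) {
          paste(sprintf("%d:%d", x[[1]], x[[2]]), collapse = ";")
        } else {
          squash(signif(x, 8))
        }
      }, character(1))
    }
  }
  readr::write_csv(flat, path)
  invisible(path)
}

#' Read or write a run-configuration YAML
#'
#' @param path YAML file.
#' @returns `read_run_config()` returns the configuration list.
#' @export
read_run_config <- function(path) {
  yaml::read_yaml(path)
}

#' @rdname read_run_config
#' @param config A named list of run parameters.
#' @export
write_run_config <- function(config, path) {
  yaml::write_yaml(config, path)
  invisible(path)
}
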