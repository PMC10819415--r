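#' Write a z-stack as a multi-page TIFF with a JSON sidecar
#'
#' The stack is written as plain multi-page 16-bit grayscale TIFF (one file
#' per channel is the convention) and the acquisition metadata — z step,
#' pixel size, channel and optional per-slice powers — as a JSON sidecar
#' next to it.
#'
#' @param stack An [image_stack()].
#' @param path Output TIFF path.
#' @param sidecar Sidecar JSON path; default `<path>.json`.
#' @return `path`, invisibly.
#' @export
write_stack <- function(stack, path, sidecar = paste0(path, ".json")) {
  stopifnot(inherits(stack, "image_stack"))
  pages <- lapply(seq_len(dim(stack$voxels)[1]), function(i) {
    stack$voxels[i, , ] / 65535
  })
  tiff::writeTIFF(pages, path, bits.per.sample = 16L)
  meta <- list(
    z_step_um = stack$z_step_um,
    pixel_size_um = stack$pixel_size_um,
    channel = stack$channel,
    powers = stack$powers
  )
  jsonlite::write_json(meta, sidecar, auto_unbox = TRUE, digits = NA,
                       null = "null", pretty = TRUE)
  invisible(path)
}

#' Read a z-stack from a multi-page TIFF and its JSON sidecar
#'
#' Pages are taken in file order, shallow to deep. Required sidecar fields
#' are `z_step_um` and `pixel_size_um`; missing fields produce an error
#' naming the field.
#'
#' @param path TIFF path.
#' @param sidecar Sidecar JSON path; default `<path>.json`.
#' @return An [image_stack()].
#' @export
read_stack <- function(path, sidecar = paste0(path, ".json")) {
  if (!file.exists(path)) stop("no such TIFF: ", path, call. = FALSE)
  if (!file.exists(sidecar)) stop("no such sidecar: ", sidecar, call. = FALSE)
  meta <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
  for (field in c("z_step_um", "pixel_size_um")) {
    if (is.null(meta[[field]])) {
      stop(sprintf("sidecar %s is missing required field \"%s\"", sidecar, field),
           call. = FALSE)
    }
  }
  pages <- tiff::readTIFF(path, all = TRUE, as.is = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  dims <- vapply(pages, dim, integer(2))
  if (any(dims[1, ] != dims[1, 1]) || any(dims[2, ] != dims[2, 1])) {
    stop("TIFF pages have inconsistent dimensions", call. = FALSE)
  }
  voxels <- array(0L, dim = c(length(pages), dims[1, 1], dims[2, 1]))
  for (i in seq_along(pages)) voxels[i, , ] <- pages[[i]]
  image_stack(
    voxels,
    z_step_um = meta$z_step_um,
    pixel_size_um = meta$pixel_size_um,
    channel = if (is.null(meta$channel) || is.na(meta$channel)) NA_character_
              else meta$channel,
    powers = meta$powers
  )
}

# md5 of the canonical JSON serialisation of a configuration list
config_hash <- function(config) {
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  jsonlite::write_json(config, tmp, auto_unbox = TRUE, digits = NA)
  unname(tools::md5sum(tmp))
}

#' Write an analysis result table as annotated CSV
#'
#' Writes any result tibble (depth profile, power fit table, SBR map, ...)
#' as CSV with a comment header recording the units convention, an optional
#' configuration hash, and fixed 6-significant-digit float formatting so
#' identical inputs reproduce byte-identical files.
#'
#' @param x A data frame.
#' @param path Output CSV path.
#' @param config Optional configuration list; its md5 hash is recorded in
#'   the header and changes iff any parameter changes.
#' @return `path`, invisibly.
#' @export
write_results <- function(x, path, config = NULL) {
  stopifnot(is.data.frame(x))
  header <- c(
    "# units: lengths/depths in um, counts in detector counts, powers relative",
    if (!is.null(config)) paste0("# config_hash: ", config_hash(config))
  )
  fmt <- function(col) {
    if (is.numeric(col)) sprintf("%.6g", col) else as.character(col)
  }
  body <- vapply(x, fmt, character(nrow(x)))
  if (nrow(x) == 1) body <- matrix(body, nrow = 1)
  lines <- c(
    header,
    paste(names(x), collapse = ","),
    apply(body, 1, paste, collapse = ",")
  )
  writeLines(lines, path)
  invisible(path)
}

#' Assemble and validate a run configuration
#'
#' A run configuration bundles the beam, medium and threshold settings of
#' an analysis or simulation run in one validated list, so runs are fully
#' described by a single JSON-serialisable object. Unknown keys are
#' rejected; units are micrometres throughout.
#'
#' @param beam Named list of [beam_parameters()] arguments.
#' @param medium Named list of [medium_properties()] arguments
#'   (`scattering_length_um` required).
#' @param threshold Named list of [threshold_config()] arguments.
#' @param order Photon order (2 or 3).
#' @return An object of class `run_config` with elements `beam`, `medium`,
#'   `threshold` (constructed objects) and `order`.
#' @export
#' @examples
#' run_config(medium = list(scattering_length_um = 120))
run_config <- function(beam = list(), medium = list(scattering_length_um = 120),
                       threshold = list(), order = 3) {
  check_keys <- function(x, allowed, block) {
    bad <- setdiff(names(x), allowed)
    if (length(bad) > 0) {
      stop(sprintf("unknown %s key(s): %s", block, paste(bad, collapse = ", ")),
           call. = FALSE)
    }
  }
  check_keys(beam, c("wavelength_um", "waist_um", "refractive_index"), "beam")
  check_keys(medium, c("scattering_length_um", "absorption_length_um",
                       "fill_fraction"), "medium")
  check_keys(threshold, c("strategy", "brighter_fraction", "count_threshold"),
             "threshold")
  structure(
    list(
      beam = do.call(beam_parameters, beam),
      medium = do.call(medium_properties, medium),
      threshold = do.call(threshold_config, threshold),
      order = check_order(order)
    ),
    class = "run_config"
  )
}

#' Read a run configuration from JSON
#'
#' @param path Path to a JSON file with optional `beam`, `medium`,
#'   `threshold` blocks and `order`.
#' @return A validated [run_config()].
#' @export
read_run_config <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  check_keys <- setdiff(names(raw), c("beam", "medium", "threshold", "order"))
  if (length(check_keys) > 0) {
    stop("unknown config block(s): ", paste(check_keys, collapse = ", "),
         call. = FALSE)
  }
  run_config(
    beam = if (is.null(raw$beam)) list() else as.list(raw$beam),
    medium = if (is.null(raw$medium)) list(scattering_length_um = 120)
             else as.list(raw$medium),
    threshold = if (is.null(raw$threshold)) list() else as.list(raw$threshold),
    order = if (is.null(raw$order)) 3 else raw$order
  )
}
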