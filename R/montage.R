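#' Default 59-channel scalp montage with eye channels
#'
#' Builds the electrode montage used throughout the package: 59 scalp
#' electrodes on an extended 10-20/10-10 grid plus 4 periocular channels
#' (inferior and outer canthus of each eye). Scalp positions are laid out on
#' a planar grid: `x` is the lateral coordinate (negative left), `y` runs
#' anterior (positive) to posterior (negative). Each scalp electrode is
#' assigned to one of 11 sagittal layers (three lateral and two medial layers
#' per hemisphere plus the midline), the classification used to organise
#' salience images.
#'
#' @return A tibble with one row per electrode and columns `label`, `x`, `y`,
#'   `layer`, `is_eye`.
#' @examples
#' m <- default_montage()
#' sum(!m$is_eye) # 59 scalp channels
#' @export
default_montage <- function() {
  row_def <- list(
    list(y = 4,  labels = c("F9", "F7", "F5", "F3", "F1", "FZ", "F2", "F4", "F6", "F8", "F10"),
         x = c(-5, -4, -3, -2, -1, 0, 1, 2, 3, 4, 5)),
    list(y = 3,  labels = c("FT9", "FT7", "FC5", "FC3", "FC1", "FCZ", "FC2", "FC4", "FC6", "FT8", "FT10"),
         x = c(-5, -4, -3, -2, -1, 0, 1, 2, 3, 4, 5)),
    list(y = 2,  labels = c("T7", "C5", "C3", "C1", "CZ", "C2", "C4", "C6", "T8"),
         x = c(-4, -3, -2, -1, 0, 1, 2, 3, 4)),
    list(y = 1,  labels = c("TP9", "TP7", "CP5", "CP3", "CP1", "CPZ", "CP2", "CP4", "CP6", "TP8", "TP10"),
         x = c(-5, -4, -3, -2, -1, 0, 1, 2, 3, 4, 5)),
    list(y = 0,  labels = c("P7", "P5", "P3", "P1", "PZ", "P2", "P4", "P6", "P8"),
         x = c(-4, -3, -2, -1, 0, 1, 2, 3, 4)),
    list(y = -1, labels = c("PO3", "PO4"), x = c(-2, 2)),
    list(y = -2, labels = c("O1", "OZ", "O2"), x = c(-1, 0, 1)),
    list(y = -3, labels = c("CB1", "IZ", "CB2"), x = c(-3, 0, 3))
  )
  scalp <- purrr::map_dfr(row_def, function(r) {
    tibble::tibble(label = r$labels, x = r$x, y = r$y)
  })
  scalp$layer <- sagittal_layer(scalp$x)
  scalp$is_eye <- FALSE
  eyes <- tibble::tibble(
    label = c("LO1", "IO1", "IO2", "LO2"),
    x = c(-5.5, -1.5, 1.5, 5.5),
    y = c(5, 5.5, 5.5, 5),
    layer = NA_character_,
    is_eye = TRUE
  )
  dplyr::bind_rows(scalp, eyes)
}

# |x| grid distance -> one of the 11 sagittal layers
sagittal_layer <- function(x) {
  band <- c("med1", "med2", "lat1", "lat2", "lat3")[pmin(abs(x), 5)]
  layer <- ifelse(x == 0, "mid",
    paste0(ifelse(x < 0, "L-", "R-"), band))
  layer
}

#' Reduced montage for small simulations
#'
#' A 20-electrode subset of [default_montage()] (plus the 4 eye channels)
#' that keeps the vertex, both regions of interest (FC1/FZ/FC2 and
#' TP9/IZ/TP10) and a spread of lateral sites. Intended for calibration
#' simulations where the full 59-channel montage is unnecessarily large.
#'
#' @return A montage tibble, as [default_montage()].
#' @export
reduced_montage <- function() {
  keep <- c(
    "F9", "F3", "FZ", "F4", "F10",
    "FT9", "FC1", "FCZ", "FC2", "FT10",
    "C3", "CZ", "C4",
    "TP9", "CPZ", "TP10",
    "PZ", "CB1", "IZ", "CB2"
  )
  m <- default_montage()
  dplyr::filter(m, .data$is_eye | .data$label %in% keep)
}

#' Minimal 12-electrode calibration montage
#'
#' A 12-electrode subset (plus eye channels) spanning the midline, both
#' regions of interest and one lateral pair, used by the null-calibration
#' simulations where statistical calibration — not spatial coverage — is
#' under test.
#'
#' @return A montage tibble, as [default_montage()].
#' @export
calibration_montage <- function() {
  keep <- c("F3", "FZ", "F4", "FC1", "FCZ", "FC2",
            "CZ", "TP9", "CPZ", "TP10", "PZ", "IZ")
  m <- default_montage()
  dplyr::filter(m, .data$is_eye | .data$label %in% keep)
}

#' Validate a montage table
#'
#' Checks the invariants the analysis relies on: unique labels, presence of
#' all electrodes referenced by the peak/ROI analyses, and exactly 11
#' sagittal layers over the scalp channels.
#'
#' @param montage A montage tibble (see [default_montage()]).
#' @param require_named If `TRUE` (default for the full montage), require all
#'   analysis-named electrodes to be present.
#' @return The montage, invisibly, or an error.
#' @export
validate_montage <- function(montage, require_named = TRUE) {
  stopifnot(is.data.frame(montage))
  need_cols <- c("label", "x", "y", "layer", "is_eye")
  missing_cols <- setdiff(need_cols, names(montage))
  if (length(missing_cols) > 0) {
    stop("montage is missing columns: ", paste(missing_cols, collapse = ", "))
  }
  if (anyDuplicated(montage$label)) {
    stop("montage labels must be unique")
  }
  if (require_named) {
    named <- c("CZ", "FZ", "FCZ", "FC1", "FC2", "F1", "F2", "F9",
               "FT9", "FT10", "TP9", "TP10", "CB1", "CB2", "IZ")
    absent <- setdiff(named, montage$label)
    if (length(absent) > 0) {
      stop("montage is missing required electrode(s): ",
           paste(absent, collapse = ", "))
    }
    n_layer <- length(unique(montage$layer[!montage$is_eye]))
    if (n_layer != 11) {
      stop("scalp montage must span exactly 11 sagittal layers, found ", n_layer)
    }
  }
  invisible(montage)
}

#' Inter-electrode distance matrix
#'
#' Euclidean distances between electrode grid positions, used to build the
#' spatially correlated noise covariance of the simulator.
#'
#' @param montage A montage tibble.
#' @return A symmetric matrix with dimnames set to electrode labels.
#' @export
electrode_distances <- function(montage) {
  pos <- as.matrix(montage[, c("x", "y")])
  d <- as.matrix(stats::dist(pos))
  dimnames(d) <- list(montage$label, montage$label)
  d
}

#' Named electrode sets for the region-of-interest analyses
#'
#' @return A named list: `vertex` (CZ), `anterior_central` (FC1, FZ, FC2) and
#'   `temporal_occipital` (TP9, IZ, TP10).
#' @export
roi_sets <- function() {
  list(
    vertex = "CZ",
    anterior_central = c("FC1", "FZ", "FC2"),
    temporal_occipital = c("TP9", "IZ", "TP10")
  )
}
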