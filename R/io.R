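## Format handling: TIFF + JSON sidecars for stacks and volumes, YAML system
## configurations.

.sidecarPath <- function(path) paste0(sub("\\.tiff?$", "", path), ".json")

#' Write a raw stack as multi-page TIFF plus JSON sidecar
#'
#' @param stack a \code{\link[=RawStack-class]{RawStack}}.
#' @param path output TIFF path; the metadata sidecar is written next to it
#'   with a \code{.json} extension.
#' @return \code{path}, invisibly.
#' @export
writeStack <- function(stack, path) {
  writeTiffStack(path, stack@frames)
  meta <- list(type = "raw_stack",
               alpha_deg = stack@alpha,
               magnification = stack@magnification,
               pixel_pitch_um = stack@pixelPitch,
               stage_step_um = stack@stageStep,
               scan_direction = stack@scanDirection,
               waveform_mode = stack@waveformMode)
  jsonlite::write_json(meta, .sidecarPath(path), auto_unbox = TRUE,
                       digits = I(17))
  invisible(path)
}

#' Read a raw stack (TIFF + JSON sidecar)
#'
#' @param path TIFF path written by \code{\link{writeStack}}.
#' @return A \code{\link[=RawStack-class]{RawStack}}; pixel data and
#'   metadata round-trip losslessly.
#' @export
readStack <- function(path) {
  side <- .sidecarPath(path)
  required <- c("alpha_deg", "magnification", "pixel_pitch_um",
                "stage_step_um", "scan_direction")
  if (!file.exists(side))
    stop("metadata sidecar ", side, " not found; required fields: ",
         paste(required, collapse = ", "))
  meta <- jsonlite::read_json(side, simplifyVector = TRUE)
  missing <- setdiff(required, names(meta))
  if (length(missing))
    stop("metadata sidecar ", side, " lacks required fields: ",
         paste(missing, collapse = ", "))
  new("RawStack", frames = readTiffStack(path),
      alpha = as.numeric(meta$alpha_deg),
      magnification = as.numeric(meta$magnification),
      pixelPitch = as.numeric(meta$pixel_pitch_um),
      stageStep = as.numeric(meta$stage_step_um),
      scanDirection = as.numeric(meta$scan_direction),
      waveformMode = if (is.null(meta$waveform_mode)) "unknown"
                     else meta$waveform_mode)
}

#' Write a deskewed volume as multi-page TIFF plus JSON sidecar
#'
#' Intensities are rounded and clipped to the 16-bit range; z-slices become
#' TIFF pages. Voxel size, origin and the unfilled-voxel fraction are
#' recorded in the sidecar.
#'
#' @param volume an \code{\link[=OPMVolume-class]{OPMVolume}}.
#' @param path output TIFF path.
#' @return \code{path}, invisibly.
#' @export
writeVolume <- function(volume, path) {
  arr <- array(as.integer(pmin(pmax(round(volume@data), 0), 65535)),
               dim(volume@data))
  writeTiffStack(path, arr)
  meta <- list(type = "volume",
               axis_order = "zyx",
               origin_um = volume@origin,
               voxel_size_um = volume@voxelSize,
               missing_fraction = volume@missingFraction)
  jsonlite::write_json(meta, .sidecarPath(path), auto_unbox = TRUE,
                       digits = I(17))
  invisible(path)
}

#' Read a deskewed volume (TIFF + JSON sidecar)
#'
#' @param path TIFF path written by \code{\link{writeVolume}}.
#' @return An \code{\link[=OPMVolume-class]{OPMVolume}}.
#' @export
readVolume <- function(path) {
  side <- .sidecarPath(path)
  required <- c("origin_um", "voxel_size_um")
  if (!file.exists(side))
    stop("metadata sidecar ", side, " not found; required fields: ",
         paste(required, collapse = ", "))
  meta <- jsonlite::read_json(side, simplifyVector = TRUE)
  missing <- setdiff(required, names(meta))
  if (length(missing))
    stop("metadata sidecar ", side, " lacks required fields: ",
         paste(missing, collapse = ", "))
  new("OPMVolume", data = readTiffStack(path),
      origin = as.numeric(meta$origin_um),
      voxelSize = as.numeric(meta$voxel_size_um),
      missingFraction = if (is.null(meta$missing_fraction)) 0
                        else as.numeric(meta$missing_fraction))
}

.knownKeys <- list(
  top = c("objective", "light_sheet", "relays", "etl", "camera",
          "total_magnification"),
  objective = c("na", "f_obj_mm", "immersion_index", "nominal_mag",
                "bfp_diameter_mm"),
  light_sheet = c("na_ls", "r_ls_mm", "aperture_ratio"),
  relays = c("focal_lengths_mm"),
  etl = c("aperture_diameter_mm", "max_power_dioptre", "flyback_time_s"),
  camera = c("n_cols", "n_rows", "pixel_pitch_um", "line_time_s",
             "bidirectional_shutter"))

.checkKeys <- function(given, section) {
  unknown <- setdiff(names(given), .knownKeys[[section]])
  if (length(unknown))
    stop(sprintf("unknown key(s) in config section '%s': %s", section,
                 paste(unknown, collapse = ", ")))
}

#' Load a system configuration from a YAML file
#'
#' Parses a structured config with sections \code{objective},
#' \code{light_sheet}, \code{relays}, \code{etl} and \code{camera} (plus an
#' optional top-level \code{total_magnification} override), validates every
#' invariant through the class constructors and rejects unknown keys.
#'
#' @param path YAML file path. Two fixtures ship with the package:
#'   \code{system.file("extdata", "config_60x.yaml", package = "rfopm")} and
#'   \code{config_20x.yaml}.
#' @return A \code{\link{SystemConfig}}.
#' @examples
#' cfg <- loadConfig(system.file("extdata", "config_20x.yaml", package = "rfopm"))
#' effectiveNA(cfg@objective, cfg@relays, cfg@etl)   # 0.37
#' @export
loadConfig <- function(path) {
  cfg <- yaml::read_yaml(path)
  .checkKeys(cfg, "top")
  for (sec in c("objective", "light_sheet", "relays", "etl", "camera")) {
    if (is.null(cfg[[sec]])) stop("config section '", sec, "' is missing")
    .checkKeys(cfg[[sec]], sec)
  }
  o <- cfg$objective
  objective <- ObjectiveSpec(
    na = o$na,
    fObj = o$f_obj_mm,
    n = if (is.null(o$immersion_index)) 1.33 else o$immersion_index,
    nominalMag = if (is.null(o$nominal_mag)) NA_real_ else o$nominal_mag,
    bfpDiameter = o$bfp_diameter_mm)
  ls <- cfg$light_sheet
  lightSheet <- LightSheetSpec(naLs = ls$na_ls, rLs = ls$r_ls_mm,
                               apertureRatio = ls$aperture_ratio,
                               objective = objective)
  relays <- RelaySpec(cfg$relays$focal_lengths_mm)
  e <- cfg$etl
  etl <- ETLSpec(
    apertureDiameter = e$aperture_diameter_mm,
    maxPower = if (is.null(e$max_power_dioptre)) 5 else e$max_power_dioptre,
    flybackTime = if (is.null(e$flyback_time_s)) 0.008 else e$flyback_time_s)
  cam <- cfg$camera
  camera <- CameraSpec(
    nCols = cam$n_cols, nRows = cam$n_rows,
    pixelPitch = cam$pixel_pitch_um, lineTime = cam$line_time_s,
    bidirectionalShutter = isTRUE(cam$bidirectional_shutter))
  SystemConfig(objective, lightSheet, relays, etl, camera,
               totalMagnification = cfg$total_magnification)
}
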