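#' Read a NIfTI volume
#'
#' Reads a NIfTI-1 file into a 3D array with its voxel spacing attached.
#' Fails loudly when the header carries no usable voxel dimensions instead of
#' silently assuming 1 mm voxels.
#'
#' @param path path to a `.nii` or `.nii.gz` file.
#' @return a volume (3D array with `spacing` attribute, mm).
#' @export
read_volume <- function(path) {
  img <- RNifti::readNifti(path)
  pix <- RNifti::pixdim(img)
  if (length(pix) < 3 || any(!is.finite(pix[1:3])) || any(pix[1:3] <= 0))
    stop(sprintf("'%s': NIfTI header has no usable voxel dimensions", path))
  x <- array(as.numeric(img), dim = dim(img)[1:3])
  as_volume(x, pix[1:3])
}

#' Write a volume as NIfTI
#'
#' HU-like integer-valued volumes can be stored lossless as signed 16-bit;
#' anything else is written as float32.
#'
#' @param x a volume.
#' @param path output path (`.nii` or `.nii.gz`).
#' @param datatype `"auto"` (int16 when lossless, else float32), `"int16"` or
#'   `"float"`.
#' @return `path`, invisibly.
#' @export
write_volume <- function(x, path, datatype = c("auto", "int16", "float")) {
  datatype <- match.arg(datatype)
  sp <- voxel_spacing(x)
  if (datatype == "auto") {
    lossless <- all(is.finite(x)) && all(x == round(x)) &&
      min(x) >= -32768 && max(x) <= 32767
    datatype <- if (lossless) "int16" else "float"
  }
  arr <- array(as.numeric(x), dim = dim(x))
  attr(arr, "pixdim") <- sp
  img <- RNifti::asNifti(arr, datatype = datatype)
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Write a phantom case to disk
#'
#' One NIfTI file per volume plus a JSON sidecar with the generating
#' specification, so a case directory is self-describing.
#'
#' @param case a `phantom_case`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_phantom <- function(case, dir) {
  stopifnot(inherits(case, "phantom_case"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_volume(case$labels, file.path(dir, "labels.nii.gz"), "int16")
  write_volume(case$ct_hu, file.path(dir, "ct.nii.gz"))
  write_volume(case$ute1, file.path(dir, "ute1.nii.gz"), "float")
  write_volume(case$ute2, file.path(dir, "ute2.nii.gz"), "float")
  write_volume(case$activity, file.path(dir, "activity.nii.gz"), "float")
  write_volume(case$background_roi + 0, file.path(dir, "background_roi.nii.gz"), "int16")
  write_volume(case$exclusion_mask + 0, file.path(dir, "exclusion_mask.nii.gz"), "int16")
  side <- unclass(case$spec)
  side$subject_id <- case$subject_id
  side$exam_index <- case$exam_index
  jsonlite::write_json(side, file.path(dir, "spec.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Read a phantom case written by [write_phantom()]
#' @param dir case directory.
#' @return a `phantom_case`.
#' @export
read_phantom <- function(dir) {
  side <- jsonlite::read_json(file.path(dir, "spec.json"), simplifyVector = TRUE)
  vol <- function(f) read_volume(file.path(dir, f))
  case <- list(
    labels = vol("labels.nii.gz"),
    ct_hu = vol("ct.nii.gz"),
    ute1 = vol("ute1.nii.gz"),
    ute2 = vol("ute2.nii.gz"),
    activity = vol("activity.nii.gz"),
    background_roi = vol("background_roi.nii.gz") > 0.5,
    exclusion_mask = vol("exclusion_mask.nii.gz") > 0.5,
    subject_id = side$subject_id,
    exam_index = side$exam_index,
    te1_ms = side$te1_ms %||% 0.07,
    te2_ms = side$te2_ms %||% 2.46,
    seed = side$seed,
    spec = side
  )
  for (m in c("background_roi", "exclusion_mask"))
    case[[m]] <- as_volume(array(case[[m]], dim(case$labels)),
                           voxel_spacing(case$labels))
  class(case) <- "phantom_case"
  case
}

`%||%` <- function(a, b) if (is.null(a)) b else a
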