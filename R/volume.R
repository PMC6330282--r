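#' Tag a 3D array as a volume with voxel spacing
#'
#' All images in the pipeline are plain 3D numeric arrays carrying a
#' `spacing` attribute (isotropic or anisotropic voxel size in mm).
#' Axis 1 is the axial slice index; axes 2 and 3 are in-plane.
#'
#' @param x 3D numeric array.
#' @param spacing voxel size in mm, length 1 (isotropic) or 3.
#' @return the array with a `spacing` attribute set.
#' @export
as_volume <- function(x, spacing) {
  if (!is.array(x) || length(dim(x)) != 3L)
    stop("a volume must be a 3D array")
  spacing <- rep_len(as.numeric(spacing), 3L)
  if (any(!is.finite(spacing)) || any(spacing <= 0))
    stop("voxel spacing must be positive and finite")
  attr(x, "spacing") <- spacing
  x
}

#' Voxel spacing of a volume in mm
#' @param x a volume created with [as_volume()] or read with [read_volume()].
#' @return numeric length-3 spacing (mm).
#' @export
voxel_spacing <- function(x) {
  sp <- attr(x, "spacing")
  if (is.null(sp)) stop("volume has no spacing attribute")
  sp
}

#' Voxel volume in mL
#' @param x a volume.
#' @return scalar, mL per voxel (1 mL = 1000 mm^3).
#' @export
voxel_volume_ml <- function(x) prod(voxel_spacing(x)) / 1000

# shared grid guard: identical dims and spacing (spacing to 1e-6 mm)
check_same_grid <- function(a, b, what = "volumes") {
  if (!identical(dim(a), dim(b)))
    stop(sprintf("%s are on different grids: %s vs %s", what,
                 paste(dim(a), collapse = "x"), paste(dim(b), collapse = "x")))
  sa <- attr(a, "spacing"); sb <- attr(b, "spacing")
  if (!is.null(sa) && !is.null(sb) && any(abs(sa - sb) > 1e-6))
    stop(sprintf("%s have different voxel spacing", what))
  invisible(TRUE)
}

# evaluate code under a temporary RNG state, restoring the caller's stream
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(code)
}

# deterministic per-stage seed fan-out from a single study seed;
# keeps results < 2^31 so they remain valid R integer seeds
substream_seed <- function(seed, stage, index = 0L) {
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  as.integer((as.double(seed) * 2654435.0 + h * 97.0 + index * 7919.0) %% 2147483587)
}
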