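# Trabecular morphometry: BvTv, BsBv and the plate-model indices TbTh, TbN,
# TbSp.  The indirect (plate-model) identities of classic histomorphometry
# are used: TbTh = 2/BsBv, TbN = BvTv/TbTh, TbSp = 1/TbN - TbTh.

morphometry_result <- function(BvTv, BsBv) {
  TbTh <- 2 / BsBv
  TbN <- BvTv / TbTh
  TbSp <- 1 / TbN - TbTh
  structure(list(BvTv = BvTv, BsBv = BsBv, TbTh = TbTh, TbN = TbN, TbSp = TbSp,
                 units = c(BvTv = "", BsBv = "mm^-1", TbTh = "mm",
                           TbN = "mm^-1", TbSp = "mm")),
            class = "morphometry_result")
}

#' @export
print.morphometry_result <- function(x, ...) {
  cat("<morphometry_result>\n")
  for (f in c("BvTv", "BsBv", "TbTh", "TbN", "TbSp"))
    cat(sprintf("  %-5s %10.4f %s\n", f, x[[f]], x$units[[f]]))
  invisible(x)
}

#' Plate-model morphometry from scalar inputs
#'
#' Applies the plate-model identities to a given bone volume fraction and
#' surface-to-volume ratio: `TbTh = 2/BsBv` (mm), `TbN = BvTv/TbTh` (mm^-1),
#' `TbSp = 1/TbN - TbTh` (mm).  A fully dense structure (`BvTv = 1`) has zero
#' separation.
#'
#' @param BvTv Bone volume fraction in (0, 1].
#' @param BsBv Bone surface over bone volume, mm^-1, > 0.
#' @return A `morphometry_result` with the five indices and their units.
#' @export
morphometry_from_scalars <- function(BvTv, BsBv) {
  if (!is.numeric(BvTv) || length(BvTv) != 1L || BvTv <= 0 || BvTv > 1)
    stop("BvTv must be in (0, 1]", call. = FALSE)
  if (!is.numeric(BsBv) || length(BsBv) != 1L || BsBv <= 0)
    stop("BsBv must be > 0", call. = FALSE)
  morphometry_result(BvTv, BsBv)
}

#' Bone morphometry of a binary mask
#'
#' `BvTv` is the object voxel fraction; `BsBv` is the configuration-count
#' surface area of the solid phase divided by its volume (see
#' [minkowski_functionals()]); the remaining indices follow from the
#' plate-model identities.
#'
#' @param bin A [binary_volume()] of the solid (bone) phase; must be
#'   non-empty.
#' @return A `morphometry_result`.
#' @export
bone_morphometry <- function(bin) {
  stopifnot(inherits(bin, "binary_volume"))
  if (!any(bin$data)) stop("empty solid phase", call. = FALSE)
  BvTv <- volume_density(bin)
  mk <- minkowski_functionals(bin)
  bone_vol_mm3 <- sum(bin$data) * voxel_mm(bin)^3
  BsBv <- mk$surface_area_mm2 / bone_vol_mm3
  morphometry_result(BvTv, BsBv)
}
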