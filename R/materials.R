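#' Linear-elastic material definitions
#'
#' Isotropic, homogeneous, linear-elastic material. Density is carried as
#' metadata only: all analyses are static. The default property set follows
#' nanoindentation measurements on ramphastid bills: rhamphotheca keratin
#' E = 6.5 GPa, rho = 1000 kg/m^3; trabecular bone (modelled as a solid
#' endocast) E = 12.7 GPa, rho = 50 kg/m^3; Poisson's ratio 0.4 for both.
#'
#' @param name material name.
#' @param E Young's modulus, Pa.
#' @param nu Poisson's ratio, in [0, 0.5).
#' @param rho density, kg/m^3.
#' @return an object of class `material`.
#' @export
material <- function(name, E, nu, rho = 1000) {
  if (E <= 0) stop("material: E must be > 0")
  if (nu < 0 || nu >= 0.5) stop("material: nu must be in [0, 0.5)")
  if (rho <= 0) stop("material: rho must be > 0")
  structure(list(name = name, E = E, nu = nu, rho = rho), class = "material")
}

#' @rdname material
#' @export
keratin <- function() material("keratin", E = 6.5e9, nu = 0.4, rho = 1000)

#' @rdname material
#' @export
bone <- function() material("bone", E = 12.7e9, nu = 0.4, rho = 50)

#' Assign materials to the two mesh regions
#'
#' Maps the mesh material ids (`rhamphotheca`, `bone`) to material property
#' sets. `composite` is the natural condition (keratin shell over bony
#' core); `all_keratin` and `all_bone` assign one material to both regions
#' for the homogeneous comparison conditions.
#'
#' @param mode one of `"composite"`, `"all_keratin"`, `"all_bone"`.
#' @param keratin_mat,bone_mat optional material overrides.
#' @return an object of class `material_assignment`: a list mapping mesh
#'   material id to `material`.
#' @export
material_assignment <- function(mode = c("composite", "all_keratin", "all_bone"),
                                keratin_mat = keratin(), bone_mat = bone()) {
  mode <- match.arg(mode)
  map <- switch(mode,
    composite   = list(rhamphotheca = keratin_mat, bone = bone_mat),
    all_keratin = list(rhamphotheca = keratin_mat, bone = keratin_mat),
    all_bone    = list(rhamphotheca = bone_mat, bone = bone_mat))
  structure(list(mode = mode, materials = map), class = "material_assignment")
}

#' Loading regime definition
#'
#' The two excavation loading regimes: `impact` applies a total tip force
#' `F` (default 10 N, the pecking-force scale of a similar-sized
#' cavity-excavator) in the -z direction with the base fully fixed;
#' `torsion` prescribes a small rotation `theta` (default 1.75 mrad, 0.1
#' degrees) of the base about the +z axis through the bony-core base
#' centroid, with the tip patch fixed.
#'
#' @param regime `"impact"` or `"torsion"`.
#' @param F total tip force in N (impact).
#' @param theta prescribed base rotation in rad (torsion).
#' @return an object of class `load_case`.
#' @export
load_case <- function(regime = c("impact", "torsion"), F = 10, theta = 1.75e-3) {
  regime <- match.arg(regime)
  if (F <= 0) stop("load_case: F must be > 0")
  if (theta < 0) stop("load_case: theta must be >= 0")
  structure(list(regime = regime, F = F, theta = theta), class = "load_case")
}
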