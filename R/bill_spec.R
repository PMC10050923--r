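#' Parametric description of a two-layer maxilla
#'
#' A `bill_spec` describes one upper bill (maxilla) as a tapering
#' superelliptic solid of axial extent `length`, made of an outer keratinous
#' shell (the rhamphotheca) of constant thickness `shell_thickness` wrapped
#' around an inner bony core. The +z axis runs from the base (z = 0) to the
#' tip (z = length); x is the width axis and y the depth axis. All lengths
#' are in metres.
#'
#' Cross-sections are superellipses `|x/A|^p + |y/B|^p = 1` whose half-axes
#' shrink from base to tip by the power law
#' `A(z) = A0 * (tip_scale + (1 - tip_scale) * (1 - z/L)^w)`,
#' and analogously for the depth half-axis, so `width_taper_exponent` and
#' `depth_taper_exponent` control how blunt or pointed the bill is while
#' `tip_scale` sets the residual tip size as a fraction of the base.
#'
#' @param length axial extent in m (default 0.05, the common scaled length).
#' @param base_width full width of the outer shell at the base, m.
#' @param base_depth full depth of the outer shell at the base, m.
#' @param shell_thickness rhamphotheca layer thickness, m; must be less than
#'   half the smaller base dimension.
#' @param width_taper_exponent,depth_taper_exponent positive taper powers;
#'   1 is a straight (conical) taper, larger values give a blunter base and
#'   more pointed tip.
#' @param section_exponent superellipse exponent `p >= 2`; 2 is an ellipse,
#'   larger values approach a rounded rectangle.
#' @param tip_scale tip half-axes as a fraction of the base half-axes, in
#'   (0, 1]; 1 gives an untapered prismatic section.
#' @param species_label text label carried through to results tables.
#' @return an object of class `bill_spec`.
#' @examples
#' spec <- bill_spec(base_width = 0.016, base_depth = 0.020)
#' spec
#' @export
bill_spec <- function(length = 0.05,
                      base_width,
                      base_depth,
                      shell_thickness = 0.0015,
                      width_taper_exponent = 1,
                      depth_taper_exponent = 1,
                      section_exponent = 2,
                      tip_scale = 0.15,
                      species_label = "unnamed") {
  spec <- structure(
    list(length = length, base_width = base_width, base_depth = base_depth,
         shell_thickness = shell_thickness,
         width_taper_exponent = width_taper_exponent,
         depth_taper_exponent = depth_taper_exponent,
         section_exponent = section_exponent,
         tip_scale = tip_scale,
         species_label = as.character(species_label)),
    class = "bill_spec")
  validate_bill_spec(spec)
  spec
}

validate_bill_spec <- function(spec) {
  num <- c("length", "base_width", "base_depth", "shell_thickness",
           "width_taper_exponent", "depth_taper_exponent",
           "section_exponent", "tip_scale")
  for (f in num) {
    v <- spec[[f]]
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v))
      stop("bill_spec: field '", f, "' must be a single finite number")
  }
  if (spec$length <= 0) stop("bill_spec: length must be > 0")
  if (spec$base_width <= 0) stop("bill_spec: base_width must be > 0")
  if (spec$base_depth <= 0) stop("bill_spec: base_depth must be > 0")
  if (spec$shell_thickness <= 0)
    stop("bill_spec: shell_thickness must be > 0")
  if (spec$shell_thickness >= min(spec$base_width, spec$base_depth) / 2)
    stop("bill_spec: shell_thickness (", spec$shell_thickness,
         ") must be < min(base_width, base_depth)/2 = ",
         min(spec$base_width, spec$base_depth) / 2)
  if (spec$width_taper_exponent <= 0 || spec$depth_taper_exponent <= 0)
    stop("bill_spec: taper exponents must be > 0")
  if (spec$section_exponent < 2)
    stop("bill_spec: section_exponent must be >= 2")
  if (spec$tip_scale <= 0 || spec$tip_scale > 1)
    stop("bill_spec: tip_scale must be in (0, 1]")
  invisible(spec)
}

#' @export
print.bill_spec <- function(x, ...) {
  cat("bill_spec:", x$species_label, "\n")
  cat(sprintf("  length %.4g m, base %dx%d mm (width x depth), shell %.3g mm\n",
              x$length, round(1000 * x$base_width), round(1000 * x$base_depth),
              1000 * x$shell_thickness))
  cat(sprintf("  taper exponents w=%.3g d=%.3g, section p=%.3g, tip scale %.3g\n",
              x$width_taper_exponent, x$depth_taper_exponent,
              x$section_exponent, x$tip_scale))
  invisible(x)
}

# taper factor g(t) in (0,1], t = z/L in [0,1]
taper_factor <- function(t, exponent, tip_scale) {
  tip_scale + (1 - tip_scale) * (1 - t)^exponent
}

# outer and core half-axes of the cross-section at relative station t
section_half_axes <- function(spec, t) {
  A <- (spec$base_width / 2) * taper_factor(t, spec$width_taper_exponent,
                                            spec$tip_scale)
  B <- (spec$base_depth / 2) * taper_factor(t, spec$depth_taper_exponent,
                                            spec$tip_scale)
  # the core shrinks with the shell but never vanishes: near the tip the
  # rhamphotheca of real bills is effectively solid keratin
  Ain <- pmax(A - spec$shell_thickness, 0.2 * A)
  Bin <- pmax(B - spec$shell_thickness, 0.2 * B)
  list(A = A, B = B, Ain = Ain, Bin = Bin)
}

# superellipse boundary point factors for angle parameter th and exponent p
superellipse_cs <- function(th, p) {
  e <- 2 / p
  list(cx = sign(cos(th)) * abs(cos(th))^e,
       cy = sign(sin(th)) * abs(sin(th))^e)
}
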