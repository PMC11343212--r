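#' Structural parameters of the F-actin helical lattice
#'
#' The canonical actin filament is two right-handed long-pitch strands
#' wrapping around each other, equivalent to a single left-handed
#' short-pitch ("genetic") helix with a rise of 27.8 Angstrom and a twist
#' of -166.67 degrees per subunit. `lattice_params()` bundles these
#' together with the radial distance of the subunit centroid from the
#' helix axis and the number of subunits.
#'
#' @param rise helical rise per subunit, Angstrom (> 0).
#' @param twist signed helical twist per subunit, degrees (|twist| <= 180).
#' @param radius distance of each subunit centroid from the helix axis,
#'   Angstrom. The canonical structure does not pin this value; the default
#'   25 Angstrom approximates the protomer-centroid radius and is an
#'   assumption of the model.
#' @param n_subunits number of subunits (>= 1).
#' @return An object of class `lattice_params`.
#' @examples
#' p <- lattice_params(n_subunits = 100)
#' p$twist
#' @export
lattice_params <- function(rise = 27.8, twist = -166.67, radius = 25,
                           n_subunits = 100L) {
  if (!is.finite(rise) || rise <= 0) stop("rise must be finite and > 0")
  if (!is.finite(twist) || abs(twist) > 180) stop("|twist| must be <= 180")
  if (!is.finite(radius) || radius <= 0) stop("radius must be finite and > 0")
  n_subunits <- as.integer(n_subunits)
  if (is.na(n_subunits) || n_subunits < 1) stop("n_subunits must be >= 1")
  structure(list(rise = rise, twist = twist, radius = radius,
                 n_subunits = n_subunits),
            class = "lattice_params")
}

#' @export
print.lattice_params <- function(x, ...) {
  cat(sprintf(
    "F-actin lattice parameters: rise %.2f A, twist %.2f deg, radius %.1f A, %d subunits\n",
    x$rise, x$twist, x$radius, x$n_subunits))
  invisible(x)
}

#' Filament configuration: ordered subunit centroid positions
#'
#' A `filament_conf` is an n x 3 matrix of subunit-centroid positions in
#' nanometres, ordered along the genetic (short-pitch) helix with 0-based
#' subunit indices `0 .. n-1`. It is the common currency of the simulator
#' and all geometry measurements.
#'
#' @param positions numeric n x 3 matrix. Interpreted in the units named by
#'   `units` and stored in nm.
#' @param units `"nm"` (default) or `"angstrom"`.
#' @return A `filament_conf` object (n x 3 matrix in nm).
#' @export
filament_conf <- function(positions, units = c("nm", "angstrom")) {
  units <- match.arg(units)
  positions <- as.matrix(positions)
  if (ncol(positions) != 3) stop("positions must have 3 columns")
  storage.mode(positions) <- "double"
  if (!all(is.finite(positions))) stop("positions must be finite")
  if (units == "angstrom") positions <- positions / 10
  if (nrow(positions) > 1) {
    step <- sqrt(rowSums((positions[-1, , drop = FALSE] -
                          positions[-nrow(positions), , drop = FALSE])^2))
    if (any(step == 0)) stop("consecutive positions must not coincide")
  }
  dimnames(positions) <- list(NULL, c("x", "y", "z"))
  class(positions) <- c("filament_conf", "matrix", "array")
  positions
}

#' @export
print.filament_conf <- function(x, ...) {
  cat(sprintf("Filament configuration: %d subunits (nm)\n", nrow(x)))
  cat(sprintf("  extent: %.2f nm end to end\n",
              sqrt(sum((x[nrow(x), ] - x[1, ])^2))))
  invisible(x)
}

#' Coordinates of a filament configuration
#'
#' @param config a `filament_conf`.
#' @param units `"nm"` or `"angstrom"`.
#' @return plain numeric n x 3 matrix.
#' @export
conf_coords <- function(config, units = c("nm", "angstrom")) {
  units <- match.arg(units)
  m <- matrix(as.vector(config), nrow = nrow(config), ncol = 3,
              dimnames = list(NULL, c("x", "y", "z")))
  if (units == "angstrom") m <- m * 10
  m
}

#' Build the canonical F-actin lattice
#'
#' Places subunit i (0-based) at cylindrical coordinates
#' (r = radius, angle = i * twist, z = i * rise), so that every pair of
#' consecutive subunits is related by exactly the stated rise and twist
#' about the z axis.
#'
#' @param params a [lattice_params()] object.
#' @return a [filament_conf()] with `params$n_subunits` rows.
#' @examples
#' conf <- build_canonical_lattice(lattice_params(n_subunits = 5))
#' @export
build_canonical_lattice <- function(params) {
  stopifnot(inherits(params, "lattice_params"))
  i <- seq_len(params$n_subunits) - 1
  ang <- i * params$twist * pi / 180
  r_nm <- params$radius / 10
  pos <- cbind(x = r_nm * cos(ang),
               y = r_nm * sin(ang),
               z = i * params$rise / 10)
  conf <- filament_conf(pos, units = "nm")
  attr(conf, "lattice_params") <- params
  conf
}
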