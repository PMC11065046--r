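#' Dye linker specification
#'
#' Mechanical description of the carbon-chain linker tethering a dye:
#' `n_links` C-C bonds of length `bond_length` joined at the tetrahedral
#' `bond_angle`, each bond acting as a spring of constant
#' `single_bond_spring`.  The chain is treated as springs in series, so the
#' effective stiffness decreases with chain length while the reach grows.
#'
#' The default bond stiffness is the tabulated vibrational-frequency value
#' for a single C-C bond; its absolute unit does not propagate into the
#' simulator (spring relaxation rates are configured in 1/ns directly), so
#' it is carried as a plain number.
#'
#' @param n_links integer >= 1, number of C-C links in the chain.
#' @param bond_length C-C bond length, Angstrom.
#' @param bond_angle C-C-C bond angle, degrees, in (0, 180].
#' @param single_bond_spring spring constant of one C-C bond (force/length).
#' @return An object of class `linker_spec`.
#' @examples
#' sp <- linker_spec(n_links = 15)
#' effective_spring_constant(sp)
#' linker_contour_length(sp)
#' @export
linker_spec <- function(n_links = 15L, bond_length = 1.54,
                        bond_angle = 109.5, single_bond_spring = 1010) {
  if (!is.numeric(n_links) || length(n_links) != 1L || is.na(n_links) ||
      n_links < 1 || n_links != round(n_links))
    .stop_invalid("'n_links' must be a positive integer")
  .check_number(bond_length, "bond_length")
  .check_number(bond_angle, "bond_angle")
  if (bond_angle > 180) .stop_invalid("'bond_angle' must be in (0, 180] degrees")
  .check_number(single_bond_spring, "single_bond_spring")
  structure(list(n_links = as.integer(n_links), bond_length = bond_length,
                 bond_angle = bond_angle,
                 single_bond_spring = single_bond_spring),
            class = "linker_spec")
}

#' Effective spring constant of a linker chain
#'
#' N identical bond springs in series: `k_eff = k / N`.
#'
#' @param spec a [linker_spec()].
#' @return Effective spring constant, same unit as `single_bond_spring`.
#' @export
effective_spring_constant <- function(spec) {
  stopifnot(inherits(spec, "linker_spec"))
  spec$single_bond_spring / spec$n_links
}

#' Effective link length
#'
#' Length per link of the zig-zag chain projected onto its axis: by the law
#' of cosines across one C-C-C unit, `2L = sqrt(2 l^2 - 2 l^2 cos(theta))`,
#' i.e. `L = (l/2) sqrt(2 - 2 cos(theta))`.
#'
#' @param spec a [linker_spec()].
#' @return Effective per-link length, Angstrom.
#' @export
effective_link_length <- function(spec) {
  stopifnot(inherits(spec, "linker_spec"))
  th <- spec$bond_angle * pi / 180
  (spec$bond_length / 2) * sqrt(2 - 2 * cos(th))
}

#' Linker contour length
#'
#' Total reach of the chain, `n_links * effective_link_length`; used to set
#' the pendulum equilibrium radius and the accessible-volume scale.
#'
#' @param spec a [linker_spec()].
#' @return Contour length, Angstrom.
#' @export
linker_contour_length <- function(spec) {
  stopifnot(inherits(spec, "linker_spec"))
  spec$n_links * effective_link_length(spec)
}

#' @export
print.linker_spec <- function(x, ...) {
  cat(sprintf("Dye linker: %d C-C links, l = %.3g A, theta = %.4g deg\n",
              x$n_links, x$bond_length, x$bond_angle))
  cat(sprintf("  k_eff = %.4g (k = %.4g per bond), contour length = %.4g A\n",
              effective_spring_constant(x), x$single_bond_spring,
              linker_contour_length(x)))
  invisible(x)
}
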