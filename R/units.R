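#' Energy unit conversion
#'
#' Energies are carried in Hartree (atomic units) everywhere inside the
#' package; kcal/mol appears only at reporting boundaries. The conversion
#' factor is fixed at 627.5095 kcal/mol per Hartree and recorded in every
#' evaluation report so that reported numbers are always traceable to it.
#'
#' @param e energy in Hartree (any numeric shape).
#' @return energy in kcal/mol, same shape.
#' @examples
#' hartree_to_kcalmol(92e-4)  # 5.77
#' @export
hartree_to_kcalmol <- function(e) {
  stopifnot(is.numeric(e))
  e * .hartree_kcalmol
}

#' @rdname hartree_to_kcalmol
#' @export
kcalmol_to_hartree <- function(e) {
  stopifnot(is.numeric(e))
  e / .hartree_kcalmol
}

.hartree_kcalmol <- 627.5095

.deg2rad <- function(x) x * pi / 180
.rad2deg <- function(x) x * 180 / pi
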