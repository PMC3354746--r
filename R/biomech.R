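#' Neo-Hookean material definition
#'
#' Constructs a (nearly incompressible) neo-Hookean hyperelastic material
#' from its two constants: `C1` (kPa), equal to half the initial shear
#' modulus, and the incompressibility parameter `d` (1/kPa), related to the
#' initial bulk modulus by `K0 = 2/d`. When `d` is omitted it is chosen so
#' that `K0 = 1000 * mu0`, the usual numerical stand-in for an
#' incompressible soft tissue.
#'
#' @param C1 Material constant in kPa; `C1 = mu0 / 2`.
#' @param d Incompressibility parameter in 1/kPa; `K0 = 2 / d`.
#' @param name Optional label for the material.
#' @return Object of class `neo_hookean` with fields `C1`, `d`, and the
#'   derived `mu0 = 2 * C1` and `K0 = 2 / d`.
#' @seealso [material_from_shear()], [tissue_materials()], [strain_energy()]
#' @export
#' @examples
#' fat <- neo_hookean(C1 = 3)
#' fat$mu0  # 6 kPa
neo_hookean <- function(C1, d = NULL, name = NULL) {
  if (!is.numeric(C1) || length(C1) != 1L || !is.finite(C1) || C1 <= 0)
    stop("C1 must be a single positive number (kPa)")
  if (is.null(d)) d <- 2 / (1000 * 2 * C1)  # K0 = 1000 * mu0
  if (!is.numeric(d) || length(d) != 1L || !is.finite(d) || d <= 0)
    stop("d must be a single positive number (1/kPa)")
  structure(list(C1 = C1, d = d, mu0 = 2 * C1, K0 = 2 / d, name = name),
            class = "neo_hookean")
}

#' Build a neo-Hookean material from shear and bulk moduli
#'
#' @param mu0 Initial shear modulus (kPa), positive.
#' @param K0 Initial bulk modulus (kPa), positive.
#' @param name Optional label.
#' @return A [neo_hookean()] material with `C1 = mu0/2` and `d = 2/K0`.
#' @export
#' @examples
#' material_from_shear(6, 6000)$C1  # 3 kPa
material_from_shear <- function(mu0, K0, name = NULL) {
  if (!is.numeric(mu0) || length(mu0) != 1L || !is.finite(mu0) || mu0 <= 0)
    stop("mu0 must be a single positive number (kPa)")
  if (!is.numeric(K0) || length(K0) != 1L || !is.finite(K0) || K0 <= 0)
    stop("K0 must be a single positive number (kPa)")
  neo_hookean(C1 = mu0 / 2, d = 2 / K0, name = name)
}

#' @export
print.neo_hookean <- function(x, ...) {
  cat(sprintf("<neo_hookean>%s C1 = %g kPa, d = %g 1/kPa (mu0 = %g kPa, K0 = %g kPa)\n",
              if (is.null(x$name)) "" else paste0(" [", x$name, "]"),
              x$C1, x$d, x$mu0, x$K0))
  invisible(x)
}

#' Bundled breast tissue material presets
#'
#' Literature constants for the three breast tissues under a neo-Hookean
#' model: fat `C1 = 3` kPa, glandular (dense) tissue `C1 = 12` kPa, skin
#' `C1 = 50` kPa, each with `d` from the incompressible approximation
#' (`K0 = 1000 * mu0`).
#'
#' @return Named list of [neo_hookean()] materials: `fat`, `glandular`,
#'   `skin`.
#' @export
tissue_materials <- function() {
  list(fat = neo_hookean(3, name = "fat"),
       glandular = neo_hookean(12, name = "glandular"),
       skin = neo_hookean(50, name = "skin"))
}

#' Deformation state for hyperelastic energy evaluation
#'
#' @param I1bar First deviatoric strain invariant; dimensionless, `>= 3`
#'   with equality at the identity deformation.
#' @param J Determinant of the elastic deformation gradient (volume ratio);
#'   strictly positive, 1 for isochoric deformation.
#' @return Object of class `deformation_state`; both fields may be vectors
#'   of equal (or recyclable) length.
#' @export
deformation_state <- function(I1bar, J = 1) {
  if (!is.numeric(I1bar) || !is.numeric(J)) stop("I1bar and J must be numeric")
  if (any(!is.finite(I1bar)) || any(I1bar < 3 - 1e-9))
    stop("I1bar must be finite and >= 3")
  if (any(!is.finite(J)) || any(J <= 0))
    stop("J must be finite and > 0")
  structure(list(I1bar = pmax(I1bar, 3), J = J), class = "deformation_state")
}

#' Neo-Hookean strain-energy density
#'
#' Evaluates `W = C1 * (I1bar - 3) + (1/d) * (J - 1)^2` in kPa. The first
#' term penalises deviatoric (shape) change, the second volumetric change;
#' `W` is zero at the identity and non-negative for every valid state.
#'
#' @param material A [neo_hookean()] material.
#' @param state A [deformation_state()], or a numeric vector of `I1bar`
#'   values (then `J` supplies the volume ratios).
#' @param J Volume ratios when `state` is given as plain `I1bar` values.
#' @return Strain-energy density in kPa (vectorised over the state).
#' @export
#' @examples
#' skin <- tissue_materials()$skin
#' strain_energy(skin, deformation_state(I1bar = 3.2, J = 1))
strain_energy <- function(material, state, J = 1) {
  if (!inherits(material, "neo_hookean")) stop("material must be a neo_hookean")
  if (!inherits(state, "deformation_state")) state <- deformation_state(state, J)
  material$C1 * (state$I1bar - 3) + (1 / material$d) * (state$J - 1)^2
}

#' Invariants of an incompressible uniaxial stretch
#'
#' Convenience for tests and examples: for stretch `lambda` along one axis
#' with incompressible transverse contraction the deformation gradient is
#' `diag(lambda, lambda^-1/2, lambda^-1/2)`, giving `J = 1` and
#' `I1bar = lambda^2 + 2/lambda`.
#'
#' @param lambda Stretch ratio(s), positive.
#' @return A [deformation_state()].
#' @export
uniaxial_stretch <- function(lambda) {
  if (any(!is.finite(lambda)) || any(lambda <= 0)) stop("lambda must be > 0")
  deformation_state(I1bar = lambda^2 + 2 / lambda, J = rep(1, length(lambda)))
}

#' Committed error between paired plate reaction forces
#'
#' Relative difference, in percent, between the plate reaction force
#' computed with the real segmented skin and with a uniform 2D-membrane skin:
#' `|F_real - F_membrane| / F_real * 100`. Scale-invariant and zero when the
#' two forces agree.
#'
#' @param F_real Reaction force with segmented (real) skin, in N; positive.
#' @param F_membrane Reaction force with the 2D-membrane skin, in N.
#' @param digits Decimal places for the reported value (default 1, matching
#'   how such errors are usually tabulated); use `NULL` for no rounding.
#' @return Committed error in percent (vectorised).
#' @export
#' @examples
#' committed_error(30.745, 25.891)  # 15.8
committed_error <- function(F_real, F_membrane, digits = 1) {
  if (!is.numeric(F_real) || !is.numeric(F_membrane))
    stop("forces must be numeric")
  if (any(!is.finite(F_real)) || any(F_real <= 0))
    stop("F_real must be finite and > 0")
  if (any(!is.finite(F_membrane)))
    stop("F_membrane must be finite")
  err <- abs(F_real - F_membrane) / F_real * 100
  if (!is.null(digits)) err <- round(err, digits)
  err
}

#' Bundled compression-study reaction forces
#'
#' Plate reaction forces from seven simulated mammographic compressions of
#' patient-specific breast models, once with the segmented real skin and
#' once with the classical uniform 2D-membrane skin, together with the
#' breast compression ratio of each run and the tabulated committed error.
#' These forces are inputs for [committed_error()]; the compression
#' percentage is carried as metadata only.
#'
#' @return A data frame with columns `case`, `compression_pct`,
#'   `force_real_n`, `force_membrane_n`, `error_printed_pct`.
#' @export
#' @examples
#' tbl <- reaction_forces()
#' committed_error(tbl$force_real_n, tbl$force_membrane_n)
reaction_forces <- function() {
  path <- system.file("extdata", "reaction_forces.csv", package = "mammoskin",
                      mustWork = TRUE)
  read.csv(path)
}
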