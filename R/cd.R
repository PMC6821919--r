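#' @include timeresolved.R
NULL

#' Mean residue ellipticity
#'
#' Converts raw circular dichroism ellipticity \eqn{\theta} (mdeg) to mean
#' residue ellipticity
#' \deqn{[\theta] = \frac{\theta}{10 \cdot [P] \cdot l \cdot n}}
#' in deg cm\eqn{^2} dmol\eqn{^{-1}}, with the protein concentration
#' \eqn{[P]} in mol/L, path length \eqn{l} in cm and \eqn{n} the number of
#' residues (584 for rat serum albumin). Linear in \eqn{\theta}, so the
#' conversion is exactly invertible.
#'
#' @param thetaMdeg ellipticity, mdeg (vectorised).
#' @param proteinM protein concentration, mol/L (> 0).
#' @param pathCm cuvette path length, cm (> 0).
#' @param nResidues number of amino-acid residues (>= 1).
#' @return mean residue ellipticity, deg cm^2/dmol.
#' @examples
#' meanResidueEllipticity(100, 4e-6, 0.01, 584)
#' @export
meanResidueEllipticity <- function(thetaMdeg, proteinM, pathCm,
                                   nResidues = 584) {
  if (proteinM <= 0 || pathCm <= 0 || nResidues < 1)
    stop("protein concentration, path length and residue count must be positive")
  thetaMdeg / (10 * proteinM * pathCm * nResidues)
}

#' Locate negative CD band minima
#'
#' Finds local minima of a CD spectrum that lie below zero — for an
#' alpha-helical protein the diagnostic pair at 208 nm (pi-pi*) and 222 nm
#' (n-pi*). Grid endpoints only count when the curve turns back inside the
#' window; resolution is the grid spacing.
#'
#' @param cd a [Spectrum-class] of kind `"cd"`.
#' @return wavelengths (nm) of negative local minima; possibly empty.
#' @export
bandMinima <- function(cd) {
  stopifnot(is(cd, "Spectrum"))
  if (cd@kind != "cd") stop("expected a spectrum of kind 'cd'")
  v <- cd@values
  n <- length(v)
  isMin <- logical(n)
  for (i in seq(2L, n - 1L))
    isMin[i] <- v[i] < 0 && v[i] <= v[i - 1L] && v[i] <= v[i + 1L] &&
      (v[i] < v[i - 1L] || v[i] < v[i + 1L])
  cd@wavelength[isMin]
}
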