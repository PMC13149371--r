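# Single-shell dielectric model and Clausius-Mossotti factor.
#
# The DEP force on a cell is proportional to the real part of the
# Clausius-Mossotti (CM) factor,
#   CM = (eps*_p - eps*_m) / (eps*_p + 2 eps*_m),   eps* = eps - j sigma/omega,
# where eps*_p is the effective complex permittivity of the cell modelled as
# a conductive core (cytoplasm) wrapped in a thin membrane shell. Re[CM]
# changes sign at the crossover frequency f_co, where the direction of
# DEP-induced motion reverses.

.EPS0 <- 8.8541878128e-12  # vacuum permittivity, F/m

#' Single-shell cell dielectric model
#'
#' @param r_cell Cell radius in metres.
#' @param membrane_thickness Membrane shell thickness in metres; must be
#'   small relative to `r_cell`.
#' @param eps_mem,eps_cyto,eps_medium Relative permittivities of membrane,
#'   cytoplasm and suspending medium.
#' @param sigma_mem,sigma_cyto,sigma_medium Conductivities in S/m.
#' @param eta Medium viscosity in Pa s.
#'
#' @details The defaults describe a 19 um diameter breast-cancer-like cell in
#'   a low-conductivity sugar buffer (60 uS/cm), for which the model yields a
#'   single crossover near 22 kHz in the 1-41 kHz band.
#' @return An object of class `shell_model`.
#' @export
shell_model <- function(r_cell = 9.5e-6, membrane_thickness = 5e-9,
                        eps_mem = 3.2, eps_cyto = 60, eps_medium = 78,
                        sigma_mem = 1e-6, sigma_cyto = 0.4,
                        sigma_medium = 6e-3, eta = 1e-3) {
  vals <- c(r_cell, membrane_thickness, eps_mem, eps_cyto, eps_medium,
            sigma_mem, sigma_cyto, sigma_medium, eta)
  if (any(!is.finite(vals)) || any(vals <= 0)) {
    stop("all shell_model parameters must be positive and finite")
  }
  if (membrane_thickness >= r_cell / 10) {
    stop("membrane_thickness must be small relative to r_cell")
  }
  structure(list(r_cell = r_cell, membrane_thickness = membrane_thickness,
                 eps_mem = eps_mem, eps_cyto = eps_cyto,
                 eps_medium = eps_medium, sigma_mem = sigma_mem,
                 sigma_cyto = sigma_cyto, sigma_medium = sigma_medium,
                 eta = eta),
            class = "shell_model")
}

#' Real part of the single-shell Clausius-Mossotti factor
#'
#' @param model A [shell_model()].
#' @param f Frequency in Hz (vectorised, all > 0).
#' @return Numeric vector of Re\[CM\] values, bounded in \[-0.5, 1\].
#' @examples
#' m <- shell_model()
#' re_cm_single_shell(m, c(1e3, 41e3))
#' @export
re_cm_single_shell <- function(model, f) {
  stopifnot(inherits(model, "shell_model"))
  if (any(!is.finite(f)) || any(f <= 0)) stop("frequency must be > 0")
  w <- 2 * pi * f
  cplx <- function(eps, sig) complex(real = eps * .EPS0, imaginary = -sig / w)
  em <- cplx(model$eps_mem, model$sigma_mem)
  ec <- cplx(model$eps_cyto, model$sigma_cyto)
  emed <- cplx(model$eps_medium, model$sigma_medium)
  g3 <- (model$r_cell / (model$r_cell - model$membrane_thickness))^3
  K <- (ec - em) / (ec + 2 * em)
  ep <- em * (g3 + 2 * K) / (g3 - K)    # effective particle permittivity
  Re((ep - emed) / (ep + 2 * emed))
}

#' Crossover frequency of a shell model
#'
#' Lowest root of Re\[CM\](f) = 0 in the given band, found by bisection.
#'
#' @param model A [shell_model()].
#' @param interval Search band in Hz.
#' @return Frequency in Hz, or `NA` if Re\[CM\] does not change sign in the
#'   band.
#' @export
crossover_frequency <- function(model, interval = c(1e3, 1e7)) {
  fgrid <- exp(seq(log(interval[1]), log(interval[2]), length.out = 600))
  v <- re_cm_single_shell(model, fgrid)
  i <- which(diff(sign(v)) != 0)
  if (length(i) == 0) return(NA_real_)
  stats::uniroot(function(f) re_cm_single_shell(model, f),
                 c(fgrid[i[1]], fgrid[i[1] + 1]), tol = 1e-6)$root
}

#' Impose a target crossover frequency on a shell model
#'
#' Solves for the membrane permittivity that places the first zero of
#' Re\[CM\] at `fco`. Cell-to-cell variation in membrane capacitance is the
#' dominant biological source of crossover heterogeneity, so this is the
#' natural dial for generating populations with known per-cell `fco`.
#'
#' @param model Base [shell_model()].
#' @param fco Target crossover frequency in Hz.
#' @return A `shell_model` with adjusted `eps_mem`.
#' @export
shell_model_with_fco <- function(model = shell_model(), fco) {
  stopifnot(fco > 0)
  root <- stats::uniroot(function(e) {
    m <- model; m$eps_mem <- e
    re_cm_single_shell(m, fco)
  }, c(0.2, 80), tol = 1e-10)
  model$eps_mem <- root$root
  model
}
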