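#' Spine head volume from head width
#'
#' Default model treats the head as a sphere of diameter `head_width`:
#' `V = (pi/6) d^3`.
#'
#' @param head_width Head diameter, um (vectorized).
#' @param model `"sphere_from_head_width"` or `"user_supplied"` (in which
#'   case `volume` must be given).
#' @param volume User-supplied volume, um^3.
#' @return Volume in um^3.
#' @examples
#' head_volume(0.44)
#' @export
head_volume <- function(head_width, model = c("sphere_from_head_width",
                                              "user_supplied"),
                        volume = NULL) {
  model <- match.arg(model)
  if (model == "user_supplied") {
    stopifnot_positive(volume = volume)
    return(volume)
  }
  if (any(!is.finite(head_width)) || any(head_width <= 0))
    abort("`head_width` must be positive", class = "spinemorph_parameter_error")
  pi / 6 * head_width^3
}

#' Neck cross-sectional area from neck width
#'
#' Disc model: `A = (pi/4) w^2`.
#'
#' @param neck_width Neck diameter, um (vectorized).
#' @return Area in um^2.
#' @examples
#' neck_cross_section(0.2)
#' @export
neck_cross_section <- function(neck_width) {
  if (any(!is.finite(neck_width)) || any(neck_width <= 0))
    abort("`neck_width` must be positive", class = "spinemorph_parameter_error")
  pi / 4 * neck_width^2
}

#' Compartmentalization factor V L / A
#'
#' The diffusional compartmentalization of a spine: head volume times neck
#' length over neck cross-sectional area. Dividing by a cytosolic diffusion
#' coefficient D gives the time constant of diffusional recovery of the
#' head after a step change at the dendrite (see
#' [diffusion_time_constant()]).
#'
#' @param V Head volume, um^3.
#' @param L Neck length, um.
#' @param A Neck cross-sectional area, um^2.
#' @return Compartmentalization factor, um^2 (vectorized).
#' @examples
#' compartmentalization_factor(0.05, 0.2, 0.03)
#' @export
compartmentalization_factor <- function(V, L, A) {
  if (any(!is.finite(c(V, L, A))) || any(V <= 0) || any(L <= 0) || any(A <= 0))
    abort("V, L and A must all be positive",
          class = "spinemorph_parameter_error")
  V * L / A
}

#' Diffusional recovery time constant
#'
#' `tau = cf / D` for a molecule with diffusion coefficient `D`.
#'
#' @param cf Compartmentalization factor, um^2.
#' @param D Diffusion coefficient, um^2/s (0.45 is a typical small-dye
#'   cytosolic value; always user-overridable).
#' @return Time constant in seconds.
#' @examples
#' diffusion_time_constant(1.35, D = 0.45) # 3 s
#' @export
diffusion_time_constant <- function(cf, D) {
  if (any(!is.finite(c(cf, D))) || any(cf <= 0) || any(D <= 0))
    abort("`cf` and `D` must be positive", class = "spinemorph_parameter_error")
  cf / D
}

#' Add compartmentalization columns to a morphometry table
#'
#' Computes per-spine `V` (sphere model on `head_width`), `A` (disc model on
#' `neck_width`), the compartmentalization factor `cf = V * L / A` with
#' `L = neck_length`, and `tau = cf / D`. Rows with missing inputs get `NA`.
#'
#' @param morpho A tibble with `head_width`, `neck_length`, `neck_width`.
#' @param D Diffusion coefficient, um^2/s.
#' @return The input with `V`, `A`, `cf`, `tau` columns added.
#' @export
add_compartmentalization <- function(morpho, D = 0.45) {
  stopifnot_positive(D = D)
  ok <- complete.cases(morpho[, c("head_width", "neck_length", "neck_width")]) &
    morpho$head_width > 0 & morpho$neck_length > 0 & morpho$neck_width > 0
  out <- dplyr::mutate(morpho,
                       V = ifelse(ok, pi / 6 * .data$head_width^3, NA_real_),
                       A = ifelse(ok, pi / 4 * .data$neck_width^2, NA_real_),
                       cf = .data$V * .data$neck_length / .data$A,
                       tau = .data$cf / D)
  out
}

#' Simulate diffusional recovery of a spine head
#'
#' Numerical oracle for the `tau = V L / (A D)` interpretation: solves 1D
#' diffusion along the neck (explicit finite differences, at least 50 grid
#' cells) coupling a well-mixed head compartment (volume `V`, initial
#' concentration 0) to a fixed-concentration dendritic reservoir
#' (concentration 1), and returns the head concentration over time. In the
#' regime where the neck holds little volume relative to the head
#' (`A L / V` small), the recovery is exponential with time constant
#' `V L / (A D)` to good accuracy.
#'
#' @param V Head volume, um^3.
#' @param L Neck length, um.
#' @param A Neck cross-sectional area, um^2.
#' @param D Diffusion coefficient, um^2/s.
#' @param dt Time step, s; must satisfy `dt <= 0.2 dx^2 / D` (defaults to
#'   the bound).
#' @param t_end Simulated time, s; defaults to six analytic time constants.
#' @param n_cells Neck grid cells (minimum 50).
#' @param n_out Number of output samples.
#' @return A `recovery_curve` tibble (`time`, `concentration`) with the
#'   geometry, `D`, and `tau_analytic` as attributes.
#' @examples
#' rc <- simulate_diffusional_recovery(0.05, 0.5, 0.01, D = 0.5)
#' fit_exponential_tau(rc)$tau # ~ 5 s
#' @export
simulate_diffusional_recovery <- function(V, L, A, D = 0.45, dt = NULL,
                                          t_end = NULL, n_cells = 50L,
                                          n_out = 400L) {
  stopifnot_positive(V = V, L = L, A = A, D = D)
  n_cells <- max(50L, as.integer(n_cells))
  dx <- L / n_cells
  dt_max <- 0.2 * dx^2 / D
  if (is.null(dt)) dt <- dt_max
  if (dt > dt_max * (1 + 1e-12))
    abort(sprintf("dt = %.3g violates the stability bound 0.2 dx^2 / D = %.3g",
                  dt, dt_max), class = "spinemorph_configuration_error")
  tau <- V * L / (A * D)
  if (is.null(t_end)) t_end <- 6 * tau
  res <- cpp_diffusion_recovery(V, L, A, D, dt, t_end, n_cells, as.integer(n_out))
  out <- tibble::tibble(time = res$time, concentration = res$concentration)
  attr(out, "geometry") <- list(V = V, L = L, A = A)
  attr(out, "D") <- D
  attr(out, "tau_analytic") <- tau
  class(out) <- c("recovery_curve", class(out))
  out
}

#' Fit an exponential recovery time constant
#'
#' Least-squares fit of `1 - exp(-t / tau)` to a recovery curve.
#'
#' @param curve A `recovery_curve` (or data frame with `time` and
#'   `concentration`).
#' @return List with `tau` (s) and `rmse`.
#' @export
fit_exponential_tau <- function(curve) {
  t <- curve$time
  y <- curve$concentration
  if (length(t) < 5 || max(y) < 0.6)
    abort("curve too short to fit a time constant (span at least ~3 tau)",
          class = "spinemorph_fit_error")
  i0 <- which(y >= 1 - exp(-1))[1]
  tau0 <- if (is.na(i0)) max(t) / 3 else t[i0]
  fit <- tryCatch(
    minpack.lm::nlsLM(y ~ 1 - exp(-t / tau), start = list(tau = tau0),
                      lower = 1e-12),
    error = function(e) abort("exponential fit failed to converge",
                              class = "spinemorph_fit_error"))
  list(tau = unname(coef(fit)[["tau"]]),
       rmse = sqrt(mean(stats::residuals(fit)^2)))
}

#' Plot a diffusional recovery curve
#'
#' @param object A `recovery_curve`.
#' @param ... Ignored.
#' @return A ggplot with the simulated curve and the analytic exponential.
#' @export
autoplot.recovery_curve <- function(object, ...) {
  tau <- attr(object, "tau_analytic")
  df <- tibble::tibble(time = object$time,
                       simulated = object$concentration,
                       analytic = 1 - exp(-object$time / tau))
  df <- tidyr::pivot_longer(df, c("simulated", "analytic"),
                            names_to = "curve", values_to = "concentration")
  ggplot2::ggplot(df, ggplot2::aes(.data$time, .data$concentration,
                                   colour = .data$curve)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "time (s)", y = "head concentration (normalized)")
}
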