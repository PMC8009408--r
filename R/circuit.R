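#' Gene-expression capacity profile
#'
#' Position-dependent multiplier on all circuit synthesis rates,
#' \eqn{\phi(d) = K_\phi^{n_\phi} / (K_\phi^{n_\phi} + d^{n_\phi})}, where
#' \code{d} is the distance from the colony edge. Capacity is 1 at the edge
#' (actively growing cells with full biosynthetic capacity) and decays into
#' the interior; a small \code{K_phi} with a large \code{n_phi} gives a sharp
#' edge-confined profile, a small \code{n_phi} a gradual one with a long
#' interior tail.
#'
#' @param d distance(s) from the colony edge, >= 0 (vectorised).
#' @param cp a [circuit_params()] object.
#' @return Capacity value(s) in `[0, 1]`.
#' @examples
#' cp <- circuit_params()
#' expression_capacity(c(0, cp$K_phi, 0.5), cp)
#' @export
expression_capacity <- function(d, cp) {
  stopifnot(inherits(cp, "circuit_params"))
  if (any(d < 0)) stop("edge distance 'd' must be non-negative", call. = FALSE)
  1 / (1 + (d / cp$K_phi)^cp$n_phi)
}

#' Metabolic-burden growth multiplier
#'
#' Heterologous expression of T7 RNAP and lysozyme taxes the host: the local
#' division rate is multiplied by
#' \eqn{1 / (1 + (b(T+L))^{h_b})}, which is 1 with no burden (\code{b = 0}) or
#' no expression and decreases monotonically with total protein load.
#'
#' @param T7,L T7 RNAP and lysozyme concentrations, >= 0 (vectorised).
#' @param cp a [circuit_params()] object.
#' @return Multiplier(s) in `(0, 1]`.
#' @examples
#' burden_factor(1, 1, circuit_params(b = 0.5, h_b = 1))
#' @export
burden_factor <- function(T7, L, cp) {
  stopifnot(inherits(cp, "circuit_params"))
  load <- cp$b * (pmax(T7, 0) + pmax(L, 0))
  1 / (1 + load^cp$h_b)
}

#' Circuit state container
#'
#' Per-marker concentrations of free T7 RNAP (\code{T7}), free lysozyme
#' (\code{L}) and T7-lysozyme complex (\code{P}), plus the single global AHL
#' concentration \code{A} shared by all positions (AHL diffuses fast relative
#' to colony growth and is treated as well mixed over the habitat).
#'
#' @param T7,L,P numeric vectors of equal length (one entry per marker).
#' @param A single global AHL concentration, >= 0.
#' @return An object of class \code{"circuit_state"}.
#' @export
circuit_state <- function(T7, L = numeric(length(T7)),
                          P = numeric(length(T7)), A = 0) {
  m <- length(T7)
  if (length(L) != m || length(P) != m)
    stop("'T7', 'L' and 'P' must have equal length", call. = FALSE)
  if (any(c(T7, L, P, A) < 0))
    stop("concentrations must be non-negative", call. = FALSE)
  if (length(A) != 1L) stop("'A' must be a single global value", call. = FALSE)
  structure(list(T7 = as.numeric(T7), L = as.numeric(L), P = as.numeric(P),
                 A = as.numeric(A)), class = "circuit_state")
}

# Linear interpolation of per-marker values onto arbitrary radii; constant
# extrapolation beyond the outermost/innermost marker.
interp_markers <- function(r, vals, xout) {
  if (length(r) == 1L) return(rep(vals, length(xout)))
  stats::approx(r, vals, xout = xout, rule = 2, ties = "ordered")$y
}

# Trapezoid cumulative integral of y over x (both sorted); cum[1] = 0.
cumtrapz1 <- function(x, y) {
  nx <- length(x)
  if (nx < 2L) return(numeric(nx))
  c(0, cumsum(diff(x) * (y[-1L] + y[-nx]) / 2))
}

#' Time derivatives of the patterning circuit
#'
#' Per-marker circuit kinetics at edge distance \eqn{d_i = R - r_i} with
#' capacity \eqn{\phi(d_i)} and local dilution rate
#' \eqn{\lambda_i = v\,\sigma(r_i)\,\beta_i} (growth dilution equals the local
#' specific volumetric growth rate in a close-packed colony; \eqn{\beta} is
#' the burden factor):
#' \deqn{\dot T_i = \phi_i \alpha_T \frac{T_i^{h_T}}{K_T^{h_T}+T_i^{h_T}}
#'   \frac{1}{1+P_i/K_P} - k_{on} T_i L_i + k_{off} P_i - (d_T+\lambda_i) T_i}
#' \deqn{\dot L_i = \phi_i \alpha_L \frac{A^{h_A}}{K_A^{h_A}+A^{h_A}}
#'   - k_{on} T_i L_i + k_{off} P_i - (d_L+\lambda_i) L_i}
#' \deqn{\dot P_i = k_{on} T_i L_i - k_{off} P_i - (d_P+\lambda_i) P_i}
#' The global AHL pool integrates capacity-weighted T7 activity over the
#' colony and is diluted over the habitat disc of radius \code{R_domain}:
#' \deqn{\dot A = \frac{2\alpha_A}{R_{domain}^2}
#'   \int_0^{R} x\,\phi(R-x)\,T(x)\,dx - d_A A,}
#' with \eqn{T(x)} linearly interpolated between markers.
#'
#' @param state a [circuit_state()] (one entry per tracked radius).
#' @param colony a [colony_state()] with matching number of tracked radii.
#' @param cp a [circuit_params()] object.
#' @param p a [growth_params()] object (for the dilution rate).
#' @param n_quad number of quadrature nodes for the AHL synthesis integral.
#' @return A list with \code{dT7}, \code{dL}, \code{dP} (vectors) and
#'   \code{dA} (scalar).
#' @export
circuit_rhs <- function(state, colony, cp, p, n_quad = 201L) {
  stopifnot(inherits(state, "circuit_state"), inherits(colony, "colony_state"),
            inherits(cp, "circuit_params"), inherits(p, "growth_params"))
  if (length(state$T7) != length(colony$r))
    stop("circuit state and colony state disagree on the number of markers",
         call. = FALSE)
  d <- circuit_derivs(r = colony$r, T7 = state$T7, L = state$L, P = state$P,
                      A = state$A, R = colony$R, n = colony$n,
                      cp = cp, p = p, n_quad = n_quad)
  d[c("dT7", "dL", "dP", "dA")]
}

# Vectorised core of the circuit kinetics; also returns the burden factors
# and the per-marker division rates so the coupled RHS can reuse them.
# All synthesis terms carry the nutrient saturation factor n/(n + n*): gene
# expression needs the same resource the cells grow on, so the pattern
# freezes as the nutrient runs out instead of accumulating at the stalled
# colony edge.
circuit_derivs <- function(r, T7, L, P, A, R, n, cp, p, n_quad = 201L) {
  T7 <- pmax(T7, 0); L <- pmax(L, 0); P <- pmax(P, 0); A <- max(A, 0)
  d_edge <- pmax(R - r, 0)
  nfac <- if (n > 0) n / (n + p$n_star) else 0
  phi <- 1 / (1 + (d_edge / cp$K_phi)^cp$n_phi)
  beta <- burden_unsafe(T7, L, cp)
  sigma_loc <- p$sigma0 * nfac * edge_hill(d_edge, p)
  lambda <- p$v * sigma_loc * beta

  hillT <- T7^cp$h_T / (cp$K_T^cp$h_T + T7^cp$h_T)
  hillT[T7 == 0] <- 0
  hillA <- A^cp$h_A / (cp$K_A^cp$h_A + A^cp$h_A)
  bind <- cp$k_on * T7 * L
  unbind <- cp$k_off * P

  dT7 <- nfac * phi * cp$alpha_T * hillT / (1 + P / cp$K_P) - bind + unbind -
    (cp$d_T + lambda) * T7
  dL <- nfac * phi * cp$alpha_L * hillA - bind + unbind -
    (cp$d_L + lambda) * L
  dP <- bind - unbind - (cp$d_P + lambda) * P

  # colony-integrated, capacity-weighted T7 activity -> global AHL synthesis
  rc <- pmin(pmax(r, 0), R)
  xg <- sort(unique(c(seq(0, R, length.out = n_quad), rc)))
  Tg <- interp_markers(rc, T7, xg)
  phig <- 1 / (1 + ((R - xg) / cp$K_phi)^cp$n_phi)
  synth <- 2 * nfac * cp$alpha_A *
    cumtrapz1(xg, xg * phig * Tg)[length(xg)] / cp$R_domain^2
  dA <- synth - cp$d_A * A

  list(dT7 = dT7, dL = dL, dP = dP, dA = dA,
       beta = beta, sigma_loc = sigma_loc, phi = phi)
}

# burden without class checks / clamping (inputs pre-clamped)
burden_unsafe <- function(T7, L, cp) {
  if (cp$b == 0) return(rep(1, length(T7)))
  1 / (1 + (cp$b * (T7 + L))^cp$h_b)
}

#' Coupled growth + circuit derivatives
#'
#' Full right-hand side of the coupled model: growth derivatives as in
#' [growth_rhs()] but with the division rate multiplied pointwise by the
#' metabolic-burden factor \eqn{\beta(T, L)} (interpolated between markers
#' inside the division integrals), circuit derivatives as in [circuit_rhs()],
#' and nutrient consumption scaled by the habitat area
#' (\eqn{\tilde\sigma_n / R_{domain}^2}: the nutrient is the concentration in
#' a well-mixed habitat disc, so larger habitats hold proportionally more
#' nutrient and sustain proportionally larger colonies). With \code{b = 0} the
#' growth subsystem is exactly independent of the circuit.
#'
#' @inheritParams circuit_rhs
#' @return A list with \code{r_dot}, \code{R_dot}, \code{n_dot}, \code{dT7},
#'   \code{dL}, \code{dP}, \code{dA}.
#' @export
coupled_rhs <- function(state, colony, cp, p, n_quad = 201L) {
  stopifnot(inherits(state, "circuit_state"), inherits(colony, "colony_state"))
  d <- coupled_derivs(r = colony$r, T7 = state$T7, L = state$L, P = state$P,
                      A = state$A, R = colony$R, n = colony$n,
                      cp = cp, p = p, n_quad = n_quad)
  d[c("r_dot", "R_dot", "n_dot", "dT7", "dL", "dP", "dA")]
}

# Vectorised coupled core. Division integrals use a dense trapezoid grid whose
# nodes include every marker (the burden profile is piecewise linear between
# markers, so the composite rule is consistent with the interpolant).
coupled_derivs <- function(r, T7, L, P, A, R, n, cp, p, n_quad = 201L) {
  n <- max(n, 0)
  cd <- circuit_derivs(r, T7, L, P, A, R, n, cp, p, n_quad)

  m <- length(r)
  rc <- pmin(pmax(r, 0), R)
  xg <- sort(unique(c(seq(0, R, length.out = n_quad), rc)))
  if (n > 0) {
    sig_g <- p$sigma0 * (n / (n + p$n_star)) * edge_hill(R - xg, p)
    beta_g <- if (cp$b == 0) rep(1, length(xg)) else
      interp_markers(rc, cd$beta, xg)
    Jg <- cumtrapz1(xg, xg * sig_g * beta_g)
    J_at <- Jg[match(rc, xg)]
    J_R <- Jg[length(Jg)]
  } else {
    J_at <- numeric(m); J_R <- 0
  }
  r_dot <- ifelse(rc > 0, p$v * J_at / pmax(rc, .Machine$double.eps), 0)

  c(list(r_dot = as.numeric(r_dot),
         R_dot = p$v * J_R / R,
         n_dot = -(p$sigma_n_tilde / cp$R_domain^2) * J_R),
    cd[c("dT7", "dL", "dP", "dA")])
}
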