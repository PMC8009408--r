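#' Growth parameters for the repulsive-expansion model
#'
#' Bundles the parameters of the coarse-grained colony growth layer: the local
#' division rate is \eqn{\sigma(x,t) = \sigma_0 \, n/(n + n^*) \cdot
#' K_\sigma^{n_\sigma} / (K_\sigma^{n_\sigma} + (R - x)^{n_\sigma})}, i.e. it
#' saturates with the shared nutrient pool and decays with distance from the
#' colony edge, and the radial velocity of a tracked position \eqn{r} is
#' \eqn{\dot r = (v/r)\int_0^r x\,\sigma(x,t)\,dx}.
#'
#' All quantities are in dimensionless model units: lengths relative to a unit
#' habitat radius, time relative to the inverse maximal division rate scale.
#' \code{v} and \code{sigma_n_tilde} are lumped constants that absorb per-cell
#' volume, packing density and colony height.
#'
#' @param sigma0 maximal division rate (1/time), > 0.
#' @param n_star nutrient half-saturation constant, > 0.
#' @param K_sigma half-saturation distance from the colony edge for division
#'   (length), > 0; \code{Inf} is allowed and gives spatially uniform division
#'   (the closed-form exponential limit).
#' @param n_sigma Hill exponent of the edge-distance dependence, >= 1.
#' @param v volume-per-cell proportionality constant converting the division
#'   integral into radial velocity, > 0.
#' @param sigma_n_tilde lumped maximal nutrient-consumption constant, >= 0
#'   (0 switches consumption off).
#'
#' @return An object of class \code{"growth_params"} (a validated list).
#' @examples
#' p <- growth_params()
#' division_rate(0.5, R = 1, n = 1, p)
#' @seealso [division_rate()], [integrate_growth()], [colony_state()]
#' @export
growth_params <- function(sigma0 = 1, n_star = 0.5, K_sigma = 0.5,
                          n_sigma = 4, v = 1, sigma_n_tilde = 0.5) {
  p <- list(sigma0 = sigma0, n_star = n_star, K_sigma = K_sigma,
            n_sigma = n_sigma, v = v, sigma_n_tilde = sigma_n_tilde)
  for (nm in names(p)) {
    val <- p[[nm]]
    if (!is.numeric(val) || length(val) != 1L || is.na(val))
      stop("growth parameter '", nm, "' must be a single finite number",
           call. = FALSE)
  }
  chk_pos <- c("sigma0", "n_star", "v")
  for (nm in chk_pos)
    if (p[[nm]] <= 0 || !is.finite(p[[nm]]))
      stop("growth parameter '", nm, "' must be strictly positive and finite",
           call. = FALSE)
  if (p$K_sigma <= 0) # Inf permitted: uniform-division limit
    stop("growth parameter 'K_sigma' must be strictly positive", call. = FALSE)
  if (p$n_sigma < 1 || !is.finite(p$n_sigma))
    stop("growth parameter 'n_sigma' must be finite and >= 1", call. = FALSE)
  if (p$sigma_n_tilde < 0 || !is.finite(p$sigma_n_tilde))
    stop("growth parameter 'sigma_n_tilde' must be finite and >= 0",
         call. = FALSE)
  structure(p, class = "growth_params")
}

#' @export
print.growth_params <- function(x, ...) {
  cat("Repulsive-expansion growth parameters:\n")
  cat(sprintf("  sigma0 = %g, n* = %g, K_sigma = %g, n_sigma = %g\n",
              x$sigma0, x$n_star, x$K_sigma, x$n_sigma))
  cat(sprintf("  v = %g, sigma_n_tilde = %g\n", x$v, x$sigma_n_tilde))
  invisible(x)
}

#' Colony state of the growth layer
#'
#' The instantaneous state of a growing colony: time, colony radius \code{R},
#' shared nutrient concentration \code{n}, and an ordered set of tracked
#' (Lagrangian) radial positions \code{r}. Tracked positions mark material
#' points advected by the growth-induced velocity field; a marker at radius 0
#' stays at the center.
#'
#' @param R colony radius, > 0.
#' @param n nutrient concentration, >= 0.
#' @param r numeric vector of tracked radii in strictly increasing order,
#'   all in [0, R]. Defaults to 10 evenly spaced positions spanning [0, R].
#' @param t time stamp (default 0).
#' @return An object of class \code{"colony_state"}.
#' @examples
#' colony_state(R = 0.1, n = 1)
#' @export
colony_state <- function(R, n, r = seq(0, R, length.out = 10), t = 0) {
  if (!is.numeric(R) || length(R) != 1L || !is.finite(R) || R <= 0)
    stop("'R' must be a single positive number", call. = FALSE)
  if (!is.numeric(n) || length(n) != 1L || !is.finite(n) || n < 0)
    stop("'n' must be a single non-negative number", call. = FALSE)
  r <- as.numeric(r)
  if (length(r) < 1L || anyNA(r))
    stop("'r' must be a non-empty numeric vector", call. = FALSE)
  if (is.unsorted(r, strictly = TRUE))
    stop("tracked radii 'r' must be strictly increasing", call. = FALSE)
  if (r[1L] < 0 || r[length(r)] > R)
    stop("tracked radii must lie in [0, R]", call. = FALSE)
  structure(list(t = t, R = R, n = n, r = r), class = "colony_state")
}

#' @export
print.colony_state <- function(x, ...) {
  cat(sprintf("Colony state at t = %g: R = %g, n = %g, %d tracked radii\n",
              x$t, x$R, x$n, length(x$r)))
  invisible(x)
}

#' Gene-circuit parameters for the patterning layer
#'
#' Parameters of the synthetic patterning circuit layered on top of colony
#' growth: a self-activating T7 RNA polymerase (T) drives synthesis of the
#' quorum signal AHL (A, a single well-mixed global variable); above a
#' threshold, AHL induces T7 lysozyme (L), which binds T7 into an inactive
#' complex (P) that also represses T7 transcription. All synthesis rates are
#' scaled by a gene-expression capacity \eqn{\phi(d) = K_\phi^{n_\phi} /
#' (K_\phi^{n_\phi} + d^{n_\phi})} that is maximal at the colony edge
#' (edge distance \eqn{d = R - r}), and expression imposes a metabolic burden
#' \eqn{1/(1 + (b(T+L))^{h_b})} on the local division rate.
#'
#' Defaults are the package's calibrated high-burden / sharp-capacity regime
#' (the single-ring base case); see the packaged presets for the other
#' regimes.
#'
#' @param alpha_T,alpha_L,alpha_A maximal synthesis rates of T7 RNAP,
#'   lysozyme and AHL.
#' @param K_T,h_T T7 autoactivation half-saturation and Hill exponent.
#' @param K_P complex concentration halving T7 transcription.
#' @param K_A,h_A AHL threshold and Hill exponent for lysozyme induction.
#' @param k_on,k_off T7-lysozyme binding and unbinding rate constants.
#' @param d_T,d_L,d_P,d_A first-order decay rates (d_A = 0 switches AHL decay
#'   off, leaving only dilution-by-domain).
#' @param K_phi,n_phi gene-expression-capacity half-distance and Hill
#'   exponent.
#' @param b metabolic-burden strength (0 decouples growth from the circuit).
#' @param h_b burden Hill exponent, >= 1.
#' @param R_domain habitat (domain) radius; sets the AHL dilution area and the
#'   nutrient reservoir scale, >= initial colony radius.
#' @param A0 initial global AHL concentration, >= 0.
#' @return An object of class \code{"circuit_params"}.
#' @examples
#' cp <- circuit_params(b = 0)      # burden-free (decoupled) circuit
#' expression_capacity(0.1, cp)
#' @export
circuit_params <- function(alpha_T = 8, alpha_L = 6, alpha_A = 2,
                           K_T = 0.1, h_T = 2, K_P = 0.5,
                           K_A = 0.3, h_A = 10,
                           k_on = 3, k_off = 1,
                           d_T = 0.5, d_L = 0.05, d_P = 0.3, d_A = 0.2,
                           K_phi = 0.06, n_phi = 6,
                           b = 0.1, h_b = 2,
                           R_domain = 1, A0 = 0) {
  p <- list(alpha_T = alpha_T, alpha_L = alpha_L, alpha_A = alpha_A,
            K_T = K_T, h_T = h_T, K_P = K_P, K_A = K_A, h_A = h_A,
            k_on = k_on, k_off = k_off,
            d_T = d_T, d_L = d_L, d_P = d_P, d_A = d_A,
            K_phi = K_phi, n_phi = n_phi, b = b, h_b = h_b,
            R_domain = R_domain, A0 = A0)
  for (nm in names(p)) {
    val <- p[[nm]]
    if (!is.numeric(val) || length(val) != 1L || !is.finite(val))
      stop("circuit parameter '", nm, "' must be a single finite number",
           call. = FALSE)
    if (val < 0)
      stop("circuit parameter '", nm, "' must be non-negative", call. = FALSE)
  }
  for (nm in c("h_T", "h_A", "n_phi", "h_b"))
    if (p[[nm]] < 1)
      stop("Hill exponent '", nm, "' must be >= 1", call. = FALSE)
  for (nm in c("K_T", "K_P", "K_A", "K_phi", "R_domain"))
    if (p[[nm]] <= 0)
      stop("circuit parameter '", nm, "' must be strictly positive",
           call. = FALSE)
  structure(p, class = "circuit_params")
}

#' @export
print.circuit_params <- function(x, ...) {
  cat("Patterning circuit parameters:\n")
  cat(sprintf("  T7:   alpha_T = %g, K_T = %g, h_T = %g, K_P = %g\n",
              x$alpha_T, x$K_T, x$h_T, x$K_P))
  cat(sprintf("  Lys:  alpha_L = %g, K_A = %g, h_A = %g\n",
              x$alpha_L, x$K_A, x$h_A))
  cat(sprintf("  AHL:  alpha_A = %g, d_A = %g, A0 = %g, R_domain = %g\n",
              x$alpha_A, x$d_A, x$A0, x$R_domain))
  cat(sprintf("  bind: k_on = %g, k_off = %g; decay d_T/d_L/d_P = %g/%g/%g\n",
              x$k_on, x$k_off, x$d_T, x$d_L, x$d_P))
  cat(sprintf("  capacity: K_phi = %g, n_phi = %g; burden b = %g, h_b = %g\n",
              x$K_phi, x$n_phi, x$b, x$h_b))
  invisible(x)
}
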