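#' Local cell-division rate
#'
#' Evaluates the coarse-grained division rate
#' \deqn{\sigma(x,t) = \sigma_0 \frac{n}{n + n^*}
#'   \frac{K_\sigma^{n_\sigma}}{K_\sigma^{n_\sigma} + (R - x)^{n_\sigma}}}
#' at radial position(s) \code{x} inside a colony of radius \code{R} with
#' shared nutrient concentration \code{n}. Division is fastest at the colony
#' edge (where nutrients and oxygen reach the cells first) and shuts down with
#' nutrient exhaustion.
#'
#' @param x radial position(s), 0 <= x <= R (vectorised).
#' @param R colony radius.
#' @param n nutrient concentration, >= 0.
#' @param p a [growth_params()] object.
#' @return Division rate(s) in `[0, sigma0]`.
#' @examples
#' p <- growth_params()
#' division_rate(c(0, 0.5, 1), R = 1, n = 1, p)
#' @export
division_rate <- function(x, R, n, p) {
  stopifnot(inherits(p, "growth_params"))
  if (any(x < 0) || any(x > R + 1e-12))
    stop("radial position 'x' must lie in [0, R]", call. = FALSE)
  if (n < 0) stop("nutrient 'n' must be non-negative", call. = FALSE)
  p$sigma0 * (n / (n + p$n_star)) * edge_hill(R - pmin(x, R), p)
}

# Edge-distance Hill factor K^ns / (K^ns + d^ns); K = Inf => uniform division.
edge_hill <- function(d, p) {
  if (is.infinite(p$K_sigma)) return(rep(1, length(d)))
  # evaluate via (d/K)^ns to stay finite for large exponents
  1 / (1 + (d / p$K_sigma)^p$n_sigma)
}

#' Cumulative division integral
#'
#' Computes \eqn{\int_0^{r} x \, \sigma(x, t)\, dx}, the area-weighted
#' division activity inside radius \code{r}, which (times \code{v/r}) is the
#' radial velocity of a tracked position at \code{r}. Uses adaptive quadrature
#' (rel. tolerance 1e-9).
#'
#' @param r_upper upper integration limit, 0 <= r_upper <= R.
#' @param R colony radius.
#' @param n nutrient concentration.
#' @param p a [growth_params()] object.
#' @return The (non-negative) integral value.
#' @examples
#' p <- growth_params(K_sigma = Inf)           # uniform division
#' growth_integral(0.5, R = 1, n = 1, p)       # sigma * r^2 / 2
#' @export
growth_integral <- function(r_upper, R, n, p) {
  stopifnot(inherits(p, "growth_params"))
  if (r_upper < 0 || r_upper > R + 1e-12)
    stop("'r_upper' must lie in [0, R]", call. = FALSE)
  if (r_upper == 0 || n <= 0) return(0)
  nfac <- n / (n + p$n_star)
  f <- function(x) x * edge_hill(R - x, p)
  val <- tryCatch(
    stats::integrate(f, 0, min(r_upper, R), rel.tol = 1e-9, abs.tol = 1e-12,
                     subdivisions = 400L)$value,
    error = function(e)
      stop("quadrature of the division integral failed on [0, ",
           format(r_upper), "]: ", conditionMessage(e), call. = FALSE))
  p$sigma0 * nfac * val
}

# Cumulative division integrals at all sorted nodes (and at R), sharing work
# across one RHS evaluation: segment-wise adaptive quadrature of x * hill(R-x),
# scaled by sigma0 * n/(n+n*). Returns list(at_r =, at_R =).
growth_integral_nodes <- function(r, R, n, p) {
  nfac <- if (n > 0) n / (n + p$n_star) else 0
  if (nfac == 0) return(list(at_r = numeric(length(r)), at_R = 0))
  f <- function(x) x * edge_hill(R - x, p)
  nodes <- c(r[r > 0], R)
  nodes <- nodes[nodes <= R]
  bounds <- sort(unique(c(0, nodes)))
  seg <- numeric(length(bounds) - 1L)
  for (i in seq_along(seg)) {
    if (bounds[i + 1L] > bounds[i])
      seg[i] <- stats::integrate(f, bounds[i], bounds[i + 1L],
                                 rel.tol = 1e-9, abs.tol = 1e-12,
                                 subdivisions = 200L)$value
  }
  cum <- c(0, cumsum(seg))
  look <- function(x) cum[match(x, bounds)]
  at_r <- numeric(length(r))
  at_r[r > 0] <- look(r[r > 0])
  list(at_r = p$sigma0 * nfac * at_r,
       at_R = p$sigma0 * nfac * look(R))
}

#' Time derivatives of the growth layer
#'
#' Right-hand side of the repulsive-expansion ODE system: each tracked radius
#' moves with the growth-induced velocity field,
#' \eqn{\dot r_i = (v/r_i)\int_0^{r_i} x\sigma\,dx}, the colony front obeys
#' the same law at \eqn{r = R}, and the shared nutrient is consumed in
#' proportion to total division activity,
#' \eqn{\dot n = -\tilde\sigma_n \int_0^{R} x\sigma\,dx}. A marker at
#' \eqn{r = 0} has \eqn{\dot r = 0} (removable singularity: the integral
#' vanishes like \eqn{r^2}).
#'
#' @param state a [colony_state()].
#' @param p a [growth_params()] object.
#' @return A list with components \code{r_dot} (vector), \code{R_dot},
#'   \code{n_dot}.
#' @examples
#' growth_rhs(colony_state(R = 0.1, n = 1), growth_params())
#' @export
growth_rhs <- function(state, p) {
  stopifnot(inherits(state, "colony_state"), inherits(p, "growth_params"))
  gi <- growth_integral_nodes(state$r, state$R, state$n, p)
  r_dot <- ifelse(state$r > 0, p$v * gi$at_r / pmax(state$r, .Machine$double.eps),
                  0)
  list(r_dot = as.numeric(r_dot),
       R_dot = p$v * gi$at_R / state$R,
       n_dot = -p$sigma_n_tilde * gi$at_R)
}

#' Integrate colony growth
#'
#' Solves the growth layer forward in time from an initial [colony_state()].
#' The integration stops early (with a recorded event) once the nutrient falls
#' to a floor \code{n_floor_frac * n(0)} — the "nutrient exhausted" time at
#' which patterning outcomes are conventionally read out.
#'
#' Each tracked radius satisfies its own ODE given \code{(R, n)}, so marker
#' trajectories are independent of how many other markers are tracked.
#'
#' @param init a [colony_state()] at the initial time.
#' @param p a [growth_params()] object.
#' @param t_end end time (> \code{init$t}).
#' @param n_out number of equally spaced output times (>= 2).
#' @param rtol,atol solver tolerances (passed to [deSolve::lsodar()]).
#' @param n_floor_frac nutrient floor as a fraction of the initial nutrient;
#'   set 0 to disable the stopping event.
#' @return An object of class \code{"colony_sim"}: a list with \code{times},
#'   \code{R}, \code{n} (vectors), \code{r} (time x marker matrix),
#'   \code{exhausted} (logical), \code{t_exhausted} (time or NA), \code{params}
#'   and the initial state.
#' @examples
#' sim <- integrate_growth(colony_state(R = 0.1, n = 1), growth_params(),
#'                         t_end = 5, n_out = 21)
#' tail(sim$R, 1)
#' @export
integrate_growth <- function(init, p, t_end, n_out = 101L,
                             rtol = 1e-10, atol = 1e-12,
                             n_floor_frac = 1e-4) {
  stopifnot(inherits(init, "colony_state"), inherits(p, "growth_params"))
  if (t_end <= init$t) stop("'t_end' must exceed the initial time",
                            call. = FALSE)
  m <- length(init$r)
  y0 <- c(init$r, init$R, init$n)
  n_floor <- n_floor_frac * init$n
  times <- seq(init$t, t_end, length.out = max(2L, n_out))

  rhs <- function(t, y, parms) {
    r <- y[seq_len(m)]
    R <- y[m + 1L]
    n <- max(y[m + 2L], 0)
    gi <- growth_integral_nodes(pmin(r, R), R, n, p)
    r_dot <- ifelse(r > 0, p$v * gi$at_r / pmax(r, .Machine$double.eps), 0)
    list(c(r_dot, p$v * gi$at_R / R, -p$sigma_n_tilde * gi$at_R))
  }
  root <- function(t, y, parms) y[m + 2L] - n_floor

  sol <- if (n_floor_frac > 0 && p$sigma_n_tilde > 0) {
    deSolve::lsodar(y0, times, rhs, parms = NULL, rtol = rtol, atol = atol,
                    rootfunc = root)
  } else {
    deSolve::lsoda(y0, times, rhs, parms = NULL, rtol = rtol, atol = atol)
  }
  if (attr(sol, "istate")[1L] < 0)
    stop("growth integration failed; last valid time ",
         format(sol[nrow(sol), 1L]), call. = FALSE)

  troot <- attr(sol, "troot")
  exhausted <- !is.null(troot) && length(troot) > 0
  out <- list(times = sol[, 1L],
              r = unname(sol[, 1L + seq_len(m), drop = FALSE]),
              R = unname(sol[, m + 2L]),
              n = pmax(unname(sol[, m + 3L]), 0),
              exhausted = exhausted,
              t_exhausted = if (exhausted) troot[1L] else NA_real_,
              params = p, init = init)
  class(out) <- "colony_sim"
  out
}

#' @export
print.colony_sim <- function(x, ...) {
  cat(sprintf(
    "Colony growth run: t in [%g, %g], R: %g -> %g, n: %g -> %g (%d markers)\n",
    x$times[1], x$times[length(x$times)], x$R[1], x$R[length(x$R)],
    x$n[1], x$n[length(x$n)], ncol(x$r)))
  if (x$exhausted)
    cat(sprintf("  nutrient exhausted at t = %g\n", x$t_exhausted))
  invisible(x)
}

#' Tidy export of a growth run
#'
#' @param sim a \code{"colony_sim"} result from [integrate_growth()].
#' @return A long data.frame with columns \code{t}, \code{R}, \code{n},
#'   \code{marker_id}, \code{r}.
#' @export
growth_to_df <- function(sim) {
  stopifnot(inherits(sim, "colony_sim"))
  m <- ncol(sim$r)
  data.frame(t = rep(sim$times, m),
             R = rep(sim$R, m),
             n = rep(sim$n, m),
             marker_id = rep(seq_len(m), each = length(sim$times)),
             r = as.vector(sim$r))
}
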