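#' Simulate the coupled colony-growth + patterning-circuit model
#'
#' Integrates the full Lagrangian system: tracked radii advected by the
#' growth-induced velocity field, the colony front, the shared nutrient pool,
#' per-marker circuit species (T7 RNAP, lysozyme, T7-lysozyme complex) and
#' the global AHL pool. Markers are spawned at the advancing front per the
#' configured [spawn_policy()] so species fields cover the whole colony at
#' all times; integration stops at the nutrient-exhaustion event (the
#' conventional pattern read-out time) or at \code{t_end}.
#'
#' Internally the run is a sequence of [deSolve::lsodar()] legs separated by
#' root events (front-gap spawn triggers and the nutrient floor); a spawned
#' marker enters at \eqn{R(1-\delta)} with the circuit state interpolated
#' from existing markers.
#'
#' @param config a [run_config()] with a non-null \code{circuit} component.
#' @return An object of class \code{"pattern_sim"}: output \code{times} and
#'   vectors \code{R}, \code{n}, \code{A}; matrices \code{r}, \code{T7},
#'   \code{L}, \code{P} (time x marker, \code{NA} before a marker's birth);
#'   \code{markers} (birth records); \code{exhausted}, \code{t_exhausted};
#'   \code{final} (state at the stop time) and the \code{config}.
#' @examples
#' \donttest{
#' cfg <- run_config(preset = "fig4_low_burden")
#' sim <- simulate_pattern(cfg)
#' }
#' @export
simulate_pattern <- function(config) {
  stopifnot(inherits(config, "run_config"))
  if (is.null(config$circuit))
    stop("simulate_pattern() needs a circuit; use integrate_growth() for ",
         "growth-only runs", call. = FALSE)
  p <- config$growth
  cp <- config$circuit
  sv <- config$solver
  pol <- config$spawn
  init <- config$init
  if (cp$R_domain < init$R0)
    stop("R_domain must be at least the initial colony radius", call. = FALSE)

  # default markers span [0, R0] but stay strictly inside the front: a marker
  # exactly at R rides the front forever and would keep the spawn gap closed
  r0 <- if (!is.null(init$marker_radii)) as.numeric(init$marker_radii)
        else {
          rr <- seq(0, init$R0, length.out = init$n_markers)
          rr[init$n_markers] <- init$R0 * (1 - pol$delta)
          rr
        }
  m <- length(r0)
  n_floor <- sv$n_floor_frac * init$n0
  times_out <- seq(0, sv$t_end, length.out = config$output$n_times)

  pack <- function(r, T7, L, P, R, n, A) c(r, T7, L, P, R, n, A)
  y <- pack(r0, rep(init$T0, m), numeric(m), numeric(m),
            init$R0, init$n0, cp$A0)

  rhs <- function(t, y, parms) {
    mm <- parms$m
    r <- y[seq_len(mm)]
    T7 <- y[mm + seq_len(mm)]
    L <- y[2L * mm + seq_len(mm)]
    P <- y[3L * mm + seq_len(mm)]
    R <- y[4L * mm + 1L]
    n <- y[4L * mm + 2L]
    A <- y[4L * mm + 3L]
    d <- coupled_derivs(r, T7, L, P, A, R, n, cp, p, n_quad = sv$n_quad)
    list(c(d$r_dot, d$dT7, d$dL, d$dP, d$R_dot, d$n_dot, d$dA))
  }
  root <- function(t, y, parms) {
    mm <- parms$m
    R <- y[4L * mm + 1L]
    g <- y[4L * mm + 2L] - n_floor
    if (parms$spawn_on) {
      wg <- widest_gap(y[seq_len(mm)], R, pol$delta)
      c(g, wg$gap - pol$gap)
    } else g
  }

  rec_t <- numeric(0)
  rec_rows <- list()   # each: list(t, r, T7, L, P, R, n, A, ids)
  births <- data.frame(id = seq_len(m), birth_time = 0, birth_radius = r0)
  ids <- seq_len(m)
  next_id <- m + 1L
  t_cur <- 0
  exhausted <- FALSE
  t_exhausted <- NA_real_

  record <- function(t, y, mm, ids) {
    rec_rows[[length(rec_rows) + 1L]] <<- list(
      t = t, r = y[seq_len(mm)], T7 = y[mm + seq_len(mm)],
      L = y[2L * mm + seq_len(mm)], P = y[3L * mm + seq_len(mm)],
      R = y[4L * mm + 1L], n = y[4L * mm + 2L], A = y[4L * mm + 3L],
      ids = ids)
    rec_t <<- c(rec_t, t)
  }

  # insert a marker at the widest coverage gap, interpolating circuit state
  do_spawn <- function() {
    r <- y[seq_len(m)]
    T7 <- y[m + seq_len(m)]
    L <- y[2L * m + seq_len(m)]
    P <- y[3L * m + seq_len(m)]
    R <- y[4L * m + 1L]
    wg <- widest_gap(r, R, pol$delta)
    r_new <- wg$r_new
    j <- findInterval(r_new, r)
    ins <- function(vec, val) append(vec, val, after = j)
    y <<- pack(ins(r, r_new),
               ins(T7, interp_markers(r, T7, r_new)),
               ins(L, interp_markers(r, L, r_new)),
               ins(P, interp_markers(r, P, r_new)),
               R, y[4L * m + 2L], y[4L * m + 3L])
    births <<- rbind(births, data.frame(id = next_id, birth_time = t_cur,
                                        birth_radius = r_new))
    ids <<- append(ids, next_id, after = j)
    next_id <<- next_id + 1L
    m <<- m + 1L
  }

  densify <- function() {
    while (pol$enabled && m < pol$max_markers &&
           widest_gap(y[seq_len(m)], y[4L * m + 1L], pol$delta)$gap >
             pol$gap)
      do_spawn()
  }
  densify()          # coverage guarantee holds from the first stored state
  record(0, y, m, ids)

  repeat {
    # close any coverage gaps already above threshold before integrating
    # (root finding only sees sign *crossings*)
    densify()
    spawn_on <- pol$enabled && m < pol$max_markers
    tt <- c(t_cur, times_out[times_out > t_cur + 1e-12])
    if (length(tt) < 2L) break
    sol <- deSolve::lsodar(y, tt, rhs, parms = list(m = m, spawn_on = spawn_on),
                           rtol = sv$rtol, atol = sv$atol,
                           rootfunc = root, maxsteps = 50000L)
    if (attr(sol, "istate")[1L] < 0)
      stop("coupled integration failed near t = ",
           format(sol[nrow(sol), 1L]), call. = FALSE)
    nr <- nrow(sol)
    t_last <- sol[nr, 1L]
    # record interior output times (skip the duplicated chunk start)
    for (k in seq_len(nr)[-1L]) {
      tk <- sol[k, 1L]
      if (any(abs(times_out - tk) < 1e-9) && tk > t_cur + 1e-12)
        record(tk, sol[k, -1L], m, ids)
    }
    y <- sol[nr, -1L]
    t_cur <- t_last

    iroot <- attr(sol, "iroot")
    rooted <- t_last < tt[length(tt)] - 1e-12 && !is.null(iroot)
    if (rooted && iroot[1L] == 1L) {       # nutrient floor reached
      exhausted <- TRUE
      t_exhausted <- t_last
      if (!any(abs(rec_t - t_last) < 1e-9)) record(t_last, y, m, ids)
      break
    }
    if (rooted && length(iroot) > 1L && iroot[2L] == 1L) {  # spawn marker
      do_spawn()
      next
    }
    if (t_last >= sv$t_end - 1e-12) break
  }
  if (!exhausted && !any(abs(rec_t - t_cur) < 1e-9)) record(t_cur, y, m, ids)

  # assemble time x marker matrices (NA before birth)
  M <- next_id - 1L
  nt <- length(rec_rows)
  mk <- function() matrix(NA_real_, nt, M)
  r_m <- mk(); T_m <- mk(); L_m <- mk(); P_m <- mk()
  Rv <- numeric(nt); nv <- numeric(nt); Av <- numeric(nt)
  for (k in seq_len(nt)) {
    rw <- rec_rows[[k]]
    r_m[k, rw$ids] <- rw$r
    T_m[k, rw$ids] <- rw$T7
    L_m[k, rw$ids] <- rw$L
    P_m[k, rw$ids] <- rw$P
    Rv[k] <- rw$R; nv[k] <- max(rw$n, 0); Av[k] <- max(rw$A, 0)
  }
  fin <- rec_rows[[nt]]
  out <- list(times = rec_t, R = Rv, n = nv, A = Av,
              r = r_m, T7 = pmax(T_m, 0), L = pmax(L_m, 0), P = pmax(P_m, 0),
              markers = births, exhausted = exhausted,
              t_exhausted = t_exhausted,
              final = list(t = fin$t, r = fin$r, T7 = pmax(fin$T7, 0),
                           L = pmax(fin$L, 0), P = pmax(fin$P, 0),
                           R = fin$R, n = max(fin$n, 0), A = max(fin$A, 0)),
              config = config)
  class(out) <- "pattern_sim"
  out
}

#' @export
print.pattern_sim <- function(x, ...) {
  cat(sprintf(
    "Coupled patterning run: t in [%g, %g], R: %g -> %g, %d markers\n",
    x$times[1], x$times[length(x$times)], x$R[1], x$R[length(x$R)],
    nrow(x$markers)))
  cat(sprintf("  final A = %.4g, final n = %.4g%s\n",
              x$final$A, x$final$n,
              if (x$exhausted) sprintf(" (exhausted at t = %g)", x$t_exhausted)
              else ""))
  invisible(x)
}

#' Kymograph of a species over (edge distance, time)
#'
#' Interpolates per-marker concentrations of one species onto a uniform
#' distance-from-edge grid at every stored output time, the spatiotemporal
#' heatmap form in which ring and core dynamics are read.
#'
#' @param sim a \code{"pattern_sim"} from [simulate_pattern()].
#' @param species one of \code{"L"}, \code{"T7"}, \code{"P"}.
#' @param n_d number of grid points in edge distance.
#' @param d_max grid extent (default: the final colony radius).
#' @return A list of class \code{"kymograph"}: \code{t}, \code{d} (uniform
#'   grid), \code{R} (colony radius per time), \code{values}
#'   (time x distance matrix, \code{NA} beyond the colony center), and
#'   \code{species}.
#' @export
build_kymograph <- function(sim, species = c("L", "T7", "P"),
                            n_d = 161L, d_max = NULL) {
  stopifnot(inherits(sim, "pattern_sim"))
  species <- match.arg(species)
  vals <- sim[[species]]
  if (is.null(d_max)) d_max <- sim$R[length(sim$R)]
  d_grid <- seq(0, d_max, length.out = n_d)
  nt <- length(sim$times)
  mat <- matrix(NA_real_, nt, n_d)
  for (k in seq_len(nt)) {
    alive <- !is.na(sim$r[k, ])
    if (sum(alive) < 2L) next
    snap <- field_snapshot(sim$r[k, alive], vals[k, alive], sim$R[k],
                           d_grid = d_grid)
    mat[k, ] <- snap$value
  }
  structure(list(t = sim$times, d = d_grid, R = sim$R, values = mat,
                 species = species), class = "kymograph")
}

#' Long-form export of a kymograph
#'
#' @param kym a \code{"kymograph"} from [build_kymograph()].
#' @return A data.frame with columns \code{t}, \code{d}, \code{species},
#'   \code{value}.
#' @export
kymograph_to_df <- function(kym) {
  stopifnot(inherits(kym, "kymograph"))
  data.frame(t = rep(kym$t, length(kym$d)),
             d = rep(kym$d, each = length(kym$t)),
             species = kym$species,
             value = as.vector(kym$values))
}

#' Final radial profile of a species in edge-distance coordinates
#'
#' @param sim a \code{"pattern_sim"}.
#' @param species one of \code{"L"}, \code{"T7"}, \code{"P"}.
#' @param n_d grid resolution.
#' @return A data.frame with columns \code{d} and \code{value} on a uniform
#'   grid from the colony edge (d = 0) to the center (d = R).
#' @export
final_profile <- function(sim, species = c("L", "T7", "P"), n_d = 201L) {
  stopifnot(inherits(sim, "pattern_sim"))
  species <- match.arg(species)
  fin <- sim$final
  vals <- fin[[species]]
  field_snapshot(fin$r, vals, fin$R,
                 d_grid = seq(0, fin$R, length.out = n_d))
}
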