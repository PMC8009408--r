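#' Marker spawning policy
#'
#' Controls how new Lagrangian markers are inserted so that the marker
#' ensemble keeps covering the whole colony as it expands. Whenever the
#' widest relative gap — between adjacent markers, or between the outermost
#' marker and the front — exceeds \code{gap}, a new marker is inserted: at
#' \eqn{R(1-\delta)} just inside the front if the front gap is widest
#' (representing newly born edge cells), otherwise at the midpoint of the
#' widest interior gap. New markers inherit the circuit state linearly
#' interpolated (in radius) from the existing ensemble. Which gap opens first
#' depends on the regime: with strong metabolic burden the edge grows slowly
#' and holes open in the interior, while with edge-dominated growth the front
#' runs away from the outermost marker.
#'
#' @param gap relative gap (fraction of the colony radius) that triggers a
#'   spawn (default 0.02, keeping kymograph resolution roughly uniform as the
#'   colony grows).
#' @param delta relative placement offset inside the front (default 1e-3).
#' @param enabled logical; disable to integrate a fixed marker set only.
#' @param max_markers hard cap on the ensemble size.
#' @return An object of class \code{"spawn_policy"}.
#' @export
spawn_policy <- function(gap = 0.02, delta = 1e-3, enabled = TRUE,
                         max_markers = 400L) {
  if (gap <= 0 || gap >= 1) stop("'gap' must be in (0, 1)", call. = FALSE)
  if (delta <= 0 || delta >= gap)
    stop("'delta' must be in (0, gap)", call. = FALSE)
  structure(list(gap = gap, delta = delta, enabled = isTRUE(enabled),
                 max_markers = as.integer(max_markers)),
            class = "spawn_policy")
}

#' Marker bookkeeping table
#'
#' @param r current marker radii (strictly increasing).
#' @param birth_time,birth_radius per-marker birth records (defaults: all
#'   present since time 0 at their current radius).
#' @return A \code{"marker_set"}: a data.frame with columns \code{id},
#'   \code{birth_time}, \code{birth_radius}, \code{current_radius}.
#' @export
marker_set <- function(r, birth_time = rep(0, length(r)), birth_radius = r) {
  r <- as.numeric(r)
  if (is.unsorted(r, strictly = TRUE))
    stop("marker radii must be strictly increasing", call. = FALSE)
  structure(data.frame(id = seq_along(r), birth_time = birth_time,
                       birth_radius = birth_radius, current_radius = r),
            class = c("marker_set", "data.frame"))
}

# Widest relative coverage gap and the radius at which a marker would be
# inserted to close it. Gaps are measured between adjacent markers and
# between the outermost marker and the front, as fractions of R.
widest_gap <- function(r, R, delta) {
  gaps <- diff(c(r, R)) / R
  i <- which.max(gaps)
  r_new <- if (i == length(gaps)) R * (1 - delta)
           else (r[i] + r[i + 1L]) / 2
  list(gap = gaps[i], r_new = r_new, at_front = i == length(gaps))
}

#' Spawn markers where colony coverage demands it
#'
#' Inserts new markers while the widest relative coverage gap (see
#' [spawn_policy()]) exceeds the policy threshold. A static colony whose
#' markers already satisfy the coverage bound never triggers a spawn.
#'
#' @param markers a [marker_set()].
#' @param state a [colony_state()] giving the current front radius and time.
#' @param policy a [spawn_policy()].
#' @return The (possibly extended) [marker_set()], sorted by current radius.
#' @export
spawn_markers <- function(markers, state, policy) {
  stopifnot(inherits(markers, "marker_set"), inherits(state, "colony_state"),
            inherits(policy, "spawn_policy"))
  if (!policy$enabled) return(markers)
  R <- state$R
  while (nrow(markers) < policy$max_markers) {
    r <- sort(markers$current_radius)
    wg <- widest_gap(r, R, policy$delta)
    if (wg$gap < policy$gap || wg$r_new %in% r) break
    markers <- rbind(markers,
                     data.frame(id = max(markers$id) + 1L,
                                birth_time = state$t,
                                birth_radius = wg$r_new,
                                current_radius = wg$r_new))
  }
  markers <- markers[order(markers$current_radius), ]
  rownames(markers) <- NULL
  class(markers) <- c("marker_set", "data.frame")
  markers
}

#' Radial profile in edge-distance coordinates
#'
#' Converts per-marker values at radii \code{r} inside a colony of radius
#' \code{R} into a profile over distance from the colony edge
#' \eqn{d = R - r}, optionally interpolated onto a uniform \code{d} grid
#' (the form used to assemble kymographs; interpolation is linear and exact
#' at marker positions).
#'
#' @param r marker radii (>= 2 markers).
#' @param values per-marker values (same length as \code{r}).
#' @param R colony radius.
#' @param d_grid optional uniform grid of edge distances; values at grid
#'   points beyond the colony center (d > R) are \code{NA}.
#' @return A data.frame with columns \code{d} and \code{value}, sorted by
#'   increasing \code{d}.
#' @export
field_snapshot <- function(r, values, R, d_grid = NULL) {
  if (length(r) < 2L)
    stop("at least 2 markers are needed for a radial profile", call. = FALSE)
  if (length(values) != length(r))
    stop("'values' must match 'r' in length", call. = FALSE)
  d <- R - r
  ord <- order(d)
  if (is.null(d_grid))
    return(data.frame(d = d[ord], value = values[ord]))
  out <- stats::approx(d[ord], values[ord], xout = d_grid, rule = 2,
                       ties = "ordered")$y
  out[d_grid > R] <- NA_real_
  data.frame(d = d_grid, value = out)
}
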