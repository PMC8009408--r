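#' Detect rings and a central core in a radial profile
#'
#' Operationalises visual ring counting: rings are local maxima of the
#' profile over edge distance whose topographic prominence is at least
#' \code{prom_frac} of the profile maximum and whose height is at least
#' \code{floor_abs}; widths are measured as full width at half prominence
#' (robust on elevated baselines, where half maximum would be undefined). A
#' \emph{core} is a qualifying maximum whose half-prominence support reaches
#' the colony center (edge distance \eqn{d = R}); it is reported separately
#' and not counted as a ring.
#'
#' @param d uniform grid of distances from the colony edge (increasing).
#' @param values profile values on \code{d} (finite).
#' @param R colony radius (defaults to \code{max(d)}); the grid point nearest
#'   \code{d = R} is the colony center.
#' @param prom_frac relative prominence threshold (default 0.1 of the profile
#'   maximum).
#' @param floor_abs absolute height floor; default 1\% of the profile
#'   maximum. Pass the global species maximum over a whole run scaled by 0.01
#'   to share a floor across times.
#' @return A \code{"pattern_summary"}: list with \code{ring_count},
#'   \code{rings} (data.frame: \code{peak_d}, \code{height},
#'   \code{prominence}, \code{width}), \code{has_core}, \code{core}
#'   (one-row data.frame or NULL), and \code{R}.
#' @examples
#' d <- seq(0, 1, length.out = 201)
#' prof <- exp(-((d - 0.4) / 0.05)^2)     # one interior ring
#' detect_rings(d, prof)$ring_count
#' @export
detect_rings <- function(d, values, R = max(d), prom_frac = 0.1,
                         floor_abs = NULL) {
  if (length(d) < 3L || length(values) != length(d))
    stop("profile must have >= 3 points with matching grid", call. = FALSE)
  keep <- is.finite(values)
  d <- d[keep]; values <- values[keep]
  if (length(d) < 3L) stop("profile has too few finite values", call. = FALSE)
  vmax <- max(values)
  if (is.null(floor_abs)) floor_abs <- 0.01 * vmax
  pk <- find_peaks(values)
  if (nrow(pk)) {
    pk <- pk[pk$prominence >= prom_frac * vmax & pk$height >= floor_abs, ,
             drop = FALSE]
  }
  feats <- lapply(seq_len(nrow(pk)), function(i) {
    w <- peak_width(d, values, pk$idx[i], pk$prominence[i])
    data.frame(peak_d = d[pk$idx[i]], height = pk$height[i],
               prominence = pk$prominence[i], width = w$width,
               support_lo = w$lo, support_hi = w$hi)
  })
  feats <- if (length(feats)) do.call(rbind, feats) else
    data.frame(peak_d = numeric(0), height = numeric(0),
               prominence = numeric(0), width = numeric(0),
               support_lo = numeric(0), support_hi = numeric(0))
  # core: support reaches the colony center (within 2 grid cells)
  tol <- 2 * (d[2L] - d[1L])
  is_core <- feats$support_hi >= min(R, max(d)) - tol
  core <- feats[is_core, , drop = FALSE]
  rings <- feats[!is_core, , drop = FALSE]
  if (nrow(core) > 1L)   # keep the most prominent center feature
    core <- core[which.max(core$prominence), , drop = FALSE]
  rings <- rings[order(rings$peak_d), , drop = FALSE]
  rownames(rings) <- NULL
  structure(list(ring_count = nrow(rings),
                 rings = rings[, c("peak_d", "height", "prominence", "width")],
                 has_core = nrow(core) > 0L,
                 core = if (nrow(core)) core[, c("peak_d", "height",
                                                 "prominence", "width")],
                 R = R),
            class = "pattern_summary")
}

#' @export
print.pattern_summary <- function(x, ...) {
  cat(sprintf("Pattern summary: %d ring(s)%s\n", x$ring_count,
              if (x$has_core) " + central core" else ""))
  if (x$ring_count)
    for (i in seq_len(x$ring_count))
      cat(sprintf("  ring %d: edge distance %.4g, width %.4g\n",
                  i, x$rings$peak_d[i], x$rings$width[i]))
  if (x$has_core)
    cat(sprintf("  core: peak at edge distance %.4g, width %.4g\n",
                x$core$peak_d, x$core$width))
  invisible(x)
}

# Plateau-aware interior local maxima with topographic prominence.
# Boundary points qualify as peaks only at the center end (handled by the
# caller via support classification); prominence at a boundary uses the
# one-sided minimum.
find_peaks <- function(y) {
  n <- length(y)
  idx <- integer(0)
  i <- 2L
  while (i <= n - 1L) {
    if (y[i] > y[i - 1L]) {
      j <- i
      while (j < n && y[j + 1L] == y[j]) j <- j + 1L   # walk plateau
      if (j == n || y[j + 1L] < y[j]) idx <- c(idx, (i + j) %/% 2L)
      i <- j + 1L
    } else i <- i + 1L
  }
  # boundary maxima (monotone approach to either end)
  if (n >= 2L && y[1L] > y[2L]) idx <- c(1L, idx)
  if (n >= 2L && y[n] > y[n - 1L]) idx <- c(idx, n)
  if (!length(idx))
    return(data.frame(idx = integer(0), height = numeric(0),
                      prominence = numeric(0)))
  prom <- vapply(idx, function(k) peak_prominence(y, k), numeric(1))
  data.frame(idx = idx, height = y[idx], prominence = prom)
}

# Standard topographic prominence: on each side walk to the first point
# higher than the peak (or the end of the profile); the key saddle is the
# minimum over that stretch; prominence = height - max(left key, right key).
peak_prominence <- function(y, k) {
  n <- length(y)
  h <- y[k]
  left <- if (k == 1L) -Inf else {
    lo <- h
    key <- h
    for (i in (k - 1L):1L) {
      if (y[i] > h) break
      lo <- min(lo, y[i])
    }
    lo
  }
  right <- if (k == n) -Inf else {
    lo <- h
    for (i in (k + 1L):n) {
      if (y[i] > h) break
      lo <- min(lo, y[i])
    }
    lo
  }
  higher_left <- k > 1L && any(y[1:(k - 1L)] > h)
  higher_right <- k < n && any(y[(k + 1L):n] > h)
  base <- if (higher_left && higher_right) max(left, right)
          else if (higher_left) left
          else if (higher_right) right
          else min(left, right, na.rm = TRUE)
  if (!is.finite(base)) base <- min(y)
  h - base
}

# Full width at half prominence by linear interpolation of the crossings of
# level = height - prominence/2; the support interval [lo, hi] is clipped at
# the profile ends.
peak_width <- function(d, y, k, prom) {
  level <- y[k] - prom / 2
  n <- length(y)
  lo <- d[1L]
  if (k > 1L) for (i in (k - 1L):1L) {
    if (y[i] <= level) {
      lo <- d[i] + (d[i + 1L] - d[i]) * (level - y[i]) / (y[i + 1L] - y[i])
      break
    }
    if (i == 1L) lo <- d[1L]
  }
  hi <- d[n]
  if (k < n) for (i in (k + 1L):n) {
    if (y[i] <= level) {
      hi <- d[i - 1L] + (d[i] - d[i - 1L]) * (y[i - 1L] - level) /
        (y[i - 1L] - y[i])
      break
    }
    if (i == n) hi <- d[n]
  }
  list(width = hi - lo, lo = lo, hi = hi)
}

#' First-appearance times of ring and core features in a kymograph
#'
#' Scans the kymograph row by row (time by time) and records the first time
#' at which an interior ring, and the first time at which a central core,
#' satisfies the [detect_rings()] criterion. The relative order of these two
#' times distinguishes "ring-before-core" patterning (outer ring laid down
#' first, as at low division rates) from "core-before-ring" (strong central
#' accumulation first).
#'
#' @param kym a \code{"kymograph"} from [build_kymograph()], or a list with
#'   \code{t}, \code{d}, \code{R} (vector, per time) and \code{values}
#'   (time x distance matrix).
#' @param prom_frac,floor_frac detection thresholds; the absolute floor is
#'   \code{floor_frac} of the global maximum over the whole kymograph.
#' @param min_R_frac features are scored only once the colony radius exceeds
#'   this fraction of its maximum over the run: in a newborn colony a few
#'   cell diameters wide, "ring" and "core" are not yet meaningful spatial
#'   categories.
#' @param min_pts minimum number of finite profile points per scored row.
#' @return A list with \code{ring_time}, \code{core_time} (NA if the feature
#'   never appears) and \code{order} (one of \code{"ring_first"},
#'   \code{"core_first"}, \code{"simultaneous"}, \code{"ring_only"},
#'   \code{"core_only"}, \code{"none"}).
#' @export
emergence_order <- function(kym, prom_frac = 0.1, floor_frac = 0.01,
                            min_R_frac = 0.2, min_pts = 9L) {
  vmax <- max(kym$values, na.rm = TRUE)
  R_gate <- min_R_frac * max(kym$R)
  ring_time <- NA_real_
  core_time <- NA_real_
  for (k in seq_along(kym$t)) {
    if (kym$R[k] < R_gate) next
    row <- kym$values[k, ]
    ok <- is.finite(row)
    if (sum(ok) < min_pts) next
    ps <- detect_rings(kym$d[ok], row[ok], R = kym$R[k],
                       prom_frac = prom_frac, floor_abs = floor_frac * vmax)
    if (is.na(ring_time) && ps$ring_count > 0L) ring_time <- kym$t[k]
    if (is.na(core_time) && ps$has_core) core_time <- kym$t[k]
    if (!is.na(ring_time) && !is.na(core_time)) break
  }
  order <- if (is.na(ring_time) && is.na(core_time)) "none"
    else if (is.na(core_time)) "ring_only"
    else if (is.na(ring_time)) "core_only"
    else if (ring_time < core_time) "ring_first"
    else if (core_time < ring_time) "core_first"
    else "simultaneous"
  list(ring_time = ring_time, core_time = core_time, order = order)
}

#' Ordinary least-squares fits of colony radius and ring width vs domain
#' radius
#'
#' Fits \code{final_R ~ domain_radius} and \code{ring_width ~ domain_radius}
#' by OLS over the "moderate" sub-range of the sweep (extreme domain sizes
#' are excluded, where nutrient excess or confinement break the
#' proportionality).
#'
#' @param df data.frame with columns \code{domain_radius}, \code{final_R},
#'   \code{ring_width} (NA ring widths are dropped from the width fit).
#' @param moderate_frac central fraction of the swept domain-radius span used
#'   for the fits (default 0.6).
#' @return A list with \code{radius_fit} and \code{width_fit}, each holding
#'   \code{slope}, \code{intercept}, \code{r_squared}, \code{n}; plus
#'   \code{used} (the subset fitted).
#' @export
scale_fits <- function(df, moderate_frac = 0.6) {
  need <- c("domain_radius", "final_R", "ring_width")
  if (!all(need %in% names(df)))
    stop("data must have columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  span <- range(df$domain_radius)
  pad <- (1 - moderate_frac) / 2 * diff(span)
  lo <- span[1] + pad - 1e-9
  hi <- span[2] - pad + 1e-9
  use <- df[df$domain_radius >= lo & df$domain_radius <= hi, , drop = FALSE]
  fit1 <- function(y, x) {
    ok <- is.finite(y) & is.finite(x)
    if (sum(ok) < 3L)
      stop("need at least 3 points inside the moderate sub-range",
           call. = FALSE)
    fm <- stats::lm(y[ok] ~ x[ok])
    # exact linear inputs trigger a harmless "perfect fit" warning
    r2 <- suppressWarnings(summary(fm)$r.squared)
    list(slope = unname(stats::coef(fm)[2L]),
         intercept = unname(stats::coef(fm)[1L]),
         r_squared = r2,
         n = sum(ok))
  }
  list(radius_fit = fit1(use$final_R, use$domain_radius),
       width_fit = fit1(use$ring_width, use$domain_radius),
       used = use)
}

#' Scale-invariance sweep over habitat size
#'
#' Reruns the full coupled simulation for each domain (habitat) radius,
#' reads the final colony radius and the primary lysozyme ring width at
#' nutrient exhaustion, and fits both against the domain radius over the
#' moderate sub-range (see [scale_fits()]). Scale-invariant patterning shows
#' up as near-proportional growth of both quantities with habitat size.
#'
#' @param config a [run_config()] with a circuit; its \code{R_domain} is
#'   overridden per sweep member.
#' @param domain_radii numeric vector of >= 3 habitat radii.
#' @param moderate_frac passed to [scale_fits()].
#' @param species profile species for ring measurement (default lysozyme).
#' @return A list with \code{results} (data.frame: \code{domain_radius},
#'   \code{final_R}, \code{ring_width}, \code{ring_count}, \code{has_core},
#'   \code{t_end}, \code{status}), \code{fits} (from [scale_fits()], or NULL
#'   if too few successful runs) and \code{sims} (the member simulations).
#' @export
scale_invariance_sweep <- function(config, domain_radii,
                                   moderate_frac = 0.6, species = "L") {
  stopifnot(inherits(config, "run_config"))
  if (length(domain_radii) < 3L)
    stop("need at least 3 domain radii for a scale-invariance sweep",
         call. = FALSE)
  rows <- vector("list", length(domain_radii))
  sims <- vector("list", length(domain_radii))
  for (i in seq_along(domain_radii)) {
    Rd <- domain_radii[i]
    row <- data.frame(domain_radius = Rd, final_R = NA_real_,
                      ring_width = NA_real_, ring_count = NA_integer_,
                      has_core = NA, t_end = NA_real_, status = "ok")
    sim <- tryCatch(
      simulate_pattern(modify_config(config,
                                     circuit = list(R_domain = Rd))),
      error = function(e) e)
    if (inherits(sim, "error")) {
      row$status <- conditionMessage(sim)
    } else {
      sims[[i]] <- sim
      prof <- final_profile(sim, species = species,
                            n_d = config$output$n_dgrid)
      ps <- detect_rings(prof$d, prof$value, R = sim$final$R)
      row$final_R <- sim$final$R
      row$ring_count <- ps$ring_count
      row$has_core <- ps$has_core
      row$t_end <- sim$final$t
      if (ps$ring_count > 0L) {
        primary <- which.max(ps$rings$prominence)
        row$ring_width <- ps$rings$width[primary]
      } else if (ps$has_core) {
        row$ring_width <- ps$core$width
      }
    }
    rows[[i]] <- row
  }
  results <- do.call(rbind, rows)
  fits <- tryCatch(scale_fits(results, moderate_frac = moderate_frac),
                   error = function(e) NULL)
  list(results = results, fits = fits, sims = sims)
}
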