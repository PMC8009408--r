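#' Phase-plane trajectory of the isolated patterning circuit
#'
#' The coupled model separates into two layers: cell trajectories set by
#' growth, and gene-expression dynamics along each trajectory. This function
#' integrates the second layer in isolation — a single cell at full
#' expression capacity with a prescribed AHL input and no growth dilution —
#' which is the phase-plane view of the circuit: starting from a small T7
#' seed and no lysozyme, T7 RNAP autoactivates and rises; once AHL exceeds
#' its threshold, lysozyme accumulates, sequesters T7 into the inhibitory
#' complex and represses its transcription, so T7 peaks and declines while
#' lysozyme keeps increasing.
#'
#' @param cp a [circuit_params()] object.
#' @param A AHL input: a single constant, or a function of time.
#' @param t_end integration horizon.
#' @param T0,L0 initial free T7 RNAP and lysozyme.
#' @param phi expression capacity held fixed (default 1, the colony edge).
#' @param lambda growth-dilution rate held fixed (default 0: pure circuit
#'   kinetics).
#' @param n_out number of output samples.
#' @return A data.frame with columns \code{t}, \code{T7}, \code{L}, \code{P},
#'   \code{A}.
#' @examples
#' tr <- circuit_phase_plane(circuit_params(), A = 1, t_end = 20)
#' which.max(tr$T7)   # interior peak: T7 rises then falls
#' @export
circuit_phase_plane <- function(cp, A = 1, t_end = 30, T0 = 0.1, L0 = 0,
                                phi = 1, lambda = 0, n_out = 301L) {
  stopifnot(inherits(cp, "circuit_params"))
  A_fun <- if (is.function(A)) A else function(t) A
  rhs <- function(t, y, parms) {
    T7 <- max(y[1L], 0); L <- max(y[2L], 0); P <- max(y[3L], 0)
    At <- max(A_fun(t), 0)
    hillT <- if (T7 > 0) T7^cp$h_T / (cp$K_T^cp$h_T + T7^cp$h_T) else 0
    hillA <- At^cp$h_A / (cp$K_A^cp$h_A + At^cp$h_A)
    bind <- cp$k_on * T7 * L
    unbind <- cp$k_off * P
    list(c(phi * cp$alpha_T * hillT / (1 + P / cp$K_P) - bind + unbind -
             (cp$d_T + lambda) * T7,
           phi * cp$alpha_L * hillA - bind + unbind - (cp$d_L + lambda) * L,
           bind - unbind - (cp$d_P + lambda) * P))
  }
  times <- seq(0, t_end, length.out = n_out)
  sol <- deSolve::lsoda(c(T0, L0, 0), times, rhs, parms = NULL,
                        rtol = 1e-8, atol = 1e-10)
  data.frame(t = sol[, 1L], T7 = pmax(sol[, 2L], 0), L = pmax(sol[, 3L], 0),
             P = pmax(sol[, 4L], 0), A = vapply(sol[, 1L], A_fun, numeric(1)))
}
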