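#' Time-activity curve
#'
#' @param time_min sample times (mid-frame times for frame data), minutes,
#'   strictly increasing.
#' @param conc activity concentration, kBq/mL.
#' @param dur_min frame durations in minutes (NA for instantaneous samples).
#' @return data.frame of class `tac`.
#' @export
tac <- function(time_min, conc, dur_min = NA_real_) {
  time_min <- as.numeric(time_min); conc <- as.numeric(conc)
  if (length(time_min) != length(conc)) stop("lengths differ")
  if (any(diff(time_min) <= 0)) stop("times must be strictly increasing")
  structure(data.frame(time_min = time_min, conc = conc,
                       dur_min = rep_len(as.numeric(dur_min), length(conc))),
            class = c("tac", "data.frame"))
}

#' Simulated arterial plasma input function
#'
#' Sum-of-exponentials bolus model
#' \deqn{C_P(t) = (A_1 t - A_2 - A_3) e^{-\lambda_1 t} + A_2 e^{-\lambda_2 t} + A_3 e^{-\lambda_3 t}}
#' which is zero at injection, peaks within the first two minutes and then
#' decays monotonically.  Default coefficients give a typical bolus FDG-like
#' plasma curve (kBq/mL, minutes); concentrations are decay-corrected.
#'
#' @param times_min evaluation times, minutes, nondecreasing, >= 0.
#' @param params list with `A1` (kBq/mL/min), `A2`, `A3` (kBq/mL) and decay
#'   rates `lam1`, `lam2`, `lam3` (1/min).
#' @return a [tac].
#' @export
simulate_input_function <- function(times_min,
                                    params = list(A1 = 851.1, lam1 = 4.1339,
                                                  A2 = 21.88, lam2 = 0.01043,
                                                  A3 = 20.81, lam3 = 0.1191)) {
  t <- as.numeric(times_min)
  if (any(t < 0)) stop("times must be >= 0")
  if (any(diff(t) <= 0)) stop("times must be strictly increasing")
  p <- params
  cp <- (p$A1 * t - p$A2 - p$A3) * exp(-p$lam1 * t) +
    p$A2 * exp(-p$lam2 * t) + p$A3 * exp(-p$lam3 * t)
  tac(t, pmax(cp, 0))
}

#' Tissue time-activity curve from the two-tissue-compartment model
#'
#' Solves
#' \deqn{dC_1/dt = K_1 C_P - (k_2 + k_3) C_1 + k_4 C_2,\quad
#'       dC_2/dt = k_3 C_1 - k_4 C_2}
#' and returns \eqn{C_T = C_1 + C_2}.  The solution is computed analytically:
#' the model's bi-exponential impulse response is convolved with the input on
#' a fine time grid and interpolated at the requested times.  `k4 = 0` gives
#' the irreversible (FDG-like) model with Patlak macro-parameter
#' \eqn{K_i = K_1 k_3 / (k_2 + k_3)}; with `k4 > 0` the total distribution
#' volume is \eqn{V_T = (K_1/k_2)(1 + k_3/k_4)}.
#'
#' @param K1 delivery rate, mL/min/mL.
#' @param k2,k3,k4 rate constants, 1/min (all >= 0).
#' @param input_tac plasma input as a [tac] sampled at least as finely as
#'   `times_min` (it is linearly interpolated onto the internal fine grid).
#' @param times_min output times, minutes.
#' @param dt fine-grid step for the convolution, minutes.
#' @return a [tac] of \eqn{C_T} at `times_min`.
#' @export
simulate_tissue_tac <- function(K1, k2, k3, k4, input_tac, times_min,
                                dt = 0.01) {
  if (any(c(K1, k2, k3, k4) < 0)) stop("rate constants must be >= 0")
  t_out <- as.numeric(times_min)
  if (K1 == 0) return(tac(t_out, rep(0, length(t_out))))
  tmax <- max(t_out, input_tac$time_min)
  tg <- seq(0, tmax + dt, by = dt)
  ti <- input_tac$time_min; ci <- input_tac$conc
  if (ti[1] > 0) { ti <- c(0, ti); ci <- c(0, ci) }
  cp <- stats::approx(ti, ci, xout = tg, rule = 2)$y
  b <- k2 + k3 + k4
  disc <- sqrt(max(b * b - 4 * k2 * k4, 0))
  a1 <- (b - disc) / 2
  a2 <- (b + disc) / 2
  if (a2 - a1 > 1e-10) {
    h <- K1 / (a2 - a1) *
      ((k3 + k4 - a1) * exp(-a1 * tg) + (a2 - k3 - k4) * exp(-a2 * tg))
  } else {                       # repeated eigenvalue limit
    h <- K1 * exp(-a1 * tg) * (1 + (k3 + k4 - a1) * tg)
  }
  ct <- stats::convolve(cp, rev(h), type = "open")[seq_along(tg)] * dt
  tac(t_out, pmax(stats::approx(tg, ct, xout = t_out, rule = 2)$y, 0))
}

#' Integrate a time-activity curve over a window
#'
#' Trapezoidal integral of concentration over `[t0, t1]` minutes with linear
#' interpolation at the window edges and an implicit (0, 0) anchor before the
#' first sample.
#'
#' @param x a [tac].
#' @param t0_min,t1_min integration window, minutes (`t1 > t0`).
#' @return integral in kBq/mL * min.
#' @export
auc <- function(x, t0_min, t1_min) {
  if (t1_min <= t0_min) stop("t1 must be > t0")
  t <- c(0, x$time_min); y <- c(0, x$conc)
  if (x$time_min[1] == 0) { t <- x$time_min; y <- x$conc }
  if (t0_min < t[1] - 1e-9 || t1_min > t[length(t)] + 1e-9)
    stop("window outside TAC support")
  f <- stats::approxfun(t, y, rule = 2)
  knots <- t[t > t0_min & t < t1_min]
  tt <- c(t0_min, knots, t1_min)
  yy <- f(tt)
  sum(diff(tt) * (yy[-1] + yy[-length(yy)]) / 2)
}

# mean of a TAC over a frame window, by trapezoid / duration
frame_average <- function(x, t0_min, t1_min) {
  auc(x, t0_min, t1_min) / (t1_min - t0_min)
}
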