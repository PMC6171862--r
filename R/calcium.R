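#' Prescribed intracellular calcium transient
#'
#' Constructs the parametric description of the imposed intracellular
#' \eqn{[Ca^{2+}](t)} waveform that drives a simulated twitch. The waveform
#' is a two-exponential difference,
#' \deqn{Ca(t) = Ca_{dias} + \frac{Ca_{peak} - Ca_{dias}}{\beta}
#'   \left[e^{-(t - t_{start})/\tau_{decay}} -
#'         e^{-(t - t_{start})/\tau_{rise}}\right],}
#' with \eqn{\beta} the analytic maximum of the bracketed term, so that the
#' waveform attains exactly \code{ca_peak} at its peak. Before
#' \code{t_start} the concentration sits at the diastolic level.
#'
#' @param ca_diastolic diastolic (resting) concentration, uM.
#' @param ca_peak peak concentration, uM; must exceed \code{ca_diastolic}.
#' @param tau_rise rise time constant, s.
#' @param tau_decay decay time constant, s; must differ from
#'   \code{tau_rise}.
#' @param t_start stimulus onset time, s. The default of 0.05 s represents
#'   the electromechanical delay between stimulus and calcium release.
#' @return An object of class \code{calcium_transient}.
#' @examples
#' ct <- calcium_transient()
#' calcium_at(c(0, 0.1, 0.5), ct)
#' @export
calcium_transient <- function(ca_diastolic = 0.09, ca_peak = 1.45,
                              tau_rise = 0.02, tau_decay = 0.11,
                              t_start = 0.05) {
  stopifnot(is.numeric(ca_diastolic), is.numeric(ca_peak),
            is.numeric(tau_rise), is.numeric(tau_decay),
            is.numeric(t_start),
            length(ca_diastolic) == 1L, length(ca_peak) == 1L,
            length(tau_rise) == 1L, length(tau_decay) == 1L,
            length(t_start) == 1L)
  if (ca_diastolic < 0)
    stop("ca_diastolic must be >= 0", call. = FALSE)
  if (ca_peak <= ca_diastolic)
    stop("ca_peak must exceed ca_diastolic", call. = FALSE)
  if (tau_rise <= 0 || tau_decay <= 0)
    stop("time constants must be positive", call. = FALSE)
  if (tau_rise == tau_decay)
    stop("tau_rise and tau_decay must differ", call. = FALSE)
  if (t_start < 0)
    stop("t_start must be >= 0", call. = FALSE)
  structure(list(ca_diastolic = ca_diastolic, ca_peak = ca_peak,
                 tau_rise = tau_rise, tau_decay = tau_decay,
                 t_start = t_start),
            class = "calcium_transient")
}

# Analytic peak of exp(-t/tau_decay) - exp(-t/tau_rise): the maximum over
# t >= 0 sits at t* = log(tau_decay/tau_rise) * tau_rise*tau_decay /
# (tau_decay - tau_rise); beta is the value there.
ca_beta <- function(ct) {
  tr <- ct$tau_rise
  td <- ct$tau_decay
  tstar <- log(td / tr) * tr * td / (td - tr)
  exp(-tstar / td) - exp(-tstar / tr)
}

#' Time of the calcium-transient peak
#'
#' @param ct a \code{\link{calcium_transient}}.
#' @return Time of the waveform maximum, s (closed form).
#' @export
calcium_peak_time <- function(ct) {
  stopifnot(inherits(ct, "calcium_transient"))
  tr <- ct$tau_rise
  td <- ct$tau_decay
  ct$t_start + log(td / tr) * tr * td / (td - tr)
}

#' Evaluate the calcium transient
#'
#' Vectorised over \code{t}. Returns the diastolic level for
#' \code{t <= t_start} and the normalized two-exponential waveform
#' afterwards; continuous in \code{t}, never below the diastolic level,
#' and decaying back to it as \code{t} grows.
#'
#' @param t time(s), s; non-negative.
#' @param ct a \code{\link{calcium_transient}}.
#' @return Concentration(s), uM.
#' @export
calcium_at <- function(t, ct) {
  stopifnot(inherits(ct, "calcium_transient"), is.numeric(t))
  if (any(t < 0)) stop("t must be >= 0", call. = FALSE)
  tt <- t - ct$t_start
  wave <- ifelse(tt > 0,
                 exp(-tt / ct$tau_decay) - exp(-tt / ct$tau_rise),
                 0)
  ct$ca_diastolic + (ct$ca_peak - ct$ca_diastolic) * wave / ca_beta(ct)
}

#' Rescale the calcium-transient amplitude
#'
#' Returns a transient whose peak-above-diastolic amplitude is
#' \code{fraction} times the original, with the diastolic level, time
#' constants and onset unchanged — the waveform shape (and in particular
#' its peak time) is preserved.
#'
#' @param ct a \code{\link{calcium_transient}}.
#' @param fraction amplitude scaling factor, in (0, 1].
#' @return A new \code{calcium_transient}.
#' @export
scale_amplitude <- function(ct, fraction) {
  stopifnot(inherits(ct, "calcium_transient"),
            is.numeric(fraction), length(fraction) == 1L)
  if (fraction <= 0) stop("fraction must be positive", call. = FALSE)
  if (fraction > 1) stop("fraction must be <= 1", call. = FALSE)
  calcium_transient(
    ca_diastolic = ct$ca_diastolic,
    ca_peak = ct$ca_diastolic + fraction * (ct$ca_peak - ct$ca_diastolic),
    tau_rise = ct$tau_rise, tau_decay = ct$tau_decay,
    t_start = ct$t_start)
}

#' @export
print.calcium_transient <- function(x, ...) {
  cat("Prescribed calcium transient\n")
  cat(sprintf("  diastolic %.3g uM, peak %.3g uM\n",
              x$ca_diastolic, x$ca_peak))
  cat(sprintf("  tau_rise %.3g s, tau_decay %.3g s, onset %.3g s\n",
              x$tau_rise, x$tau_decay, x$t_start))
  invisible(x)
}
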