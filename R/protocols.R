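#' Twitch metrics: peak tension and time to 50% relaxation
#'
#' Peak tension is the trace maximum; \code{t_r50} is the duration from
#' the peak until tension first falls to 50\% of the peak, located by
#' linear interpolation between adjacent time samples (so the value is
#' insensitive to the output sampling grid). Resting tension in the model
#' is essentially zero, so 50\%-of-peak and 50\%-of-amplitude coincide.
#'
#' @param r a \code{twitch_result} from \code{\link{simulate_twitch}}, or
#'   any list with numeric fields \code{t} and \code{tension} (optionally
#'   \code{l_sarc}, \code{ct}).
#' @return An object of class \code{twitch_metrics}: \code{peak_tension}
#'   (kPa), \code{t_peak} (s), \code{t_r50} (s), \code{l_sarc} (um),
#'   \code{ca_peak} (uM).
#' @export
compute_metrics <- function(r) {
  t <- r$t
  s <- r$tension
  stopifnot(is.numeric(t), is.numeric(s), length(t) == length(s),
            length(t) >= 3L)
  i <- which.max(s)
  peak <- s[i]
  if (peak <= 0) stop("trace has no positive peak", call. = FALSE)
  after <- seq_along(s) > i
  j <- which(after & s <= peak / 2)
  if (length(j) == 0L)
    stop("tension never falls to 50% of peak within the trace; ",
         "re-simulate with a longer t_end", call. = FALSE)
  j <- j[1L]
  t50 <- t[j - 1L] + (t[j] - t[j - 1L]) *
    (peak / 2 - s[j - 1L]) / (s[j] - s[j - 1L])
  structure(list(peak_tension = peak, t_peak = t[i], t_r50 = t50 - t[i],
                 l_sarc = if (is.null(r$l_sarc)) NA_real_ else r$l_sarc,
                 ca_peak = if (is.null(r$ct)) NA_real_ else r$ct$ca_peak),
            class = "twitch_metrics")
}

#' @export
print.twitch_metrics <- function(x, ...) {
  cat(sprintf(
    "Twitch metrics: peak %.4g kPa at %.4g s, t_R50 = %.4g s\n",
    x$peak_tension, x$t_peak, x$t_r50))
  invisible(x)
}

sweep_table <- function(rows, kind, key) {
  df <- do.call(rbind, lapply(rows, function(m)
    data.frame(peak_tension = m$peak_tension, t_peak = m$t_peak,
               t_r50 = m$t_r50, l_sarc = m$l_sarc, ca_peak = m$ca_peak)))
  df <- cbind(df[key], df[setdiff(names(df), key)])
  structure(df, sweep_kind = kind,
            class = c("sweep_table", "data.frame"))
}

#' Sarcomere-length sweep protocol
#'
#' Simulates one isometric twitch per sarcomere length with an identical
#' calcium transient and collects the twitch metrics. The default grid of
#' 7 lengths from 1.90 to 2.20 um (0.05 um spacing) with a 1.45 uM peak
#' transient is the model's reference protocol: peak tension rises close
#' to linearly with length, and relaxation slows as the peak tension
#' grows.
#'
#' @param p a \code{\link{model_parameters}}.
#' @param lengths sarcomere lengths, um, strictly increasing.
#' @param ct a \code{\link{calcium_transient}}.
#' @param ... further arguments to \code{\link{simulate_twitch}}.
#' @return A \code{sweep_table} data frame, one row of metrics per
#'   length.
#' @export
length_sweep <- function(p, lengths = seq(1.90, 2.20, by = 0.05),
                         ct = calcium_transient(), ...) {
  stopifnot(length(lengths) >= 1L, !is.unsorted(lengths, strictly = TRUE))
  rows <- lapply(lengths, function(ls)
    compute_metrics(simulate_twitch(p, ls, ct, ...)))
  sweep_table(rows, "length", "l_sarc")
}

#' Calcium-amplitude sweep protocol
#'
#' Holds the sarcomere length fixed and rescales the calcium-transient
#' amplitude (above diastolic) stepwise, keeping the rise and decay time
#' constants unchanged, to separate the effect of peak tension from that
#' of length-dependent calcium affinity. Default: l_sarc 2.2 um,
#' fractions 60\%-100\% in 10\% steps.
#'
#' @param p a \code{\link{model_parameters}}.
#' @param l_sarc fixed sarcomere length, um.
#' @param ct the full-amplitude \code{\link{calcium_transient}}.
#' @param fractions amplitude fractions in (0, 1], strictly increasing.
#' @param ... further arguments to \code{\link{simulate_twitch}}.
#' @return A \code{sweep_table} data frame, one row of metrics per
#'   fraction (with the scaled \code{ca_peak}).
#' @export
calcium_sweep <- function(p, l_sarc = 2.2, ct = calcium_transient(),
                          fractions = seq(0.6, 1.0, by = 0.1), ...) {
  stopifnot(length(fractions) >= 1L,
            !is.unsorted(fractions, strictly = TRUE))
  rows <- lapply(fractions, function(f)
    compute_metrics(simulate_twitch(p, l_sarc, scale_amplitude(ct, f),
                                    ...)))
  tab <- sweep_table(rows, "calcium", "ca_peak")
  tab$fraction <- fractions
  tab
}

#' @export
print.sweep_table <- function(x, ...) {
  cat(sprintf("Twitch sweep (%s), %d conditions\n",
              attr(x, "sweep_kind"), nrow(x)))
  print.data.frame(x, row.names = FALSE, digits = 4)
  invisible(x)
}
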