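#' Tension trace container
#'
#' A uniformly sampled isometric tension trace at a known sarcomere
#' length — the unit of data shared by the experiment-style file reader
#' and the synthetic-trace generator. Experiment-style traces are
#' nominally sampled every 0.02 s.
#'
#' @param t time samples, s; strictly increasing.
#' @param s tension samples, kPa; non-negative.
#' @param l_sarc sarcomere length of the preparation, um.
#' @return An object of class \code{tension_trace}.
#' @export
tension_trace <- function(t, s, l_sarc) {
  stopifnot(is.numeric(t), is.numeric(s), length(t) == length(s),
            length(t) >= 2L, is.numeric(l_sarc), length(l_sarc) == 1L)
  if (is.unsorted(t, strictly = TRUE))
    stop("time samples must be strictly increasing", call. = FALSE)
  if (any(s < 0)) stop("tension must be non-negative", call. = FALSE)
  structure(list(t = as.numeric(t), s = as.numeric(s),
                 l_sarc = as.numeric(l_sarc)),
            class = "tension_trace")
}

#' @export
print.tension_trace <- function(x, ...) {
  cat(sprintf(
    "Tension trace: %d samples over [%.3g, %.3g] s at l_sarc %.3g um (peak %.4g kPa)\n",
    length(x$t), min(x$t), max(x$t), x$l_sarc, max(x$s)))
  invisible(x)
}

# Simulate model tension at the time points of each trace. One twitch per
# distinct sarcomere length; model tension is linearly interpolated onto
# the trace's time base.
model_tension_at <- function(candidate, fixed, traces, ct, sim_opts) {
  p <- model_parameters(a = candidate[["a"]], b = candidate[["b"]],
                        n = fixed$n, c_s = candidate[["c_s"]],
                        c_f = candidate[["c_f"]], f_da = fixed$f_da,
                        f_ad = fixed$f_ad)
  lengths <- vapply(traces, `[[`, numeric(1), "l_sarc")
  uniq <- unique(lengths)
  sims <- lapply(uniq, function(ls) {
    t_end <- max(vapply(traces[lengths == ls], function(tr) max(tr$t),
                        numeric(1)))
    suppressWarnings(do.call(simulate_twitch,
                             c(list(p = p, l_sarc = ls, ct = ct,
                                    t_end = t_end), sim_opts)))
  })
  names(sims) <- as.character(uniq)
  lapply(traces, function(tr) {
    tw <- sims[[as.character(tr$l_sarc)]]
    stats::approx(tw$t, tw$tension, xout = tr$t, rule = 2)$y
  })
}

#' Mean-squared-error objective for parameter estimation
#'
#' Simulates a twitch per trace's sarcomere length under the candidate
#' mechano-chemical parameters, samples model tension at each trace's
#' time points, and returns the squared differences pooled over all
#' points of all traces, divided by the total point count. Candidates for
#' which the equilibrium constant \eqn{K_{TnCa0} = -a\,L_{sarc} + b}
#' would be non-positive at any trace length, or whose simulation fails,
#' receive a large penalty value (with a warning) so that derivative-free
#' optimizers can continue.
#'
#' @param candidate named numeric vector or list with \code{a}, \code{b},
#'   \code{c_f}, \code{c_s}.
#' @param traces list of \code{\link{tension_trace}} objects.
#' @param ct a \code{\link{calcium_transient}}.
#' @param fixed the non-fitted constants: list with \code{n},
#'   \code{f_da}, \code{f_ad}.
#' @param sim_opts list of overrides passed to
#'   \code{\link{simulate_twitch}} (e.g. \code{n_x}, tolerances).
#' @return Pooled mean squared error, kPa^2.
#' @export
trace_objective <- function(candidate, traces, ct,
                            fixed = list(n = 3, f_da = 40, f_ad = 12),
                            sim_opts = list()) {
  stopifnot(length(traces) >= 1L,
            all(vapply(traces, inherits, logical(1), "tension_trace")))
  candidate <- as.list(candidate)
  lengths <- vapply(traces, `[[`, numeric(1), "l_sarc")
  k <- -candidate$a * lengths + candidate$b
  if (any(k <= 0) || any(unlist(candidate) <= 0)) {
    warning("candidate violates positivity constraints; penalized",
            call. = FALSE)
    return(1e8)
  }
  model <- tryCatch(
    model_tension_at(candidate, fixed, traces, ct, sim_opts),
    error = function(e) {
      warning("simulation failed for candidate (", conditionMessage(e),
              "); penalized", call. = FALSE)
      NULL
    })
  if (is.null(model)) return(1e8)
  resid2 <- mapply(function(m, tr) sum((m - tr$s)^2), model, traces)
  j <- sum(vapply(traces, function(tr) length(tr$t), integer(1)))
  sum(resid2) / j
}

# logistic box transform: R^k -> (lo, hi)^k, used to run an unconstrained
# simplex search inside the parameter bounds
box_from_z <- function(z, lo, hi) lo + (hi - lo) / (1 + exp(-z))
z_from_box <- function(x, lo, hi) {
  f <- pmin(pmax((x - lo) / (hi - lo), 1e-8), 1 - 1e-8)
  log(f / (1 - f))
}

#' Estimate mechano-chemical parameters from tension traces
#'
#' Minimizes \code{\link{trace_objective}} over (\code{a}, \code{b},
#' \code{c_f}, \code{c_s}) with a bounded derivative-free simplex search
#' (Nelder-Mead on a logistic transform of the box constraints). The
#' objective involves a stiff ODE solve per trace length, so gradients
#' are noisy; a simplex search is robust to that. Deterministic given
#' \code{init}.
#'
#' @param traces list of \code{\link{tension_trace}} objects.
#' @param ct a \code{\link{calcium_transient}}.
#' @param init named numeric vector of starting values (\code{a},
#'   \code{b}, \code{c_f}, \code{c_s}); defaults to the published values.
#' @param bounds list with named numeric vectors \code{lower} and
#'   \code{upper}; defaults to [0.2x, 5x] of the published values, wide
#'   enough to keep the model in its validity regime.
#' @param fixed non-fitted constants, as in \code{\link{trace_objective}}.
#' @param sim_opts simulation overrides used during fitting; defaults to
#'   a 61-point spatial grid (objective accuracy well below the data
#'   noise at a fraction of the cost).
#' @param control passed to \code{\link[stats]{optim}}; \code{maxit}
#'   defaults to 800 and \code{reltol} to 1e-8.
#' @return An object of class \code{fit_result}: fitted \code{a},
#'   \code{b}, \code{c_f}, \code{c_s}, \code{objective_value} (kPa^2),
#'   \code{n_evaluations}, \code{converged}, and the optimizer
#'   \code{message} if any.
#' @export
fit_parameters <- function(traces, ct,
                           init = c(a = 1.39, b = 7.76, c_f = 0.283,
                                    c_s = 0.127),
                           bounds = NULL,
                           fixed = list(n = 3, f_da = 40, f_ad = 12),
                           sim_opts = list(n_x = 61L, dt_out = 0.005),
                           control = list()) {
  par_names <- c("a", "b", "c_f", "c_s")
  init <- init[par_names]
  stopifnot(!anyNA(init), all(init > 0))
  if (is.null(bounds)) {
    ref <- c(a = 1.39, b = 7.76, c_f = 0.283, c_s = 0.127)
    bounds <- list(lower = 0.2 * ref, upper = 5 * ref)
  }
  lo <- bounds$lower[par_names]
  hi <- bounds$upper[par_names]
  stopifnot(all(lo > 0), all(lo < hi), all(init >= lo), all(init <= hi))
  control <- utils::modifyList(list(maxit = 800, reltol = 1e-8), control)
  fn <- function(z) {
    x <- box_from_z(z, lo, hi)
    names(x) <- par_names
    trace_objective(x, traces, ct, fixed = fixed, sim_opts = sim_opts)
  }
  opt <- stats::optim(z_from_box(init, lo, hi), fn,
                      method = "Nelder-Mead", control = control)
  est <- box_from_z(opt$par, lo, hi)
  names(est) <- par_names
  structure(list(a = est[["a"]], b = est[["b"]], c_f = est[["c_f"]],
                 c_s = est[["c_s"]], objective_value = opt$value,
                 n_evaluations = unname(opt$counts["function"]),
                 converged = opt$convergence == 0,
                 message = opt$message),
            class = "fit_result")
}

#' @export
print.fit_result <- function(x, ...) {
  cat("Fitted mechano-chemical parameters",
      if (!x$converged) "(NOT converged)", "\n")
  cat(sprintf("  a = %.4g uM/um, b = %.4g uM, c_f = %.4g kPa/nm, c_s = %.4g 1/kPa\n",
              x$a, x$b, x$c_f, x$c_s))
  cat(sprintf("  objective %.4g kPa^2 after %d evaluations\n",
              x$objective_value, x$n_evaluations))
  invisible(x)
}

#' Generate synthetic experiment-style tension traces
#'
#' Simulates model twitches at the given sarcomere lengths, samples them
#' every \code{dt} seconds (the experiment-style sampling interval), and
#' adds i.i.d. Gaussian noise of standard deviation \code{noise_sd},
#' clamping negatives to zero. Reproducible for a given \code{seed};
#' the caller's RNG state is left untouched.
#'
#' @param p a \code{\link{model_parameters}} (the ground truth).
#' @param lengths sarcomere lengths, um.
#' @param ct a \code{\link{calcium_transient}}.
#' @param noise_sd noise standard deviation, kPa (>= 0).
#' @param seed integer RNG seed (required: traces must be reproducible).
#' @param dt sampling interval, s.
#' @param t_end trace duration, s.
#' @param ... further arguments to \code{\link{simulate_twitch}}.
#' @return List of \code{\link{tension_trace}} objects, one per length.
#' @export
generate_synthetic_traces <- function(p, lengths = seq(1.90, 2.20, 0.05),
                                      ct = calcium_transient(),
                                      noise_sd = 0, seed, dt = 0.02,
                                      t_end = 1.0, ...) {
  stopifnot(noise_sd >= 0, is.numeric(seed), length(seed) == 1L)
  old_seed <- if (exists(".Random.seed", globalenv()))
    get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old_seed))
    assign(".Random.seed", old_seed, globalenv()))
  set.seed(as.integer(seed))
  lapply(lengths, function(ls) {
    tw <- simulate_twitch(p, ls, ct, t_end = t_end, dt_out = dt, ...)
    s <- tw$tension
    if (noise_sd > 0) s <- pmax(s + stats::rnorm(length(s), 0, noise_sd), 0)
    tension_trace(tw$t, s, ls)
  })
}

#' Write / read tension-trace files
#'
#' One tab-delimited text file per trace: a metadata comment line
#' (\code{# l_sarc_um: <value>}), a header (\code{t_s}, \code{tension_kPa}),
#' then the samples. \code{write_traces} fills a directory with files
#' named \code{trace_<l_sarc>um.tsv}; \code{read_traces} reads a single
#' file or every \code{*.tsv} in a directory, and rejects malformed files
#' with the offending line number.
#'
#' @param traces list of \code{\link{tension_trace}} objects.
#' @param path directory (created if absent) for \code{write_traces};
#'   file or directory for \code{read_traces}.
#' @return \code{write_traces}: the file paths, invisibly.
#'   \code{read_traces}: a list of \code{tension_trace} objects.
#' @export
write_traces <- function(traces, path) {
  stopifnot(all(vapply(traces, inherits, logical(1), "tension_trace")))
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  files <- vapply(traces, function(tr) {
    f <- file.path(path, sprintf("trace_%.2fum.tsv", tr$l_sarc))
    con <- file(f, "w")
    on.exit(close(con))
    writeLines(sprintf("# l_sarc_um: %.17g", tr$l_sarc), con)
    writeLines("t_s\ttension_kPa", con)
    writeLines(sprintf("%.17g\t%.17g", tr$t, tr$s), con)
    f
  }, character(1))
  invisible(files)
}

#' @rdname write_traces
#' @export
read_traces <- function(path) {
  if (dir.exists(path)) {
    files <- sort(list.files(path, pattern = "\\.tsv$", full.names = TRUE))
    if (length(files) == 0L)
      stop("no .tsv trace files found in ", path, call. = FALSE)
    return(lapply(files, read_trace_file))
  }
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  list(read_trace_file(path))
}

read_trace_file <- function(file) {
  lines <- readLines(file)
  if (length(lines) == 0L)
    stop("empty trace file: ", file, call. = FALSE)
  meta <- regmatches(lines[1],
                     regexec("^#\\s*l_sarc_um:\\s*([0-9.eE+-]+)\\s*$",
                             lines[1]))[[1]]
  if (length(meta) != 2L)
    stop("line 1 of ", file, ": expected '# l_sarc_um: <value>'",
         call. = FALSE)
  l_sarc <- as.numeric(meta[2])
  if (length(lines) < 2L || !grepl("^t_s\\ttension_kPa$", lines[2]))
    stop("line 2 of ", file, ": expected header 't_s\\ttension_kPa'",
         call. = FALSE)
  if (length(lines) < 4L)
    stop("trace file ", file, " has fewer than 2 samples", call. = FALSE)
  body <- lines[-(1:2)]
  parts <- strsplit(body, "\t", fixed = TRUE)
  bad <- which(vapply(parts, length, integer(1)) != 2L)
  if (length(bad))
    stop("line ", bad[1] + 2L, " of ", file,
         ": expected two tab-separated fields", call. = FALSE)
  vals <- suppressWarnings(
    vapply(parts, function(p) as.numeric(p), numeric(2)))
  nonnum <- which(apply(is.na(vals), 2L, any))
  if (length(nonnum))
    stop("line ", nonnum[1] + 2L, " of ", file, ": non-numeric value",
         call. = FALSE)
  tr <- tryCatch(tension_trace(vals[1, ], vals[2, ], l_sarc),
                 error = function(e)
                   stop("invalid trace in ", file, ": ",
                        conditionMessage(e), call. = FALSE))
  tr
}
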