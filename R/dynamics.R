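#' Troponin activation under tension
#'
#' Fraction of active troponin complexes at steady state given local
#' thin-filament tension and calcium concentration:
#' \deqn{P = \frac{1}{1 + e^{\,n(-C_s S - \ln([Ca^{2+}]/K_{TnCa0}))}}.}
#' Tension lowers the free energy of the calcium-bound state, so P is
#' strictly increasing in both \code{s} and \code{ca}. Steady-state
#' calcium binding is justified because the cross-bridge cycle is
#' rate-limiting relative to calcium kinetics.
#'
#' @param s thin-filament tension, kPa (vectorised).
#' @param ca calcium concentration, uM; must be positive.
#' @param k zero-tension equilibrium constant \eqn{K_{TnCa0}}, uM.
#' @param p a \code{\link{model_parameters}} (uses \code{n}, \code{c_s}).
#' @return Activation fraction(s) in (0, 1).
#' @export
troponin_activation <- function(s, ca, k, p) {
  stopifnot(inherits(p, "model_parameters"))
  if (any(ca <= 0)) stop("ca must be positive", call. = FALSE)
  if (any(k <= 0)) stop("k must be positive", call. = FALSE)
  1 / (1 + exp(p$n * (-p$c_s * s - log(ca / k))))
}

#' Thin-filament tension profile from the activation field
#'
#' Integrates the cross-bridge force density along the single-overlap
#' region: \eqn{\partial S/\partial x = C_f A(x,t)} with boundary
#' condition \eqn{S(0,t) = 0}, so tension accumulates from the loose
#' mid-line-proximal end toward the z-disk. The default quadrature is the
#' trapezoidal rule on the uniform grid; \code{method = "riemann"} uses
#' the left-endpoint cumulative sum instead.
#'
#' @param a activation field: cross-bridge fraction per grid position.
#' @param grid a \code{\link{make_grid}} spatial grid.
#' @param p a \code{\link{model_parameters}} (uses \code{c_f}).
#' @param method quadrature rule, \code{"trapezoid"} or \code{"riemann"}.
#' @return Tension per grid position, kPa; \code{S[1] = 0}, non-decreasing
#'   when \code{a >= 0}.
#' @export
tension_profile <- function(a, grid, p, method = c("trapezoid", "riemann")) {
  stopifnot(inherits(grid, "spatial_grid"), inherits(p, "model_parameters"))
  method <- match.arg(method)
  if (length(a) != grid$n_x)
    stop("activation field length (", length(a),
         ") does not match grid (", grid$n_x, ")", call. = FALSE)
  cs <- cumsum(a)
  if (method == "trapezoid") {
    p$c_f * grid$dx * (cs - (a[1] + a) / 2)
  } else {
    p$c_f * grid$dx * c(0, cs[-grid$n_x])
  }
}

#' Cross-bridge attachment/detachment rate
#'
#' Two-state cross-bridge cycle: myosin heads enter the bound,
#' force-generating state at rate \eqn{f_{DA}} gated by the fraction of
#' active troponins, and detach at rate \eqn{f_{AD}}:
#' \deqn{\partial A/\partial t = (1 - A)\,P\,f_{DA} - A\,f_{AD}.}
#'
#' @param a cross-bridge fractions in [0, 1] (vectorised).
#' @param p_act active-troponin fractions in [0, 1], same length.
#' @param p a \code{\link{model_parameters}} (uses \code{f_da},
#'   \code{f_ad}).
#' @return Elementwise time derivative of \code{a}, 1/s.
#' @export
xb_rate <- function(a, p_act, p) {
  stopifnot(inherits(p, "model_parameters"), length(a) == length(p_act))
  (1 - a) * p_act * p$f_da - a * p$f_ad
}

# Method-of-lines right-hand side: tension (cumulative quadrature of A)
# -> troponin activation (with the instantaneous calcium level) ->
# cross-bridge kinetics. Pure function of (t, state) given the context.
twitch_rhs <- function(t, a, ctx) {
  s <- tension_profile(a, ctx$grid, ctx$p, method = ctx$quadrature)
  p_act <- troponin_activation(s, calcium_at(t, ctx$ct), ctx$k, ctx$p)
  list(xb_rate(a, p_act, ctx$p))
}

# Inlined copy of twitch_rhs without per-call S3 dispatch/validation;
# the integrator calls the RHS thousands of times per twitch. Kept in
# exact agreement with the documented operations (see test suite).
make_fast_rhs <- function(grid, p, ct, k, quadrature) {
  dx <- grid$dx
  cfdx <- p$c_f * dx
  n <- p$n; cs <- p$c_s; fda <- p$f_da; fad <- p$f_ad
  dias <- ct$ca_diastolic
  amp <- ct$ca_peak - ct$ca_diastolic
  tr <- ct$tau_rise; td <- ct$tau_decay; t0 <- ct$t_start
  beta <- ca_beta(ct)
  n_x <- grid$n_x
  trapezoid <- quadrature == "trapezoid"
  function(t, a, parms) {
    s <- if (trapezoid) cfdx * (cumsum(a) - (a[1] + a) / 2)
         else cfdx * c(0, cumsum(a)[-n_x])
    tt <- t - t0
    ca <- if (tt > 0) dias + amp * (exp(-tt / td) - exp(-tt / tr)) / beta
          else dias
    list((1 - a) / (1 + exp(n * (-cs * s - log(ca / k)))) * fda - a * fad)
  }
}

#' Steady-state activation profile at constant calcium
#'
#' Solves the algebraic fixed-point system
#' \eqn{A(x) = P(x) f_{DA} / (P(x) f_{DA} + f_{AD})} with the tension
#' profile recomputed from \eqn{A} at each sweep, by damped fixed-point
#' iteration. Used to initialise twitch simulations at the diastolic
#' equilibrium (no startup transient) and as the long-time limit under a
#' time-constant calcium level.
#'
#' @param ca constant calcium concentration, uM.
#' @param l_sarc sarcomere length, um.
#' @param p a \code{\link{model_parameters}}.
#' @param grid optional \code{\link{make_grid}}; built from \code{l_sarc}
#'   with \code{n_x} samples when omitted.
#' @param n_x grid samples when \code{grid} is omitted.
#' @param tol convergence tolerance on the sup-norm change per iteration.
#' @param max_iter iteration cap.
#' @param quadrature passed to \code{\link{tension_profile}}.
#' @return Activation fractions per grid position.
#' @export
steady_state_profile <- function(ca, l_sarc, p, grid = NULL, n_x = 101L,
                                 tol = 1e-12, max_iter = 10000L,
                                 quadrature = "trapezoid") {
  stopifnot(inherits(p, "model_parameters"))
  if (is.null(grid)) grid <- make_grid(single_overlap_length(l_sarc), n_x)
  k <- k_tnca0(l_sarc, p)
  a <- rep(0, grid$n_x)
  for (i in seq_len(max_iter)) {
    s <- tension_profile(a, grid, p, method = quadrature)
    p_act <- troponin_activation(s, ca, k, p)
    a_new <- p_act * p$f_da / (p_act * p$f_da + p$f_ad)
    if (max(abs(a_new - a)) < tol) return(a_new)
    a <- a_new
  }
  warning("steady-state iteration did not reach tol = ", tol,
          " in ", max_iter, " iterations")
  a
}

#' Simulate an isometric twitch
#'
#' Integrates the spatially resolved activation field \eqn{A(x,t)} over
#' the single-overlap region at fixed sarcomere length, driven by the
#' prescribed calcium transient, using a stiff method-of-lines solver.
#' The initial condition is the diastolic equilibrium profile at
#' \code{ct$ca_diastolic}. Total sarcomere tension is reported as the
#' thin-filament tension at the z-disk-proximal end of the overlap
#' region, \eqn{S(L_{so}, t)} — the accumulated sum of all cross-bridge
#' forces.
#'
#' @param p a \code{\link{model_parameters}}.
#' @param l_sarc sarcomere length, um (held constant; isometric).
#' @param ct a \code{\link{calcium_transient}}.
#' @param t_end simulation end time, s. Should cover the full twitch
#'   (tension back below 50\% of peak); if it does not, the result is
#'   flagged via \code{relaxed_50 = FALSE}.
#' @param n_x spatial samples over the single-overlap region.
#' @param dt_out output sampling interval, s (1 ms default resolves peak
#'   and relaxation times well below the 2 ms contract).
#' @param rtol,atol solver relative/absolute tolerances.
#' @param method a \code{deSolve} integrator name; the default
#'   \code{"lsoda"} switches automatically to a stiff scheme.
#' @param quadrature quadrature for the tension integral
#'   (\code{"trapezoid"} or \code{"riemann"}).
#' @param geometry optional \code{\link{sarcomere_geometry}} overriding
#'   the default filament constants for \code{l_sarc}.
#' @return An object of class \code{twitch_result}: fields \code{t} (s),
#'   \code{tension} (kPa), \code{ca} (uM), \code{A} (time-by-position
#'   activation matrix), \code{grid}, \code{l_sarc}, \code{params},
#'   \code{ct}, \code{relaxed_50}.
#' @examples
#' \donttest{
#' tw <- simulate_twitch(model_parameters(), 2.05, calcium_transient())
#' compute_metrics(tw)
#' }
#' @export
simulate_twitch <- function(p, l_sarc, ct, t_end = 1.0, n_x = 101L,
                            dt_out = 0.001, rtol = 1e-6, atol = 1e-9,
                            method = "lsoda",
                            quadrature = c("trapezoid", "riemann"),
                            geometry = NULL) {
  stopifnot(inherits(p, "model_parameters"),
            inherits(ct, "calcium_transient"),
            t_end > 0, dt_out > 0)
  quadrature <- match.arg(quadrature)
  if (is.null(geometry)) geometry <- sarcomere_geometry(l_sarc)
  grid <- make_grid(single_overlap_length(geometry), n_x)
  rhs <- make_fast_rhs(grid, p, ct, k_tnca0(l_sarc, p), quadrature)
  a0 <- steady_state_profile(ct$ca_diastolic, l_sarc, p, grid = grid,
                             quadrature = quadrature)
  times <- seq(0, t_end, by = dt_out)
  sol <- deSolve::ode(y = a0, times = times, func = rhs,
                      parms = NULL, method = method,
                      rtol = rtol, atol = atol)
  if (attr(sol, "istate")[1] < 0 || nrow(sol) < length(times)) {
    diagn <- utils::capture.output(deSolve::diagnostics(sol))
    stop("stiff solver failed to integrate the twitch (istate = ",
         attr(sol, "istate")[1], "); solver report:\n",
         paste(diagn, collapse = "\n"), call. = FALSE)
  }
  a_field <- unname(sol[, -1, drop = FALSE])
  # S(L_so, t): quadrature weights collapse to a single inner product
  w <- if (quadrature == "trapezoid")
    p$c_f * grid$dx * c(0.5, rep(1, grid$n_x - 2L), 0.5)
  else p$c_f * grid$dx * c(rep(1, grid$n_x - 1L), 0)
  tension <- drop(a_field %*% w)
  peak_i <- which.max(tension)
  relaxed <- any(tension[seq_along(tension) > peak_i] <=
                   0.5 * tension[peak_i])
  if (!relaxed)
    warning("tension did not relax below 50% of peak within t_end = ",
            t_end, " s; increase t_end", call. = FALSE)
  structure(list(t = times, tension = tension,
                 ca = calcium_at(times, ct), A = a_field, grid = grid,
                 l_sarc = l_sarc, params = p, ct = ct,
                 relaxed_50 = relaxed),
            class = "twitch_result")
}

#' Activation time course at a position
#'
#' @param tw a \code{twitch_result}.
#' @param x position along the single-overlap region, nm; the nearest
#'   grid point is used.
#' @return A list with \code{x} (the grid position used), \code{t} and
#'   \code{a} (the activation trace there).
#' @export
activation_at <- function(tw, x) {
  stopifnot(inherits(tw, "twitch_result"), is.numeric(x), length(x) == 1L)
  i <- which.min(abs(tw$grid$positions - x))
  list(x = tw$grid$positions[i], t = tw$t, a = tw$A[, i])
}

#' @export
print.twitch_result <- function(x, ...) {
  cat(sprintf("Isometric twitch at l_sarc = %.3g um (L_so = %.4g nm)\n",
              x$l_sarc, x$grid$positions[x$grid$n_x]))
  cat(sprintf("  %d time samples over [0, %.3g] s, %d spatial samples\n",
              length(x$t), max(x$t), x$grid$n_x))
  cat(sprintf("  peak tension %.4g kPa at t = %.3g s%s\n",
              max(x$tension), x$t[which.max(x$tension)],
              if (x$relaxed_50) "" else " (50% relaxation NOT reached)"))
  invisible(x)
}
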