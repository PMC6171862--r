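#' Mechano-chemical model parameters
#'
#' The six fitted/fixed constants of the sarcomere model plus the Hill
#' exponent. Defaults are the published fitted values:
#' \describe{
#'   \item{a}{slope of the zero-tension calcium equilibrium constant vs
#'     sarcomere length, uM/um (1.39)}
#'   \item{b}{its intercept, uM (7.76)}
#'   \item{n}{Hill coefficient of calcium binding to troponin at zero
#'     tension, dimensionless (3)}
#'   \item{c_s}{tension sensitivity of troponin, 1/kPa (0.127)}
#'   \item{c_f}{tension per unit length of the thin filament at full
#'     cross-bridge occupancy, kPa/nm (0.283)}
#'   \item{f_da}{cross-bridge attachment rate, 1/s (40)}
#'   \item{f_ad}{cross-bridge detachment rate, 1/s (12)}
#' }
#'
#' @param a,b,n,c_s,c_f,f_da,f_ad see Description; strictly positive,
#'   except that \code{a = 0} (no length dependence of the calcium
#'   affinity) and \code{c_s = 0} (no tension feedback on troponin, which
#'   collapses the spatial model to a single uniform cross-bridge ODE)
#'   are allowed as degenerate cases.
#' @return An object of class \code{model_parameters}.
#' @export
model_parameters <- function(a = 1.39, b = 7.76, n = 3, c_s = 0.127,
                             c_f = 0.283, f_da = 40, f_ad = 12) {
  v <- c(a = a, b = b, n = n, c_s = c_s, c_f = c_f,
         f_da = f_da, f_ad = f_ad)
  stopifnot(is.numeric(v), length(v) == 7L)
  strict <- c("b", "n", "c_f", "f_da", "f_ad")
  if (any(v[strict] <= 0) || any(v < 0))
    stop("model parameters must be positive (a, c_s may be zero): ",
         paste(names(v)[v <= 0], collapse = ", "), call. = FALSE)
  structure(as.list(v), class = "model_parameters")
}

#' Zero-tension calcium equilibrium constant
#'
#' The equilibrium calcium concentration constant of troponin binding at
#' zero thin-filament tension decreases linearly with sarcomere length
#' (so the calcium affinity of troponin rises with length):
#' \eqn{K_{TnCa0} = -a \, L_{sarc} + b}.
#'
#' @param l_sarc sarcomere length, um.
#' @param p a \code{\link{model_parameters}}.
#' @return \eqn{K_{TnCa0}}, uM (strictly positive or error).
#' @examples
#' k_tnca0(2.05, model_parameters())  # 4.9105 uM
#' @export
k_tnca0 <- function(l_sarc, p) {
  stopifnot(inherits(p, "model_parameters"), is.numeric(l_sarc))
  k <- -p$a * l_sarc + p$b
  if (any(k <= 0))
    stop("K_TnCa0 non-positive at l_sarc = ",
         paste(l_sarc[k <= 0], collapse = ", "),
         "; equilibrium constant must be positive", call. = FALSE)
  k
}

#' @export
print.model_parameters <- function(x, ...) {
  cat("Mechano-chemical sarcomere model parameters\n")
  cat(sprintf("  a    %8.4g uM/um    b    %8.4g uM\n", x$a, x$b))
  cat(sprintf("  n    %8.4g          c_s  %8.4g 1/kPa\n", x$n, x$c_s))
  cat(sprintf("  c_f  %8.4g kPa/nm   f_da %8.4g 1/s   f_ad %8.4g 1/s\n",
              x$c_f, x$f_da, x$f_ad))
  invisible(x)
}
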