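#' Sarcomere filament geometry
#'
#' Bundles the sarcomere length with the filament constants that determine
#' the single-overlap region. Defaults are the standard thin/thick filament
#' lengths and bare-zone width of the prescribed-geometry formulation this
#' model adopts.
#'
#' @param l_sarc sarcomere length, um. Working range of the model is
#'   roughly 1.9-2.2 um; values outside [1.5, 2.4] um are rejected.
#' @param len_thin thin (actin) filament length, um.
#' @param len_thick thick (myosin) filament length, um.
#' @param len_hbare bare-zone (cross-bridge free central) length of the
#'   thick filament, um.
#' @return An object of class \code{sarcomere_geometry}.
#' @export
sarcomere_geometry <- function(l_sarc, len_thin = 1.2, len_thick = 1.65,
                               len_hbare = 0.1) {
  stopifnot(is.numeric(l_sarc), length(l_sarc) == 1L)
  if (l_sarc < 1.5 || l_sarc > 2.4)
    stop("l_sarc outside the model's validity range [1.5, 2.4] um",
         call. = FALSE)
  if (len_thin <= 0 || len_thick <= 0 || len_hbare <= 0)
    stop("filament lengths must be positive", call. = FALSE)
  if (len_thin >= l_sarc)
    stop("len_thin must be < l_sarc (no double-overlap regime)",
         call. = FALSE)
  structure(list(l_sarc = l_sarc, len_thin = len_thin,
                 len_thick = len_thick, len_hbare = len_hbare),
            class = "sarcomere_geometry")
}

#' Length of the single-overlap region
#'
#' The single-overlap region is the span of the thin filament overlapped
#' exactly once by the thick filament — the only region where
#' cross-bridges form in the model. Its half-sarcomere extent runs from
#' \code{sovr_cle = max(l_sarc/2 - (l_sarc - len_thin), len_hbare/2)}
#' (centre-line end) to \code{sovr_ze = min(len_thick/2, l_sarc/2)}
#' (z-disk end), measured from the sarcomere mid-line.
#'
#' @param geom a \code{\link{sarcomere_geometry}} (or a bare sarcomere
#'   length in um, for convenience).
#' @return Single-overlap length \eqn{L_{so}}, nm.
#' @examples
#' single_overlap_length(sarcomere_geometry(2.05))  # 650 nm
#' @export
single_overlap_length <- function(geom) {
  if (is.numeric(geom)) geom <- sarcomere_geometry(geom)
  stopifnot(inherits(geom, "sarcomere_geometry"))
  sovr_ze <- min(geom$len_thick / 2, geom$l_sarc / 2)
  sovr_cle <- max(geom$l_sarc / 2 - (geom$l_sarc - geom$len_thin),
                  geom$len_hbare / 2)
  l_so <- (sovr_ze - sovr_cle) * 1000  # um -> nm
  if (l_so <= 0)
    stop("non-positive single-overlap length: geometry outside model validity",
         call. = FALSE)
  l_so
}

#' Uniform spatial grid over the single-overlap region
#'
#' Position x is arc position along the single-overlap region: 0 at the
#' mid-line-proximal edge, \code{l_so} at the z-disk-proximal edge, both
#' endpoints included as samples.
#'
#' @param l_so single-overlap length, nm.
#' @param n_x number of samples (>= 2).
#' @return An object of class \code{spatial_grid} with fields
#'   \code{positions} (nm), \code{n_x} and \code{dx}.
#' @export
make_grid <- function(l_so, n_x = 101L) {
  stopifnot(is.numeric(l_so), length(l_so) == 1L, l_so > 0)
  n_x <- as.integer(n_x)
  if (is.na(n_x) || n_x < 2L)
    stop("n_x must be an integer >= 2", call. = FALSE)
  structure(list(positions = seq(0, l_so, length.out = n_x),
                 n_x = n_x, dx = l_so / (n_x - 1L)),
            class = "spatial_grid")
}

#' @export
print.spatial_grid <- function(x, ...) {
  cat(sprintf("Spatial grid: %d samples over [0, %.6g] nm (dx = %.6g nm)\n",
              x$n_x, x$positions[x$n_x], x$dx))
  invisible(x)
}
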