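#' Default run configuration
#'
#' Nested list of every tunable the simulator and protocols accept, with
#' the published model parameters and the package's documented defaults
#' baked in: running the length-sweep protocol on an unmodified default
#' configuration reproduces the reference 7-length protocol.
#'
#' Blocks: \code{model} (the mechano-chemical constants), \code{calcium}
#' (transient shape), \code{geometry} (filament constants), \code{numerics}
#' (\code{n_x}, solver tolerances, \code{t_end}, \code{dt_out},
#' \code{quadrature}), \code{protocol} (sweep lengths / fractions,
#' \code{l_sarc}), \code{fitting} (noise level for synthetic fixtures),
#' and \code{seed}.
#'
#' @return A nested list of class \code{run_config}.
#' @export
default_config <- function() {
  structure(list(
    model = list(a = 1.39, b = 7.76, n = 3, c_s = 0.127, c_f = 0.283,
                 f_da = 40, f_ad = 12),
    calcium = list(ca_diastolic = 0.09, ca_peak = 1.45, tau_rise = 0.02,
                   tau_decay = 0.11, t_start = 0.05),
    geometry = list(len_thin = 1.2, len_thick = 1.65, len_hbare = 0.1),
    numerics = list(n_x = 101L, t_end = 1.0, dt_out = 0.001,
                    rtol = 1e-6, atol = 1e-9, quadrature = "trapezoid"),
    protocol = list(l_sarc = 2.05,
                    lengths = seq(1.90, 2.20, by = 0.05),
                    fractions = seq(0.6, 1.0, by = 0.1)),
    fitting = list(noise_sd = 0, fit_n_x = 61L),
    seed = 1L), class = "run_config")
}

#' Read and validate a run configuration
#'
#' Reads a YAML configuration file and merges it over
#' \code{\link{default_config}}: any omitted field keeps its default, so
#' a config file only needs the overrides. The merged configuration is
#' validated field by field before anything runs.
#'
#' @param path YAML file, or \code{NULL} for pure defaults.
#' @return A validated \code{run_config}.
#' @export
read_config <- function(path = NULL) {
  cfg <- default_config()
  if (!is.null(path)) {
    if (!file.exists(path)) stop("config file not found: ", path,
                                 call. = FALSE)
    user <- yaml::read_yaml(path)
    if (!is.list(user)) stop("config must be a YAML mapping", call. = FALSE)
    unknown <- setdiff(names(user), names(cfg))
    if (length(unknown))
      stop("unknown config block(s): ", paste(unknown, collapse = ", "),
           call. = FALSE)
    for (blk in names(user)) {
      if (is.list(cfg[[blk]])) {
        bad <- setdiff(names(user[[blk]]), names(cfg[[blk]]))
        if (length(bad))
          stop("unknown field(s) in '", blk, "': ",
               paste(bad, collapse = ", "), call. = FALSE)
        cfg[[blk]] <- utils::modifyList(cfg[[blk]], user[[blk]])
      } else {
        cfg[[blk]] <- user[[blk]]
      }
    }
  }
  validate_config(cfg)
}

#' @rdname read_config
#' @param cfg a \code{run_config} list to validate.
#' @export
validate_config <- function(cfg) {
  # constructors carry the invariant checks; build each object once here
  # so an invalid config fails fast with a field-level message
  do.call(model_parameters, cfg$model)
  do.call(calcium_transient, cfg$calcium)
  for (ls in c(cfg$protocol$l_sarc, cfg$protocol$lengths))
    do.call(sarcomere_geometry, c(list(l_sarc = ls), cfg$geometry))
  with(cfg$numerics, {
    stopifnot(n_x >= 2L, t_end > 0, dt_out > 0, rtol > 0, atol > 0,
              quadrature %in% c("trapezoid", "riemann"))
  })
  stopifnot(all(cfg$protocol$fractions > 0),
            all(cfg$protocol$fractions <= 1),
            cfg$fitting$noise_sd >= 0)
  cfg$seed <- as.integer(cfg$seed)
  stopifnot(!is.na(cfg$seed))
  structure(cfg, class = "run_config")
}

config_objects <- function(cfg) {
  list(p = do.call(model_parameters, cfg$model),
       ct = do.call(calcium_transient, cfg$calcium),
       sim = cfg$numerics)
}

#' Run a named protocol from a configuration
#'
#' The programmatic core behind the command-line interface: executes one
#' subcommand and writes its artifacts (delimited text plus JSON
#' sidecars) into \code{out_dir}, together with a run manifest holding
#' the fully resolved configuration, its hash, the seed and package
#' version.
#'
#' Subcommands: \code{simulate} (single twitch: trace file, activation
#' field, metrics JSON), \code{sweep-length}, \code{sweep-calcium}
#' (sweep tables), \code{fit} (parameter estimation against trace files
#' in \code{traces_dir}), \code{make-fixtures} (synthetic trace files),
#' \code{ca-wave} (sampled calcium transient), \code{overlap}
#' (single-overlap length for the configured lengths).
#'
#' @param cfg a validated \code{run_config}.
#' @param subcommand one of the names above.
#' @param out_dir output directory (created if needed).
#' @param traces_dir directory of trace files (\code{fit} only).
#' @return The subcommand's primary result object, invisibly; artifacts
#'   on disk.
#' @export
run_protocol <- function(cfg, subcommand, out_dir,
                         traces_dir = NULL) {
  cfg <- validate_config(cfg)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  ob <- config_objects(cfg)
  sim_args <- function(extra = list())
    c(list(p = ob$p, ct = ob$ct), cfg$numerics["n_x"],
      cfg$numerics["t_end"], cfg$numerics["dt_out"],
      cfg$numerics["rtol"], cfg$numerics["atol"],
      list(quadrature = cfg$numerics$quadrature), extra)
  res <- switch(
    subcommand,
    "simulate" = {
      tw <- do.call(simulate_twitch,
                    sim_args(list(l_sarc = cfg$protocol$l_sarc)))
      utils::write.table(
        data.frame(t_s = tw$t, ca_uM = tw$ca, tension_kPa = tw$tension),
        file.path(out_dir, "twitch.tsv"), sep = "\t", row.names = FALSE,
        quote = FALSE)
      afield <- rbind(tw$grid$positions, tw$A)
      utils::write.table(
        afield, file.path(out_dir, "activation_field.tsv"), sep = "\t",
        row.names = FALSE, col.names = FALSE, quote = FALSE)
      m <- compute_metrics(tw)
      jsonlite::write_json(unclass(m), file.path(out_dir, "metrics.json"),
                           auto_unbox = TRUE, digits = NA)
      tw
    },
    "sweep-length" = {
      tab <- length_sweep(ob$p, cfg$protocol$lengths, ob$ct,
                          n_x = cfg$numerics$n_x,
                          t_end = cfg$numerics$t_end,
                          dt_out = cfg$numerics$dt_out,
                          rtol = cfg$numerics$rtol,
                          atol = cfg$numerics$atol)
      write_sweep(tab, out_dir, "sweep_length")
      tab
    },
    "sweep-calcium" = {
      tab <- calcium_sweep(ob$p, cfg$protocol$l_sarc, ob$ct,
                           cfg$protocol$fractions,
                           n_x = cfg$numerics$n_x,
                           t_end = cfg$numerics$t_end,
                           dt_out = cfg$numerics$dt_out,
                           rtol = cfg$numerics$rtol,
                           atol = cfg$numerics$atol)
      write_sweep(tab, out_dir, "sweep_calcium")
      tab
    },
    "fit" = {
      if (is.null(traces_dir))
        stop("'fit' needs a directory of trace files", call. = FALSE)
      traces <- read_traces(traces_dir)
      fit <- fit_parameters(traces, ob$ct,
                            fixed = cfg$model[c("n", "f_da", "f_ad")],
                            sim_opts = list(n_x = cfg$fitting$fit_n_x))
      jsonlite::write_json(unclass(fit), file.path(out_dir, "fit.json"),
                           auto_unbox = TRUE, digits = NA)
      resid <- residual_table(fit, traces, ob$ct, cfg)
      utils::write.table(resid, file.path(out_dir, "residuals.tsv"),
                         sep = "\t", row.names = FALSE, quote = FALSE)
      fit
    },
    "make-fixtures" = {
      traces <- generate_synthetic_traces(
        ob$p, cfg$protocol$lengths, ob$ct,
        noise_sd = cfg$fitting$noise_sd, seed = cfg$seed,
        n_x = cfg$numerics$n_x)
      write_traces(traces, out_dir)
      traces
    },
    "ca-wave" = {
      t <- seq(0, cfg$numerics$t_end, by = cfg$numerics$dt_out)
      utils::write.table(
        data.frame(t_s = t, ca_uM = calcium_at(t, ob$ct)),
        file.path(out_dir, "calcium.tsv"), sep = "\t", row.names = FALSE,
        quote = FALSE)
      invisible(NULL)
    },
    "overlap" = {
      lso <- vapply(cfg$protocol$lengths, function(ls)
        single_overlap_length(do.call(sarcomere_geometry,
                                      c(list(l_sarc = ls),
                                        cfg$geometry))),
        numeric(1))
      df <- data.frame(l_sarc_um = cfg$protocol$lengths, l_so_nm = lso)
      utils::write.table(df, file.path(out_dir, "overlap.tsv"),
                         sep = "\t", row.names = FALSE, quote = FALSE)
      df
    },
    stop("unknown subcommand: ", subcommand, call. = FALSE))
  write_manifest(cfg, subcommand, out_dir)
  invisible(res)
}

write_sweep <- function(tab, out_dir, stem) {
  utils::write.table(as.data.frame(tab),
                     file.path(out_dir, paste0(stem, ".tsv")),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  jsonlite::write_json(as.data.frame(tab),
                       file.path(out_dir, paste0(stem, ".json")),
                       digits = NA)
}

residual_table <- function(fit, traces, ct, cfg) {
  cand <- c(a = fit$a, b = fit$b, c_f = fit$c_f, c_s = fit$c_s)
  model <- model_tension_at(as.list(cand),
                            cfg$model[c("n", "f_da", "f_ad")],
                            traces, ct,
                            list(n_x = cfg$fitting$fit_n_x))
  do.call(rbind, mapply(function(m, tr)
    data.frame(l_sarc_um = tr$l_sarc, t_s = tr$t, observed_kPa = tr$s,
               model_kPa = m, residual_kPa = tr$s - m),
    model, traces, SIMPLIFY = FALSE))
}

write_manifest <- function(cfg, subcommand, out_dir) {
  cfg_plain <- unclass(cfg)
  tmp <- tempfile()
  on.exit(unlink(tmp))
  writeLines(deparse(cfg_plain), tmp)
  hash <- unname(tools::md5sum(tmp))
  manifest <- list(
    subcommand = subcommand,
    package = "sarcotwitch",
    version = as.character(utils::packageVersion("sarcotwitch")),
    r_version = R.version.string,
    seed = cfg$seed,
    config_hash = hash,
    config = cfg_plain)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}
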