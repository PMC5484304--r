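#' Default run configuration
#'
#' Defaults reproduce a 3 T eight-channel body-coil cardiac bSSFP protocol:
#' per-channel limits of 1 kW peak and 100 W average with RF chain gain
#' A = 2.5 W/uT^2; IEC normal-mode SAR limits of 10 W/kg (local 10 g) and
#' 2 W/kg (whole body); amplifier gating duty-cycle limit 0.5; encoding time
#' 1.7 ms; a truncated-Gaussian pulse (delta1 = 0.53, delta2 = 0.40) at a
#' 45-degree target flip angle.
#'
#' @return Nested list of class `run_config`.
#' @export
default_config <- function() {
  structure(list(
    limits = list(p_peak = 1000, p_av = 100, a = 2.5,
                  lsar_max = 10, wbsar_max = 2, delta0 = 0.5),
    pulse = list(preset = "gaussian", samples = NULL, theta0_deg = 45),
    timing = list(t_enc = 1.7),
    solver = list(max_exchange = 20L, exchange_tol = 1e-4,
                  accelerate = TRUE, bias_tolerance = 5,
                  penalty_weight = 1),
    outer = list(tau_min = 0.2, tau_max = 5, max_iter = 10L),
    vop = list(epsilon_work = 0.03),
    phantom = list(grid = c(64L, 64L), voxel_size = 5, n_channels = 8L,
                   semi_axes = c(130, 85), coil_radius = 150,
                   noise_sd = 0),
    seed = 1L), class = "run_config")
}

# Recursively overlay user values onto defaults, rejecting unknown keys.
overlay_config <- function(def, user, path = "") {
  if (is.null(user)) return(def)
  if (!is.list(user)) stop(sprintf("config error: '%s' must be a section",
                                   path))
  unknown <- setdiff(names(user), names(def))
  if (length(unknown))
    stop(sprintf("config error: unknown field '%s%s'", path, unknown[1L]))
  for (k in names(user)) {
    if (is.list(def[[k]]) && !is.null(names(def[[k]]))) {
      def[[k]] <- overlay_config(def[[k]], user[[k]],
                                 paste0(path, k, "."))
    } else {
      def[k] <- list(user[[k]])  # preserves explicit NULLs
    }
  }
  def
}

validate_config <- function(cfg) {
  chk_pos <- function(x, nm) {
    if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x <= 0)
      stop(sprintf("config error: field '%s' must be a positive number", nm))
  }
  for (nm in c("p_peak", "p_av", "a", "lsar_max", "wbsar_max"))
    chk_pos(cfg$limits[[nm]], paste0("limits.", nm))
  if (cfg$limits$delta0 <= 0 || cfg$limits$delta0 > 1)
    stop("config error: field 'limits.delta0' must lie in (0, 1]")
  th <- cfg$pulse$theta0_deg
  if (!is.numeric(th) || th <= 0 || th >= 180)
    stop("config error: field 'pulse.theta0_deg' must lie in (0, 180)")
  chk_pos(cfg$timing$t_enc, "timing.t_enc")
  if (!is.null(cfg$pulse$preset) &&
      !cfg$pulse$preset %in% names(PULSE_PRESETS))
    stop("config error: field 'pulse.preset' unknown")
  if (cfg$outer$tau_min <= 0 || cfg$outer$tau_max <= cfg$outer$tau_min)
    stop("config error: field 'outer.tau_min/tau_max' invalid bracket")
  if (cfg$vop$epsilon_work < 0)
    stop("config error: field 'vop.epsilon_work' must be >= 0")
  cfg
}

#' Load a run configuration
#'
#' Reads a YAML (or JSON) configuration, overlays it onto the defaults of
#' [default_config()], rejects unknown keys, and validates field ranges. An
#' empty file yields the full default configuration.
#'
#' @param path Path to a `.yaml`/`.yml`/`.json` file, or `NULL` for defaults.
#' @return Validated `run_config`.
#' @export
load_config <- function(path = NULL) {
  if (is.null(path)) return(validate_config(default_config()))
  if (!file.exists(path)) stop(sprintf("config error: no such file '%s'",
                                       path))
  user <- if (grepl("\\.json$", path, ignore.case = TRUE))
    jsonlite::read_json(path, simplifyVector = TRUE)
  else yaml::read_yaml(path)
  if (length(user) == 0L) user <- list()
  cfg <- overlay_config(default_config(), user)
  class(cfg) <- "run_config"
  validate_config(cfg)
}

#' Save a run configuration
#'
#' @param cfg A `run_config`.
#' @param path Output path; format chosen by extension (`.yaml` or `.json`).
#' @return `path`, invisibly.
#' @export
save_config <- function(cfg, path) {
  if (grepl("\\.json$", path, ignore.case = TRUE))
    jsonlite::write_json(unclass(cfg), path, auto_unbox = TRUE, digits = NA,
                         null = "null")
  else yaml::write_yaml(unclass(cfg), path)
  invisible(path)
}

rf_pulse_from_config <- function(cfg, tau = 1.0) {
  if (!is.null(cfg$pulse$samples))
    rf_pulse(waveform = as.numeric(cfg$pulse$samples), tau = tau)
  else rf_pulse(preset = cfg$pulse$preset, tau = tau)
}

limits_from_config <- function(cfg) {
  hardware_limits(p_peak = cfg$limits$p_peak, p_av = cfg$limits$p_av,
                  a = cfg$limits$a, lsar_max = cfg$limits$lsar_max,
                  wbsar_max = cfg$limits$wbsar_max)
}

# --- map container -------------------------------------------------------

# Numeric payloads are stored as base64-encoded little-endian IEEE doubles so
# a read-back is bit-exact (decimal JSON numbers lose the last ulp or two).
b64_num <- function(x)
  jsonlite::base64_enc(writeBin(as.vector(x), raw(), size = 8L,
                                endian = "little"))
num_b64 <- function(s, n)
  readBin(jsonlite::base64_dec(s), "double", n = n, size = 8L,
          endian = "little")

carr <- function(x) list(real = b64_num(Re(x)), imag = b64_num(Im(x)),
                         dim = dim(x), n = length(x))
uncarr <- function(l) {
  n <- as.integer(l$n)
  z <- complex(real = num_b64(l$real, n), imaginary = num_b64(l$imag, n))
  array(z, dim = as.integer(l$dim))
}
rarr <- function(x) list(data = b64_num(x), dim = dim(x), n = length(x))
unrarr <- function(l) {
  array(num_b64(l$data, as.integer(l$n)), dim = as.integer(l$dim))
}

#' Write phantom maps (and optionally Q-matrices) to a container file
#'
#' Single-file JSON container mirroring the package's logical layout:
#' groups `b1`, `e`, `masks`, `maps`, optional `q` and `vops`, plus an
#' `attributes` group (`voxel_size`, `seed`, `normalization`, `grid`).
#' Complex arrays are stored as real/imag parts with dimensions; numeric
#' payloads are base64-encoded IEEE doubles inside the (text) JSON file, so
#' a read-back reproduces every value bit-exactly.
#'
#' @param phantom A `phantom_model`.
#' @param path Output path (`.json`).
#' @param qset Optional `qmatrix_set`.
#' @param vops Optional `vop_set`.
#' @return `path`, invisibly.
#' @export
write_maps <- function(phantom, path, qset = NULL, vops = NULL) {
  stopifnot(inherits(phantom, "phantom_model"))
  obj <- list(
    attributes = list(voxel_size = phantom$voxel_size,
                      seed = phantom$spec$seed,
                      normalization = phantom$normalization,
                      normalization_raw = b64_num(phantom$normalization),
                      grid = phantom$spec$grid,
                      n_channels = phantom$spec$n_channels),
    b1 = carr(phantom$b1),
    e = carr(phantom$e),
    masks = list(body = as.vector(phantom$masks$body),
                 roi = as.vector(phantom$masks$roi),
                 blood = as.vector(phantom$masks$blood)),
    maps = list(conductivity = rarr(phantom$conductivity),
                density = rarr(phantom$density)),
    spec = unclass(phantom$spec))
  if (!is.null(qset)) {
    obj$q <- list(local = carr(qset$local),
                  wholebody = carr(qset$wholebody),
                  voxel = qset$voxel, grid = qset$grid,
                  mass_target = qset$mass_target)
  }
  if (!is.null(vops)) {
    obj$vops <- list(matrices = carr(vops$matrices), raw = carr(vops$raw),
                     Z = carr(vops$Z), wholebody = carr(vops$wholebody),
                     epsilon = vops$epsilon, provenance = vops$provenance,
                     n_full = vops$n_full)
  }
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE,
                       null = "null")
  invisible(path)
}

need_field <- function(obj, name, path) {
  parts <- strsplit(name, "/", fixed = TRUE)[[1L]]
  for (p in parts) {
    if (is.null(obj[[p]]))
      stop(sprintf("format error: missing dataset '%s' in '%s'", name, path))
    obj <- obj[[p]]
  }
  obj
}

#' Read a map container written by [write_maps()]
#'
#' @param path Container path.
#' @return List with `phantom` (a `phantom_model`), and `qset` / `vops` when
#'   present (otherwise `NULL`). Missing required datasets raise an error
#'   naming the dataset.
#' @export
read_maps <- function(path) {
  if (!file.exists(path)) stop(sprintf("format error: no such file '%s'",
                                       path))
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  att <- need_field(obj, "attributes", path)
  grid <- as.integer(need_field(obj, "attributes/grid", path))
  b1 <- uncarr(need_field(obj, "b1", path))
  e <- uncarr(need_field(obj, "e", path))
  masks <- list(
    body = matrix(need_field(obj, "masks/body", path), grid[1L], grid[2L]),
    roi = matrix(need_field(obj, "masks/roi", path), grid[1L], grid[2L]),
    blood = matrix(need_field(obj, "masks/blood", path), grid[1L], grid[2L]))
  spec <- obj$spec
  spec$grid <- as.integer(spec$grid)
  class(spec) <- "phantom_spec"
  phantom <- structure(list(
    b1 = b1, e = e, masks = masks,
    conductivity = unrarr(need_field(obj, "maps/conductivity", path)),
    density = unrarr(need_field(obj, "maps/density", path)),
    voxel_size = att$voxel_size,
    normalization = if (!is.null(att$normalization_raw))
      num_b64(att$normalization_raw, 1L) else att$normalization,
    spec = spec), class = "phantom_model")
  qset <- NULL
  if (!is.null(obj$q)) {
    qset <- structure(list(local = uncarr(need_field(obj, "q/local", path)),
                           wholebody = uncarr(need_field(obj, "q/wholebody",
                                                         path)),
                           voxel = as.integer(need_field(obj, "q/voxel",
                                                         path)),
                           grid = as.integer(obj$q$grid),
                           mass_target = obj$q$mass_target),
                      class = "qmatrix_set")
  }
  vops <- NULL
  if (!is.null(obj$vops)) {
    vops <- structure(list(matrices = uncarr(obj$vops$matrices),
                           raw = uncarr(obj$vops$raw),
                           Z = uncarr(obj$vops$Z),
                           wholebody = uncarr(obj$vops$wholebody),
                           epsilon = obj$vops$epsilon,
                           provenance = as.integer(obj$vops$provenance),
                           n_full = obj$vops$n_full),
                      class = "vop_set")
  }
  list(phantom = phantom, qset = qset, vops = vops)
}

# --- reporting -----------------------------------------------------------

#' Write run reports
#'
#' Writes, with deterministic ordering: `summary.json` (full numeric
#' summary), `comparison.csv` (one row per mode: tau, TR, bias, cov, SAR,
#' active constraints), `polar.csv` (per-channel shim amplitude/phase with
#' the amplitude cap radii, for polar plotting), and per-mode
#' `sar_map_<mode>.csv` when the solutions carry SAR maps.
#'
#' @param result A [compare_modes()] result, or a list with `table` and
#'   `solutions`.
#' @param out_dir Output directory, created if needed.
#' @return Character vector of files written, invisibly.
#' @export
report <- function(result, out_dir) {
  ok <- dir.exists(out_dir) || dir.create(out_dir, recursive = TRUE)
  if (!ok || file.access(out_dir, 2L) != 0L)
    stop(sprintf("I/O error: cannot write to '%s'", out_dir))
  files <- character(0)
  tabf <- file.path(out_dir, "comparison.csv")
  utils::write.csv(result$table, tabf, row.names = FALSE)
  files <- c(files, tabf)

  polar <- list()
  for (m in names(result$solutions)) {
    sol <- result$solutions[[m]]
    if (!isTRUE(sol$feasible)) next
    w <- sol$shims$w
    polar[[m]] <- data.frame(
      mode = m, channel = seq_along(w), amplitude = abs(w),
      phase_deg = Arg(w * Conj(quadrature_weights(length(w)))) * 180 / pi,
      amp_peak_cap = sol$cons$amp_peak_cap,
      amp_avg_cap = sol$cons$amp_avg_cap, stringsAsFactors = FALSE)
  }
  if (length(polar)) {
    pf <- file.path(out_dir, "polar.csv")
    utils::write.csv(do.call(rbind, polar), pf, row.names = FALSE)
    files <- c(files, pf)
  }
  for (m in names(result$solutions)) {
    sol <- result$solutions[[m]]
    if (!isTRUE(sol$feasible) || is.null(sol$sar_report$map)) next
    sf <- file.path(out_dir, sprintf("sar_map_%s.csv", m))
    utils::write.csv(sol$sar_report$map, sf, row.names = FALSE)
    files <- c(files, sf)
  }
  summ <- list(modes = lapply(result$solutions, function(sol) {
    if (!isTRUE(sol$feasible)) return(list(feasible = FALSE))
    list(feasible = TRUE, tau = sol$tau, tr = sol$tr,
         theta0_deg = sol$theta0 * 180 / pi,
         bias_pct = sol$metrics[["bias_pct"]], cov = sol$metrics[["cov"]],
         lsar = sol$sar_report$local_max, wbsar = sol$sar_report$wholebody,
         active = as.list(sol$active),
         margins = as.list(sol$margins),
         w = lapply(sol$shims$w, function(z) c(Re(z), Im(z))))
  }))
  jf <- file.path(out_dir, "summary.json")
  jsonlite::write_json(summ, jf, digits = NA, auto_unbox = TRUE)
  files <- c(files, jf)
  invisible(files)
}
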