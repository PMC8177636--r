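# End-to-end orchestration: segment -> average -> align -> anneal ->
# forces, with JSON config, deterministic outputs and optional figures.
#
# Config is an R list or a JSON file. Recognised fields (defaults in
# parentheses): initial / target (path(s) to contour CSVs, or in-memory
# contours), model ("solid"), E (5000), nu (0.5), h (0.1),
# strain_convention ("as-printed"), rings (20), height (4.7) or
# geometry (list of channel_geometry arguments), n_points (NULL),
# anneal (list of anneal_config arguments), plots (FALSE),
# arrow_scale_pa (250: one unit of axis length per 250 Pa of traction).

#' @keywords internal
resolve_config <- function(config) {
  if (is.character(config) && length(config) == 1)
    config <- jsonlite::read_json(config, simplifyVector = TRUE)
  if (!is.list(config)) stopf("config must be a list or a JSON file path")
  defaults <- list(model = "solid", E = 5000, nu = 0.5, h = 0.1,
                   strain_convention = "as-printed", rings = 20,
                   height = 4.7, geometry = NULL, n_points = NULL,
                   anneal = list(), plots = FALSE, arrow_scale_pa = 250)
  out <- utils::modifyList(defaults, config)
  out$anneal <- do.call(anneal_config, out$anneal)
  out
}

#' @keywords internal
load_stage <- function(x, n_points = NULL) {
  if (is_contour(x)) return(x)
  if (is.list(x) && all(vapply(x, is_contour, TRUE))) {
    if (length(x) == 1) return(x[[1]])
    return(average_contours(x, n_points))
  }
  paths <- as.character(x)
  missing <- paths[!file.exists(paths)]
  if (length(missing)) stopf("input contour file not found: %s", missing[1])
  cs <- lapply(paths, read_contour_csv)
  if (length(cs) == 1) cs[[1]] else average_contours(cs, n_points)
}

#' Run the pipeline on one stage pair
#'
#' Loads (and if several, spoke-averages) the initial and target
#' outlines, removes translation, anneals the boundary correspondence
#' under the chosen model, computes the traction profile of the best
#' mapping and writes `traction_<model>.csv`, `energy_trace.csv`,
#' `alignment.json` and `config_effective.json` (plus optional
#' vector-field and arclength-profile figures) into `out_dir`.
#' Deterministic given the config seed: re-running reproduces every
#' output byte for byte. On failure, partial outputs are removed.
#'
#' @param config list or JSON path; see the package vignette
#' @param out_dir output directory (created if needed)
#' @return (invisibly) list with `mapping`, `traction`, `anneal`,
#'   `alignment` and the effective config
#' @export
run_stage_pair <- function(config, out_dir) {
  cfg <- resolve_config(config)
  if (is.null(cfg$initial) || is.null(cfg$target))
    stopf("config must name 'initial' and 'target' stages")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  written <- character(0)
  ok <- FALSE
  on.exit(if (!ok) unlink(written), add = TRUE)

  params <- elastic_params(cfg$E, cfg$nu, cfg$h, cfg$strain_convention)
  geometry <- if (!is.null(cfg$geometry)) do.call(channel_geometry, cfg$geometry)
  height <- geometry %||% cfg$height
  init <- load_stage(cfg$initial, cfg$n_points)
  targ <- load_stage(cfg$target, cfg$n_points)
  al <- align_pair(init, targ)
  res <- anneal(al$initial, al$target, model = cfg$model, params = params,
                config = cfg$anneal, rings = cfg$rings, height = height,
                n = cfg$n_points)
  frames <- contour_frames(contour(res$mapping$initial, validate = FALSE))
  traction <- if (cfg$model == "solid")
    solid_traction(res$mapping, params, cfg$rings, frames)
  else shell_traction(res$mapping, frames = frames, params = params)

  f_traction <- file.path(out_dir, sprintf("traction_%s.csv", cfg$model))
  write_traction_csv(traction, f_traction); written <- c(written, f_traction)
  f_trace <- file.path(out_dir, "energy_trace.csv")
  write_energy_trace_csv(res, f_trace); written <- c(written, f_trace)
  f_align <- file.path(out_dir, "alignment.json")
  jsonlite::write_json(list(shift_um = al$shift,
                            offset_from_centroid_um = al$offset_from_centroid,
                            T0 = res$T0, best_energy = res$energy),
                       f_align, auto_unbox = TRUE, digits = NA)
  written <- c(written, f_align)
  f_cfg <- file.path(out_dir, "config_effective.json")
  cfg_out <- cfg
  cfg_out$anneal <- unclass(cfg_out$anneal)
  cfg_out$initial <- if (is.character(cfg$initial)) cfg$initial else "<in-memory>"
  cfg_out$target <- if (is.character(cfg$target)) cfg$target else "<in-memory>"
  jsonlite::write_json(cfg_out, f_cfg, auto_unbox = TRUE, digits = NA,
                       null = "null")
  written <- c(written, f_cfg)
  if (isTRUE(cfg$plots)) {
    f_fig <- file.path(out_dir, sprintf("forces_%s.pdf", cfg$model))
    plot_stage_pair(res$mapping, traction, cfg$arrow_scale_pa, f_fig)
    written <- c(written, f_fig)
  }
  ok <- TRUE
  invisible(list(mapping = res$mapping, traction = traction, anneal = res,
                 alignment = al, config = cfg))
}

# Vector-field panel plus arclength profiles (|t|, t_x, t_y vs s1), the
# usual layout for these force maps. Arrows: one axis unit of length per
# `arrow_scale_pa` Pa.
#' @keywords internal
plot_stage_pair <- function(mapping, traction, arrow_scale_pa, path) {
  grDevices::pdf(path, width = 10, height = 8)
  on.exit(grDevices::dev.off())
  graphics::par(mfrow = c(2, 2), mar = c(4, 4, 2, 1))
  ip <- mapping$initial; tp <- mapping$target
  graphics::plot(rbind(ip, ip[1, ]), type = "l", asp = 1, col = "black",
                 xlab = "x (um)", ylab = "y (um)", main = "deformation and traction")
  graphics::lines(rbind(tp, tp[1, ]), col = "darkgreen")
  scale_len <- max(diff(range(ip[, 1])), diff(range(ip[, 2])))
  nz <- sqrt(rowSums((tp - ip)^2)) > 1e-6 * scale_len
  graphics::arrows(ip[nz, 1], ip[nz, 2], tp[nz, 1], tp[nz, 2],
                   length = 0.04, col = "blue")
  sc <- 1 / arrow_scale_pa
  nz <- traction$tmag_Pa * sc > 1e-6 * scale_len
  graphics::arrows(ip[nz, 1], ip[nz, 2],
                   ip[nz, 1] + traction$tx_Pa[nz] * sc,
                   ip[nz, 2] + traction$ty_Pa[nz] * sc,
                   length = 0.04, col = "red")
  o <- order(traction$s1_um)
  graphics::plot(traction$s1_um[o], traction$tmag_Pa[o], type = "l", col = "red",
                 xlab = "s1 (um)", ylab = "|t| (Pa)", main = "traction magnitude")
  graphics::plot(traction$s1_um[o], traction$tx_Pa[o], type = "l", col = "blue",
                 xlab = "s1 (um)", ylab = "t_x (Pa)", main = "x component")
  graphics::plot(traction$s1_um[o], traction$ty_Pa[o], type = "l", col = "magenta",
                 xlab = "s1 (um)", ylab = "t_y (Pa)", main = "y component")
}

#' Per-stage nuclear volume table
#'
#' Estimates each outline's volume as area x local channel height,
#' splitting outlines that span the constriction at its entrance and
#' exit, and summarises per migration stage (mean and standard
#' deviation) - the usual volume-conservation check.
#'
#' @param contours list of [contour()] objects or contour CSV paths, in
#'   coordinates where the constriction occupies `0 <= x <= length`
#' @param stages character vector of stage labels, one per contour (no
#'   missing values)
#' @param geometry [channel_geometry()]
#' @return list with `per_contour` (stage, area_um2, volume_um3) and
#'   `per_stage` (stage, n, mean_um3, sd_um3) data frames
#' @export
volume_report <- function(contours, stages, geometry = channel_geometry()) {
  if (length(contours) != length(stages) || anyNA(stages) ||
      any(!nzchar(stages)))
    stopf("every contour needs a stage tag")
  cs <- lapply(contours, function(x) if (is_contour(x)) x else read_contour_csv(x))
  vol <- vapply(cs, estimate_volume, 1, height = geometry)
  area <- vapply(cs, polygon_area, 1)
  per_contour <- data.frame(stage = as.character(stages), area_um2 = area,
                            volume_um3 = vol, stringsAsFactors = FALSE)
  agg <- split(vol, per_contour$stage)
  per_stage <- data.frame(stage = names(agg),
                          n = vapply(agg, length, 1L),
                          mean_um3 = vapply(agg, mean, 1),
                          sd_um3 = vapply(agg, function(v)
                            if (length(v) > 1) stats::sd(v) else 0, 1),
                          stringsAsFactors = FALSE, row.names = NULL)
  list(per_contour = per_contour, per_stage = per_stage)
}
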