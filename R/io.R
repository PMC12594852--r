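#' Read a single-channel TIFF image
#'
#' Images are returned as numeric matrices indexed `img[x + 1, y + 1]`
#' (0-based pixel coordinates with x as the first index). Multi-channel
#' images are reduced to their first channel; intensities are as decoded
#' by the TIFF reader (integer images scale to `[0, 1]`).
#'
#' @param path TIFF file path.
#' @return Numeric matrix.
#' @export
read_image_tiff <- function(path) {
  if (!file.exists(path)) stop(sprintf("image file not found: %s", path))
  x <- tiff::readTIFF(path)
  if (length(dim(x)) == 3) x <- x[, , 1]
  img <- t(x)  # reader returns [row = y, col = x]
  if (any(!is.finite(img))) stop("image contains non-finite values")
  if (nrow(img) < 16 || ncol(img) < 16) stop("image must be at least 16 x 16")
  pmax(img, 0)
}

#' Write a matrix as a TIFF image
#'
#' @param img Numeric matrix indexed `[x + 1, y + 1]`.
#' @param path Output path.
#' @param bits 16 (intensities rescaled to the full range) or 32
#'   (IEEE float, values written as-is).
#' @return `path`, invisibly.
#' @export
write_image_tiff <- function(img, path, bits = 16) {
  stopifnot(is.matrix(img))
  x <- t(img)
  if (bits == 32) {
    tiff::writeTIFF(x, path, bits.per.sample = 32L)
  } else {
    mx <- max(x)
    if (mx > 0) x <- x / mx
    tiff::writeTIFF(pmin(pmax(x, 0), 1), path, bits.per.sample = 16L)
  }
  invisible(path)
}

#' Read ellipse-pair annotations from JSON
#'
#' The schema is a list of objects
#' `{"inner": {"cx", "cy", "a", "b", "theta"}, "outer": {...}}`.
#'
#' @param path JSON file path.
#' @return List of `annulus_annotation`.
#' @export
read_annotations <- function(path) {
  if (!file.exists(path))
    stop(config_error(sprintf("annotation file not found: %s", path)))
  raw <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  lapply(raw, function(r) {
    for (side in c("inner", "outer"))
      if (is.null(r[[side]]))
        stop(config_error("annotation entries need 'inner' and 'outer' ellipses"))
    mk <- function(e) ellipse(e$cx, e$cy, e$a, e$b,
                              if (is.null(e$theta)) 0 else e$theta)
    annulus_annotation(mk(r$inner), mk(r$outer))
  })
}

#' Write ellipse-pair annotations to JSON
#'
#' @param annotations List of `annulus_annotation`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_annotations <- function(annotations, path) {
  if (inherits(annotations, "annulus_annotation"))
    annotations <- list(annotations)
  ser <- lapply(annotations, function(a)
    list(inner = a$inner[c("cx", "cy", "a", "b", "theta")],
         outer = a$outer[c("cx", "cy", "a", "b", "theta")]))
  jsonlite::write_json(ser, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Save / load a trajectory
#'
#' Trajectories are stored as RDS (the full snapshot list plus
#' configuration); the scalar series are additionally exportable as CSV
#' via [write_series_csv()] and field snapshots as TIFF via
#' [write_field_renders()].
#'
#' @param traj A `pf_trajectory`.
#' @param path Output `.rds` path.
#' @return `path`, invisibly.
#' @export
write_trajectory <- function(traj, path) {
  stopifnot(inherits(traj, "pf_trajectory"))
  saveRDS(traj, path)
  invisible(path)
}

#' @rdname write_trajectory
#' @export
read_trajectory <- function(path) {
  traj <- readRDS(path)
  if (!inherits(traj, "pf_trajectory")) stop("not a trajectory file")
  traj
}

#' Export energy and mass series of a trajectory as CSV
#'
#' @param traj A `pf_trajectory`.
#' @param path Output CSV path.
#' @return The exported data frame, invisibly.
#' @export
write_series_csv <- function(traj, path) {
  df <- data.frame(time = traj$times, energy = traj$energy,
                   mass_eta = traj$mass_eta)
  if (ncol(traj$mass_chi) > 0) {
    mc <- as.data.frame(traj$mass_chi)
    names(mc) <- paste0("mass_chi_", seq_len(ncol(mc)))
    df <- cbind(df, mc)
  }
  utils::write.csv(df, path, row.names = FALSE)
  invisible(df)
}

#' Render trajectory snapshots to TIFF
#'
#' Writes one 32-bit float TIFF per field per snapshot
#' (`eta_t<T>.tif`, `phi_t<T>.tif`, `chi<s>_t<T>.tif`).
#'
#' @param traj A `pf_trajectory`.
#' @param dir Output directory (created if missing).
#' @return Character vector of written paths, invisibly.
#' @export
write_field_renders <- function(traj, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(0)
  for (st in traj$snapshots) {
    tag <- sprintf("t%g", st$t)
    p <- file.path(dir, sprintf("eta_%s.tif", tag))
    write_image_tiff(st$eta, p, bits = 32); paths <- c(paths, p)
    p <- file.path(dir, sprintf("phi_%s.tif", tag))
    write_image_tiff(st$phi, p, bits = 32); paths <- c(paths, p)
    for (s in seq_along(st$chi)) {
      p <- file.path(dir, sprintf("chi%d_%s.tif", s, tag))
      write_image_tiff(st$chi[[s]], p, bits = 32); paths <- c(paths, p)
    }
  }
  invisible(paths)
}

config_error <- function(msg) {
  structure(class = c("hollowcond_config_error", "error", "condition"),
            list(message = msg, call = NULL))
}

#' Read a simulation configuration from YAML
#'
#' The file may contain `grid`, `params`, `ic` and `run` sections whose
#' fields are named exactly as the arguments of [grid_spec()],
#' [model_params()], [initial_condition()] and [run_simulation()].
#'
#' @param path YAML file path.
#' @param overrides Optional named list overriding single fields, as
#'   `section.field` (e.g. `list("params.psi_c" = 0.95)`).
#' @return List with `grid`, `params`, `ic` and `run` (run options list).
#' @export
read_config_yaml <- function(path, overrides = list()) {
  if (!file.exists(path))
    stop(config_error(sprintf("config file not found: %s", path)))
  cfg <- tryCatch(yaml::read_yaml(path), error = function(e)
    stop(config_error(sprintf("YAML parse error in %s: %s", path,
                              conditionMessage(e)))))
  if (!is.list(cfg)) stop(config_error("config must be a YAML mapping"))
  for (key in names(overrides)) {
    parts <- strsplit(key, ".", fixed = TRUE)[[1]]
    if (length(parts) != 2) stop(config_error(sprintf("bad override '%s'", key)))
    if (is.null(cfg[[parts[1]]])) cfg[[parts[1]]] <- list()
    cfg[[parts[1]]][[parts[2]]] <- overrides[[key]]
  }
  build <- function(fun, args) {
    if (is.null(args)) args <- list()
    bad <- setdiff(names(args), names(formals(fun)))
    if (length(bad))
      stop(config_error(sprintf("unknown config field(s): %s",
                                paste(bad, collapse = ", "))))
    do.call(fun, args)
  }
  grid <- build(grid_spec, utils::modifyList(list(nx = 128, ny = 128),
                                             if (is.null(cfg$grid)) list() else cfg$grid))
  params <- build(model_params, cfg$params)
  ic <- build(initial_condition, cfg$ic)
  run <- if (is.null(cfg$run)) list() else cfg$run
  list(grid = grid, params = params, ic = ic, run = run)
}

#' Write a run manifest
#'
#' Every artifact-writing command records one JSON manifest: the command,
#' configuration snapshot, seeds, package version, input/output paths and
#' a timestamp.
#'
#' @param command Command name.
#' @param config Configuration snapshot (list).
#' @param inputs,outputs Character vectors of paths.
#' @param path Output JSON path.
#' @return `path`, invisibly.
#' @export
write_manifest <- function(command, config, inputs, outputs, path) {
  manifest <- list(
    command = command,
    config = config,
    inputs = as.list(inputs),
    outputs = as.list(outputs),
    package = "hollowcond",
    version = as.character(utils::packageVersion("hollowcond")),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"))
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}
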