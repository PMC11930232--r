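# File interchange: image stacks, traces, VTK flow snapshots, config.

#' Write a frame stack to numbered PNG or multi-page TIFF
#'
#' @param stack a `frame_stack` (or any list of `[0,1]` matrices under
#'   `$frames`).
#' @param path output file (`.tif`) or directory (numbered PNGs).
#' @return the path, invisibly.
#' @export
write_frame_stack <- function(stack, path) {
  frames <- stack$frames %||% stack
  if (grepl("\\.tiff?$", path, ignore.case = TRUE)) {
    if (!requireNamespace("tiff", quietly = TRUE))
      stop("the 'tiff' package is required for TIFF output", call. = FALSE)
    tiff::writeTIFF(frames, path, bits.per.sample = 8)
  } else {
    dir.create(path, showWarnings = FALSE, recursive = TRUE)
    for (i in seq_along(frames)) {
      png::writePNG(frames[[i]],
                    file.path(path, sprintf("frame_%05d.png", i)))
    }
  }
  invisible(path)
}

#' Read a frame stack from a TIFF file or a directory of PNGs
#'
#' @param path `.tif` file or directory with PNG frames.
#' @param dt frame interval (s).
#' @param pixel_scale mm per pixel.
#' @return a `frame_stack`.
#' @export
read_frame_stack <- function(path, dt, pixel_scale) {
  if (dir.exists(path)) {
    files <- sort(list.files(path, pattern = "\\.png$", full.names = TRUE))
    frames <- lapply(files, function(f) {
      img <- png::readPNG(f)
      if (length(dim(img)) == 3) img <- img[, , 1]
      img
    })
  } else {
    if (!requireNamespace("tiff", quietly = TRUE))
      stop("the 'tiff' package is required for TIFF input", call. = FALSE)
    frames <- tiff::readTIFF(path, all = TRUE)
  }
  structure(list(frames = frames, dt = dt, pixel_scale = pixel_scale),
            class = "frame_stack")
}

#' Write a rigid-motion trace as CSV
#'
#' Columns: frame, t, cm_x_mm, cm_y_mm, alpha_deg.
#'
#' @param rigid tibble (see [procrustes_isolate()]).
#' @param path output CSV.
#' @return the path, invisibly.
#' @export
write_rigid_trace <- function(rigid, path) {
  write.csv(rigid, path, row.names = FALSE)
  invisible(path)
}

#' Write a flow snapshot as a legacy-VTK structured-points file
#'
#' Cell-centered velocity, pressure, vorticity, Q-criterion and the solid
#' characteristic function on the uniform grid, readable by ParaView.
#'
#' @param flow a [flow_state()].
#' @param path output `.vtk` file.
#' @param chi optional solid characteristic function (cells).
#' @return the path, invisibly.
#' @export
write_vtk_snapshot <- function(flow, path, chi = NULL) {
  nx <- flow$nx; ny <- flow$ny; h <- flow$h
  cc <- cc_velocity(flow)
  om <- vorticity(flow); Q <- q_criterion(flow)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("# vtk DataFile Version 3.0",
               sprintf("zfescape flow t=%g", flow$t),
               "ASCII", "DATASET STRUCTURED_POINTS",
               sprintf("DIMENSIONS %d %d 1", nx, ny),
               sprintf("ORIGIN %g %g 0", h / 2, h / 2),
               sprintf("SPACING %g %g 1", h, h),
               sprintf("POINT_DATA %d", nx * ny)), con)
  scalars <- list(pressure = flow$p, vorticity = om, q_criterion = Q)
  if (!is.null(chi)) scalars$chi <- chi
  for (nm in names(scalars)) {
    writeLines(c(sprintf("SCALARS %s double 1", nm),
                 "LOOKUP_TABLE default"), con)
    writeLines(format(as.vector(scalars[[nm]]), digits = 7), con)
  }
  writeLines("VECTORS velocity double", con)
  vec <- cbind(as.vector(cc$u), as.vector(cc$v), 0)
  writeLines(apply(vec, 1, function(r) paste(format(r, digits = 7),
                                             collapse = " ")), con)
  invisible(path)
}

#' Read a solver/experiment configuration from YAML
#'
#' @param path YAML file.
#' @return named list.
#' @export
read_config <- function(path) yaml::read_yaml(path)
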