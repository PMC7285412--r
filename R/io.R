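#' Pipeline configuration
#'
#' All tunable parameters of the extraction/registration/smoothness/en face
#' pipeline with their default values: a 20-pixel first-peak search window,
#' noise level at mean + 3 SD of the saline region, ICP stopping at a
#' 0.01 um RMS difference between iterations (at most 200 iterations),
#' first-order waviness and fifth-order roughness references, and the en
#' face slab thickness series used for the two modalities.
#'
#' @param ... named overrides of the defaults; unknown names are rejected.
#' @return A named list of class `pipeline_config`.
#' @export
pipeline_config <- function(...) {
  cfg <- list(
    window_px = 20L,
    noise_k = 3,
    subpixel = FALSE,
    ct_min_run = 2L,
    ct_window_um = 500,
    ct_mad_k = NULL,
    icp_tol_um = 0.01,
    icp_max_iter = 200L,
    icp_trim = 1,
    waviness_order = 1L,
    roughness_order = 5L,
    slab_thickness_us_um = c(15, 45, 105, 150),
    slab_thickness_ct_um = c(21, 42, 105, 147),
    seed = 1L
  )
  ov <- list(...)
  if (length(ov)) {
    bad <- setdiff(names(ov), names(cfg))
    if (length(bad) || is.null(names(ov)) || any(names(ov) == ""))
      stop("unknown config keys: ", paste(bad, collapse = ", "))
    cfg[names(ov)] <- ov
  }
  for (nm in c("window_px", "ct_min_run", "icp_max_iter", "waviness_order",
               "roughness_order", "seed"))
    cfg[[nm]] <- as.integer(cfg[[nm]])
  for (nm in c("noise_k", "ct_window_um", "icp_tol_um", "icp_trim",
               "slab_thickness_us_um", "slab_thickness_ct_um"))
    cfg[[nm]] <- as.numeric(cfg[[nm]])
  if (!is.null(cfg$ct_mad_k)) cfg$ct_mad_k <- as.numeric(cfg$ct_mad_k)
  cfg$subpixel <- as.logical(cfg$subpixel)
  stopifnot(cfg$window_px >= 3, cfg$icp_tol_um > 0, cfg$icp_max_iter >= 1,
            cfg$waviness_order == 1L, cfg$roughness_order == 5L)
  class(cfg) <- "pipeline_config"
  cfg
}

#' Write / read a pipeline configuration as JSON
#'
#' Round-trips losslessly; unknown keys in the file are rejected.
#'
#' @param cfg a [pipeline_config()].
#' @param path file path.
#' @return `write_config` returns `path` invisibly; `read_config` returns a
#'   `pipeline_config`.
#' @export
write_config <- function(cfg, path) {
  stopifnot(inherits(cfg, "pipeline_config"))
  x <- unclass(cfg)
  x <- x[!vapply(x, is.null, logical(1L))]   # absent key = NULL (off)
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  do.call(pipeline_config, jsonlite::read_json(path, simplifyVector = TRUE))
}

config_hash <- function(cfg) rlang::hash(unclass(cfg))

#' Read a volumetric image stack
#'
#' Supported inputs: a multi-page TIFF file, a directory of single-frame
#' TIFF/PNG images (frame order = lexicographic file order), or a raw
#' float64 binary with a JSON header (as written by
#' `write_volume(format = "raw")`). TIFF intensities are rescaled by the
#' `scale` recorded in the JSON sidecar when present.
#'
#' @param path file or directory.
#' @param spacing `(elevational, axial, lateral)` um; mandatory unless a
#'   sidecar/header provides it.
#' @param origin physical origin, um.
#' @return A [volume3d()].
#' @export
read_volume <- function(path, spacing = NULL, origin = c(0, 0, 0)) {
  if (!file.exists(path)) stop("no such file or directory: ", path)
  sidecar <- paste0(path, ".json")
  meta <- if (file.exists(sidecar)) jsonlite::read_json(sidecar, simplifyVector = TRUE)
  if (grepl("\\.json$", path)) {           # raw + header
    meta <- jsonlite::read_json(path, simplifyVector = TRUE)
    bin <- file.path(dirname(path), meta$data)
    v <- readBin(bin, "double", n = prod(meta$dim))
    return(volume3d(array(v, dim = meta$dim), meta$spacing,
                    meta$origin %||% origin))
  }
  frames <- if (dir.exists(path)) {
    files <- sort(list.files(path, pattern = "\\.(tif|tiff|png)$",
                             ignore.case = TRUE, full.names = TRUE))
    if (!length(files)) stop("no image frames found in ", path)
    lapply(files, read_frame)
  } else {
    fr <- tiff::readTIFF(path, all = TRUE)
    if (!is.list(fr)) fr <- list(fr)
    fr
  }
  shp <- vapply(frames, dim, integer(2L))
  if (any(shp[1, ] != shp[1, 1]) || any(shp[2, ] != shp[2, 1]))
    stop("mixed frame shapes in volume")
  if (!is.null(meta)) {
    spacing <- spacing %||% meta$spacing
    origin <- meta$origin %||% origin
  }
  if (is.null(spacing)) stop("spacing must be supplied (argument or sidecar)")
  a <- aperm(simplify2array(frames), c(3L, 1L, 2L))
  if (!is.null(meta$scale)) a <- a * meta$scale
  volume3d(a, spacing, origin)
}

read_frame <- function(f) {
  if (grepl("\\.png$", f, ignore.case = TRUE)) {
    if (!requireNamespace("png", quietly = TRUE)) stop("png package required")
    png::readPNG(f)
  } else tiff::readTIFF(f)
}

#' Write a volume to disk
#'
#' `format = "tiff"` writes a 16-bit multi-page TIFF (intensities divided by
#' their maximum, recorded as `scale` in the JSON sidecar together with the
#' spacing, origin and config hash). `format = "raw"` writes the float64
#' array plus a JSON header and round-trips bit-exactly.
#'
#' @param vol a [volume3d()].
#' @param path output path (for `"raw"`, the `.json` header path).
#' @param format `"tiff"` or `"raw"`.
#' @param config optional [pipeline_config()] whose hash is recorded for
#'   provenance.
#' @return `path`, invisibly.
#' @export
write_volume <- function(vol, path, format = c("tiff", "raw"), config = NULL) {
  stopifnot(inherits(vol, "volume3d"))
  format <- match.arg(format)
  meta <- list(spacing = vol$spacing, origin = vol$origin,
               dim = dim(vol$intensities))
  if (!is.null(config)) meta$config_hash <- config_hash(config)
  if (format == "raw") {
    if (!grepl("\\.json$", path)) path <- paste0(path, ".json")
    bin <- sub("\\.json$", ".f64", basename(path))
    meta$data <- bin
    meta$dtype <- "float64"
    writeBin(as.vector(vol$intensities), file.path(dirname(path), bin))
    jsonlite::write_json(meta, path, auto_unbox = TRUE, digits = NA)
  } else {
    scale <- max(vol$intensities, 1e-12)
    meta$scale <- scale
    frames <- lapply(seq_len(n_frames(vol)),
                     function(i) pmin(pmax(vol$intensities[i, , ] / scale, 0), 1))
    tiff::writeTIFF(frames, path, bits.per.sample = 16L)
    jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                         digits = NA)
  }
  invisible(path)
}

#' Write a surface grid to disk
#'
#' `"stl"` writes an ASCII STL of the [surface_to_mesh()] triangulation in
#' millimetres (the conventional STL unit here); `"ply"` an ASCII PLY point
#' cloud in micrometres; `"csv"` the gridded height table (row =
#' elevational index, column = lateral index) with the spacings and origin
#' in header comment lines.
#'
#' @param s a [surface_grid()].
#' @param path output file.
#' @param format `"stl"`, `"ply"`, or `"csv"`.
#' @return `path`, invisibly.
#' @export
write_surface <- function(s, path, format = c("stl", "ply", "csv")) {
  stopifnot(inherits(s, "surface_grid"))
  format <- match.arg(format)
  if (format == "stl") {
    mesh <- surface_to_mesh(s)
    v <- mesh$vertices / 1000               # um -> mm
    f <- mesh$faces
    con <- file(path, "w")
    on.exit(close(con))
    writeLines("solid tidemark", con)
    a <- v[f[, 2], , drop = FALSE] - v[f[, 1], , drop = FALSE]
    b <- v[f[, 3], , drop = FALSE] - v[f[, 1], , drop = FALSE]
    nrm <- cbind(a[, 2] * b[, 3] - a[, 3] * b[, 2],
                 a[, 3] * b[, 1] - a[, 1] * b[, 3],
                 a[, 1] * b[, 2] - a[, 2] * b[, 1])
    nrm <- nrm / sqrt(rowSums(nrm^2))
    for (k in seq_len(nrow(f))) {
      writeLines(sprintf("facet normal %.9g %.9g %.9g", nrm[k, 1], nrm[k, 2],
                         nrm[k, 3]), con)
      writeLines("  outer loop", con)
      for (q in 1:3)
        writeLines(sprintf("    vertex %.9g %.9g %.9g", v[f[k, q], 1],
                           v[f[k, q], 2], v[f[k, q], 3]), con)
      writeLines(c("  endloop", "endfacet"), con)
    }
    writeLines("endsolid tidemark", con)
  } else if (format == "ply") {
    pts <- surface_to_pointcloud(s)
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(c("ply", "format ascii 1.0",
                 "comment units micrometres",
                 sprintf("element vertex %d", nrow(pts)),
                 "property double x", "property double y", "property double z",
                 "end_header"), con)
    writeLines(sprintf("%.12g %.12g %.12g", pts[, 1], pts[, 2], pts[, 3]), con)
  } else {
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(sprintf("# dy_um=%.12g dx_um=%.12g y0_um=%.12g x0_um=%.12g",
                       s$spacing[1], s$spacing[2], s$origin[1], s$origin[2]), con)
    write.table(format(s$heights, digits = 12, trim = TRUE, scientific = FALSE),
                con, sep = ",", row.names = FALSE, col.names = FALSE,
                quote = FALSE)
  }
  invisible(path)
}

#' Read a surface grid written as CSV
#'
#' @param path a file written by `write_surface(format = "csv")`.
#' @return A [surface_grid()] (validity mask all `TRUE`; the mask is not
#'   serialized in the CSV layout).
#' @export
read_surface_csv <- function(path) {
  hdr <- readLines(path, n = 1L)
  nums <- as.numeric(regmatches(hdr, gregexpr("-?[0-9.]+(e-?[0-9]+)?", hdr))[[1L]])
  h <- as.matrix(read.table(path, sep = ",", comment.char = "#"))
  surface_grid(unname(h), spacing = nums[1:2], origin = nums[3:4])
}
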