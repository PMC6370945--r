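# Raster I/O and the shared data containers.
#
# Conventions used throughout the package:
#   * raster coordinates are (row, col), 1-based as usual in R; z index 1 is
#     the most apical slice
#   * all angles are reported in degrees; orientations are axial (mod 180)
#   * intensities are handled as doubles internally whatever the on-disk depth

#' Clone-map region codes
#'
#' Genotype regions of a mosaic wing as stored on disk and in [CloneMap]
#' rasters: `0` = excluded, `1` = wild-type, `2` = mutant clone.
#' @export
CLONE_CODES <- c(excluded = 0L, wildtype = 1L, mutant = 2L)

#' Construct an image stack
#'
#' A z-ordered stack of single-channel fluorescence planes with voxel spacing
#' metadata. Voxels are stored as a `z x row x col` numeric array.
#'
#' @param voxels numeric array `z x row x col` (a matrix is promoted to a
#'   single-slice stack); all values must be finite and non-negative.
#' @param pixel_size_um lateral pixel size in micrometres.
#' @param z_step_um spacing between z slices in micrometres.
#' @param channel_name label of the imaged channel.
#' @return an `ImageStack` object.
#' @export
image_stack <- function(voxels, pixel_size_um = 0.1, z_step_um = 0.15,
                        channel_name = "") {
  if (is.matrix(voxels)) {
    voxels <- array(voxels, dim = c(1L, nrow(voxels), ncol(voxels)))
  }
  stopifnot(is.array(voxels), length(dim(voxels)) == 3L)
  if (!all(is.finite(voxels)) || any(voxels < 0)) {
    stop("stack intensities must be finite and >= 0")
  }
  d <- dim(voxels)
  if (d[1] < 1L || d[2] < 2L || d[3] < 2L) {
    stop("stack must have >= 1 slice and spatial dims >= 2x2")
  }
  if (!is.numeric(pixel_size_um) || pixel_size_um <= 0 ||
      !is.numeric(z_step_um) || z_step_um <= 0) {
    stop("pixel_size_um and z_step_um must be positive scalars")
  }
  structure(
    list(voxels = voxels * 1.0, pixel_size_um = pixel_size_um,
         z_step_um = z_step_um, channel_name = channel_name),
    class = "ImageStack")
}

#' @export
print.ImageStack <- function(x, ...) {
  d <- dim(x$voxels)
  cat(sprintf("ImageStack: %d slice(s), %d x %d px, pixel %.3g um, z-step %.3g um%s\n",
              d[1], d[2], d[3], x$pixel_size_um, x$z_step_um,
              if (nzchar(x$channel_name)) paste0(" [", x$channel_name, "]") else ""))
  invisible(x)
}

#' Extract one plane of a stack as a matrix
#' @param stack an [image_stack()].
#' @param z slice index (1-based from the apical side).
#' @return numeric matrix.
#' @export
stack_plane <- function(stack, z) {
  stopifnot(inherits(stack, "ImageStack"))
  d <- dim(stack$voxels)
  if (z < 1L || z > d[1]) stop("z out of range")
  matrix(stack$voxels[z, , ], d[2], d[3])
}

#' Construct a cell-label mask
#'
#' Integer raster of per-pixel cell identity: `0` marks membrane/background,
#' `k >= 1` marks cell `k`. Label values need not be consecutive.
#'
#' @param labels integer matrix of non-negative labels.
#' @return a `LabelMask` (integer matrix with class attribute).
#' @export
label_mask <- function(labels) {
  stopifnot(is.matrix(labels))
  if (any(!is.finite(labels)) || any(labels < 0) || any(labels != round(labels))) {
    stop("labels must be non-negative integers")
  }
  storage.mode(labels) <- "integer"
  structure(labels, class = c("LabelMask", "matrix", "array"))
}

#' Construct a clone (genotype-region) map
#'
#' @param regions integer matrix over the codes in [CLONE_CODES]
#'   (0 excluded, 1 wild-type, 2 mutant).
#' @return a `CloneMap` (integer matrix with class attribute).
#' @export
clone_map <- function(regions) {
  stopifnot(is.matrix(regions))
  if (!all(regions %in% CLONE_CODES)) {
    stop("unknown clone code: regions must be 0 (excluded), 1 (wildtype) or 2 (mutant)")
  }
  storage.mode(regions) <- "integer"
  structure(regions, class = c("CloneMap", "matrix", "array"))
}

#' IDs of the cells present in a label mask
#' @param label a [label_mask()].
#' @return sorted integer vector of nonzero labels.
#' @export
cell_ids <- function(label) sort(unique(as.integer(label[label > 0L])))

sidecar_path <- function(path) paste0(path, ".json")

#' Write an image stack to a multi-page TIFF
#'
#' Integer-valued stacks within 16-bit range are stored losslessly; other
#' stacks are stored as 32-bit float scaled into `[0, 1]`, with the scale
#' recorded in a JSON sidecar (`<path>.json`) together with the spacing
#' metadata, and undone on read.
#'
#' @param stack an [image_stack()].
#' @param path output file path (`.tif`).
#' @return `path`, invisibly.
#' @export
write_stack <- function(stack, path) {
  stopifnot(inherits(stack, "ImageStack"))
  v <- stack$voxels
  d <- dim(v)
  planes <- lapply(seq_len(d[1]), function(z) matrix(v[z, , ], d[2], d[3]))
  is_int <- all(v == round(v)) && max(v) <= 65535
  meta <- list(pixel_size_um = stack$pixel_size_um, z_step_um = stack$z_step_um,
               channel_name = stack$channel_name)
  if (is_int) {
    tiff::writeTIFF(lapply(planes, function(p) p / 65535), path,
                    bits.per.sample = 16L)
  } else {
    scale <- max(v)
    if (scale <= 0) scale <- 1
    tiff::writeTIFF(lapply(planes, function(p) p / scale), path,
                    bits.per.sample = 32L)
    meta$intensity_scale <- scale
  }
  jsonlite::write_json(meta, sidecar_path(path), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a single-channel image stack from TIFF
#'
#' Reads a single- or multi-page TIFF as one channel. Spacing metadata are
#' taken from the JSON sidecar written by [write_stack()] when present,
#' otherwise from the `config` list, otherwise defaults.
#'
#' @param path TIFF file path.
#' @param config optional list with `pixel_size_um`, `z_step_um`,
#'   `channel_name` used when no sidecar exists.
#' @return an [image_stack()].
#' @export
read_stack <- function(path, config = NULL) {
  if (!file.exists(path)) stop("cannot read stack: no such file: ", path)
  pages <- tryCatch(tiff::readTIFF(path, all = TRUE, info = TRUE),
                    error = function(e) stop("not a readable TIFF: ", path))
  if (!is.list(pages)) pages <- list(pages)
  if (any(vapply(pages, function(p) length(dim(p)) > 2L, logical(1)))) {
    stop("RGB/multi-sample TIFF rejected: one channel per file")
  }
  meta <- config
  sc <- sidecar_path(path)
  if (file.exists(sc)) meta <- jsonlite::read_json(sc, simplifyVector = TRUE)
  scale <- if (!is.null(meta$intensity_scale)) meta$intensity_scale else 1
  d <- dim(pages[[1]])
  v <- array(0, dim = c(length(pages), d[1], d[2]))
  for (z in seq_along(pages)) {
    p <- pages[[z]]
    bps <- attr(p, "bits.per.sample")
    # 8/16-bit TIFFs arrive scaled into [0,1]; 32-bit pages are true floats
    if (!is.null(bps) && bps < 32L) p <- round(p * (2^bps - 1))
    v[z, , ] <- p * scale
  }
  image_stack(v,
              pixel_size_um = if (!is.null(meta$pixel_size_um)) meta$pixel_size_um else 0.1,
              z_step_um = if (!is.null(meta$z_step_um)) meta$z_step_um else 0.15,
              channel_name = if (!is.null(meta$channel_name)) meta$channel_name else "")
}

#' Write an integer mask (labels or clone codes) to TIFF
#' @param mask a [label_mask()] or [clone_map()] (or plain integer matrix).
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_mask <- function(mask, path) {
  m <- unclass(mask)
  stopifnot(is.matrix(m), all(m >= 0), max(m) <= 65535)
  tiff::writeTIFF(m / 65535, path, bits.per.sample = 16L)
  invisible(path)
}

#' Read a cell-label mask and a clone map from raster files
#'
#' @param label_path TIFF/PNG of integer cell labels (0 = membrane).
#' @param clone_path TIFF/PNG of clone codes per [CLONE_CODES].
#' @return list with elements `label` ([label_mask()]) and `clone`
#'   ([clone_map()]); shapes are checked to agree.
#' @export
read_masks <- function(label_path, clone_path) {
  rd <- function(p) {
    if (!file.exists(p)) stop("cannot read mask: no such file: ", p)
    m <- tiff::readTIFF(p, info = TRUE)
    if (length(dim(m)) > 2L) stop("mask must be single-channel: ", p)
    bps <- attr(m, "bits.per.sample")
    if (!is.null(bps) && bps < 32L) m <- round(m * (2^bps - 1))
    matrix(as.vector(m), nrow(m), ncol(m))
  }
  lab <- rd(label_path)
  cln <- rd(clone_path)
  if (!all(dim(lab) == dim(cln))) {
    stop("label and clone rasters differ in shape: ",
         paste(dim(lab), collapse = "x"), " vs ", paste(dim(cln), collapse = "x"))
  }
  list(label = label_mask(lab), clone = clone_map(cln))
}

#' Assemble a tidy result table
#'
#' Long-format measurement table shared by all pipeline stages: one row per
#' (wing, region, measure) with a finite value.
#'
#' @param wing_id,genotype_region,measure,value equal-length vectors.
#' @return a `data.frame` with class `ResultTable`.
#' @export
result_table <- function(wing_id = character(), genotype_region = character(),
                         measure = character(), value = numeric()) {
  df <- data.frame(wing_id = as.character(wing_id),
                   genotype_region = as.character(genotype_region),
                   measure = as.character(measure),
                   value = as.numeric(value),
                   stringsAsFactors = FALSE)
  validate_result_table(df)
  class(df) <- c("ResultTable", "data.frame")
  df
}

validate_result_table <- function(df) {
  stopifnot(is.data.frame(df),
            all(c("wing_id", "genotype_region", "measure", "value") %in% names(df)))
  if (nrow(df) > 0) {
    if (any(is.na(df$wing_id) | !nzchar(df$wing_id))) stop("missing wing_id")
    if (any(!is.finite(df$value))) stop("non-finite value in result table")
  }
  invisible(df)
}

#' Write a result table to CSV
#'
#' Stable column order and default numeric formatting (15 significant digits),
#' so identical tables produce byte-identical files.
#'
#' @param table a [result_table()] (or compatible data frame).
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_results <- function(table, path) {
  validate_result_table(table)
  cols <- c("wing_id", "genotype_region", "measure", "value")
  extra <- setdiff(names(table), cols)
  df <- as.data.frame(table)[, c(cols, extra), drop = FALSE]
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Read a result table written by [write_results()]
#' @param path CSV path.
#' @return a `ResultTable` data frame.
#' @export
read_results <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  df$wing_id <- as.character(df$wing_id)
  validate_result_table(df)
  class(df) <- c("ResultTable", "data.frame")
  df
}
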