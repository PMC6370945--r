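# Geometric front end: brightest-slice selection, membrane skeleton with
# genotype region tags, and per-cell boundary sampling.

shift_mat <- function(m, dr, dc, fill = 0L) {
  H <- nrow(m); W <- ncol(m)
  out <- matrix(fill, H, W)
  rs <- max(1, 1 + dr):min(H, H + dr)
  cs <- max(1, 1 + dc):min(W, W + dc)
  out[rs, cs] <- m[rs - dr, cs - dc]
  out
}

NEIGH8 <- cbind(dr = c(-1, -1, -1, 0, 0, 1, 1, 1),
                dc = c(-1, 0, 1, -1, 1, -1, 0, 1))

#' Centroids of all cells in a label mask
#' @param label a [label_mask()].
#' @return matrix with rownames = cell id, columns `row`, `col`.
#' @export
cell_centroids <- function(label) {
  ids <- cell_ids(label)
  rows <- row(label)[label > 0L]
  cols <- col(label)[label > 0L]
  labs <- label[label > 0L]
  cr <- tapply(rows, labs, mean)
  cc <- tapply(cols, labs, mean)
  out <- cbind(row = cr[as.character(ids)], col = cc[as.character(ids)])
  rownames(out) <- as.character(ids)
  out
}

#' Build the membrane skeleton with genotype region tags
#'
#' Membrane pixels are 0-label pixels with at least two distinct nonzero
#' labels in their 3x3 (8-connected) neighbourhood. Each is tagged by the
#' genotypes of its adjacent cells (a cell's genotype is the clone code at
#' its centroid): `mutant` if all adjacent cells are mutant, `wildtype` if
#' all are wild-type, otherwise `excluded` — clone-border membranes are
#' shared between genotypes and counted in neither region.
#'
#' @param label a [label_mask()].
#' @param clone a [clone_map()] of the same shape.
#' @return a `MembraneSkeleton`: list with `pixels` (data frame `row`, `col`,
#'   `region`), `adjacent` (list of adjacent cell-id vectors per pixel),
#'   `cell_genotype` (named vector), and `dim`.
#' @export
build_skeleton <- function(label, clone) {
  if (!all(dim(label) == dim(clone))) stop("label and clone maps differ in shape")
  H <- nrow(label); W <- ncol(label)
  lab <- unclass(label)

  neigh <- lapply(seq_len(nrow(NEIGH8)), function(i)
    shift_mat(lab, NEIGH8[i, 1], NEIGH8[i, 2], fill = 0L))
  zi <- which(lab == 0L)
  if (length(zi) == 0) stop("no membrane pixels in label mask")
  nb <- vapply(neigh, function(m) m[zi], integer(length(zi)))
  if (is.null(dim(nb))) nb <- matrix(nb, nrow = 1)
  adj <- apply(nb, 1, function(v) sort(unique(v[v > 0L])), simplify = FALSE)
  keep <- lengths(adj) >= 2L
  if (!any(keep)) stop("no membrane pixels adjacent to two cells")
  zi <- zi[keep]
  adj <- adj[keep]

  cents <- cell_centroids(label)
  geno <- unclass(clone)[cbind(round(cents[, "row"]), round(cents[, "col"]))]
  names(geno) <- rownames(cents)

  region <- vapply(adj, function(cells) {
    g <- geno[as.character(cells)]
    if (all(g == CLONE_CODES[["mutant"]])) "mutant"
    else if (all(g == CLONE_CODES[["wildtype"]])) "wildtype"
    else "excluded"
  }, character(1))

  pixels <- data.frame(row = ((zi - 1L) %% H) + 1L,
                       col = ((zi - 1L) %/% H) + 1L,
                       region = region, stringsAsFactors = FALSE)
  structure(list(pixels = pixels, adjacent = adj, cell_genotype = geno,
                 dim = c(H, W)),
            class = "MembraneSkeleton")
}

#' @export
print.MembraneSkeleton <- function(x, ...) {
  cat(sprintf("MembraneSkeleton: %d pixels (%s)\n", nrow(x$pixels),
              paste(sprintf("%s %d", names(table(x$pixels$region)),
                            table(x$pixels$region)), collapse = ", ")))
  invisible(x)
}

skeleton_logical <- function(skeleton) {
  m <- matrix(FALSE, skeleton$dim[1], skeleton$dim[2])
  m[cbind(skeleton$pixels$row, skeleton$pixels$col)] <- TRUE
  m
}

#' Select and average the brightest junctional slices
#'
#' Scores each z slice by its mean intensity over membrane pixels, keeps the
#' `k` brightest (ties broken toward smaller z, i.e. the apical side), and
#' returns their pixelwise mean. This operationalizes selecting the slices
#' around the apicolateral junctions by brightness rather than by eye.
#'
#' @param stack an [image_stack()].
#' @param membrane a `MembraneSkeleton` or a logical matrix marking membrane
#'   pixels.
#' @param k number of slices to keep (default 3).
#' @return list with `plane` (mean of the chosen slices) and `chosen_z`
#'   (sorted 1-based slice indices).
#' @export
select_bright_slices <- function(stack, membrane, k = 3L) {
  stopifnot(inherits(stack, "ImageStack"))
  if (inherits(membrane, "MembraneSkeleton")) membrane <- skeleton_logical(membrane)
  stopifnot(is.matrix(membrane))
  d <- dim(stack$voxels)
  if (k > d[1]) stop("k exceeds the number of z slices")
  if (!any(membrane)) stop("membrane mask is empty")
  score <- vapply(seq_len(d[1]), function(z) mean(stack_plane(stack, z)[membrane]),
                  numeric(1))
  chosen <- sort(order(-score, seq_along(score))[seq_len(k)])
  planes <- lapply(chosen, function(z) stack_plane(stack, z))
  plane <- Reduce(`+`, planes) / k
  list(plane = plane, chosen_z = chosen)
}

#' Sample a cell's boundary intensities and axial directions
#'
#' One sample per skeleton pixel adjacent to the cell: its intensity on the
#' analysis plane and the axial direction `psi` (degrees, mod 180) of the
#' centroid-to-pixel vector, measured from the column (x) axis.
#'
#' @param plane 2D intensity matrix (e.g. from [select_bright_slices()]).
#' @param label a [label_mask()] of the same shape.
#' @param cell_id the cell to sample.
#' @param skeleton optional precomputed [build_skeleton()] result (any clone
#'   map may be used to build it; only adjacency is read here).
#' @return data frame of `BoundarySample`s: `row`, `col`, `intensity`, `psi`,
#'   `cell_id`.
#' @export
sample_cell_boundary <- function(plane, label, cell_id, skeleton = NULL) {
  stopifnot(all(dim(plane) == dim(label)))
  if (!cell_id %in% label) stop("cell ", cell_id, " not present in mask")
  if (is.null(skeleton)) {
    skeleton <- build_skeleton(label,
                               clone_map(matrix(CLONE_CODES[["wildtype"]],
                                                nrow(label), ncol(label))))
  }
  hit <- vapply(skeleton$adjacent, function(a) cell_id %in% a, logical(1))
  if (!any(hit)) stop("cell ", cell_id, " has no adjacent membrane pixels")
  px <- skeleton$pixels[hit, , drop = FALSE]
  idx <- which(unclass(label) == cell_id)
  crow <- mean(((idx - 1L) %% nrow(label)) + 1L)
  ccol <- mean(((idx - 1L) %/% nrow(label)) + 1L)
  psi <- (atan2(px$row - crow, px$col - ccol) * 180 / pi) %% 180
  data.frame(row = px$row, col = px$col,
             intensity = plane[cbind(px$row, px$col)],
             psi = psi, cell_id = cell_id)
}

#' Cells whose pixels touch the image border
#' @param label a [label_mask()].
#' @return integer vector of border cell ids.
#' @export
border_cells <- function(label) {
  ids <- unique(c(label[1, ], label[nrow(label), ],
                  label[, 1], label[, ncol(label)]))
  sort(ids[ids > 0L])
}
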