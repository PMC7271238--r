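# soma-volume morphometry on labeled/thresholdable 3D stacks

.check_voxel <- function(voxel_size) {
  if (is.null(voxel_size) || any(is.na(voxel_size)))
    stop(errorCondition("voxel size must be given explicitly (um per axis)",
                        class = c("picramp_configuration_error", "picramp_error")))
  if (!length(voxel_size) %in% c(1L, 3L) || any(voxel_size <= 0))
    stop(errorCondition("voxel size must be one value (isotropic) or three per-axis values",
                        class = c("picramp_configuration_error", "picramp_error")))
  rep_len(as.numeric(voxel_size), 3L)
}

#' Render a labeled 3D stack of spherical somata
#'
#' Places one sphere per requested volume at non-overlapping positions on a
#' coarse grid and voxelizes it (a voxel belongs to a sphere when its center
#' lies within the radius). Sphere centers sit on voxel centers. Synthetic
#' stand-in for a segmented two-photon stack; the fixture oracle for the
#' morphometry operations.
#'
#' @param volumes Numeric vector of target volumes (um^3); may be empty.
#' @param stack_shape Integer dimensions `c(nx, ny, nz)` of the stack.
#' @param voxel_size Voxel edge length(s), um (1 or 3 values).
#' @return Integer array of `stack_shape` with 0 = background and labels
#'   1..length(volumes).
#' @export
render_label_volume <- function(volumes, stack_shape = c(64, 64, 64),
                                voxel_size = 1) {
  vox <- .check_voxel(voxel_size)
  stack <- array(0L, dim = stack_shape)
  attr(stack, "voxel_size") <- vox
  if (!length(volumes)) return(stack)
  if (any(volumes <= 0)) stop_invalid("volumes must be positive")
  radii <- (3 * volumes / (4 * pi))^(1 / 3)       # um
  r_vox <- ceiling(radii / min(vox))
  # grid placement: cells of side 2*max radius + 1 voxel margin
  cell <- 2L * max(r_vox) + 3L
  per_axis <- pmax(1L, stack_shape %/% cell)
  if (prod(per_axis) < length(volumes))
    stop(errorCondition("cannot place all spheres without overlap in this stack",
                        class = c("picramp_placement_error", "picramp_error")))
  slots <- as.matrix(expand.grid(x = seq_len(per_axis[1]),
                                 y = seq_len(per_axis[2]),
                                 z = seq_len(per_axis[3])))
  ax <- lapply(1:3, function(k) (seq_len(stack_shape[k]) - 0.5) * vox[k])
  for (i in seq_along(volumes)) {
    center_vox <- (slots[i, ] - 1L) * cell + cell %/% 2L + 1L
    if (any(center_vox + r_vox[i] > stack_shape) || any(center_vox - r_vox[i] < 1))
      stop(errorCondition("sphere does not fit inside the stack",
                          class = c("picramp_placement_error", "picramp_error")))
    center <- (center_vox - 0.5) * vox
    xr <- which(abs(ax[[1]] - center[1]) <= radii[i])
    yr <- which(abs(ax[[2]] - center[2]) <= radii[i])
    zr <- which(abs(ax[[3]] - center[3]) <= radii[i])
    g <- expand.grid(x = xr, y = yr, z = zr)
    d2 <- (ax[[1]][g$x] - center[1])^2 + (ax[[2]][g$y] - center[2])^2 +
      (ax[[3]][g$z] - center[3])^2
    inside <- g[d2 <= radii[i]^2, ]
    stack[cbind(inside$x, inside$y, inside$z)] <- i
  }
  attr(stack, "voxel_size") <- vox
  stack
}

#' Segment somata as 6-connected components of a thresholded stack
#'
#' Foreground = voxels with intensity strictly above `threshold`; connected
#' components are computed on the 6-neighborhood adjacency graph (via
#' igraph) and components below `min_voxels` are discarded.
#'
#' @param stack 3D numeric/integer array.
#' @param threshold Intensity threshold (default 0: any positive voxel is
#'   foreground, which matches label stacks).
#' @param voxel_size Voxel edge length(s), um; defaults to the stack's
#'   `voxel_size` attribute. Anisotropic stacks require an explicit
#'   3-vector.
#' @param min_voxels Minimum component size retained.
#' @return List of `soma_region` objects: `label`, `coords` (n x 3 integer
#'   matrix of voxel indices), `voxel_size`.
#' @export
segment_somata <- function(stack, threshold = 0, voxel_size = NULL,
                           min_voxels = 27L) {
  if (length(dim(stack)) != 3L) stop_invalid("stack must be a 3D array")
  vox <- .check_voxel(if (is.null(voxel_size)) attr(stack, "voxel_size")
                      else voxel_size)
  fg <- which(stack > threshold)
  if (!length(fg)) return(list())
  dims <- dim(stack)
  pos <- arrayInd(fg, dims)
  # map linear voxel index -> vertex id among foreground voxels
  vid <- integer(prod(dims))
  vid[fg] <- seq_along(fg)
  edges <- integer(0)
  strides <- c(1L, dims[1], dims[1] * dims[2])
  for (k in 1:3) {
    ok <- pos[, k] < dims[k]
    nb <- fg[ok] + strides[k]
    has <- vid[nb] > 0L
    if (any(has))
      edges <- c(edges, rbind(vid[fg[ok]][has], vid[nb][has]))
  }
  g <- igraph::make_empty_graph(n = length(fg), directed = FALSE)
  if (length(edges)) g <- igraph::add_edges(g, edges)
  comp <- igraph::components(g)
  keep <- which(comp$csize >= min_voxels)
  out <- lapply(seq_along(keep), function(i) {
    members <- which(comp$membership == keep[i])
    structure(list(label = i,
                   coords = pos[members, , drop = FALSE],
                   voxel_size = vox),
              class = "soma_region")
  })
  first_voxel <- vapply(seq_along(keep), function(i)
    min(fg[comp$membership == keep[i]]), numeric(1))
  out <- out[order(first_voxel)]
  for (i in seq_along(out)) out[[i]]$label <- i
  out
}

#' @export
print.soma_region <- function(x, ...) {
  cat(sprintf("<soma_region> label %d: %d voxels, volume %.0f um^3, max diameter %.1f um\n",
              x$label, nrow(x$coords), soma_volume(x), max_diameter(x)))
  invisible(x)
}

#' Soma volume of a region
#'
#' Voxel count times voxel volume.
#'
#' @param region A `soma_region`.
#' @return Volume in um^3.
#' @export
soma_volume <- function(region) {
  stopifnot(inherits(region, "soma_region"))
  nrow(region$coords) * prod(region$voxel_size)
}

#' Maximum soma diameter of a region
#'
#' Maximal pairwise distance between surface-voxel centers (surface voxels
#' have fewer than six foreground 6-neighbors), floored at one voxel
#' diagonal so a single voxel reports its diagonal. For large regions the
#' candidate set is reduced to directional extremes before the exact
#' pairwise maximum, which is exact for convex shapes to within a voxel.
#'
#' @param region A `soma_region`.
#' @return Diameter in um.
#' @export
max_diameter <- function(region) {
  stopifnot(inherits(region, "soma_region"))
  vox <- region$voxel_size
  xyz <- sweep(region$coords, 2L, vox, `*`)
  diag_floor <- sqrt(sum(vox^2))
  n <- nrow(xyz)
  if (n == 1L) return(diag_floor)
  # surface voxels: fewer than 6 foreground neighbors
  key <- function(m) paste(m[, 1], m[, 2], m[, 3])
  have <- new.env(hash = TRUE, parent = emptyenv())
  for (k in key(region$coords)) assign(k, TRUE, envir = have)
  nb_count <- integer(n)
  shifts <- rbind(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0),
                  c(0, -1, 0), c(0, 0, 1), c(0, 0, -1))
  for (s in seq_len(6)) {
    nb <- sweep(region$coords, 2L, shifts[s, ], `+`)
    nb_count <- nb_count + vapply(key(nb), function(k)
      exists(k, envir = have, inherits = FALSE), logical(1))
  }
  surf <- xyz[nb_count < 6L, , drop = FALSE]
  if (nrow(surf) > 400L) {
    # deterministic Fibonacci-sphere direction set (no RNG side effects)
    k <- seq_len(60)
    phi <- acos(1 - 2 * (k - 0.5) / 60)
    theta <- pi * (1 + sqrt(5)) * (k - 0.5)
    dirs <- cbind(sin(phi) * cos(theta), sin(phi) * sin(theta), cos(phi))
    dirs <- rbind(dirs, diag(3), -diag(3))
    proj <- surf %*% t(dirs)
    cand <- unique(c(apply(proj, 2, which.min), apply(proj, 2, which.max)))
    surf <- surf[cand, , drop = FALSE]
  }
  d <- stats::dist(surf)
  max(max(d), diag_floor)
}

#' Bin soma volumes into a fixed-width histogram
#'
#' Half-open, lower-inclusive bins `[0, w), [w, 2w), ...` of width
#' `bin_width`; a value exactly on an edge goes to the upper bin.
#' Percentages are within-sample: count in bin / total count * 100.
#'
#' @param volumes Numeric vector of volumes (um^3).
#' @param bin_width Bin width (um^3), default 5000.
#' @param n_bins Optional fixed number of bins (to align histograms across
#'   groups); default: enough to cover `max(volumes)`.
#' @return Data frame with `bin_lo`, `bin_hi`, `count`, `pct`.
#' @export
histogram_volumes <- function(volumes, bin_width = 5000, n_bins = NULL) {
  if (!length(volumes)) stop_data("no volumes to bin")
  if (any(volumes < 0)) stop_invalid("volumes must be non-negative")
  if (is.null(n_bins)) n_bins <- floor(max(volumes) / bin_width) + 1L
  idx <- pmin(floor(volumes / bin_width), n_bins - 1L) + 1L
  count <- tabulate(idx, nbins = n_bins)
  data.frame(bin_lo = (seq_len(n_bins) - 1L) * bin_width,
             bin_hi = seq_len(n_bins) * bin_width,
             count = count,
             pct = 100 * count / length(volumes))
}

#' Cumulative upper-tail percentage of soma volumes
#'
#' Percentage of volumes strictly greater than `cutoff`.
#'
#' @param volumes Numeric vector of volumes (um^3).
#' @param cutoff Tail cutoff (um^3), default 15000.
#' @return Percentage in `[0, 100]`.
#' @export
tail_fraction <- function(volumes, cutoff = 15000) {
  if (!length(volumes)) return(0)
  100 * mean(volumes > cutoff)
}

#' Per-region morphometry table
#'
#' @param regions List of `soma_region`s (from [segment_somata()]).
#' @return Data frame with `label`, `volume_um3`, `max_diam_um`.
#' @export
region_table <- function(regions) {
  data.frame(label = vapply(regions, `[[`, numeric(1), "label"),
             volume_um3 = vapply(regions, soma_volume, numeric(1)),
             max_diam_um = vapply(regions, max_diameter, numeric(1)))
}

#' Write / read a label stack as a multi-page TIFF
#'
#' Thin wrappers around the `tiff` package (one z-slice per page, labels
#' scaled to `[0, 1]` by the maximum label on write and restored on read).
#'
#' @param stack Integer 3D array.
#' @param path TIFF file path.
#' @return `write_label_tiff`: `path` invisibly; `read_label_tiff`: the
#'   integer array.
#' @export
write_label_tiff <- function(stack, path) {
  if (!requireNamespace("tiff", quietly = TRUE))
    stop_data("the 'tiff' package is required for TIFF export")
  mx <- max(stack, 1L)
  pages <- lapply(seq_len(dim(stack)[3]), function(z) stack[, , z] / mx)
  tiff::writeTIFF(pages, path, bits.per.sample = 16L)
  jsonlite::write_json(list(max_label = mx,
                            voxel_size = attr(stack, "voxel_size")),
                       paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_label_tiff
#' @export
read_label_tiff <- function(path) {
  if (!requireNamespace("tiff", quietly = TRUE))
    stop_data("the 'tiff' package is required for TIFF import")
  pages <- tiff::readTIFF(path, all = TRUE)
  side <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  stack <- array(0L, dim = c(dim(pages[[1]]), length(pages)))
  for (z in seq_along(pages))
    stack[, , z] <- as.integer(round(pages[[z]] * side$max_label))
  attr(stack, "voxel_size") <- side$voxel_size
  stack
}
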