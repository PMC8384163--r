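#' Per-slice contour stack
#'
#' An ordered set of closed planar polygons, one or more slices each carrying
#' one polygon, delineating a structure (typically the pancreas) in the same
#' physical millimetre frame as the image volumes: a vertex `(x, y)` lies at
#' physical position x along the row axis and y along the column axis of the
#' grid, and `slice` is the 1-based slice number.  Polygons are implicitly
#' closed (first vertex not repeated).
#'
#' @param contours list of `list(slice = <integer>, vertices = <n x 2 numeric
#'   matrix, mm>)`; each polygon needs at least 3 vertices and slice numbers
#'   must be unique.  Stored sorted by ascending slice.
#' @param frame_spacing mm distance between contoured slices (slice thickness
#'   plus gap of the series the contours were drawn on).
#' @return an object of class `contour_stack`.
#' @export
contour_stack <- function(contours, frame_spacing) {
  check_spacing(frame_spacing, "frame_spacing", 1L)
  stopifnot(is.list(contours))
  contours <- lapply(contours, function(ct) {
    v <- ct$vertices
    if (is.data.frame(v)) v <- as.matrix(v)
    if (!is.matrix(v) || ncol(v) != 2L || !is.numeric(v))
      stop("contour vertices must be an n x 2 numeric matrix")
    if (nrow(v) >= 2L && all(v[1, ] == v[nrow(v), ]))
      v <- v[-nrow(v), , drop = FALSE]       # drop explicit closure
    if (nrow(v) < 3L)
      stop("polygon on slice ", ct$slice, " has fewer than 3 vertices")
    if (any(!is.finite(v))) stop("non-finite contour vertex on slice ", ct$slice)
    s <- ct$slice
    if (length(s) != 1L || !is.finite(s) || s != round(s))
      stop("contour slice index must be a single integer")
    list(slice = as.integer(s), vertices = unname(v))
  })
  slices <- vapply(contours, `[[`, integer(1), "slice")
  if (anyDuplicated(slices))
    stop("duplicate contour slice index: ",
         paste(unique(slices[duplicated(slices)]), collapse = ", "))
  structure(list(contours = contours[order(slices)],
                 frame_spacing = as.numeric(frame_spacing)),
            class = "contour_stack")
}

#' @export
print.contour_stack <- function(x, ...) {
  cat(sprintf("<contour_stack> %d slice contour(s), frame spacing %g mm\n",
              length(x$contours), x$frame_spacing))
  invisible(x)
}

#' Read / write contour stacks as JSON
#'
#' Contours persist in a small documented JSON schema:
#' `{"frame_spacing_mm": <mm>, "contours": [{"slice": <1-based int>,
#' "vertices_mm": [[x, y], ...]}, ...]}`.  Round-tripping preserves slice
#' indices exactly and vertex coordinates to at least 6 decimal places.
#'
#' @param path JSON file path.
#' @return `read_contours` returns a `contour_stack`; `write_contours`
#'   returns `path` invisibly.
#' @export
read_contours <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  doc <- jsonlite::fromJSON(path, simplifyVector = TRUE,
                            simplifyDataFrame = FALSE)
  if (is.null(doc$frame_spacing_mm) || is.null(doc$contours))
    stop("contour JSON schema error: need fields 'frame_spacing_mm' and 'contours'")
  contours <- lapply(doc$contours, function(ct) {
    if (is.null(ct$slice) || is.null(ct$vertices_mm))
      stop("contour JSON schema error: each contour needs 'slice' and 'vertices_mm'")
    v <- ct$vertices_mm
    if (is.list(v)) v <- do.call(rbind, v)
    list(slice = ct$slice, vertices = v)
  })
  contour_stack(contours, doc$frame_spacing_mm)
}

#' @rdname read_contours
#' @param stack a `contour_stack`.
#' @export
write_contours <- function(stack, path) {
  stopifnot(inherits(stack, "contour_stack"))
  doc <- list(
    frame_spacing_mm = stack$frame_spacing,
    contours = lapply(stack$contours, function(ct)
      list(slice = ct$slice, vertices_mm = ct$vertices)))
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

# Even-odd point-in-polygon, vectorized over points; points lying on a
# polygon edge (within eps, mm) count as inside for determinism on shared
# boundaries.
points_in_polygon <- function(px, py, vertices, eps = 1e-9) {
  n <- nrow(vertices)
  inside <- logical(length(px))
  on_edge <- logical(length(px))
  j <- n
  for (i in seq_len(n)) {
    x1 <- vertices[j, 1]; y1 <- vertices[j, 2]
    x2 <- vertices[i, 1]; y2 <- vertices[i, 2]
    crosses <- ((y1 > py) != (y2 > py)) &
      (px < x1 + (py - y1) * (x2 - x1) / (y2 - y1))
    crosses[is.na(crosses)] <- FALSE
    inside <- xor(inside, crosses)
    # on-segment test
    dx <- x2 - x1; dy <- y2 - y1
    len2 <- dx * dx + dy * dy
    if (len2 > 0) {
      t <- ((px - x1) * dx + (py - y1) * dy) / len2
      t <- pmin(pmax(t, 0), 1)
      d2 <- (px - (x1 + t * dx))^2 + (py - (y1 + t * dy))^2
      on_edge <- on_edge | d2 <= eps^2
    } else {
      on_edge <- on_edge | ((px - x1)^2 + (py - y1)^2 <= eps^2)
    }
    j <- i
  }
  inside | on_edge
}

#' Rasterize contours to a binary mask
#'
#' Builds the whole-structure region of interest on the target grid: a voxel
#' is inside (1) iff its physical center lies inside the polygon of its slice
#' under the even-odd rule, with centers on the polygon boundary counted
#' inside.  Slices without contours are all-outside.  This re-gridding of the
#' traced outline to each parametric map's own resolution is the mechanism by
#' which one set of contours serves maps of different resolution.
#'
#' @param stack a `contour_stack` with slice indices valid on `target`.
#' @param target a `grid_spec` (or `image_volume`).
#' @return a binary `image_volume` mask (0/1) on the target grid.
#' @export
rasterize_contours <- function(stack, target) {
  stopifnot(inherits(stack, "contour_stack"))
  if (inherits(target, "image_volume")) target <- grid_of(target)
  stopifnot(inherits(target, "grid_spec"))
  slices <- vapply(stack$contours, `[[`, integer(1), "slice")
  bad <- slices < 1L | slices > target$shape[3]
  if (any(bad))
    stop("contour slice index out of target range [1, ", target$shape[3],
         "]: ", paste(slices[bad], collapse = ", "))
  ax <- grid_axes(target)
  px <- rep(ax$x, times = target$shape[2])
  py <- rep(ax$y, each = target$shape[1])
  mask <- array(0, dim = target$shape)
  for (ct in stack$contours) {
    inside <- points_in_polygon(px, py, ct$vertices)
    mask[, , ct$slice] <- mask[, , ct$slice] + inside
  }
  mask[mask > 1] <- 1
  image_volume(mask, target$in_plane_spacing, target$slice_spacing,
               origin = target$origin, description = "contour mask",
               space = target$space)
}
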