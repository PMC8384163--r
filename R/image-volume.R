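#' 3D image volume
#'
#' The basic carrier of all acquisitions and parametric maps: a 3D scalar
#' array on an axial grid with physical voxel spacing.  Voxel `[i, j, k]`
#' (1-based) has its physical center at
#' `origin + c((i - 1) * in_plane_spacing[1], (j - 1) * in_plane_spacing[2],
#' (k - 1) * slice_spacing)` millimetres.  The first array axis is the
#' in-plane row direction (x), the second the in-plane column direction (y),
#' and the third the slice (body) axis, increasing monotonically along it.
#' Invalid voxels carry the reserved sentinel `NA`; every operation in the
#' package propagates it.
#'
#' @param data numeric 3D array (row, column, slice).  `NA`/`NaN` entries are
#'   stored as the invalid-voxel sentinel `NA`; all other values must be
#'   finite.
#' @param in_plane_spacing length-1 or length-2 positive numeric, mm per voxel
#'   along the row and column axes.
#' @param slice_spacing positive numeric, mm between slice centers (slice
#'   thickness plus gap).
#' @param origin length-3 numeric, mm position of the center of voxel
#'   `[1, 1, 1]`.
#' @param description free-text acquisition label (stored in the NIfTI
#'   `descrip` field on write).
#' @param space label of the physical coordinate frame; volumes and grids can
#'   only be combined when their frames match.
#' @return an object of class `image_volume`.
#' @seealso [grid_spec()], [read_volume()], [regrid_volume()]
#' @export
image_volume <- function(data, in_plane_spacing, slice_spacing,
                         origin = c(0, 0, 0), description = "",
                         space = "scanner") {
  if (!is.array(data) || length(dim(data)) != 3L)
    stop("`data` must be a 3D array, got ", length(dim(data)), " dimension(s)")
  storage.mode(data) <- "double"
  data[is.nan(data)] <- NA_real_
  if (any(is.infinite(data)))
    stop("`data` contains infinite values; flag invalid voxels with NA instead")
  if (length(in_plane_spacing) == 1L)
    in_plane_spacing <- rep(in_plane_spacing, 2L)
  check_spacing(in_plane_spacing, "in_plane_spacing", 2L)
  check_spacing(slice_spacing, "slice_spacing", 1L)
  stopifnot(is.numeric(origin), length(origin) == 3L, all(is.finite(origin)))
  structure(
    list(data = data,
         in_plane_spacing = as.numeric(in_plane_spacing),
         slice_spacing = as.numeric(slice_spacing),
         origin = as.numeric(origin),
         description = as.character(description)[1L],
         space = as.character(space)[1L]),
    class = "image_volume")
}

check_spacing <- function(x, name, len) {
  if (!is.numeric(x) || length(x) != len || any(!is.finite(x)) || any(x <= 0))
    stop("`", name, "` must be ", len, " strictly positive finite value(s)")
  invisible(x)
}

#' @export
print.image_volume <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<image_volume> %d x %d x %d, spacing %g x %g x %g mm",
              d[1], d[2], d[3],
              x$in_plane_spacing[1], x$in_plane_spacing[2], x$slice_spacing))
  n_inv <- sum(is.na(x$data))
  if (n_inv > 0) cat(sprintf(", %d invalid voxel(s)", n_inv))
  if (nzchar(x$description)) cat(" [", x$description, "]", sep = "")
  cat("\n")
  invisible(x)
}

#' Target grid geometry
#'
#' Describes a voxel grid (shape, spacing, origin) without data, used as the
#' target of regridding and contour rasterization.
#'
#' @param shape length-3 positive integer vector `(rows, cols, slices)`.
#' @inheritParams image_volume
#' @return an object of class `grid_spec`.
#' @export
grid_spec <- function(shape, in_plane_spacing, slice_spacing,
                      origin = c(0, 0, 0), space = "scanner") {
  stopifnot(length(shape) == 3L, all(shape >= 1), all(shape == round(shape)))
  if (length(in_plane_spacing) == 1L)
    in_plane_spacing <- rep(in_plane_spacing, 2L)
  check_spacing(in_plane_spacing, "in_plane_spacing", 2L)
  check_spacing(slice_spacing, "slice_spacing", 1L)
  structure(
    list(shape = as.integer(shape),
         in_plane_spacing = as.numeric(in_plane_spacing),
         slice_spacing = as.numeric(slice_spacing),
         origin = as.numeric(origin),
         space = as.character(space)[1L]),
    class = "grid_spec")
}

#' @rdname grid_spec
#' @param volume an `image_volume`.
#' @export
grid_of <- function(volume) {
  stopifnot(inherits(volume, "image_volume"))
  grid_spec(dim(volume$data), volume$in_plane_spacing, volume$slice_spacing,
            volume$origin, volume$space)
}

# physical coordinates of voxel centers along each axis
grid_axes <- function(grid) {
  list(x = grid$origin[1] + (seq_len(grid$shape[1]) - 1) * grid$in_plane_spacing[1],
       y = grid$origin[2] + (seq_len(grid$shape[2]) - 1) * grid$in_plane_spacing[2],
       z = grid$origin[3] + (seq_len(grid$shape[3]) - 1) * grid$slice_spacing)
}

#' Voxel volume of a grid in cubic millimetres
#' @param grid a `grid_spec` or `image_volume`.
#' @export
voxel_volume_mm3 <- function(grid) {
  if (inherits(grid, "image_volume")) grid <- grid_of(grid)
  prod(grid$in_plane_spacing) * grid$slice_spacing
}

same_grid <- function(a, b, tol = 1e-6) {
  ga <- if (inherits(a, "image_volume")) grid_of(a) else a
  gb <- if (inherits(b, "image_volume")) grid_of(b) else b
  identical(ga$shape, gb$shape) &&
    all(abs(ga$in_plane_spacing - gb$in_plane_spacing) < tol) &&
    abs(ga$slice_spacing - gb$slice_spacing) < tol &&
    all(abs(ga$origin - gb$origin) < tol)
}

check_same_space <- function(a, b) {
  if (!identical(a$space, b$space))
    stop("coordinate frame mismatch: '", a$space, "' vs '", b$space,
         "'; volumes must share a physical frame (translation-only alignment)")
  invisible(TRUE)
}

#' Read / write an image volume as NIfTI-1
#'
#' Volumes are stored as standard NIfTI-1 files (`.nii` or `.nii.gz`): voxel
#' spacing in `pixdim`, the origin in the qform/sform offsets, and the
#' description in `descrip`.  Data are written as 64-bit floats so the
#' write-read round trip is bit exact; invalid (`NA`) voxels are encoded as
#' NaN, the conventional missing value of floating-point NIfTI, and flagged
#' `NA` again on read.
#'
#' @param path file path ending in `.nii` or `.nii.gz`.
#' @return `read_volume` returns an `image_volume`; `write_volume` returns
#'   `path` invisibly.
#' @export
read_volume <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  hdr <- tryCatch(RNifti::niftiHeader(path),
                  error = function(e) stop("malformed NIfTI file '", path,
                                           "': ", conditionMessage(e)))
  # validate the raw header before the reader sanitizes it
  pd <- hdr$pixdim[2:4]
  if (any(!is.finite(pd)) || any(pd <= 0))
    stop("non-positive voxel spacing in NIfTI header field `pixdim` of '",
         path, "': ", paste(pd, collapse = " x "))
  img <- tryCatch(RNifti::readNifti(path),
                  error = function(e) stop("malformed NIfTI file '", path,
                                           "': ", conditionMessage(e)))
  d <- dim(img)
  if (length(d) != 3L)
    stop("expected a 3D payload in '", path, "', got ", length(d),
         " dimensions (header field `dim`)")
  origin <- c(hdr$qoffset_x, hdr$qoffset_y, hdr$qoffset_z)
  if (any(!is.finite(origin))) origin <- c(0, 0, 0)
  image_volume(array(as.numeric(img), dim = d), pd[1:2], pd[3],
               origin = origin, description = hdr$descrip)
}

#' @rdname read_volume
#' @param volume an `image_volume`.
#' @export
write_volume <- function(volume, path) {
  stopifnot(inherits(volume, "image_volume"))
  img <- RNifti::asNifti(volume$data)
  RNifti::pixdim(img) <- c(volume$in_plane_spacing, volume$slice_spacing)
  q <- diag(c(volume$in_plane_spacing, volume$slice_spacing, 1))
  q[1:3, 4] <- volume$origin
  img <- RNifti::`qform<-`(img, structure(q, code = 2L))
  img <- RNifti::asNifti(img, datatype = "double")
  img$descrip <- volume$description
  RNifti::writeNifti(img, path, datatype = "double")
  invisible(path)
}

#' Regrid a volume onto a target grid
#'
#' Resamples `source` at the voxel centers of `target`, in physical
#' (millimetre) coordinates, assuming the two grids share an axis-aligned
#' frame (translation and resolution change only; no rotation).  Target
#' voxels whose centers fall outside the source extent (beyond the outermost
#' source voxel centers) are flagged invalid, as are trilinear outputs with
#' any invalid source neighbor.
#'
#' @param source an `image_volume`.
#' @param target a `grid_spec` (or `image_volume`, whose grid is used).
#' @param method `"trilinear"` (default) or `"nearest"`.
#' @return an `image_volume` on the target grid.
#' @export
regrid_volume <- function(source, target, method = c("trilinear", "nearest")) {
  method <- match.arg(method)
  stopifnot(inherits(source, "image_volume"))
  if (inherits(target, "image_volume")) target <- grid_of(target)
  stopifnot(inherits(target, "grid_spec"))
  check_same_space(source, target)

  src_dim <- dim(source$data)
  sp <- c(source$in_plane_spacing, source$slice_spacing)
  tsp <- c(target$in_plane_spacing, target$slice_spacing)
  # continuous (1-based) source index of each target voxel center, per axis
  idx <- lapply(1:3, function(ax) {
    tx <- target$origin[ax] + (seq_len(target$shape[ax]) - 1) * tsp[ax]
    ci <- (tx - source$origin[ax]) / sp[ax] + 1
    snap <- abs(ci - round(ci)) < 1e-9
    ci[snap] <- round(ci[snap])
    ci
  })

  nt <- prod(target$shape)
  ci <- array(rep(idx[[1]], times = nt / target$shape[1]), dim = target$shape)
  cj <- aperm(array(rep(idx[[2]], times = nt / target$shape[2]),
                    dim = target$shape[c(2, 1, 3)]), c(2, 1, 3))
  ck <- aperm(array(rep(idx[[3]], times = nt / target$shape[3]),
                    dim = target$shape[c(3, 1, 2)]), c(2, 3, 1))

  inside <- ci >= 1 & ci <= src_dim[1] &
            cj >= 1 & cj <= src_dim[2] &
            ck >= 1 & ck <= src_dim[3]
  inside[is.na(inside)] <- FALSE
  out <- array(NA_real_, dim = target$shape)

  if (method == "nearest") {
    ri <- pmin(pmax(round(ci), 1), src_dim[1])
    rj <- pmin(pmax(round(cj), 1), src_dim[2])
    rk <- pmin(pmax(round(ck), 1), src_dim[3])
    lin <- ri + (rj - 1) * src_dim[1] + (rk - 1) * src_dim[1] * src_dim[2]
    vals <- source$data[lin]
    out[inside] <- vals[inside]
  } else {
    f <- function(c0, n) { i0 <- floor(c0); i0[i0 >= n] <- n - 1; i0[i0 < 1] <- 1; i0 }
    i0 <- f(ci, src_dim[1]); j0 <- f(cj, src_dim[2]); k0 <- f(ck, src_dim[3])
    ti <- ci - i0; tj <- cj - j0; tk <- ck - k0
    acc <- array(0, dim = target$shape)
    for (di in 0:1) for (dj in 0:1) for (dk in 0:1) {
      w <- (if (di) ti else 1 - ti) * (if (dj) tj else 1 - tj) *
           (if (dk) tk else 1 - tk)
      lin <- (i0 + di) + (j0 + dj - 1) * src_dim[1] +
             (k0 + dk - 1) * src_dim[1] * src_dim[2]
      term <- w * source$data[lin]   # NA neighbors with w > 0 poison the sum
      term[w == 0] <- 0              # zero-weight neighbors cannot invalidate
      acc <- acc + term
    }
    out[inside] <- acc[inside]
  }

  image_volume(out, target$in_plane_spacing, target$slice_spacing,
               origin = target$origin, description = source$description,
               space = target$space)
}
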