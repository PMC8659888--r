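# Preprocessing: per-volume min-max normalization to [0, 1], cubic-spline
# resampling to 256x256 at 1 mm, reorientation to the RAS+ anatomical
# convention, and paired rotation/flip/translation augmentation.
# All slice coordinates are (row, col), 0-based, origin top-left.

#' Construct a volume
#'
#' @param voxels 3-d numeric array.
#' @param spacing mm per axis (length 3, strictly positive).
#' @param orientation three-letter axis-direction code (one of R/L, A/P,
#'   S/I per axis, e.g. `"RAS"`), giving the anatomical direction of
#'   increasing index along each array axis.
#' @return an object of class `dcnet_volume`.
#' @export
as_volume <- function(voxels, spacing = c(1, 1, 1), orientation = "RAS") {
  if (length(dim(voxels)) != 3L) stop("voxels must be a 3-d array")
  if (length(spacing) == 1L) spacing <- rep(spacing, 3L)
  if (any(spacing <= 0)) stop("spacing must be strictly positive")
  check_orientation(orientation)
  structure(list(voxels = voxels, spacing = as.numeric(spacing),
                 orientation = toupper(orientation)),
            class = "dcnet_volume")
}

axis_letters <- c(R = 1L, L = 1L, A = 2L, P = 2L, S = 3L, I = 3L)
positive_letter <- c("R", "A", "S")

check_orientation <- function(code) {
  if (is.null(code) || is.na(code) || !nzchar(code))
    stop("orientation metadata is missing; refusing to guess")
  code <- toupper(code)
  l <- strsplit(code, "")[[1]]
  if (length(l) != 3L || anyNA(axis_letters[l]) ||
      length(unique(axis_letters[l])) != 3L)
    stop("invalid orientation code: ", code)
  invisible(code)
}

#' Construct a paired slice
#'
#' @param image 2-d numeric matrix with values in \[0, 1\].
#' @param mask 2-d binary matrix of the same shape.
#' @return an object of class `slice_pair`.
#' @export
slice_pair <- function(image, mask) {
  if (!identical(dim(image), dim(mask)))
    stop("image and mask shapes differ")
  if (any(image < 0 | image > 1)) stop("image values must lie in [0, 1]")
  if (!all(mask %in% c(0, 1))) stop("mask must be binary")
  structure(list(image = image,
                 mask = matrix(as.integer(mask), nrow(mask), ncol(mask)),
                 fg_fraction = mean(mask != 0)),
            class = "slice_pair")
}

#' Min-max normalization to \[0, 1\]
#'
#' Rescales so the minimum maps to 0 and the maximum to 1 (a monotone,
#' order-preserving map).  A constant input has no contrast; it maps to
#' all zeros with a warning.
#'
#' @param x a numeric array or a `dcnet_volume`.
#' @return the normalized object (same type as the input).
#' @export
normalize <- function(x) {
  if (inherits(x, "dcnet_volume")) {
    x$voxels <- normalize(x$voxels)
    return(x)
  }
  if (any(!is.finite(x))) stop("non-finite voxel values")
  rng <- range(x)
  if (rng[1] == rng[2]) {
    warning("constant-valued input has no contrast; returning zeros")
    return(x * 0)
  }
  (x - rng[1]) / (rng[2] - rng[1])
}

#' Resample a 2-d slice to a fixed grid
#'
#' Maps the slice to `target_size` pixels per side at `target_spacing` mm
#' using separable natural cubic-spline interpolation for images
#' (reproduces linear ramps exactly) and nearest-neighbour sampling for
#' masks (preserves binarity).  Pixel `i` (0-based) is taken to lie at
#' physical coordinate `i * spacing`.
#'
#' @param image 2-d numeric matrix.
#' @param in_spacing mm per pixel of the input (scalar or length 2).
#' @param target_size output pixels per side (default 256).
#' @param target_spacing output mm per pixel (default 1).
#' @param method `"spline"` (images) or `"nearest"` (masks).
#' @return a `target_size` x `target_size` matrix.
#' @export
resample_slice <- function(image, in_spacing, target_size = 256L,
                           target_spacing = 1,
                           method = c("spline", "nearest")) {
  method <- match.arg(method)
  if (length(dim(image)) != 2L) stop("expected a 2-d slice")
  if (any(in_spacing <= 0)) stop("spacing must be positive")
  if (length(in_spacing) == 1L) in_spacing <- rep(in_spacing, 2L)
  out_coord <- (seq_len(target_size) - 1) * target_spacing
  interp_axis <- function(mat, spacing, axis) {
    src <- (seq_len(dim(mat)[axis]) - 1) * spacing
    if (method == "nearest") {
      idx <- vapply(out_coord, function(z) which.min(abs(src - z)), 0L)
      return(if (axis == 1L) mat[idx, , drop = FALSE]
             else mat[, idx, drop = FALSE])
    }
    if (axis == 1L) {
      apply(mat, 2, function(col)
        stats::spline(src, col, xout = out_coord, method = "natural")$y)
    } else {
      t(apply(mat, 1, function(row)
        stats::spline(src, row, xout = out_coord, method = "natural")$y))
    }
  }
  out <- interp_axis(image, in_spacing[1], 1L)
  out <- interp_axis(out, in_spacing[2], 2L)
  if (any(!is.finite(out)))
    stop("non-finite values after interpolation; corrupt input?")
  out
}

#' Reorient a volume to the RAS+ convention
#'
#' Permutes and flips the voxel axes so that increasing index along axes
#' 1, 2, 3 points Right, Anterior, Superior.  The voxel multiset is
#' unchanged; spacing follows the permutation.  Idempotent.
#'
#' @param volume a [as_volume()] object.
#' @return the reoriented volume with orientation `"RAS"`.
#' @export
reorient_ras <- function(volume) {
  stopifnot(inherits(volume, "dcnet_volume"))
  code <- check_orientation(volume$orientation)
  letters3 <- strsplit(code, "")[[1]]
  anat <- axis_letters[letters3]          # anatomical axis of each array axis
  perm <- match(1:3, anat)                # array axis supplying R, A, S
  v <- aperm(volume$voxels, perm)
  sp <- volume$spacing[perm]
  for (a in 1:3) {
    if (letters3[perm[a]] != positive_letter[a]) {
      idx <- rev(seq_len(dim(v)[a]))
      v <- switch(a, v[idx, , , drop = FALSE], v[, idx, , drop = FALSE],
                  v[, , idx, drop = FALSE])
    }
  }
  as_volume(v, sp, "RAS")
}

#' Transverse slices of a volume
#'
#' @param volume a `dcnet_volume` (reoriented to RAS+, so axis 3 is
#'   inferior-superior and each slice is a transverse plane).
#' @return list of 2-d matrices.
#' @export
volume_slices <- function(volume) {
  stopifnot(inherits(volume, "dcnet_volume"))
  lapply(seq_len(dim(volume$voxels)[3]), function(k) volume$voxels[, , k])
}

#' Read / write NIfTI volumes
#'
#' Thin wrappers around RNifti preserving spacing and orientation
#' metadata.
#'
#' @param path file path (`.nii` or `.nii.gz`).
#' @return `read_volume()`: a `dcnet_volume`.
#' @export
read_volume <- function(path) {
  img <- RNifti::readNifti(path)
  sp <- RNifti::pixdim(img)[1:3]
  vox <- array(as.numeric(img), dim(img))
  as_volume(vox, sp, RNifti::orientation(img))
}

#' @rdname read_volume
#' @param volume a `dcnet_volume`.
#' @export
write_volume <- function(volume, path) {
  stopifnot(inherits(volume, "dcnet_volume"))
  img <- RNifti::asNifti(volume$voxels)
  RNifti::pixdim(img) <- volume$spacing
  RNifti::writeNifti(img, path)
  invisible(path)
}

# ---- augmentation ----------------------------------------------------------

#' Augmentation parameters
#'
#' Each of rotation, flip and translation is applied independently with
#' its own probability; the rotation angle is uniform in
#' `[-max_angle, max_angle]` degrees and the shift uniform over integer
#' pixel offsets in `[-max_shift, max_shift]` per axis.
#'
#' @param max_angle rotation bound in degrees (default 10).
#' @param max_shift translation bound in pixels (default 10).
#' @param p_rotate,p_flip,p_shift per-transform application probabilities.
#' @return an object of class `augment_params`.
#' @export
augment_params <- function(max_angle = 10, max_shift = 10L,
                           p_rotate = 0.5, p_flip = 0.5, p_shift = 0.5) {
  structure(list(max_angle = max_angle, max_shift = as.integer(max_shift),
                 p_rotate = p_rotate, p_flip = p_flip, p_shift = p_shift),
            class = "augment_params")
}

# Sample an output grid from an input image under rotation (degrees,
# positive rotates content from row-axis toward column-axis), horizontal
# flip (columns reversed first) and integer shift (content moves by
# shift_r rows, shift_c cols), about the image center; zero fill outside.
affine_sample <- function(img, angle, flip, shift, nearest = FALSE) {
  h <- nrow(img); w <- ncol(img)
  cr <- (h - 1) / 2; cc <- (w - 1) / 2
  th <- angle * pi / 180
  rr <- matrix(rep(0:(h - 1), w), h, w) - cr
  cgrid <- matrix(rep(0:(w - 1), each = h), h, w) - cc
  # inverse map: undo shift, then rotation, then flip
  r2 <- rr - shift[1]
  c2 <- cgrid - shift[2]
  sr <- cos(th) * r2 + sin(th) * c2
  sc <- -sin(th) * r2 + cos(th) * c2
  if (flip) sc <- -sc
  sr <- sr + cr
  sc <- sc + cc
  if (nearest) {
    ri <- round(sr); ci <- round(sc)
    ok <- ri >= 0 & ri < h & ci >= 0 & ci < w
    out <- matrix(0, h, w)
    out[ok] <- img[cbind(ri[ok] + 1, ci[ok] + 1)]
    return(out)
  }
  r0 <- floor(sr); c0 <- floor(sc)
  fr <- sr - r0; fc <- sc - c0
  out <- matrix(0, h, w)
  gather <- function(ri, ci) {
    ok <- ri >= 0 & ri < h & ci >= 0 & ci < w
    v <- matrix(0, h, w)
    v[ok] <- img[cbind(ri[ok] + 1, ci[ok] + 1)]
    v
  }
  out <- gather(r0, c0) * (1 - fr) * (1 - fc) +
    gather(r0 + 1, c0) * fr * (1 - fc) +
    gather(r0, c0 + 1) * (1 - fr) * fc +
    gather(r0 + 1, c0 + 1) * fr * fc
  out
}

#' Apply a fixed geometric transform to an image/mask pair
#'
#' The same transform acts on both: bilinear interpolation for the image
#' (re-clamped to \[0, 1\]), nearest-neighbour for the mask (stays
#' binary).  Order: horizontal flip, then rotation about the center, then
#' translation; regions mapped from outside are zero.
#'
#' @param pair a `slice_pair`.
#' @param angle rotation in degrees (a point at offset (dr, dc) from the
#'   center maps to (dr cos a - dc sin a, dr sin a + dc cos a)).
#' @param flip reverse the column (left-right) axis.
#' @param shift integer `(rows, cols)` translation.
#' @return the transformed `slice_pair`.
#' @export
augment_apply <- function(pair, angle = 0, flip = FALSE, shift = c(0L, 0L)) {
  img <- affine_sample(pair$image, angle, flip, shift, nearest = FALSE)
  img[img < 0] <- 0
  img[img > 1] <- 1
  msk <- affine_sample(pair$mask, angle, flip, shift, nearest = TRUE)
  slice_pair(img, msk)
}

#' Randomly augment an image/mask pair
#'
#' Draws the transform from [augment_params()] using the current RNG
#' state and applies it with [augment_apply()].
#'
#' @param pair a `slice_pair`.
#' @param params an [augment_params()].
#' @return an augmented `slice_pair`.
#' @export
augment <- function(pair, params = augment_params()) {
  angle <- if (stats::runif(1) < params$p_rotate)
    stats::runif(1, -params$max_angle, params$max_angle) else 0
  flip <- stats::runif(1) < params$p_flip
  shift <- if (stats::runif(1) < params$p_shift)
    sample(seq(-params$max_shift, params$max_shift), 2, replace = TRUE)
  else c(0L, 0L)
  augment_apply(pair, angle, flip, shift)
}
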