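#' @importFrom stats optim rnorm runif sd var
#' @importFrom utils read.delim write.table
NULL

# ---- angles ----------------------------------------------------------------

deg2rad <- function(x) x * pi / 180
rad2deg <- function(x) x * 180 / pi

#' Canonicalize angles to the interval (-180, 180]
#'
#' Scanner-console angulation angles are reported as signed degrees; this
#' wraps arbitrary angles into the canonical range, resolving ties at
#' +/-180 to +180.
#'
#' @param x numeric vector of angles in degrees.
#' @return numeric vector in (-180, 180].
#' @export
canonical_angle <- function(x) {
  stopifnot(is.numeric(x), all(is.finite(x)))
  y <- x %% 360
  y[y > 180] <- y[y > 180] - 360
  y[y == -180] <- 180
  y
}

#' Angulation triple
#'
#' Voxel angulation as entered at the scanner console: rotation about the
#' x axis (`t_s`, the console's T>S angle), about the y axis (`t_c`, T>C)
#' and about the z axis (`rot`, in-plane rotation), all in degrees.
#'
#' @param t_s,t_c,rot rotation angles in degrees about x, y and z.
#' @return a named numeric vector of class `angulation`.
#' @export
angulation <- function(t_s, t_c, rot) {
  a <- c(t_s = t_s, t_c = t_c, rot = rot)
  if (!all(is.finite(a)))
    stop("angulation angles must be finite", call. = FALSE)
  structure(canonical_angle(a), names = c("t_s", "t_c", "rot"),
            class = "angulation")
}

as_angulation <- function(x) {
  if (inherits(x, "angulation")) return(x)
  stopifnot(is.numeric(x), length(x) == 3)
  angulation(x[[1]], x[[2]], x[[3]])
}

rot_x <- function(a) {
  c1 <- cos(a); s1 <- sin(a)
  matrix(c(1, 0, 0, 0, c1, s1, 0, -s1, c1), 3, 3)
}
rot_y <- function(a) {
  c1 <- cos(a); s1 <- sin(a)
  matrix(c(c1, 0, -s1, 0, 1, 0, s1, 0, c1), 3, 3)
}
rot_z <- function(a) {
  c1 <- cos(a); s1 <- sin(a)
  matrix(c(c1, s1, 0, -s1, c1, 0, 0, 0, 1), 3, 3)
}

#' Rotation matrix from an angulation triple
#'
#' Builds the 3x3 rotation matrix for the intrinsic x -> y -> z sequence,
#' i.e. `R = Rz(rot) %*% Ry(t_c) %*% Rx(t_s)`. This single convention is
#' used everywhere in the package, for both construction and decomposition,
#' so round trips are exact away from gimbal lock.
#'
#' @param a an [angulation()] or numeric length-3 `(t_s, t_c, rot)` degrees.
#' @return 3x3 orthonormal matrix with determinant +1.
#' @seealso [angulation_from_rotation()]
#' @export
rotation_from_angulation <- function(a) {
  a <- as_angulation(a)
  r <- deg2rad(unclass(a))
  rot_z(r[3]) %*% rot_y(r[2]) %*% rot_x(r[1])
}

is_rotation_matrix <- function(m, tol = 1e-6) {
  is.matrix(m) && all(dim(m) == c(3, 3)) && all(is.finite(m)) &&
    max(abs(crossprod(m) - diag(3))) < tol && abs(det(m) - 1) < tol
}

#' Angulation triple from a rotation matrix
#'
#' Decomposes a rotation matrix under the package's `Rz %*% Ry %*% Rx`
#' convention. Gimbal lock (`t_c` within 0.01 degrees of +/-90) is refused
#' explicitly rather than silently resolving the x/z ambiguity.
#'
#' @param m 3x3 rotation matrix (orthonormal within 1e-6, det +1).
#' @return an [angulation()] with angles in (-180, 180].
#' @export
angulation_from_rotation <- function(m) {
  if (!is_rotation_matrix(m))
    stop("'m' is not an orthonormal rotation matrix (det +1) within 1e-6",
         call. = FALSE)
  s <- -m[3, 1]
  s <- min(1, max(-1, s))
  t_c <- asin(s)
  if (abs(abs(rad2deg(t_c)) - 90) < 0.01)
    stop("gimbal lock: |t_c| within 0.01 deg of 90; ",
         "x/z angles are not separable for this orientation", call. = FALSE)
  t_s <- atan2(m[3, 2], m[3, 3])
  rot <- atan2(m[2, 1], m[1, 1])
  angulation(rad2deg(t_s), rad2deg(t_c), rad2deg(rot))
}

# ---- voxel specification ---------------------------------------------------

valid_orientation_label <- function(x) {
  if (!is.character(x) || length(x) != 1 || nchar(x) != 3) return(FALSE)
  ch <- strsplit(toupper(x), "")[[1]]
  pairs <- list(c("L", "R"), c("A", "P"), c("S", "I"))
  used <- vapply(ch, function(c1) {
    hit <- vapply(pairs, function(p) c1 %in% p, logical(1))
    if (!any(hit)) return(NA_integer_)
    which(hit)
  }, integer(1))
  !anyNA(used) && length(unique(used)) == 3
}

#' Single-voxel prescription
#'
#' The complete scanner-entry description of one MRS voxel: its dimensions,
#' centre coordinate (mm, world frame of the named image), angulation about
#' each axis, and the image orientation label (e.g. `"LAS"`).
#'
#' @param study study name (character scalar).
#' @param description voxel description, e.g. `"l_dlpfc"`.
#' @param dims length-3 positive voxel dimensions in mm.
#' @param center length-3 centre coordinate in mm (world frame).
#' @param angulation an [angulation()] or numeric `(t_s, t_c, rot)` degrees.
#' @param orientation 3-letter axis-order label, one letter from each of
#'   L/R, A/P, S/I.
#' @return object of class `voxel_spec`.
#' @export
voxel_spec <- function(study, description, dims, center, angulation,
                       orientation = "LAS") {
  stopifnot(is.character(study), length(study) == 1,
            is.character(description), length(description) == 1,
            is.numeric(dims), length(dims) == 3,
            is.numeric(center), length(center) == 3,
            all(is.finite(dims)), all(is.finite(center)))
  if (any(dims <= 0))
    stop("voxel dimensions must be strictly positive", call. = FALSE)
  if (!valid_orientation_label(orientation))
    stop("'orientation' must be a 3-letter label with one letter from each ",
         "of {L/R}, {A/P}, {S/I}, e.g. \"LAS\"", call. = FALSE)
  structure(list(study = study, description = description,
                 dims = as.numeric(dims), center = as.numeric(center),
                 angulation = as_angulation(angulation),
                 orientation = toupper(orientation)),
            class = "voxel_spec")
}

#' @export
print.voxel_spec <- function(x, ...) {
  cat(sprintf("<voxel_spec> %s / %s [%s]\n", x$study, x$description,
              x$orientation))
  cat(sprintf("  dims   : %g x %g x %g mm (%.2f cm^3)\n",
              x$dims[1], x$dims[2], x$dims[3], nominal_volume(x) / 1000))
  cat(sprintf("  center : (%g, %g, %g) mm\n",
              x$center[1], x$center[2], x$center[3]))
  cat(sprintf("  angles : T>S %g, T>C %g, Rot %g deg\n",
              x$angulation[1], x$angulation[2], x$angulation[3]))
  invisible(x)
}

#' Nominal (unrotated) voxel volume in mm^3
#' @param spec a [voxel_spec()].
#' @export
nominal_volume <- function(spec) prod(spec$dims)

#' Is a voxel spec rotated?
#'
#' A spec counts as unrotated iff all three angulation angles are zero
#' within 1e-6 degrees; this drives threshold selection.
#'
#' @param spec a [voxel_spec()].
#' @export
is_rotated <- function(spec) any(abs(unclass(spec$angulation)) > 1e-6)

#' Pose difference between two voxel prescriptions
#'
#' Componentwise translation and rotation-angle differences of `b` relative
#' to `a` (`b - a`), the bookkeeping used when comparing acquired voxels
#' against a template row for row-wise delta reporting.
#'
#' @param a,b [voxel_spec()] objects in the same frame.
#' @return list with `translation` (mm triple) and `rotation`
#'   (degree triple, canonicalized to (-180, 180]).
#' @export
delta_pose <- function(a, b) {
  stopifnot(inherits(a, "voxel_spec"), inherits(b, "voxel_spec"))
  if (!identical(a$orientation, b$orientation))
    stop("voxel specs have different orientation labels: ",
         a$orientation, " vs ", b$orientation, call. = FALSE)
  list(translation = b$center - a$center,
       rotation = canonical_angle(unclass(b$angulation) -
                                    unclass(a$angulation)))
}

#' Corner coordinates of a voxel prescription
#'
#' The eight corners of the rotated cuboid,
#' `center + R %*% (+-dx/2, +-dy/2, +-dz/2)`.
#'
#' @param spec a [voxel_spec()].
#' @return 8x3 matrix of corner coordinates in mm.
#' @export
voxel_corners <- function(spec) {
  stopifnot(inherits(spec, "voxel_spec"))
  R <- rotation_from_angulation(spec$angulation)
  h <- spec$dims / 2
  signs <- as.matrix(expand.grid(x = c(-1, 1), y = c(-1, 1), z = c(-1, 1)))
  corners <- t(R %*% t(signs * rep(h, each = 8))) +
    matrix(spec$center, 8, 3, byrow = TRUE)
  dimnames(corners) <- list(NULL, c("x", "y", "z"))
  corners
}

# ---- homogeneous transforms ------------------------------------------------

#' Rigid (6-dof) spatial transform
#'
#' A homogeneous 4x4 world-to-world transform whose linear part is a proper
#' rotation. Validated on construction: `t(R) %*% R = I` and `det(R) = 1`
#' within 1e-8.
#'
#' @param rotation 3x3 rotation matrix.
#' @param translation length-3 translation in mm.
#' @param matrix alternatively, a full 4x4 homogeneous matrix.
#' @return object of class `c("rigid_transform", "spatial_transform")`.
#' @export
rigid_transform <- function(rotation = diag(3), translation = c(0, 0, 0),
                            matrix = NULL) {
  if (!is.null(matrix)) {
    stopifnot(all(dim(matrix) == c(4, 4)))
    rotation <- matrix[1:3, 1:3]
    translation <- matrix[1:3, 4]
  }
  if (max(abs(crossprod(rotation) - diag(3))) > 1e-8 ||
      abs(det(rotation) - 1) > 1e-8)
    stop("rigid transform rotation must be orthonormal with det +1 ",
         "within 1e-8", call. = FALSE)
  m <- diag(4)
  m[1:3, 1:3] <- rotation
  m[1:3, 4] <- translation
  structure(list(matrix = m), class = c("rigid_transform",
                                        "spatial_transform"))
}

#' Rotation + anisotropic scale (9-dof) spatial transform
#'
#' A homogeneous 4x4 transform whose linear part decomposes as
#' rotation times positive diagonal scale (no shear), validated by polar
#' decomposition within 1e-6.
#'
#' @param rotation 3x3 rotation matrix.
#' @param scales length-3 positive scale factors.
#' @param translation length-3 translation in mm.
#' @param matrix alternatively, a full 4x4 homogeneous matrix.
#' @return object of class `c("affine_transform9", "spatial_transform")`.
#' @export
affine_transform9 <- function(rotation = diag(3), scales = c(1, 1, 1),
                              translation = c(0, 0, 0), matrix = NULL) {
  if (!is.null(matrix)) {
    stopifnot(all(dim(matrix) == c(4, 4)))
    A <- matrix[1:3, 1:3]
    translation <- matrix[1:3, 4]
    # polar-style factorization for the no-shear case: A = R diag(s)
    s <- sqrt(colSums(A^2))
    rotation <- sweep(A, 2, s, "/")
    scales <- s
  }
  if (any(scales <= 0))
    stop("scale factors must be positive", call. = FALSE)
  if (max(abs(crossprod(rotation) - diag(3))) > 1e-6 ||
      abs(det(rotation) - 1) > 1e-6)
    stop("9-dof transform must decompose as rotation %*% diag(scales): ",
         "rotation factor not orthonormal within 1e-6", call. = FALSE)
  m <- diag(4)
  m[1:3, 1:3] <- rotation %*% diag(scales)
  m[1:3, 4] <- translation
  structure(list(matrix = m, scales = as.numeric(scales)),
            class = c("affine_transform9", "spatial_transform"))
}

#' @export
print.spatial_transform <- function(x, ...) {
  cat(sprintf("<%s>\n", class(x)[1]))
  print(round(x$matrix, 6))
  invisible(x)
}

as_transform_matrix <- function(t) {
  if (inherits(t, "spatial_transform")) return(t$matrix)
  if (is.matrix(t) && all(dim(t) == c(4, 4))) return(t)
  stop("not a spatial transform or 4x4 matrix", call. = FALSE)
}

#' Compose two spatial transforms
#'
#' Returns the transform applying `b` first, then `a` (matrix product
#' `a %*% b`).
#'
#' @param a,b spatial transforms or 4x4 matrices.
#' @export
tf_compose <- function(a, b) {
  m <- as_transform_matrix(a) %*% as_transform_matrix(b)
  wrap_transform(m, rigid = inherits(a, "rigid_transform") &&
                   inherits(b, "rigid_transform"))
}

#' Invert a spatial transform
#' @param t spatial transform or 4x4 matrix.
#' @export
tf_invert <- function(t) {
  m <- solve(as_transform_matrix(t))
  wrap_transform(m, rigid = inherits(t, "rigid_transform"))
}

wrap_transform <- function(m, rigid = FALSE) {
  if (rigid) rigid_transform(matrix = m) else affine_transform9(matrix = m)
}

#' Apply a spatial transform to points
#'
#' @param t spatial transform or 4x4 matrix.
#' @param pts n x 3 matrix or length-3 vector of mm coordinates.
#' @return transformed coordinates, same shape as input.
#' @export
tf_apply <- function(t, pts) {
  m <- as_transform_matrix(t)
  single <- is.null(dim(pts))
  if (single) pts <- matrix(pts, 1, 3)
  out <- pts %*% t(m[1:3, 1:3]) + matrix(m[1:3, 4], nrow(pts), 3,
                                         byrow = TRUE)
  if (single) as.numeric(out) else out
}
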