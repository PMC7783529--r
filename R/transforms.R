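#' Affine transform in model units
#'
#' A 3x3 linear part plus a translation vector, applied to vertices as
#' `v %*% t(linear) + translation`. The linear part must be invertible.
#'
#' @param linear 3x3 numeric matrix (default identity).
#' @param translation numeric length-3 vector (default zero).
#' @return An object of class `affine_transform`.
#' @seealso [bake_transform()], [transform_scale()], [transform_translate()],
#'   [transform_compose()]
#' @export
affine_transform <- function(linear = diag(3), translation = c(0, 0, 0)) {
  linear <- as.matrix(linear)
  storage.mode(linear) <- "double"
  translation <- as.double(translation)
  if (!identical(dim(linear), c(3L, 3L))) stop("linear part must be 3x3")
  if (length(translation) != 3L) stop("translation must have length 3")
  d <- det(linear)
  if (!is.finite(d) || d == 0) stop("singular linear part: transform not invertible")
  structure(list(linear = linear, translation = translation),
            class = "affine_transform")
}

#' @rdname affine_transform
#' @param s scale factor(s): a scalar for uniform scaling or a length-3 vector.
#' @export
transform_scale <- function(s) {
  if (length(s) == 1L) s <- rep(s, 3L)
  affine_transform(diag(as.double(s)))
}

#' @rdname affine_transform
#' @param v translation vector, length 3.
#' @export
transform_translate <- function(v) affine_transform(diag(3), v)

#' @rdname affine_transform
#' @param t2,t1 transforms; `transform_compose(t2, t1)` applies `t1` first.
#' @export
transform_compose <- function(t2, t1) {
  affine_transform(t2$linear %*% t1$linear,
                   drop(t2$linear %*% t1$translation) + t2$translation)
}

#' Bake an affine transform into vertex coordinates
#'
#' Mirrors the Blender "apply transform" operation the original measurement
#' workflow used before measuring: every vertex is replaced by the transformed
#' point and the object-level transform is discarded. When the determinant of
#' the linear part is negative (a mirror), face winding is flipped so outward
#' orientation — and hence the sign of the volume — is preserved.
#'
#' @param mesh a [triangle_mesh()].
#' @param t an [affine_transform()].
#' @return The transformed mesh.
#' @export
bake_transform <- function(mesh, t) {
  stopifnot(inherits(mesh, "triangle_mesh"), inherits(t, "affine_transform"))
  mesh$vertices <- mesh$vertices %*% t(t$linear) +
    matrix(t$translation, nrow(mesh$vertices), 3L, byrow = TRUE)
  if (det(t$linear) < 0) mesh <- flip_faces(mesh)
  mesh
}
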