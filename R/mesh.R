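#' Triangle mesh of a single cell
#'
#' A named, indexed triangle surface. Vertices are kept in the file's native
#' "model units"; conversion to physical units happens only through an explicit
#' [calibrate()] step downstream. Faces are stored 1-based (R convention);
#' conversion to/from the 0-based PLY/STL disk conventions happens at the I/O
#' boundary only. Face winding is counter-clockwise when viewed from outside
#' for an outward-oriented surface.
#'
#' @param vertices numeric matrix, one row per vertex, 3 columns (x, y, z).
#' @param faces integer matrix, one row per triangle, 3 columns of 1-based
#'   vertex indices.
#' @param name cell identifier; conventionally the source file stem.
#' @param collection tissue-collection label from the source directory layout,
#'   or `NA` when the mesh was not read from a collection.
#' @return An object of class `triangle_mesh`: a list with elements `name`,
#'   `vertices`, `faces`, `collection`.
#' @examples
#' cube <- make_box(c(1, 1, 1))
#' signed_volume(cube)
#' @export
triangle_mesh <- function(vertices, faces, name = "mesh", collection = NA_character_) {
  vertices <- as.matrix(vertices)
  storage.mode(vertices) <- "double"
  faces <- as.matrix(faces)
  storage.mode(faces) <- "integer"
  if (ncol(vertices) != 3L) stop("vertices must have 3 columns")
  if (ncol(faces) != 3L) stop("faces must have 3 columns (triangles only)")
  if (nrow(faces) == 0L) stop("empty mesh: no faces")
  if (!all(is.finite(vertices))) stop("vertex coordinates must be finite")
  if (any(faces < 1L) || any(faces > nrow(vertices)))
    stop("face index out of range [1, ", nrow(vertices), "]")
  degen <- faces[, 1L] == faces[, 2L] | faces[, 2L] == faces[, 3L] |
    faces[, 1L] == faces[, 3L]
  if (any(degen))
    stop("degenerate face(s) referencing the same vertex twice: rows ",
         paste(which(degen), collapse = ", "))
  dimnames(vertices) <- NULL
  dimnames(faces) <- NULL
  structure(
    list(name = as.character(name), vertices = vertices, faces = faces,
         collection = as.character(collection)),
    class = "triangle_mesh"
  )
}

#' @export
print.triangle_mesh <- function(x, ...) {
  cat(sprintf("<triangle_mesh '%s'%s: %d vertices, %d faces>\n",
              x$name,
              if (is.na(x$collection)) "" else paste0(" [", x$collection, "]"),
              nrow(x$vertices), nrow(x$faces)))
  invisible(x)
}

#' Reverse the winding of every face
#'
#' Flipping all faces negates the signed volume exactly.
#'
#' @param mesh a [triangle_mesh()].
#' @return The mesh with columns 2 and 3 of `faces` swapped.
#' @export
flip_faces <- function(mesh) {
  mesh$faces <- mesh$faces[, c(1L, 3L, 2L), drop = FALSE]
  mesh
}
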