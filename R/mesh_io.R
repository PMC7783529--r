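#' Read a triangle mesh from OBJ, PLY or STL
#'
#' Supported dialects: Wavefront OBJ (ASCII, `v`/`f` records, negative indices
#' resolved per the standard, other records ignored), PLY (ASCII and binary
#' little-endian, vertex + face elements), STL (ASCII and binary; vertices are
#' welded at exact coordinate equality on read). Polygonal faces with more
#' than three vertices are fan-triangulated from the first vertex. Coordinates
#' stay in the file's native model units; calibration to physical units is an
#' explicit downstream step ([calibrate()]).
#'
#' @param path file to read.
#' @param format `"obj"`, `"ply"`, `"stl"`, or `"auto"` (detect from the
#'   file extension).
#' @param name mesh name; defaults to the file stem.
#' @param collection optional tissue-collection label to attach.
#' @return A [triangle_mesh()].
#' @examples
#' f <- tempfile(fileext = ".obj")
#' write_mesh(make_box(c(2, 3, 4)), f)
#' m <- read_mesh(f)
#' signed_volume(m)  # 24
#' @export
read_mesh <- function(path, format = c("auto", "obj", "ply", "stl"),
                      name = NULL, collection = NA_character_) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    if (!ext %in% c("obj", "ply", "stl"))
      stop("cannot auto-detect mesh format from extension '", ext, "': ", path)
    format <- ext
  }
  parsed <- switch(format,
                   obj = read_obj(path),
                   ply = read_ply(path),
                   stl = read_stl(path))
  triangle_mesh(parsed$vertices, parsed$faces,
                name = if (is.null(name)) tools::file_path_sans_ext(basename(path)) else name,
                collection = collection)
}

#' Write a triangle mesh to OBJ, PLY or STL
#'
#' @inheritParams read_mesh
#' @param mesh a [triangle_mesh()].
#' @param binary for PLY/STL, write the binary encoding (PLY binary is
#'   little-endian with double-precision coordinates; STL binary stores
#'   float32 and is therefore lossy beyond single precision).
#' @return `path`, invisibly.
#' @export
write_mesh <- function(mesh, path, format = c("auto", "obj", "ply", "stl"),
                       binary = FALSE) {
  stopifnot(inherits(mesh, "triangle_mesh"))
  format <- match.arg(format)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    if (!ext %in% c("obj", "ply", "stl"))
      stop("cannot auto-detect mesh format from extension '", ext, "': ", path)
    format <- ext
  }
  switch(format,
         obj = write_obj(mesh, path),
         ply = write_ply(mesh, path, binary = binary),
         stl = write_stl(mesh, path, binary = binary))
  invisible(path)
}

#' Read a directory of tissue collections
#'
#' Expects the layout `<root>/<tissue>/<cell>.<ext>`: one subdirectory per
#' tissue collection, one mesh file per cell, mirroring how the Virtual Worm
#' groups cell objects into tissue collections. Cell names (file stems) must
#' be unique across the whole root. Ordering is deterministic: collections and
#' files in C-locale lexicographic order.
#'
#' @param root directory containing one subdirectory per tissue.
#' @return A list of [triangle_mesh()] objects with `collection` set to the
#'   subdirectory name.
#' @export
read_collection <- function(root) {
  if (!dir.exists(root)) stop("collection root not found: ", root)
  subs <- list.dirs(root, recursive = FALSE, full.names = TRUE)
  subs <- subs[order(basename(subs), method = "radix")]
  files <- unlist(lapply(subs, function(d) {
    fs <- list.files(d, pattern = "\\.(obj|ply|stl)$", ignore.case = TRUE,
                     full.names = TRUE)
    fs[order(basename(fs), method = "radix")]
  }))
  if (!length(files))
    stop("no mesh files (.obj/.ply/.stl) under collection root: ", root)
  meshes <- lapply(files, function(f)
    read_mesh(f, collection = basename(dirname(f))))
  nm <- vapply(meshes, `[[`, "", "name")
  if (anyDuplicated(nm)) {
    dups <- sort(unique(nm[duplicated(nm)]))
    stop("duplicate cell names across collections: ", paste(dups, collapse = ", "))
  }
  meshes
}
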