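# Wavefront OBJ, ASCII. Only v/f records are interpreted (vn/vt/usemtl and
# friends are ignored — anatomy-model exports carry no materials we need).
# Faces are 1-based on disk; negative indices are relative to the vertex count
# at the point of use, per the OBJ standard. N-gons are fan-triangulated from
# the first vertex.

read_obj <- function(path) {
  lines <- readLines(path, warn = FALSE)
  keys <- sub("^[ \t]*([^ \t]*).*$", "\\1", lines)

  v_lines <- which(keys == "v")
  verts <- matrix(numeric(0), 0L, 3L)
  if (length(v_lines)) {
    toks <- strsplit(trimws(lines[v_lines]), "[ \t]+")
    bad <- which(lengths(toks) < 4L)
    if (length(bad))
      stop(sprintf("OBJ format error in '%s' at line %d: vertex record needs 3 coordinates",
                   path, v_lines[bad[1L]]))
    verts <- t(vapply(toks, function(tk) {
      xyz <- suppressWarnings(as.numeric(tk[2:4]))
      xyz
    }, numeric(3)))
    if (anyNA(verts)) {
      bad <- v_lines[which(rowSums(is.na(verts)) > 0L)[1L]]
      stop(sprintf("OBJ format error in '%s' at line %d: non-numeric vertex coordinate",
                   path, bad))
    }
  }

  f_lines <- which(keys == "f")
  if (!length(f_lines))
    stop(sprintf("empty mesh: '%s' contains no faces", path))

  # vertex count visible to each face line (negative-index resolution)
  n_before <- vapply(f_lines, function(i) sum(v_lines < i), integer(1))

  faces <- vector("list", length(f_lines))
  for (k in seq_along(f_lines)) {
    i <- f_lines[k]
    tk <- strsplit(trimws(lines[i]), "[ \t]+")[[1]][-1L]
    if (length(tk) < 3L)
      stop(sprintf("OBJ format error in '%s' at line %d: face needs >= 3 vertices", path, i))
    vi <- suppressWarnings(as.integer(sub("/.*$", "", tk)))
    if (anyNA(vi) || any(vi == 0L))
      stop(sprintf("OBJ format error in '%s' at line %d: bad face index", path, i))
    vi <- ifelse(vi < 0L, n_before[k] + vi + 1L, vi)
    if (any(vi < 1L) || any(vi > nrow(verts)))
      stop(sprintf("OBJ format error in '%s' at line %d: face index out of range", path, i))
    n <- length(vi)
    faces[[k]] <- cbind(vi[1L], vi[2:(n - 1L)], vi[3:n])
  }
  list(vertices = verts, faces = do.call(rbind, faces))
}

write_obj <- function(mesh, path) {
  con <- file(path, "wb")  # binary: stable LF line endings
  on.exit(close(con))
  writeLines(c(
    sprintf("# %s", mesh$name),
    sprintf("v %.17g %.17g %.17g",
            mesh$vertices[, 1L], mesh$vertices[, 2L], mesh$vertices[, 3L]),
    sprintf("f %d %d %d", mesh$faces[, 1L], mesh$faces[, 2L], mesh$faces[, 3L])
  ), con)
  invisible(path)
}
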