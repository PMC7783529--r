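# STL, ASCII and binary. STL carries bare triangle soup (no vertex indexing),
# so on read vertices are welded at exact coordinate equality to recover the
# connectivity that watertightness validation needs. Binary STL stores float32
# coordinates: a write/read round trip is exact only for float32-representable
# values; ASCII STL is written at full double precision.

.stl_weld <- function(tri_coords) {
  # tri_coords: (3*nfaces) x 3 matrix, consecutive triples are one facet
  key <- sprintf("%a|%a|%a", tri_coords[, 1L], tri_coords[, 2L], tri_coords[, 3L])
  uk <- !duplicated(key)
  verts <- tri_coords[uk, , drop = FALSE]
  idx <- match(key, key[uk])
  list(vertices = verts,
       faces = matrix(idx, ncol = 3L, byrow = TRUE))
}

.stl_is_binary <- function(path) {
  sz <- file.size(path)
  if (sz < 84) return(FALSE)
  con <- file(path, "rb")
  on.exit(close(con))
  invisible(readBin(con, "raw", 80L))
  n <- readBin(con, "integer", 1L, size = 4L, endian = "little")
  !is.na(n) && n >= 0 && sz == 84 + 50 * as.double(n)
}

read_stl <- function(path) {
  if (.stl_is_binary(path)) {
    raw <- readBin(path, "raw", n = file.size(path))
    n <- readBin(raw[81:84], "integer", 1L, size = 4L, endian = "little")
    if (n == 0L) stop(sprintf("empty mesh: '%s' contains no facets", path))
    off <- 84L + 50L * (seq_len(n) - 1L)
    idx <- as.vector(outer(1:48, off, `+`))          # facet-major float block
    fl <- readBin(raw[idx], "numeric", n = 12L * n, size = 4L, endian = "little")
    block <- matrix(fl, nrow = 12L)                  # col per facet; rows 4:12 = vertices
    coords <- matrix(as.vector(block[4:12, ]), ncol = 3L, byrow = TRUE)
  } else {
    lines <- trimws(readLines(path, warn = FALSE))
    vlines <- grep("^vertex[ \t]", lines)
    if (!length(vlines)) stop(sprintf("empty mesh: '%s' contains no facets", path))
    if (length(vlines) %% 3L != 0L)
      stop(sprintf("STL format error in '%s': vertex count %d not a multiple of 3",
                   path, length(vlines)))
    toks <- strsplit(lines[vlines], "[ \t]+")
    coords <- t(vapply(toks, function(tk) suppressWarnings(as.numeric(tk[2:4])),
                       numeric(3)))
    if (anyNA(coords)) {
      bad <- vlines[which(rowSums(is.na(coords)) > 0L)[1L]]
      stop(sprintf("STL format error in '%s' at line %d: non-numeric vertex", path, bad))
    }
  }
  .stl_weld(coords)
}

write_stl <- function(mesh, path, binary = FALSE) {
  v <- mesh$vertices; f <- mesh$faces
  if (binary) {
    con <- file(path, "wb")
    on.exit(close(con))
    writeBin(rep(as.raw(0L), 80L), con)
    writeBin(nrow(f), con, size = 4L, endian = "little")
    for (i in seq_len(nrow(f))) {
      tri <- v[f[i, ], , drop = FALSE]
      nrm <- .face_normal(tri)
      writeBin(c(nrm, as.vector(t(tri))), con, size = 4L, endian = "little")
      writeBin(as.raw(c(0L, 0L)), con)
    }
  } else {
    con <- file(path, "wb")
    on.exit(close(con))
    out <- character(0)
    lines <- vector("list", nrow(f))
    for (i in seq_len(nrow(f))) {
      tri <- v[f[i, ], , drop = FALSE]
      nrm <- .face_normal(tri)
      lines[[i]] <- c(
        sprintf("  facet normal %.9g %.9g %.9g", nrm[1L], nrm[2L], nrm[3L]),
        "    outer loop",
        sprintf("      vertex %.17g %.17g %.17g", tri[, 1L], tri[, 2L], tri[, 3L]),
        "    endloop",
        "  endfacet")
    }
    writeLines(c(sprintf("solid %s", mesh$name),
                 unlist(lines),
                 sprintf("endsolid %s", mesh$name)), con)
  }
  invisible(path)
}

.face_normal <- function(tri) {
  e1 <- tri[2L, ] - tri[1L, ]
  e2 <- tri[3L, ] - tri[1L, ]
  n <- c(e1[2L] * e2[3L] - e1[3L] * e2[2L],
         e1[3L] * e2[1L] - e1[1L] * e2[3L],
         e1[1L] * e2[2L] - e1[2L] * e2[1L])
  len <- sqrt(sum(n^2))
  if (len > 0) n / len else c(0, 0, 0)
}
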