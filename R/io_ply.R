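# PLY, ASCII and binary little-endian. Only the vertex and face elements are
# supported; vertex properties may come in any order and any scalar type as
# long as x, y, z are present; the face element must be a single list property
# (vertex_indices / vertex_index), 0-based on disk.

.ply_type_size <- c(char = 1L, int8 = 1L, uchar = 1L, uint8 = 1L,
                    short = 2L, int16 = 2L, ushort = 2L, uint16 = 2L,
                    int = 4L, int32 = 4L, uint = 4L, uint32 = 4L,
                    float = 4L, float32 = 4L, double = 8L, float64 = 8L)
.ply_type_float <- c("float", "float32", "double", "float64")
.ply_type_signed <- c("char", "int8", "short", "int16", "int", "int32",
                      "float", "float32", "double", "float64")

.ply_read_scalar <- function(con, type, n = 1L) {
  sz <- .ply_type_size[[type]]
  if (type %in% .ply_type_float) {
    readBin(con, "numeric", n = n, size = sz, endian = "little")
  } else {
    readBin(con, "integer", n = n, size = sz,
            signed = sz == 4L || type %in% .ply_type_signed, endian = "little")
  }
}

read_ply <- function(path) {
  raw <- readBin(path, "raw", n = file.size(path))
  # locate end of header ("end_header" line)
  hdr_end <- NULL
  nl <- which(raw == as.raw(10L))
  txt_upto <- function(i) rawToChar(raw[seq_len(i)])
  for (i in nl) {
    h <- txt_upto(i)
    if (grepl("end_header\r?\n$", h)) { hdr_end <- i; break }
    if (i > 65536L) break
  }
  if (is.null(hdr_end)) stop(sprintf("PLY format error in '%s': no end_header", path))
  hdr <- strsplit(txt_upto(hdr_end), "\r?\n")[[1]]
  if (!length(hdr) || hdr[1L] != "ply")
    stop(sprintf("PLY format error in '%s': missing 'ply' magic", path))

  fmt_line <- grep("^format ", hdr, value = TRUE)
  if (length(fmt_line) != 1L)
    stop(sprintf("PLY format error in '%s': missing format line", path))
  fmt <- strsplit(fmt_line, "[ \t]+")[[1]][2L]
  if (!fmt %in% c("ascii", "binary_little_endian"))
    stop(sprintf("PLY format '%s' not supported in '%s'", fmt, path))

  # parse element/property declarations in order
  elements <- list(); cur <- NULL
  for (k in seq_along(hdr)) {
    ln <- hdr[k]
    tk <- strsplit(trimws(ln), "[ \t]+")[[1]]
    if (!length(tk)) next
    if (tk[1L] == "element") {
      if (!is.null(cur)) elements[[cur$name]] <- cur
      cur <- list(name = tk[2L], count = as.integer(tk[3L]), props = list())
    } else if (tk[1L] == "property") {
      if (is.null(cur))
        stop(sprintf("PLY format error in '%s' at header line %d: property before element", path, k))
      if (tk[2L] == "list") {
        cur$props[[length(cur$props) + 1L]] <-
          list(list = TRUE, count_type = tk[3L], type = tk[4L], name = tk[5L])
      } else {
        cur$props[[length(cur$props) + 1L]] <-
          list(list = FALSE, type = tk[2L], name = tk[3L])
      }
    }
  }
  if (!is.null(cur)) elements[[cur$name]] <- cur
  if (is.null(elements$vertex) || is.null(elements$face))
    stop(sprintf("PLY format error in '%s': need vertex and face elements", path))
  extra <- setdiff(names(elements), c("vertex", "face"))
  if (length(extra))
    stop(sprintf("PLY elements not supported in '%s': %s", path,
                 paste(extra, collapse = ", ")))

  vel <- elements$vertex; fel <- elements$face
  vprop_names <- vapply(vel$props, `[[`, "", "name")
  if (!all(c("x", "y", "z") %in% vprop_names))
    stop(sprintf("PLY format error in '%s': vertex element lacks x/y/z", path))
  if (any(vapply(vel$props, `[[`, TRUE, "list")))
    stop(sprintf("PLY format error in '%s': list-typed vertex property", path))
  if (length(fel$props) != 1L || !fel$props[[1L]]$list)
    stop(sprintf("PLY format error in '%s': face element must be one list property", path))

  if (fmt == "ascii") {
    body <- rawToChar(raw[(hdr_end + 1L):length(raw)])
    toks <- scan(text = body, what = character(), quiet = TRUE)
    p <- 1L
    nvp <- length(vel$props)
    need <- vel$count * nvp
    if (length(toks) < need)
      stop(sprintf("PLY format error in '%s': truncated vertex data", path))
    vmat <- matrix(as.numeric(toks[p:(p + need - 1L)]), vel$count, nvp, byrow = TRUE)
    p <- p + need
    verts <- vmat[, match(c("x", "y", "z"), vprop_names), drop = FALSE]
    faces <- vector("list", fel$count)
    for (i in seq_len(fel$count)) {
      n <- as.integer(toks[p]); p <- p + 1L
      if (is.na(n) || n < 3L)
        stop(sprintf("PLY format error in '%s': face %d has %s vertices", path, i, toks[p - 1L]))
      vi <- as.integer(toks[p:(p + n - 1L)]) + 1L; p <- p + n
      faces[[i]] <- cbind(vi[1L], vi[2:(n - 1L)], vi[3:n])
    }
  } else {
    con <- rawConnection(raw[(hdr_end + 1L):length(raw)])
    on.exit(close(con))
    vtypes <- vapply(vel$props, `[[`, "", "type")
    if (length(unique(vtypes)) == 1L) {
      vmat <- matrix(.ply_read_scalar(con, vtypes[1L], vel$count * length(vtypes)),
                     vel$count, length(vtypes), byrow = TRUE)
    } else {
      vmat <- matrix(0, vel$count, length(vtypes))
      for (i in seq_len(vel$count))
        for (j in seq_along(vtypes))
          vmat[i, j] <- .ply_read_scalar(con, vtypes[j])
    }
    verts <- vmat[, match(c("x", "y", "z"), vprop_names), drop = FALSE]
    fp <- fel$props[[1L]]
    faces <- vector("list", fel$count)
    for (i in seq_len(fel$count)) {
      n <- .ply_read_scalar(con, fp$count_type)
      if (!length(n) || is.na(n) || n < 3L)
        stop(sprintf("PLY format error in '%s': truncated or bad face record %d", path, i))
      vi <- .ply_read_scalar(con, fp$type, n) + 1L
      faces[[i]] <- cbind(vi[1L], vi[2:(n - 1L)], vi[3:n])
    }
  }
  if (anyNA(verts))
    stop(sprintf("PLY format error in '%s': non-numeric vertex data", path))
  list(vertices = verts, faces = do.call(rbind, faces))
}

write_ply <- function(mesh, path, binary = FALSE) {
  con <- file(path, "wb")
  on.exit(close(con))
  hdr <- c("ply",
           sprintf("format %s 1.0", if (binary) "binary_little_endian" else "ascii"),
           sprintf("comment %s", mesh$name),
           sprintf("element vertex %d", nrow(mesh$vertices)),
           "property double x", "property double y", "property double z",
           sprintf("element face %d", nrow(mesh$faces)),
           "property list uchar int vertex_indices",
           "end_header")
  writeLines(hdr, con)
  if (binary) {
    writeBin(as.vector(t(mesh$vertices)), con, size = 8L, endian = "little")
    f0 <- mesh$faces - 1L
    for (i in seq_len(nrow(f0))) {
      writeBin(as.raw(3L), con)
      writeBin(f0[i, ], con, size = 4L, endian = "little")
    }
  } else {
    writeLines(sprintf("%.17g %.17g %.17g",
                       mesh$vertices[, 1L], mesh$vertices[, 2L], mesh$vertices[, 3L]), con)
    writeLines(sprintf("3 %d %d %d",
                       mesh$faces[, 1L] - 1L, mesh$faces[, 2L] - 1L, mesh$faces[, 3L] - 1L), con)
  }
  invisible(path)
}
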