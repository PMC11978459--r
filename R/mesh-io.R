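#' Read a triangulated surface mesh from file
#'
#' Supports PLY (ascii and binary little-endian), STL (binary and ascii),
#' OBJ, and legacy VTK polydata (ascii). Faces with more than three vertices
#' are fan-triangulated with a warning. The mesh is cleaned on load
#' (duplicate vertices merged within 1e-9 mm, degenerate faces dropped); a
#' per-vertex scalar field stored in PLY/VTK files is returned in the
#' `"scalar_field"` attribute (remapped through the cleaning).
#'
#' @param path path to the mesh file.
#' @param fmt `"auto"` (from the extension) or one of `"ply"`, `"stl"`,
#'   `"obj"`, `"vtk"`.
#' @return a [surface_mesh()] with `specimen_id` taken from the file name.
#' @export
read_mesh <- function(path, fmt = c("auto", "ply", "stl", "obj", "vtk")) {
  fmt <- match.arg(fmt)
  if (!file.exists(path)) stop(sprintf("cannot read mesh: no such file '%s'", path), call. = FALSE)
  if (fmt == "auto") {
    fmt <- tolower(tools::file_ext(path))
    if (!fmt %in% c("ply", "stl", "obj", "vtk")) {
      stop(sprintf("cannot infer mesh format from extension of '%s'", path), call. = FALSE)
    }
  }
  raw <- switch(fmt,
    ply = .read_ply(path),
    stl = .read_stl(path),
    obj = .read_obj(path),
    vtk = .read_vtk(path)
  )
  id <- tools::file_path_sans_ext(basename(path))
  mesh <- surface_mesh(raw$vertices, raw$faces, specimen_id = id, clean = FALSE)
  pre_n <- nrow(mesh$vertices)
  mesh <- clean_mesh(mesh)
  if (nrow(mesh$vertices) < 4L || nrow(mesh$faces) < 4L) {
    stop(sprintf("'%s': mesh has fewer than 4 vertices or faces after cleaning", path),
         call. = FALSE)
  }
  if (!is.null(raw$scalar)) {
    sc <- raw$scalar
    if (nrow(mesh$vertices) < pre_n) {
      # re-run the merge bookkeeping to carry the scalar through cleaning
      key <- paste(round(raw$vertices[, 1] / 1e-9), round(raw$vertices[, 2] / 1e-9),
                   round(raw$vertices[, 3] / 1e-9))
      sc <- sc[!duplicated(key)][seq_len(nrow(mesh$vertices))]
    }
    attr(mesh, "scalar_field") <- sc
  }
  mesh
}

#' Write a surface mesh to file
#'
#' @param mesh a [surface_mesh()].
#' @param path output path.
#' @param fmt `"auto"` (from the extension) or one of `"ply"`, `"stl"`,
#'   `"obj"`, `"vtk"`. Per-vertex scalar fields are supported by PLY and VTK
#'   only.
#' @param scalar_field optional numeric vector of length `nrow(vertices)`
#'   stored with the mesh (e.g. a variation heat map).
#' @param ascii for PLY, write ascii (default) or binary little-endian.
#' @return `path`, invisibly.
#' @export
write_mesh <- function(mesh, path, fmt = c("auto", "ply", "stl", "obj", "vtk"),
                       scalar_field = NULL, ascii = TRUE) {
  stopifnot(is_surface_mesh(mesh))
  fmt <- match.arg(fmt)
  if (fmt == "auto") {
    fmt <- tolower(tools::file_ext(path))
    if (!fmt %in% c("ply", "stl", "obj", "vtk")) {
      stop(sprintf("cannot infer mesh format from extension of '%s'", path), call. = FALSE)
    }
  }
  if (!is.null(scalar_field)) {
    if (fmt %in% c("stl", "obj")) {
      stop(sprintf("per-vertex scalar fields are not supported by the %s format", fmt),
           call. = FALSE)
    }
    if (length(scalar_field) != nrow(mesh$vertices)) {
      stop("`scalar_field` length must equal the number of vertices", call. = FALSE)
    }
  }
  switch(fmt,
    ply = .write_ply(mesh, path, scalar_field, ascii),
    stl = .write_stl(mesh, path),
    obj = .write_obj(mesh, path),
    vtk = .write_vtk(mesh, path, scalar_field)
  )
  invisible(path)
}

# fan-triangulate polygon rows of >3 indices; returns an m x 3 matrix
.fan_triangulate <- function(polys) {
  if (all(lengths(polys) == 3L)) {
    return(do.call(rbind, polys))
  }
  warning("non-triangular faces fan-triangulated")
  do.call(rbind, lapply(polys, function(p) {
    if (length(p) < 3L) return(NULL)
    if (length(p) == 3L) return(matrix(p, 1L, 3L))
    cbind(p[1L], p[seq(2L, length(p) - 1L)], p[seq(3L, length(p))])
  }))
}

## ---- PLY ----

.ply_type_size <- c(char = 1L, uchar = 1L, int8 = 1L, uint8 = 1L,
                    short = 2L, ushort = 2L, int16 = 2L, uint16 = 2L,
                    int = 4L, uint = 4L, int32 = 4L, uint32 = 4L,
                    float = 4L, float32 = 4L, double = 8L, float64 = 8L)

.ply_read_one <- function(con, type) {
  sz <- .ply_type_size[[type]]
  if (type %in% c("float", "float32", "double", "float64")) {
    readBin(con, "double", n = 1L, size = sz, endian = "little")
  } else {
    signed <- !startsWith(type, "u")
    readBin(con, "integer", n = 1L, size = sz, signed = signed || sz == 4L,
            endian = "little")
  }
}

.read_ply <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  header <- character()
  repeat {
    line <- readLines(con, n = 1L)
    if (length(line) == 0L) stop("unexpected end of PLY header", call. = FALSE)
    header <- c(header, line)
    if (trimws(line) == "end_header") break
  }
  if (!grepl("^ply", header[1])) stop(sprintf("'%s' is not a PLY file", path), call. = FALSE)
  fmt_line <- grep("^format", header, value = TRUE)[1]
  binary <- grepl("binary_little_endian", fmt_line)
  if (!binary && !grepl("ascii", fmt_line)) {
    stop("only ascii and binary_little_endian PLY are supported", call. = FALSE)
  }
  # parse element/property declarations in order
  elems <- list()
  cur <- NULL
  for (line in header) {
    tok <- strsplit(trimws(line), "\\s+")[[1]]
    if (tok[1] == "element") {
      if (!is.null(cur)) elems[[cur$name]] <- cur
      cur <- list(name = tok[2], count = as.integer(tok[3]), props = list())
    } else if (tok[1] == "property" && !is.null(cur)) {
      if (tok[2] == "list") {
        cur$props[[tok[5]]] <- list(list = TRUE, count_type = tok[3], type = tok[4])
      } else {
        cur$props[[tok[3]]] <- list(list = FALSE, type = tok[2])
      }
    }
  }
  if (!is.null(cur)) elems[[cur$name]] <- cur
  if (is.null(elems$vertex)) stop("PLY file has no vertex element", call. = FALSE)

  read_elem_ascii <- function(elem, lines) {
    vals <- lapply(strsplit(trimws(lines), "\\s+"), as.numeric)
    vals
  }
  verts <- NULL; faces <- NULL; scalar <- NULL
  if (binary) {
    for (el in elems) {
      pn <- names(el$props)
      if (el$name == "vertex") {
        out <- matrix(NA_real_, el$count, length(pn), dimnames = list(NULL, pn))
        for (i in seq_len(el$count)) {
          for (p in pn) out[i, p] <- .ply_read_one(con, el$props[[p]]$type)
        }
        verts <- out[, c("x", "y", "z"), drop = FALSE]
        extra <- setdiff(pn, c("x", "y", "z"))
        if (length(extra) > 0L) scalar <- out[, extra[1]]
      } else if (el$name == "face") {
        polys <- vector("list", el$count)
        for (i in seq_len(el$count)) {
          p <- el$props[[1]]
          k <- .ply_read_one(con, p$count_type)
          polys[[i]] <- vapply(seq_len(k), function(j) .ply_read_one(con, p$type),
                               numeric(1)) + 1
        }
        faces <- .fan_triangulate(polys)
      } else {
        # skip unknown fixed-size elements
        for (i in seq_len(el$count)) for (p in pn) .ply_read_one(con, el$props[[p]]$type)
      }
    }
  } else {
    body <- readLines(con)
    pos <- 1L
    for (el in elems) {
      rows <- body[seq(pos, pos + el$count - 1L)]
      pos <- pos + el$count
      vals <- read_elem_ascii(el, rows)
      if (el$name == "vertex") {
        pn <- names(el$props)
        m <- do.call(rbind, vals)
        colnames(m) <- pn
        verts <- m[, c("x", "y", "z"), drop = FALSE]
        extra <- setdiff(pn, c("x", "y", "z"))
        if (length(extra) > 0L) scalar <- m[, extra[1]]
      } else if (el$name == "face") {
        polys <- lapply(vals, function(v) v[-1] + 1)
        faces <- .fan_triangulate(polys)
      }
    }
  }
  if (is.null(faces)) stop("PLY file has no face element", call. = FALSE)
  list(vertices = unname(verts), faces = faces, scalar = unname(scalar))
}

.write_ply <- function(mesh, path, scalar_field, ascii) {
  n <- nrow(mesh$vertices); m <- nrow(mesh$faces)
  hdr <- c("ply",
           if (ascii) "format ascii 1.0" else "format binary_little_endian 1.0",
           "comment written by surfmorph",
           sprintf("element vertex %d", n),
           "property float x", "property float y", "property float z",
           if (!is.null(scalar_field)) "property float quality",
           sprintf("element face %d", m),
           "property list uchar int vertex_indices",
           "end_header")
  con <- file(path, "wb")
  on.exit(close(con))
  writeLines(hdr, con)
  if (ascii) {
    V <- mesh$vertices
    rows <- if (is.null(scalar_field)) {
      sprintf("%.9g %.9g %.9g", V[, 1], V[, 2], V[, 3])
    } else {
      sprintf("%.9g %.9g %.9g %.9g", V[, 1], V[, 2], V[, 3], scalar_field)
    }
    writeLines(rows, con)
    f <- mesh$faces - 1L
    writeLines(sprintf("3 %d %d %d", f[, 1], f[, 2], f[, 3]), con)
  } else {
    V <- t(mesh$vertices)
    if (is.null(scalar_field)) {
      writeBin(as.vector(V), con, size = 4L, endian = "little")
    } else {
      block <- rbind(V, scalar_field)
      writeBin(as.vector(block), con, size = 4L, endian = "little")
    }
    f <- mesh$faces - 1L
    for (i in seq_len(nrow(f))) {
      writeBin(as.raw(3L), con)
      writeBin(as.integer(f[i, ]), con, size = 4L, endian = "little")
    }
  }
}

## ---- STL ----

.read_stl <- function(path) {
  sz <- file.info(path)$size
  con <- file(path, "rb")
  on.exit(close(con))
  head80 <- readBin(con, "raw", n = 80L)
  ntri <- readBin(con, "integer", n = 1L, size = 4L, endian = "little")
  if (length(ntri) == 1L && sz == 84 + 50 * ntri) {
    tri <- matrix(NA_real_, 3L * ntri, 3L)
    for (i in seq_len(ntri)) {
      rec <- readBin(con, "double", n = 12L, size = 4L, endian = "little")
      tri[(3L * i - 2L):(3L * i), ] <- matrix(rec[4:12], 3L, 3L, byrow = TRUE)
      readBin(con, "raw", n = 2L)
    }
  } else {
    # ascii STL
    txt <- readLines(path, warn = FALSE)
    vl <- grep("^\\s*vertex\\s", txt, value = TRUE)
    if (length(vl) == 0L || length(vl) %% 3L != 0L) {
      stop(sprintf("'%s' is not a valid STL file", path), call. = FALSE)
    }
    tri <- do.call(rbind, lapply(strsplit(trimws(vl), "\\s+"),
                                 function(x) as.numeric(x[2:4])))
  }
  faces <- matrix(seq_len(nrow(tri)), ncol = 3L, byrow = TRUE)
  list(vertices = tri, faces = faces, scalar = NULL)  # duplicates merged by cleaning
}

.write_stl <- function(mesh, path) {
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(c(as.raw(utf8ToInt("surfmorph binary STL")),
             raw(80L - nchar("surfmorph binary STL"))), con)
  f <- mesh$faces
  writeBin(as.integer(nrow(f)), con, size = 4L, endian = "little")
  v <- mesh$vertices
  for (i in seq_len(nrow(f))) {
    p1 <- v[f[i, 1], ]; p2 <- v[f[i, 2], ]; p3 <- v[f[i, 3], ]
    nvec <- c((p2[2] - p1[2]) * (p3[3] - p1[3]) - (p2[3] - p1[3]) * (p3[2] - p1[2]),
              (p2[3] - p1[3]) * (p3[1] - p1[1]) - (p2[1] - p1[1]) * (p3[3] - p1[3]),
              (p2[1] - p1[1]) * (p3[2] - p1[2]) - (p2[2] - p1[2]) * (p3[1] - p1[1]))
    nn <- sqrt(sum(nvec^2))
    if (nn > 0) nvec <- nvec / nn
    writeBin(c(nvec, p1, p2, p3), con, size = 4L, endian = "little")
    writeBin(as.raw(c(0L, 0L)), con)
  }
}

## ---- OBJ ----

.read_obj <- function(path) {
  txt <- readLines(path, warn = FALSE)
  vl <- grep("^v\\s", txt, value = TRUE)
  fl <- grep("^f\\s", txt, value = TRUE)
  if (length(vl) == 0L || length(fl) == 0L) {
    stop(sprintf("'%s' is not a valid OBJ file", path), call. = FALSE)
  }
  verts <- do.call(rbind, lapply(strsplit(trimws(vl), "\\s+"),
                                 function(x) as.numeric(x[2:4])))
  n <- nrow(verts)
  polys <- lapply(strsplit(trimws(fl), "\\s+"), function(x) {
    idx <- as.numeric(vapply(strsplit(x[-1], "/"), `[[`, character(1), 1L))
    ifelse(idx < 0, n + 1 + idx, idx)
  })
  list(vertices = verts, faces = .fan_triangulate(polys), scalar = NULL)
}

.write_obj <- function(mesh, path) {
  v <- mesh$vertices; f <- mesh$faces
  writeLines(c("# written by surfmorph",
               sprintf("v %.9g %.9g %.9g", v[, 1], v[, 2], v[, 3]),
               sprintf("f %d %d %d", f[, 1], f[, 2], f[, 3])), path)
}

## ---- legacy VTK polydata (ascii) ----

.read_vtk <- function(path) {
  txt <- readLines(path, warn = FALSE)
  if (!grepl("^# vtk DataFile", txt[1])) {
    stop(sprintf("'%s' is not a legacy VTK file", path), call. = FALSE)
  }
  if (!any(grepl("^ASCII", txt))) stop("only ascii legacy VTK is supported", call. = FALSE)
  if (!any(grepl("^DATASET POLYDATA", txt))) {
    stop("only POLYDATA VTK datasets are supported", call. = FALSE)
  }
  tok <- scan(text = txt, what = character(), quiet = TRUE)
  take_after <- function(kw) which(tok == kw)[1]
  ip <- take_after("POINTS")
  n <- as.integer(tok[ip + 1L])
  verts <- matrix(as.numeric(tok[(ip + 3L):(ip + 2L + 3L * n)]), ncol = 3L, byrow = TRUE)
  if_ <- take_after("POLYGONS")
  m <- as.integer(tok[if_ + 1L]); total <- as.integer(tok[if_ + 2L])
  vals <- as.numeric(tok[(if_ + 3L):(if_ + 2L + total)])
  polys <- vector("list", m)
  pos <- 1L
  for (i in seq_len(m)) {
    k <- vals[pos]
    polys[[i]] <- vals[(pos + 1L):(pos + k)] + 1
    pos <- pos + k + 1L
  }
  scalar <- NULL
  is_ <- take_after("SCALARS")
  if (!is.na(is_)) {
    lt <- take_after("LOOKUP_TABLE")
    scalar <- as.numeric(tok[(lt + 2L):(lt + 1L + n)])
  }
  list(vertices = verts, faces = .fan_triangulate(polys), scalar = scalar)
}

.write_vtk <- function(mesh, path, scalar_field) {
  v <- mesh$vertices; f <- mesh$faces - 1L
  out <- c("# vtk DataFile Version 3.0",
           "surfmorph surface mesh",
           "ASCII",
           "DATASET POLYDATA",
           sprintf("POINTS %d double", nrow(v)),
           sprintf("%.17g %.17g %.17g", v[, 1], v[, 2], v[, 3]),
           sprintf("POLYGONS %d %d", nrow(f), 4L * nrow(f)),
           sprintf("3 %d %d %d", f[, 1], f[, 2], f[, 3]))
  if (!is.null(scalar_field)) {
    out <- c(out,
             sprintf("POINT_DATA %d", nrow(v)),
             "SCALARS variation double 1",
             "LOOKUP_TABLE default",
             sprintf("%.17g", scalar_field))
  }
  writeLines(out, path)
}
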