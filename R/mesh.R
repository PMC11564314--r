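#' Triangle surface meshes
#'
#' A `trimesh` is a list with `vertices` (n x 3 numeric matrix, mm),
#' `faces` (m x 3 integer matrix, 1-based, counter-clockwise outward
#' orientation) and `components` (length-m integer vector labelling the
#' closed solid each face belongs to). A mesh may consist of several
#' watertight components; the modelled bone is the union of their interiors.
#'
#' @param vertices n x 3 numeric matrix of vertex positions (mm).
#' @param faces m x 3 integer matrix of vertex indices (1-based).
#' @param components optional integer vector of per-face component labels;
#'   computed from face connectivity when missing.
#' @param validate check watertightness and triangle quality (default TRUE).
#' @return An object of class `trimesh`.
#' @export
trimesh <- function(vertices, faces, components = NULL, validate = TRUE) {
  vertices <- as.matrix(vertices)
  storage.mode(vertices) <- "double"
  faces <- as.matrix(faces)
  storage.mode(faces) <- "integer"
  if (ncol(vertices) != 3L || ncol(faces) != 3L)
    stop("vertices and faces must have 3 columns")
  if (nrow(faces) == 0L) stop("empty mesh")
  if (min(faces) < 1L || max(faces) > nrow(vertices))
    stop("face indices out of range")
  if (is.null(components)) components <- mesh_components(faces)
  m <- structure(list(vertices = vertices, faces = faces,
                      components = as.integer(components)),
                 class = "trimesh")
  if (validate) validate_trimesh(m)
  m
}

#' @export
print.trimesh <- function(x, ...) {
  cat(sprintf("trimesh: %d vertices, %d faces, %d component(s)\n",
              nrow(x$vertices), nrow(x$faces), max(x$components)))
  invisible(x)
}

# connected components of faces via shared vertices (union-find)
mesh_components <- function(faces) {
  nv <- max(faces)
  parent <- seq_len(nv)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  for (r in seq_len(nrow(faces))) {
    a <- find(faces[r, 1]); b <- find(faces[r, 2]); c <- find(faces[r, 3])
    parent[b] <- a
    parent[find(c)] <- find(a)
  }
  roots <- vapply(faces[, 1], find, integer(1))
  match(roots, unique(roots))
}

#' Validate mesh invariants
#'
#' Checks that every undirected edge is shared by exactly two faces, that
#' every directed edge occurs exactly once (consistent orientation) and that
#' no triangle is degenerate (area below `area_tol`).
#'
#' @param mesh a [trimesh].
#' @param area_tol minimum admissible triangle area (mm^2).
#' @return `mesh`, invisibly; errors otherwise.
#' @export
validate_trimesh <- function(mesh, area_tol = 1e-10) {
  f <- mesh$faces
  v <- mesh$vertices
  e <- rbind(f[, c(1, 2)], f[, c(2, 3)], f[, c(3, 1)])
  key_dir <- paste(e[, 1], e[, 2])
  if (anyDuplicated(key_dir))
    stop("mesh is not watertight: duplicated directed edge (inconsistent orientation or duplicate face)")
  key_und <- paste(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]))
  cnt <- table(key_und)
  if (any(cnt != 2L))
    stop(sprintf("mesh is not watertight: %d edge(s) not shared by exactly two faces",
                 sum(cnt != 2L)))
  a <- v[f[, 2], ] - v[f[, 1], ]
  b <- v[f[, 3], ] - v[f[, 1], ]
  cx <- a[, 2] * b[, 3] - a[, 3] * b[, 2]
  cy <- a[, 3] * b[, 1] - a[, 1] * b[, 3]
  cz <- a[, 1] * b[, 2] - a[, 2] * b[, 1]
  area2 <- sqrt(cx^2 + cy^2 + cz^2)
  if (any(area2 < 2 * area_tol)) stop("mesh contains degenerate (zero-area) triangles")
  invisible(mesh)
}

#' @rdname validate_trimesh
#' @export
is_watertight <- function(mesh) {
  ok <- TRUE
  tryCatch(validate_trimesh(mesh), error = function(e) ok <<- FALSE)
  ok
}

# signed volume by divergence theorem; positive for outward orientation
mesh_volume <- function(mesh) {
  v <- mesh$vertices
  f <- mesh$faces
  a <- v[f[, 1], , drop = FALSE]
  b <- v[f[, 2], , drop = FALSE]
  c_ <- v[f[, 3], , drop = FALSE]
  sum(a[, 1] * (b[, 2] * c_[, 3] - b[, 3] * c_[, 2]) -
      a[, 2] * (b[, 1] * c_[, 3] - b[, 3] * c_[, 1]) +
      a[, 3] * (b[, 1] * c_[, 2] - b[, 2] * c_[, 1])) / 6
}

# flip faces so each component encloses positive volume
orient_outward <- function(mesh) {
  for (ci in unique(mesh$components)) {
    idx <- mesh$components == ci
    sub <- list(vertices = mesh$vertices, faces = mesh$faces[idx, , drop = FALSE])
    if (mesh_volume(sub) < 0)
      mesh$faces[idx, ] <- mesh$faces[idx, c(1, 3, 2)]
  }
  mesh
}

# weld duplicate vertices (STL soups); tol in mm
weld_vertices <- function(vertices, faces, tol = 1e-6) {
  key <- apply(round(vertices / tol) * tol, 1, paste, collapse = ",")
  first <- !duplicated(key)
  map <- match(key, key[first])
  newv <- vertices[first, , drop = FALSE]
  newf <- matrix(map[faces], ncol = 3)
  keep <- newf[, 1] != newf[, 2] & newf[, 2] != newf[, 3] & newf[, 1] != newf[, 3]
  list(vertices = newv, faces = newf[keep, , drop = FALSE])
}

# merge a list of trimesh-like parts into one multi-component trimesh
merge_meshes <- function(parts, validate = TRUE) {
  off <- 0L
  vs <- list(); fs <- list(); comps <- list()
  for (i in seq_along(parts)) {
    p <- parts[[i]]
    vs[[i]] <- p$vertices
    fs[[i]] <- p$faces + off
    comps[[i]] <- rep(i, nrow(p$faces))
    off <- off + nrow(p$vertices)
  }
  trimesh(do.call(rbind, vs), do.call(rbind, fs),
          components = unlist(comps), validate = validate)
}

#' Read a surface mesh from STL, PLY or OBJ
#'
#' STL (binary or ASCII) files are triangle soups: vertices are welded at
#' `weld_tol` before the watertightness check. PLY (ASCII) and OBJ files are
#' read as indexed meshes. By default a non-watertight mesh is an error; with
#' `repair = TRUE` duplicate vertices are welded and degenerate faces
#' dropped before re-checking (no hole filling is attempted).
#'
#' @param path file path; format inferred from the extension unless given.
#' @param format one of `"stl"`, `"ply"`, `"obj"`.
#' @param repair attempt duplicate-vertex welding on failure (default FALSE).
#' @param weld_tol vertex welding tolerance in mm.
#' @return A [trimesh].
#' @export
load_mesh <- function(path, format = NULL, repair = FALSE, weld_tol = 1e-6) {
  if (!file.exists(path)) stop("file not found: ", path)
  if (is.null(format))
    format <- tolower(tools::file_ext(path))
  format <- match.arg(format, c("stl", "ply", "obj"))
  raw <- switch(format,
    stl = read_stl(path),
    ply = read_ply(path),
    obj = read_obj(path))
  if (nrow(raw$faces) == 0L) stop("empty mesh")
  if (format == "stl") raw <- weld_vertices(raw$vertices, raw$faces, weld_tol)
  build <- function(r) trimesh(r$vertices, r$faces, validate = TRUE)
  tryCatch(build(raw), error = function(e) {
    if (!repair) stop(e)
    build(weld_vertices(raw$vertices, raw$faces, weld_tol))
  })
}

#' Write a surface mesh
#'
#' @param mesh a [trimesh].
#' @param path output path.
#' @param format `"stl"` (ASCII), `"stl_binary"`, `"ply"` or `"obj"`;
#'   inferred from the extension when `NULL` (`.stl` writes ASCII).
#' @return `path`, invisibly.
#' @export
write_mesh <- function(mesh, path, format = NULL) {
  if (is.null(format)) {
    format <- tolower(tools::file_ext(path))
  }
  format <- match.arg(format, c("stl", "stl_binary", "ply", "obj"))
  switch(format,
    stl = write_stl_ascii(mesh, path),
    stl_binary = write_stl_binary(mesh, path),
    ply = write_ply(mesh, path),
    obj = write_obj(mesh, path))
  invisible(path)
}

# ---- STL ----

read_stl <- function(path) {
  con <- file(path, "rb")
  head <- readBin(con, "raw", 80)
  close(con)
  txt <- rawToChar(head[head != as.raw(0)])
  # binary files can start with "solid" too; check size consistency
  if (grepl("^\\s*solid", txt)) {
    sz <- file.info(path)$size
    con <- file(path, "rb")
    invisible(readBin(con, "raw", 80))
    ntri <- readBin(con, "integer", 1, size = 4, endian = "little")
    close(con)
    if (!isTRUE(sz == 84 + 50 * ntri)) return(read_stl_ascii(path))
  }
  read_stl_binary(path)
}

read_stl_ascii <- function(path) {
  lines <- readLines(path, warn = FALSE)
  vl <- grep("^\\s*vertex", lines, value = TRUE)
  if (length(vl) %% 3 != 0) stop("malformed ASCII STL")
  nums <- lapply(strsplit(trimws(vl), "\\s+"), function(x) as.numeric(x[2:4]))
  v <- do.call(rbind, nums)
  n <- nrow(v) / 3
  list(vertices = v, faces = matrix(seq_len(3 * n), ncol = 3, byrow = TRUE))
}

read_stl_binary <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  invisible(readBin(con, "raw", 80))
  ntri <- readBin(con, "integer", 1, size = 4, endian = "little")
  if (!length(ntri) || ntri <= 0) stop("malformed binary STL")
  rec <- readBin(con, "raw", 50 * ntri)
  if (length(rec) < 50 * ntri) stop("truncated binary STL")
  m <- matrix(rec, nrow = 50)
  fl <- readBin(as.vector(m[1:48, ]), "numeric", size = 4, n = 12 * ntri,
                endian = "little")
  tri <- matrix(fl, nrow = 12)  # normal(3), v1(3), v2(3), v3(3) per column
  v <- matrix(as.vector(tri[4:12, , drop = FALSE]), ncol = 3, byrow = TRUE)
  list(vertices = v, faces = matrix(seq_len(3 * ntri), ncol = 3, byrow = TRUE))
}

write_stl_ascii <- function(mesh, path) {
  v <- mesh$vertices
  f <- mesh$faces
  a <- v[f[, 2], , drop = FALSE] - v[f[, 1], , drop = FALSE]
  b <- v[f[, 3], , drop = FALSE] - v[f[, 1], , drop = FALSE]
  n <- cbind(a[, 2] * b[, 3] - a[, 3] * b[, 2],
             a[, 3] * b[, 1] - a[, 1] * b[, 3],
             a[, 1] * b[, 2] - a[, 2] * b[, 1])
  n <- n / pmax(sqrt(rowSums(n^2)), 1e-30)
  out <- character(2 + 7 * nrow(f))
  out[1] <- "solid glenplan"
  k <- 2
  fmt <- function(p) sprintf("%.9g %.9g %.9g", p[1], p[2], p[3])
  for (i in seq_len(nrow(f))) {
    out[k] <- paste0("  facet normal ", fmt(n[i, ])); k <- k + 1
    out[k] <- "    outer loop"; k <- k + 1
    for (j in 1:3) {
      out[k] <- paste0("      vertex ", fmt(v[f[i, j], ])); k <- k + 1
    }
    out[k] <- "    endloop"; k <- k + 1
    out[k] <- "  endfacet"; k <- k + 1
  }
  out[k] <- "endsolid glenplan"
  writeLines(out, path)
}

write_stl_binary <- function(mesh, path) {
  v <- mesh$vertices
  f <- mesh$faces
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(as.raw(rep(0, 80)), con)
  writeBin(as.integer(nrow(f)), con, size = 4, endian = "little")
  for (i in seq_len(nrow(f))) {
    tri <- rbind(c(0, 0, 0), v[f[i, 1], ], v[f[i, 2], ], v[f[i, 3], ])
    writeBin(as.numeric(t(tri)), con, size = 4, endian = "little")
    writeBin(as.raw(c(0, 0)), con)
  }
}

# ---- PLY (ASCII) ----

read_ply <- function(path) {
  lines <- readLines(path, warn = FALSE)
  if (!grepl("^ply", lines[1])) stop("not a PLY file")
  endh <- match("end_header", trimws(lines))
  if (is.na(endh)) stop("malformed PLY header")
  head <- lines[seq_len(endh)]
  nv <- as.integer(sub(".*element vertex\\s+", "", grep("element vertex", head, value = TRUE)[1]))
  nf <- as.integer(sub(".*element face\\s+", "", grep("element face", head, value = TRUE)[1]))
  body <- lines[(endh + 1):length(lines)]
  vrows <- strsplit(trimws(body[seq_len(nv)]), "\\s+")
  v <- do.call(rbind, lapply(vrows, function(x) as.numeric(x[1:3])))
  frows <- strsplit(trimws(body[nv + seq_len(nf)]), "\\s+")
  f <- do.call(rbind, lapply(frows, function(x) {
    k <- as.integer(x[1])
    if (k != 3L) stop("only triangular PLY faces are supported")
    as.integer(x[2:4]) + 1L
  }))
  list(vertices = v, faces = f)
}

write_ply <- function(mesh, path) {
  v <- mesh$vertices
  f <- mesh$faces
  head <- c("ply", "format ascii 1.0",
            sprintf("element vertex %d", nrow(v)),
            "property double x", "property double y", "property double z",
            sprintf("element face %d", nrow(f)),
            "property list uchar int vertex_indices", "end_header")
  vb <- sprintf("%.9g %.9g %.9g", v[, 1], v[, 2], v[, 3])
  fb <- sprintf("3 %d %d %d", f[, 1] - 1L, f[, 2] - 1L, f[, 3] - 1L)
  writeLines(c(head, vb, fb), path)
}

# ---- OBJ ----

read_obj <- function(path) {
  lines <- readLines(path, warn = FALSE)
  vl <- grep("^v\\s", lines, value = TRUE)
  fl <- grep("^f\\s", lines, value = TRUE)
  v <- do.call(rbind, lapply(strsplit(trimws(vl), "\\s+"),
                             function(x) as.numeric(x[2:4])))
  f <- do.call(rbind, lapply(strsplit(trimws(fl), "\\s+"), function(x) {
    ix <- as.integer(sub("/.*", "", x[-1]))
    if (length(ix) != 3L) stop("only triangular OBJ faces are supported")
    ix
  }))
  list(vertices = v, faces = f)
}

write_obj <- function(mesh, path) {
  v <- mesh$vertices
  f <- mesh$faces
  writeLines(c(sprintf("v %.9g %.9g %.9g", v[, 1], v[, 2], v[, 3]),
               sprintf("f %d %d %d", f[, 1], f[, 2], f[, 3])), path)
}
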