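#' Read and write STL meshes
#'
#' STL (ASCII or binary) stores a triangle soup; on reading, vertices that
#' coincide exactly are welded back into a shared mesh. STL carries no
#' per-vertex attributes -- intensities require PLY.
#'
#' @param path file path.
#' @return [read_stl()]: a [trimesh()].
#' @export
read_stl <- function(path) {
  con <- file(path, "rb")
  head5 <- readBin(con, "raw", 5L)
  close(con)
  is_ascii <- identical(rawToChar(head5), "solid") && {
    # a binary file may also start with "solid": check the size formula
    sz <- file.size(path)
    con <- file(path, "rb")
    invisible(readBin(con, "raw", 80L))
    nt <- readBin(con, "integer", 1L, size = 4L, endian = "little")
    close(con)
    !isTRUE(sz == 84 + 50 * nt)
  }
  tri <- if (is_ascii) read_stl_ascii(path) else read_stl_binary(path)
  soup_to_mesh(tri)
}

read_stl_ascii <- function(path) {
  lines <- readLines(path, warn = FALSE)
  vl <- grep("^\\s*vertex\\s", lines, value = TRUE)
  if (!length(vl)) stop("no vertices found in ASCII STL")
  parts <- strsplit(trimws(vl), "\\s+")
  coords <- t(vapply(parts, function(p) as.numeric(p[2:4]), numeric(3)))
  if (nrow(coords) %% 3 != 0) stop("ASCII STL vertex count not divisible by 3")
  coords
}

read_stl_binary <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  invisible(readBin(con, "raw", 80L))
  nt <- readBin(con, "integer", 1L, size = 4L, endian = "little")
  tri <- matrix(NA_real_, 3L * nt, 3L)
  for (k in seq_len(nt)) {
    vals <- readBin(con, "numeric", 12L, size = 4L, endian = "little")
    tri[(3L * k - 2L):(3L * k), ] <- matrix(vals[4:12], 3L, 3L,
                                            byrow = TRUE)
    invisible(readBin(con, "raw", 2L))
  }
  tri
}

# Triangle soup (3k x 3 coordinates) -> welded trimesh.
soup_to_mesh <- function(coords) {
  key <- apply(coords, 1, paste, collapse = ",")
  first <- !duplicated(key)
  V <- coords[first, , drop = FALSE]
  idx <- match(key, key[first])
  Fm <- matrix(idx, ncol = 3L, byrow = TRUE)
  trimesh(V, Fm)
}

#' @rdname read_stl
#' @param mesh a [trimesh()].
#' @param binary write binary STL (default) or ASCII.
#' @export
write_stl <- function(mesh, path, binary = TRUE) {
  fn <- face_normals(mesh)$normals
  Fm <- mesh$faces
  V <- mesh$vertices
  if (binary) {
    con <- file(path, "wb")
    on.exit(close(con))
    writeBin(raw(80L), con)
    writeBin(as.integer(nrow(Fm)), con, size = 4L, endian = "little")
    for (k in seq_len(nrow(Fm))) {
      writeBin(as.numeric(c(fn[k, ], t(V[Fm[k, ], ]))), con, size = 4L,
               endian = "little")
      writeBin(raw(2L), con)
    }
  } else {
    con <- file(path, "w")
    on.exit(close(con))
    writeLines("solid bonereduce", con)
    for (k in seq_len(nrow(Fm))) {
      writeLines(sprintf("  facet normal %.9e %.9e %.9e",
                         fn[k, 1], fn[k, 2], fn[k, 3]), con)
      writeLines("    outer loop", con)
      for (j in 1:3) {
        v <- V[Fm[k, j], ]
        writeLines(sprintf("      vertex %.9e %.9e %.9e", v[1], v[2],
                           v[3]), con)
      }
      writeLines(c("    endloop", "  endfacet"), con)
    }
    writeLines("endsolid bonereduce", con)
  }
  invisible(path)
}

#' Read and write PLY meshes with per-vertex scalars
#'
#' ASCII PLY with the standard `x y z` vertex properties, optionally
#' carrying `intensity` (Hounsfield units), `label` (0 intact /
#' 1 fracture) and `patch` (patch id, -1 when none) scalars.
#'
#' @param path file path.
#' @return [read_ply()]: a [trimesh()] (with `intensity` when present);
#'   `label`/`patch` columns are attached as attributes of the same names.
#' @export
read_ply <- function(path) {
  lines <- readLines(path, warn = FALSE)
  if (!identical(lines[1L], "ply")) stop("not a PLY file")
  hdr_end <- match("end_header", lines)
  if (is.na(hdr_end)) stop("PLY header not terminated")
  hdr <- lines[seq_len(hdr_end)]
  if (!any(grepl("^format ascii", hdr)))
    stop("only ASCII PLY is supported")
  nv <- as.integer(sub("^element vertex\\s+", "",
                       grep("^element vertex", hdr, value = TRUE)))
  nf <- as.integer(sub("^element face\\s+", "",
                       grep("^element face", hdr, value = TRUE)))
  # vertex property names in declaration order
  vstart <- grep("^element vertex", hdr)
  vend <- grep("^element", hdr)
  vend <- c(vend[vend > vstart], hdr_end)[1L]
  props <- sub("^property\\s+\\S+\\s+", "",
               grep("^property", hdr[(vstart + 1L):(vend - 1L)],
                    value = TRUE))
  body <- lines[(hdr_end + 1L):length(lines)]
  vlines <- body[seq_len(nv)]
  vm <- do.call(rbind, lapply(strsplit(trimws(vlines), "\\s+"),
                              as.numeric))
  colnames(vm) <- props[seq_len(ncol(vm))]
  flines <- body[nv + seq_len(nf)]
  fm <- do.call(rbind, lapply(strsplit(trimws(flines), "\\s+"),
                              function(p) as.integer(p[2:4]) + 1L))
  m <- trimesh(vm[, c("x", "y", "z"), drop = FALSE], fm,
               intensity = if ("intensity" %in% props)
                 vm[, "intensity"] else NULL)
  if ("label" %in% props) attr(m, "label") <- as.integer(vm[, "label"])
  if ("patch" %in% props) attr(m, "patch") <- as.integer(vm[, "patch"])
  m
}

#' @rdname read_ply
#' @param mesh a [trimesh()].
#' @param label optional integer per-vertex label (0 intact / 1 fracture).
#' @param patch optional integer per-vertex patch id (-1 when none).
#' @export
write_ply <- function(mesh, path, label = NULL, patch = NULL) {
  V <- mesh$vertices
  n <- nrow(V)
  cols <- list(x = V[, 1], y = V[, 2], z = V[, 3])
  types <- c("float x", "float y", "float z")
  if (!is.null(mesh$intensity)) {
    cols$intensity <- mesh$intensity
    types <- c(types, "float intensity")
  }
  if (!is.null(label)) {
    stopifnot(length(label) == n)
    cols$label <- as.integer(label)
    types <- c(types, "int label")
  }
  if (!is.null(patch)) {
    stopifnot(length(patch) == n)
    cols$patch <- as.integer(patch)
    types <- c(types, "int patch")
  }
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("ply", "format ascii 1.0",
               sprintf("element vertex %d", n),
               paste("property", types),
               sprintf("element face %d", nrow(mesh$faces)),
               "property list uchar int vertex_indices",
               "end_header"), con)
  vm <- do.call(cbind, cols)
  writeLines(apply(vm, 1, function(r)
    paste(format(r, trim = TRUE, digits = 17), collapse = " ")), con)
  writeLines(paste(3L, mesh$faces[, 1] - 1L, mesh$faces[, 2] - 1L,
                   mesh$faces[, 3] - 1L), con)
  invisible(path)
}

#' Read and write rigid transforms as plain text
#'
#' 4 x 4 homogeneous matrices stored row-major, one row per line.
#'
#' @param tf a [rigid_transform()].
#' @param path file path.
#' @export
write_transform <- function(tf, path) {
  m <- as.matrix(tf)
  writeLines(apply(m, 1, function(r)
    paste(format(r, trim = TRUE, digits = 17), collapse = " ")), path)
  invisible(path)
}

#' @rdname write_transform
#' @export
read_transform <- function(path) {
  m <- do.call(rbind, lapply(strsplit(trimws(readLines(path)), "\\s+"),
                             as.numeric))
  stopifnot(all(dim(m) == c(4L, 4L)))
  rigid_transform(m[1:3, 1:3], m[1:3, 4])
}

#' Read an operator pairing file
#'
#' YAML list of fracture-surface correspondences, e.g.
#' ```yaml
#' pairs:
#'   - {fragment: frag1, frag_patch: 1, target: base, target_patch: 1}
#' ```
#'
#' @param path YAML file path.
#' @return data.frame with columns `fragment`, `frag_patch`, `target`,
#'   `target_patch`, `provenance` (`"operator"`).
#' @export
read_pairs <- function(path) {
  y <- yaml::read_yaml(path)
  entries <- if (!is.null(y$pairs)) y$pairs else y
  if (!length(entries)) stop("pairing file contains no pairs")
  out <- do.call(rbind, lapply(entries, function(e) {
    data.frame(fragment = as.character(e$fragment),
               frag_patch = if (is.null(e$frag_patch)) NA_integer_
               else as.integer(e$frag_patch),
               target = if (is.null(e$target)) "base"
               else as.character(e$target),
               target_patch = if (is.null(e$target_patch)) NA_integer_
               else as.integer(e$target_patch),
               stringsAsFactors = FALSE)
  }))
  out$provenance <- "operator"
  out
}
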