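#' Triangle mesh
#'
#' A minimal triangle-mesh container: an `n x 3` matrix of vertex
#' coordinates (millimetres, right-handed frame) and an `m x 3` integer
#' matrix of 1-based vertex indices, one row per triangular face.
#'
#' @param vertices Numeric matrix, `n x 3`, finite coordinates in mm.
#' @param faces Integer matrix, `m x 3`, 1-based vertex indices.
#' @return An object of class `tri_mesh` with elements `vertices` and
#'   `faces`.
#' @examples
#' m <- tri_mesh(rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0)),
#'               rbind(c(1L, 2L, 3L)))
#' n_vertices(m)
#' @export
tri_mesh <- function(vertices, faces) {
  vertices <- as.matrix(vertices)
  storage.mode(vertices) <- "double"
  dimnames(vertices) <- NULL
  faces <- as.matrix(faces)
  storage.mode(faces) <- "integer"
  dimnames(faces) <- NULL
  mesh <- structure(list(vertices = vertices, faces = faces),
                    class = "tri_mesh")
  validate_mesh(mesh)
  mesh
}

#' @rdname tri_mesh
#' @param mesh A `tri_mesh`.
#' @export
validate_mesh <- function(mesh) {
  v <- mesh$vertices
  f <- mesh$faces
  if (!is.matrix(v) || ncol(v) != 3L || nrow(v) < 3L) {
    abort("mesh must have an n x 3 vertex matrix with n >= 3",
          "rotometry_invalid_input")
  }
  if (!all(is.finite(v))) {
    abort("mesh vertices contain non-finite coordinates",
          "rotometry_invalid_input")
  }
  if (!is.matrix(f) || ncol(f) != 3L || nrow(f) < 1L) {
    abort("mesh must have an m x 3 face matrix with m >= 1",
          "rotometry_invalid_input")
  }
  if (anyNA(f) || min(f) < 1L || max(f) > nrow(v)) {
    abort("face indices must lie in [1, vertex count]",
          "rotometry_invalid_input")
  }
  if (any(f[, 1L] == f[, 2L] | f[, 2L] == f[, 3L] | f[, 1L] == f[, 3L])) {
    abort("mesh contains a face with a repeated vertex",
          "rotometry_invalid_input")
  }
  invisible(mesh)
}

#' @rdname tri_mesh
#' @export
n_vertices <- function(mesh) nrow(mesh$vertices)

#' @rdname tri_mesh
#' @export
n_faces <- function(mesh) nrow(mesh$faces)

#' @export
print.tri_mesh <- function(x, ...) {
  cat(sprintf("<tri_mesh: %d vertices, %d faces>\n",
              n_vertices(x), n_faces(x)))
  invisible(x)
}

#' Weld duplicate vertices
#'
#' Merges vertices that coincide within `tol` so that adjacent faces share
#' indices, and drops faces that degenerate (repeated vertex) after the
#' merge. Welding is idempotent.
#'
#' @param mesh A `tri_mesh`.
#' @param tol Welding tolerance in mm.
#' @return A welded `tri_mesh`.
#' @export
weld_vertices <- function(mesh, tol = 1e-6) {
  v <- mesh$vertices
  key <- paste(round(v[, 1L] / tol), round(v[, 2L] / tol),
               round(v[, 3L] / tol))
  first <- !duplicated(key)
  remap <- match(key, key[first])
  newv <- v[first, , drop = FALSE]
  f <- matrix(remap[mesh$faces], ncol = 3L)
  keep <- f[, 1L] != f[, 2L] & f[, 2L] != f[, 3L] & f[, 1L] != f[, 3L]
  if (!any(keep)) {
    abort("all faces degenerate after welding", "rotometry_invalid_input")
  }
  tri_mesh(newv, f[keep, , drop = FALSE])
}

# ---- STL input/output -------------------------------------------------

#' Read and write STL files
#'
#' Reads binary (80-byte header, little-endian) or ASCII STL. Duplicate
#' vertices within 1e-6 mm are welded so faces share indices; facet normals
#' stored in the file are ignored and implied by vertex winding.
#'
#' @param path File path.
#' @return `read_stl` returns a `tri_mesh`.
#' @export
read_stl <- function(path) {
  if (!file.exists(path)) {
    abort(sprintf("STL file not found: %s", path), "rotometry_io_error")
  }
  size <- file.info(path)$size
  is_binary <- FALSE
  if (size >= 84) {
    con <- file(path, "rb")
    on.exit(close(con))
    header <- readBin(con, "raw", 80L)
    count <- readBin(con, "integer", 1L, size = 4L, endian = "little")
    ascii_start <- all(header[1:5] == charToRaw("solid"))
    if (!is.na(count) &&
        (size == 84 + 50 * as.numeric(count) || !ascii_start)) {
      is_binary <- TRUE
    } else {
      close(con)
      on.exit()
    }
  }
  mesh <- if (is_binary) {
    if (size != 84 + 50 * as.numeric(count)) {
      abort(sprintf(
        "binary STL %s: facet count %d implies %.0f bytes, file has %.0f",
        path, count, 84 + 50 * as.numeric(count), size),
        "rotometry_format_error")
    }
    read_stl_binary(con, count, path)
  } else {
    read_stl_ascii(path)
  }
  weld_vertices(mesh, tol = 1e-6)
}

read_stl_binary <- function(con, count, path) {
  if (count < 1L) {
    abort(sprintf("empty binary STL: %s", path), "rotometry_invalid_input")
  }
  payload <- readBin(con, "raw", 50L * count)
  if (length(payload) != 50L * count) {
    abort(sprintf(
      "truncated binary STL %s: facet count %d but payload ends at byte %d",
      path, count, 84L + length(payload)), "rotometry_format_error")
  }
  idx <- rep(seq_len(count) - 1L, each = 48L) * 50L +
    rep(seq_len(48L), times = count)
  floats <- readBin(payload[idx], "double", n = 12L * count, size = 4L,
                    endian = "little")
  m <- matrix(floats, ncol = 12L, byrow = TRUE)  # normal + 3 vertices
  tri <- m[, 4:12, drop = FALSE]
  verts <- matrix(t(tri), ncol = 3L, byrow = TRUE)
  if (!all(is.finite(verts))) {
    abort(sprintf("non-finite coordinates in %s", path),
          "rotometry_format_error")
  }
  faces <- matrix(seq_len(3L * count), ncol = 3L, byrow = TRUE)
  tri_mesh(verts, faces)
}

read_stl_ascii <- function(path) {
  lines <- readLines(path, warn = FALSE)
  vl <- grep("^\\s*vertex\\s", lines)
  if (length(vl) == 0L || length(vl) %% 3L != 0L) {
    bad <- if (length(vl) == 0L) 1L else vl[length(vl)]
    abort(sprintf("malformed ASCII STL %s near line %d: vertex count %d",
                  path, bad, length(vl)), "rotometry_format_error")
  }
  fields <- strsplit(trimws(lines[vl]), "\\s+")
  coords <- vapply(fields, function(f) as.numeric(f[2:4]), numeric(3L))
  verts <- t(coords)
  if (!all(is.finite(verts))) {
    abort(sprintf("non-numeric vertex coordinate in %s", path),
          "rotometry_format_error")
  }
  faces <- matrix(seq_len(nrow(verts)), ncol = 3L, byrow = TRUE)
  tri_mesh(verts, faces)
}

#' @rdname read_stl
#' @param mesh A valid `tri_mesh`.
#' @param mode `"binary"` (default) or `"ascii"`.
#' @param name Solid name written into the file header.
#' @return `write_stl` returns `path` invisibly.
#' @export
write_stl <- function(mesh, path, mode = c("binary", "ascii"),
                      name = "rotometry") {
  mode <- match.arg(mode)
  validate_mesh(mesh)
  v <- mesh$vertices
  f <- mesh$faces
  e1 <- v[f[, 2L], ] - v[f[, 1L], ]
  e2 <- v[f[, 3L], ] - v[f[, 1L], ]
  nrm <- cbind(e1[, 2] * e2[, 3] - e1[, 3] * e2[, 2],
               e1[, 3] * e2[, 1] - e1[, 1] * e2[, 3],
               e1[, 1] * e2[, 2] - e1[, 2] * e2[, 1])
  len <- sqrt(rowSums(nrm^2))
  nrm <- nrm / ifelse(len > 0, len, 1)
  if (mode == "binary") {
    con <- tryCatch(file(path, "wb"),
                    error = function(e) abort(
                      sprintf("cannot write STL: %s", path),
                      "rotometry_io_error"))
    on.exit(close(con))
    header <- charToRaw(formatC(name, width = -80))[1:80]
    header[is.na(header)] <- as.raw(32L)
    writeBin(header, con)
    writeBin(nrow(f), con, size = 4L, endian = "little")
    block <- t(cbind(nrm,
                     v[f[, 1L], , drop = FALSE],
                     v[f[, 2L], , drop = FALSE],
                     v[f[, 3L], , drop = FALSE]))
    raw_f <- writeBin(as.vector(block), raw(), size = 4L, endian = "little")
    m <- matrix(raw_f, nrow = 48L)
    out <- rbind(m, matrix(as.raw(0L), nrow = 2L, ncol = ncol(m)))
    writeBin(as.vector(out), con)
  } else {
    fmt <- function(x) sprintf("%.9g", x)
    out <- character(7L * nrow(f) + 2L)
    out[1L] <- paste("solid", name)
    for (i in seq_len(nrow(f))) {
      b <- 7L * (i - 1L) + 1L
      out[b + 1L] <- sprintf("  facet normal %s %s %s",
                             fmt(nrm[i, 1]), fmt(nrm[i, 2]), fmt(nrm[i, 3]))
      out[b + 2L] <- "    outer loop"
      for (k in 1:3) {
        p <- v[f[i, k], ]
        out[b + 2L + k] <- sprintf("      vertex %s %s %s",
                                   fmt(p[1]), fmt(p[2]), fmt(p[3]))
      }
      out[b + 6L] <- "    endloop"
      out[b + 7L] <- "  endfacet"
    }
    out[length(out)] <- paste("endsolid", name)
    tryCatch(writeLines(out, path),
             error = function(e) abort(sprintf("cannot write STL: %s", path),
                                       "rotometry_io_error"))
  }
  invisible(path)
}

# ---- FDI numbering and tooth types ------------------------------------

#' FDI tooth-type helpers
#'
#' FDI two-digit codes: quadrant digit (1 maxillary right, 2 maxillary
#' left, 3 mandibular left, 4 mandibular right) followed by position 1-8
#' counted from the midline. Third molars (position 8) are outside the
#' 7-type vocabulary used here.
#'
#' @param fdi Integer vector of FDI codes.
#' @return `fdi_tooth_type` returns the tooth-type string; `fdi_arch`
#'   returns `"mandibular"` or `"maxillary"`.
#' @export
fdi_tooth_type <- function(fdi) {
  pos <- fdi %% 10L
  quad <- fdi %/% 10L
  ok <- quad %in% 1:4 & pos %in% 1:7
  if (!all(ok)) {
    abort(sprintf("FDI code outside supported range: %s",
                  paste(fdi[!ok], collapse = ", ")),
          "rotometry_invalid_input")
  }
  tooth_types()[pos]
}

#' @rdname fdi_tooth_type
#' @export
fdi_arch <- function(fdi) {
  quad <- fdi %/% 10L
  ifelse(quad %in% c(1L, 2L), "maxillary", "mandibular")
}

#' @rdname fdi_tooth_type
#' @export
tooth_types <- function() {
  c("central_incisor", "lateral_incisor", "canine", "first_premolar",
    "second_premolar", "first_molar", "second_molar")
}

#' Landmark roles required for a tooth type
#'
#' Two landmarks define the rotation vector of each tooth:
#' disto-vestibular and mesio-lingual cusps for molars, vestibular
#' (buccal) and lingual cusps for premolars, and the most mesial and most
#' distal points of the incisal edge for incisors and canines. The order
#' fixes which landmark is the vector tail (first role) and head (second).
#'
#' @param tooth_type One of [tooth_types()].
#' @return Character vector of length 2 (tail role, head role).
#' @export
landmark_roles <- function(tooth_type) {
  if (!tooth_type %in% tooth_types()) {
    abort(sprintf("unknown tooth type: %s", tooth_type),
          "rotometry_invalid_input")
  }
  if (grepl("premolar", tooth_type)) {
    c("buccal-cusp", "lingual-cusp")
  } else if (grepl("molar", tooth_type)) {
    c("disto-vestibular-cusp", "mesio-lingual-cusp")
  } else {
    c("mesial-point", "distal-point")
  }
}

# ---- tooth label map --------------------------------------------------

#' Tooth label map
#'
#' Assigns mesh vertices to FDI tooth codes. `assignments` is a named list
#' mapping FDI code (as character) to 1-based vertex indices; unlisted
#' vertices are background (gingiva, base). Tooth types are derived from
#' the FDI position digit and must be consistent with it.
#'
#' @param assignments Named list, FDI code -> integer vertex indices.
#' @param n_vertices Vertex count of the labelled mesh.
#' @return An object of class `tooth_label_map`.
#' @export
tooth_label_map <- function(assignments, n_vertices) {
  fdi <- as.integer(names(assignments))
  if (anyNA(fdi)) {
    abort("label names must be FDI codes", "rotometry_invalid_input")
  }
  types <- fdi_tooth_type(fdi)
  for (i in seq_along(assignments)) {
    idx <- as.integer(assignments[[i]])
    if (length(idx) == 0L || anyNA(idx) || min(idx) < 1L ||
        max(idx) > n_vertices) {
      abort(sprintf("labels for tooth %d reference invalid vertices",
                    fdi[i]), "rotometry_invalid_input")
    }
    assignments[[i]] <- idx
  }
  structure(list(assignments = assignments,
                 tooth_types = stats::setNames(types, names(assignments)),
                 n_vertices = as.integer(n_vertices)),
            class = "tooth_label_map")
}

#' @export
print.tooth_label_map <- function(x, ...) {
  cat(sprintf("<tooth_label_map: %d teeth over %d vertices>\n",
              length(x$assignments), x$n_vertices))
  invisible(x)
}

#' @rdname tooth_label_map
#' @export
labelled_teeth <- function(labels) {
  as.integer(names(labels$assignments))
}

#' Extract the submesh of one tooth
#'
#' Keeps faces whose three vertices all carry the tooth's label
#' (boundary faces with mixed labels are excluded) and reindexes them.
#' Vertex positions are identical to the parent mesh.
#'
#' @param mesh Parent `tri_mesh`.
#' @param labels A `tooth_label_map` for `mesh`.
#' @param tooth FDI code.
#' @return A `tri_mesh`.
#' @export
extract_tooth_submesh <- function(mesh, labels, tooth) {
  key <- as.character(tooth)
  if (!key %in% names(labels$assignments)) {
    abort(sprintf("tooth %s not present in label map", key),
          "rotometry_not_found")
  }
  idx <- labels$assignments[[key]]
  inset <- logical(n_vertices(mesh))
  inset[idx] <- TRUE
  f <- mesh$faces
  keep <- inset[f[, 1L]] & inset[f[, 2L]] & inset[f[, 3L]]
  if (!any(keep)) {
    abort(sprintf("tooth %s has no fully-labelled faces", key),
          "rotometry_invalid_segmentation")
  }
  f <- f[keep, , drop = FALSE]
  used <- sort(unique(as.vector(f)))
  remap <- integer(n_vertices(mesh))
  remap[used] <- seq_along(used)
  tri_mesh(mesh$vertices[used, , drop = FALSE],
           matrix(remap[f], ncol = 3L))
}

# ---- landmark table and JSON sidecars ---------------------------------

#' Landmark table constructor
#'
#' Landmarks are kept in a data frame with columns `tooth` (FDI), `role`,
#' `x`, `y`, `z` (mm) and `frame` (timepoint tag `"T0"`, `"T1"` or
#' `"T2"`). Roles must be admissible for the tooth's type.
#'
#' @param tooth Integer FDI codes.
#' @param role Landmark role strings.
#' @param xyz Numeric matrix of positions, one row per landmark.
#' @param frame Timepoint tag, recycled.
#' @return A data frame of landmarks.
#' @export
landmark_table <- function(tooth, role, xyz, frame = "T0") {
  xyz <- matrix(as.numeric(xyz), ncol = 3L)
  if (!all(is.finite(xyz))) {
    abort("landmark positions must be finite", "rotometry_invalid_input")
  }
  tooth <- as.integer(tooth)
  types <- fdi_tooth_type(tooth)
  for (i in seq_along(tooth)) {
    if (!role[i] %in% landmark_roles(types[i])) {
      abort(sprintf("role '%s' not admissible for tooth %d (%s)",
                    role[i], tooth[i], types[i]),
            "rotometry_invalid_input")
    }
  }
  data.frame(tooth = tooth, role = as.character(role),
             x = xyz[, 1L], y = xyz[, 2L], z = xyz[, 3L],
             frame = rep_len(as.character(frame), length(tooth)))
}

#' Read and write label / landmark sidecar JSON
#'
#' STL carries neither labels nor landmarks, so they travel in sidecar
#' JSON files. Vertex indices in the labels JSON are 1-based.
#'
#' @param labels A `tooth_label_map`.
#' @param path File path.
#' @param n_vertices Vertex count of the labelled mesh (checked on read).
#' @export
write_tooth_labels <- function(labels, path) {
  jsonlite::write_json(
    list(tooth_labels = labels$assignments,
         tooth_types = as.list(labels$tooth_types)),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_tooth_labels
#' @export
read_tooth_labels <- function(path, n_vertices) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (is.null(obj$tooth_labels)) {
    abort(sprintf("no tooth_labels field in %s", path),
          "rotometry_format_error")
  }
  tooth_label_map(obj$tooth_labels, n_vertices)
}

#' @rdname write_tooth_labels
#' @param landmarks A landmark data frame.
#' @export
write_landmarks <- function(landmarks, path) {
  rows <- lapply(seq_len(nrow(landmarks)), function(i) {
    list(tooth = landmarks$tooth[i], role = landmarks$role[i],
         xyz = c(landmarks$x[i], landmarks$y[i], landmarks$z[i]),
         frame = landmarks$frame[i])
  })
  jsonlite::write_json(rows, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_tooth_labels
#' @export
read_landmarks <- function(path) {
  rows <- jsonlite::read_json(path, simplifyVector = FALSE)
  landmark_table(
    tooth = vapply(rows, function(r) as.integer(r$tooth), integer(1L)),
    role = vapply(rows, function(r) r$role, character(1L)),
    xyz = t(vapply(rows, function(r) as.numeric(unlist(r$xyz)),
                   numeric(3L))),
    frame = vapply(rows, function(r) r$frame, character(1L)))
}
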