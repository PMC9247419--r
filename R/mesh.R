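# Triangulated hemisphere surfaces: icosphere construction, ellipsoid
# scaling, mirroring, ASCII PLY input/output, and mesh geometry helpers.
#
# Coordinate convention (mm): x = left-right (mirror axis), y =
# anterior-posterior, z = dorso-ventral. Synthetic hemispheres are closed
# ellipsoid meshes; the right hemisphere is the exact mirror image of the
# left (x negated) with an identity vertex correspondence.

#' Construct a surface mesh object
#'
#' @param vertices numeric matrix, one row per vertex, columns x/y/z (mm).
#' @param faces integer matrix, one row per triangle, 1-based vertex indices.
#' @param hemisphere \code{"left"} or \code{"right"}.
#' @param mirror_index optional integer vector: \code{mirror_index[i]} is the
#'   vertex on the contralateral mesh corresponding to vertex \code{i}.
#' @return An object of class \code{"surface_mesh"}.
#' @export
surface_mesh <- function(vertices, faces, hemisphere = c("left", "right"),
                         mirror_index = NULL) {
  hemisphere <- match.arg(hemisphere)
  vertices <- as.matrix(vertices)
  faces <- as.matrix(faces)
  storage.mode(faces) <- "integer"
  stopifnot(ncol(vertices) == 3L, ncol(faces) == 3L)
  if (min(faces) < 1L || max(faces) > nrow(vertices)) {
    stop_("face indices out of range")
  }
  if (!is.null(mirror_index)) {
    mirror_index <- as.integer(mirror_index)
    if (length(mirror_index) != nrow(vertices) || anyDuplicated(mirror_index)) {
      stop_("mirror correspondence must be a bijection over vertices")
    }
  }
  structure(list(vertices = vertices, faces = faces, hemisphere = hemisphere,
                 mirror_index = mirror_index),
            class = "surface_mesh")
}

#' @export
print.surface_mesh <- function(x, ...) {
  cat("surface_mesh (", x$hemisphere, "): ", nrow(x$vertices), " vertices, ",
      nrow(x$faces), " faces, area ", format(mesh_area(x), digits = 6),
      " mm^2", if (!is.null(x$mirror_index)) ", mirror correspondence" else "",
      "\n", sep = "")
  invisible(x)
}

#' Total surface area of a triangulated mesh
#'
#' @param mesh a \code{"surface_mesh"}.
#' @return Sum of triangle areas (mm^2).
#' @export
mesh_area <- function(mesh) {
  v <- mesh$vertices; f <- mesh$faces
  a <- v[f[, 2], ] - v[f[, 1], ]
  b <- v[f[, 3], ] - v[f[, 1], ]
  cx <- a[, 2] * b[, 3] - a[, 3] * b[, 2]
  cy <- a[, 3] * b[, 1] - a[, 1] * b[, 3]
  cz <- a[, 1] * b[, 2] - a[, 2] * b[, 1]
  sum(sqrt(cx^2 + cy^2 + cz^2)) / 2
}

#' Euler characteristic V - E + F of a mesh
#'
#' Equals 2 for a closed surface of genus 0 (the synthetic hemispheres).
#'
#' @param mesh a \code{"surface_mesh"}.
#' @export
euler_characteristic <- function(mesh) {
  e <- mesh_edges(mesh)
  nrow(mesh$vertices) - nrow(e) + nrow(mesh$faces)
}

# Unique undirected edges of the triangulation, as a 2-column index matrix.
mesh_edges <- function(mesh) {
  f <- mesh$faces
  e <- rbind(f[, c(1, 2)], f[, c(2, 3)], f[, c(1, 3)])
  e <- cbind(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]))
  unique(e)
}

# Weighted edge graph of the mesh (igraph), edge weights = Euclidean length.
mesh_graph <- function(mesh) {
  e <- mesh_edges(mesh)
  w <- sqrt(rowSums((mesh$vertices[e[, 1], ] - mesh$vertices[e[, 2], ])^2))
  g <- igraph::make_graph(t(e), n = nrow(mesh$vertices), directed = FALSE)
  igraph::E(g)$weight <- w
  g
}

# ---- icosphere --------------------------------------------------------------

# Unit icosahedron; subdivision splits each triangle into 4 and reprojects
# new vertices to the unit sphere. Vertex count after n subdivisions is
# 10 * 4^n + 2.
.icosahedron <- function() {
  phi <- (1 + sqrt(5)) / 2
  v <- rbind(
    c(-1,  phi, 0), c(1,  phi, 0), c(-1, -phi, 0), c(1, -phi, 0),
    c(0, -1,  phi), c(0, 1,  phi), c(0, -1, -phi), c(0, 1, -phi),
    c( phi, 0, -1), c( phi, 0, 1), c(-phi, 0, -1), c(-phi, 0, 1))
  v <- v / sqrt(rowSums(v^2))
  f <- rbind(
    c(1, 12, 6), c(1, 6, 2), c(1, 2, 8), c(1, 8, 11), c(1, 11, 12),
    c(2, 6, 10), c(6, 12, 5), c(12, 11, 3), c(11, 8, 7), c(8, 2, 9),
    c(4, 10, 5), c(4, 5, 3), c(4, 3, 7), c(4, 7, 9), c(4, 9, 10),
    c(5, 10, 6), c(3, 5, 12), c(7, 3, 11), c(9, 7, 8), c(10, 9, 2))
  list(vertices = v, faces = f)
}

.subdivide <- function(vertices, faces) {
  nv <- nrow(vertices)
  edge_key <- new.env(hash = TRUE)
  verts <- vertices
  midpoint <- function(i, j) {
    key <- paste(min(i, j), max(i, j))
    idx <- edge_key[[key]]
    if (is.null(idx)) {
      m <- (verts[i, ] + verts[j, ]) / 2
      m <- m / sqrt(sum(m^2))
      verts <<- rbind(verts, m)
      idx <- nrow(verts)
      edge_key[[key]] <- idx
    }
    idx
  }
  new_faces <- matrix(0L, nrow(faces) * 4L, 3L)
  for (k in seq_len(nrow(faces))) {
    a <- faces[k, 1]; b <- faces[k, 2]; c <- faces[k, 3]
    ab <- midpoint(a, b); bc <- midpoint(b, c); ca <- midpoint(c, a)
    new_faces[(k - 1L) * 4L + 1:4, ] <- rbind(
      c(a, ab, ca), c(b, bc, ab), c(c, ca, bc), c(ab, bc, ca))
  }
  list(vertices = verts, faces = new_faces)
}

icosphere <- function(subdivisions) {
  m <- .icosahedron()
  for (i in seq_len(subdivisions)) m <- .subdivide(m$vertices, m$faces)
  m
}

#' Generate a synthetic hemisphere surface
#'
#' Builds a subdivided icosphere projected onto an ellipsoid whose
#' anterior-posterior (y) axis is the longest, scaled so the triangulated
#' surface area equals the requested area. The right-hemisphere mesh is the
#' exact mirror image of the left (x negated) and carries an identity vertex
#' correspondence, giving synthetic data an explicit homotopy map that real
#' cortices obtain from surface registration.
#'
#' @param surface_area_cm2 total hemisphere surface area (cm^2).
#' @param ap_elongation ratio of the AP semi-axis to the other two
#'   (default 1.6, an elongated brain-like ellipsoid).
#' @param subdivisions icosphere subdivision level; vertex count is
#'   \eqn{10 \cdot 4^n + 2} (default 4, 2562 vertices).
#' @param side \code{"left"} or \code{"right"}.
#' @return A \code{"surface_mesh"} in mm with mirror correspondence.
#' @export
generate_hemisphere_mesh <- function(surface_area_cm2, ap_elongation = 1.6,
                                     subdivisions = 4, side = c("left", "right")) {
  side <- match.arg(side)
  stopifnot(surface_area_cm2 > 0, ap_elongation > 0, is_count(subdivisions + 1))
  ico <- icosphere(subdivisions)
  v <- ico$vertices
  v[, 2] <- v[, 2] * ap_elongation          # stretch AP axis
  m <- surface_mesh(v, ico$faces, "left")
  target_mm2 <- surface_area_cm2 * 100       # cm^2 -> mm^2
  s <- sqrt(target_mm2 / mesh_area(m))       # area scales with s^2
  v <- v * s
  if (side == "right") v[, 1] <- -v[, 1]
  surface_mesh(v, ico$faces, side, mirror_index = seq_len(nrow(v)))
}

#' Anterior-posterior extent of a mesh (mm)
#'
#' Coordinate range along the designated AP axis (y by package convention).
#'
#' @param mesh a \code{"surface_mesh"}.
#' @param ap_axis column index of the AP axis (default 2).
#' @export
ap_extent <- function(mesh, ap_axis = 2) {
  diff(range(mesh$vertices[, ap_axis]))
}

# ---- ASCII PLY input/output -------------------------------------------------

#' Write a mesh as ASCII PLY
#'
#' @param mesh a \code{"surface_mesh"}.
#' @param file output path.
#' @export
write_ply <- function(mesh, file) {
  con <- file(file, "w")
  on.exit(close(con))
  writeLines(c("ply", "format ascii 1.0",
               paste("element vertex", nrow(mesh$vertices)),
               "property float x", "property float y", "property float z",
               paste("element face", nrow(mesh$faces)),
               "property list uchar int vertex_indices", "end_header"), con)
  utils::write.table(format(mesh$vertices, trim = TRUE, digits = 10), con,
                     row.names = FALSE, col.names = FALSE, quote = FALSE)
  utils::write.table(cbind(3L, mesh$faces - 1L), con,
                     row.names = FALSE, col.names = FALSE, quote = FALSE)
  invisible(file)
}

#' Read an ASCII PLY mesh
#'
#' @param file path to an ASCII PLY file with vertex x/y/z and triangular
#'   faces.
#' @param hemisphere hemisphere tag for the returned mesh.
#' @return A \code{"surface_mesh"}.
#' @export
read_ply <- function(file, hemisphere = "left") {
  lines <- readLines(file)
  if (length(lines) < 3L || lines[1] != "ply") stop_("not an ASCII PLY file: ", file)
  hdr_end <- match("end_header", lines)
  if (is.na(hdr_end)) stop_("PLY header not terminated")
  hdr <- lines[seq_len(hdr_end)]
  nv <- as.integer(sub("element vertex ", "", grep("^element vertex", hdr, value = TRUE)))
  nf <- as.integer(sub("element face ", "", grep("^element face", hdr, value = TRUE)))
  vtx <- do.call(rbind, lapply(lines[hdr_end + seq_len(nv)], function(l)
    as.numeric(strsplit(trimws(l), "\\s+")[[1]][1:3])))
  fc <- do.call(rbind, lapply(lines[hdr_end + nv + seq_len(nf)], function(l) {
    xs <- as.integer(strsplit(trimws(l), "\\s+")[[1]])
    if (xs[1] != 3L) stop_("non-triangular face in PLY file")
    xs[2:4] + 1L
  }))
  surface_mesh(vtx, fc, hemisphere)
}
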