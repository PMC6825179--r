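# Triangle meshes: ASCII STL I/O, watertightness audit, point-in-mesh parity
# tests and ray-mesh intersection. Meshes may consist of several closed
# components (e.g. a soma sphere plus dendrite cylinders); the interior is the
# union of the component interiors.

#' Construct a triangle mesh
#'
#' @param vertices V x 3 numeric matrix.
#' @param faces F x 3 integer matrix of 1-based vertex indices, wound
#'   counter-clockwise seen from outside.
#' @param components Optional integer vector (length F) labelling closed
#'   components; defaults to a single component.
#' @return An object of class `tri_mesh`.
#' @export
tri_mesh <- function(vertices, faces, components = NULL) {
  vertices <- as.matrix(vertices); storage.mode(vertices) <- "double"
  faces <- as.matrix(faces); storage.mode(faces) <- "integer"
  stopifnot(ncol(vertices) == 3, ncol(faces) == 3,
            max(faces) <= nrow(vertices), min(faces) >= 1)
  if (is.null(components)) components <- rep(1L, nrow(faces))
  structure(list(vertices = vertices, faces = faces,
                 components = as.integer(components)),
            class = "tri_mesh")
}

#' @export
print.tri_mesh <- function(x, ...) {
  cat(sprintf("<tri_mesh> %d vertices, %d faces, %d component(s)\n",
              nrow(x$vertices), nrow(x$faces), length(unique(x$components))))
  invisible(x)
}

#' Mesh bounding box
#'
#' @param mesh A `tri_mesh`.
#' @return 2 x 3 matrix with rows `min`, `max`.
#' @export
mesh_bbox <- function(mesh) {
  rbind(min = apply(mesh$vertices, 2, min),
        max = apply(mesh$vertices, 2, max))
}

face_vertices <- function(mesh) {
  list(v0 = mesh$vertices[mesh$faces[, 1], , drop = FALSE],
       v1 = mesh$vertices[mesh$faces[, 2], , drop = FALSE],
       v2 = mesh$vertices[mesh$faces[, 3], , drop = FALSE])
}

#' Watertightness audit
#'
#' A mesh is accepted when, within every component, each undirected edge is
#' shared by exactly two faces with opposite orientation (closed 2-manifold
#' with consistent winding).
#'
#' @param mesh A `tri_mesh`.
#' @return `TRUE` or `FALSE`.
#' @export
mesh_is_watertight <- function(mesh) {
  for (comp in unique(mesh$components)) {
    f <- mesh$faces[mesh$components == comp, , drop = FALSE]
    he <- rbind(f[, c(1, 2)], f[, c(2, 3)], f[, c(3, 1)])  # directed edges
    key <- paste(pmin(he[, 1], he[, 2]), pmax(he[, 1], he[, 2]))
    cnt <- table(key)
    if (any(cnt != 2)) return(FALSE)
    # opposite orientation: each directed edge must appear exactly once
    dkey <- paste(he[, 1], he[, 2])
    if (anyDuplicated(dkey)) return(FALSE)
  }
  TRUE
}

# Hits of rays (common direction d) against all triangles of a face subset.
# Returns an n x 1 count of crossings with t > 0 (Moller-Trumbore).
count_crossings <- function(vertices, faces, pts, d, eps = 1e-12) {
  n <- nrow(pts)
  cnt <- integer(n)
  for (j in seq_len(nrow(faces))) {
    v0 <- vertices[faces[j, 1], ]; v1 <- vertices[faces[j, 2], ]
    v2 <- vertices[faces[j, 3], ]
    e1 <- v1 - v0; e2 <- v2 - v0
    h <- c(d[2] * e2[3] - d[3] * e2[2],
           d[3] * e2[1] - d[1] * e2[3],
           d[1] * e2[2] - d[2] * e2[1])
    a <- sum(e1 * h)
    if (abs(a) < eps) next
    f <- 1 / a
    s <- sweep(pts, 2, v0)
    u <- f * as.numeric(s %*% h)
    q <- cbind(s[, 2] * e1[3] - s[, 3] * e1[2],
               s[, 3] * e1[1] - s[, 1] * e1[3],
               s[, 1] * e1[2] - s[, 2] * e1[1])
    v <- f * as.numeric(q %*% d)
    t <- f * as.numeric(q %*% e2)
    hit <- u >= 0 & v >= 0 & (u + v) <= 1 & t > eps
    cnt <- cnt + hit
  }
  cnt
}

#' Point-in-mesh test
#'
#' Ray-parity test against each closed component; a point is inside the mesh
#' when it is inside any component (union semantics). Requires a watertight
#' mesh.
#'
#' @param mesh A `tri_mesh` passing [mesh_is_watertight()].
#' @param pts n x 3 matrix of query points.
#' @return Logical vector of length n.
#' @export
points_in_mesh <- function(mesh, pts) {
  if (!mesh_is_watertight(mesh))
    stop("inside test undefined for a non-watertight mesh")
  pts <- as.matrix(pts)
  if (ncol(pts) != 3) stop("pts must be n x 3")
  d <- c(0.57735026, 0.57745026, 0.57725023)  # fixed skew direction
  d <- d / sqrt(sum(d^2))
  inside <- rep(FALSE, nrow(pts))
  for (comp in unique(mesh$components)) {
    f <- mesh$faces[mesh$components == comp, , drop = FALSE]
    cnt <- count_crossings(mesh$vertices, f, pts, d)
    inside <- inside | (cnt %% 2L == 1L)
  }
  inside
}

#' Distance to the mesh surface along ray directions
#'
#' Smallest positive intersection distance per ray (rays with individual
#' directions); `Inf` where the ray never meets the surface.
#'
#' @param mesh A `tri_mesh`.
#' @param pos n x 3 ray origins.
#' @param dir n x 3 unit directions.
#' @param eps Minimum accepted hit distance (guards self-intersection at the
#'   surface).
#' @return Numeric vector of distances.
#' @export
mesh_exit_distance <- function(mesh, pos, dir, eps = 1e-9) {
  n <- nrow(pos)
  tmin <- rep(Inf, n)
  for (j in seq_len(nrow(mesh$faces))) {
    v0 <- mesh$vertices[mesh$faces[j, 1], ]
    v1 <- mesh$vertices[mesh$faces[j, 2], ]
    v2 <- mesh$vertices[mesh$faces[j, 3], ]
    e1 <- v1 - v0; e2 <- v2 - v0
    h <- cbind(dir[, 2] * e2[3] - dir[, 3] * e2[2],
               dir[, 3] * e2[1] - dir[, 1] * e2[3],
               dir[, 1] * e2[2] - dir[, 2] * e2[1])
    a <- h %*% e1
    ok <- abs(a) > 1e-14
    if (!any(ok)) next
    f <- ifelse(ok, 1 / a, 0)
    s <- sweep(pos, 2, v0)
    u <- f * rowSums(s * h)
    q <- cbind(s[, 2] * e1[3] - s[, 3] * e1[2],
               s[, 3] * e1[1] - s[, 1] * e1[3],
               s[, 1] * e1[2] - s[, 2] * e1[1])
    v <- f * rowSums(q * dir)
    t <- f * as.numeric(q %*% e2)
    hit <- ok & u >= -1e-12 & v >= -1e-12 & (u + v) <= 1 + 1e-12 & t > eps
    tmin <- ifelse(hit & t < tmin, t, tmin)
  }
  as.numeric(tmin)
}

#' Write a mesh as ASCII STL
#'
#' Deterministic formatting: identical meshes produce byte-identical files.
#'
#' @param mesh A `tri_mesh`.
#' @param file Output path.
#' @param name Solid name written to the header.
#' @return The path, invisibly.
#' @export
write_stl <- function(mesh, file, name = "polmc") {
  fv <- face_vertices(mesh)
  nrm <- vcross(fv$v1 - fv$v0, fv$v2 - fv$v0)
  len <- vnorm(nrm)
  len[len == 0] <- 1
  nrm <- nrm / len
  con <- file(file, "wb")
  on.exit(close(con))
  lines <- character(2 + 7 * nrow(mesh$faces))
  lines[1] <- sprintf("solid %s", name)
  fmt <- function(v) sprintf("%.9e %.9e %.9e", v[, 1], v[, 2], v[, 3])
  idx <- seq_len(nrow(mesh$faces))
  lines[2 + (idx - 1) * 7] <- sprintf("  facet normal %s", fmt(nrm))
  lines[3 + (idx - 1) * 7] <- "    outer loop"
  lines[4 + (idx - 1) * 7] <- sprintf("      vertex %s", fmt(fv$v0))
  lines[5 + (idx - 1) * 7] <- sprintf("      vertex %s", fmt(fv$v1))
  lines[6 + (idx - 1) * 7] <- sprintf("      vertex %s", fmt(fv$v2))
  lines[7 + (idx - 1) * 7] <- "    endloop"
  lines[8 + (idx - 1) * 7] <- "  endfacet"
  lines[2 + 7 * nrow(mesh$faces)] <- sprintf("endsolid %s", name)
  writeLines(lines, con, sep = "\n")
  invisible(file)
}

#' Read an ASCII STL file
#'
#' Vertices are merged on exact coordinate equality of their formatted
#' representation; connectivity is rebuilt from the merged set. Components are
#' recovered as connected face groups.
#'
#' @param file Path to an ASCII STL file.
#' @return A `tri_mesh`.
#' @export
read_stl <- function(file) {
  if (!file.exists(file)) stop("STL file not found: ", file)
  txt <- readLines(file)
  vl <- grep("^\\s*vertex", txt, value = TRUE)
  if (length(vl) == 0 || length(vl) %% 3 != 0)
    stop("not a valid ASCII STL file: ", file)
  nums <- do.call(rbind, lapply(strsplit(trimws(vl), "\\s+"), function(p)
    as.numeric(p[2:4])))
  key <- apply(nums, 1, function(r) paste(sprintf("%.9e", r), collapse = " "))
  uk <- !duplicated(key)
  verts <- nums[uk, , drop = FALSE]
  idx <- match(key, key[uk])
  faces <- matrix(idx, ncol = 3, byrow = TRUE)
  mesh <- tri_mesh(verts, faces)
  mesh$components <- mesh_components(mesh)
  mesh
}

# Connected-component labels of faces via shared vertices.
mesh_components <- function(mesh) {
  nv <- nrow(mesh$vertices)
  parent <- seq_len(nv)
  find <- function(i) { while (parent[i] != i) { parent[i] <<- parent[parent[i]]; i <- parent[i] }; i }
  for (j in seq_len(nrow(mesh$faces))) {
    a <- find(mesh$faces[j, 1]); b <- find(mesh$faces[j, 2]); c3 <- find(mesh$faces[j, 3])
    parent[b] <- a; parent[c3] <- a
  }
  roots <- vapply(mesh$faces[, 1], find, integer(1))
  as.integer(factor(roots))
}

# ---------------------------------------------------------------------------
# Mesh constructors

# Unit icosahedron subdivided `subdiv` times and scaled to `radius`.
make_icosphere <- function(radius = 1, subdiv = 2L, center = c(0, 0, 0)) {
  t <- (1 + sqrt(5)) / 2
  v <- rbind(c(-1, t, 0), c(1, t, 0), c(-1, -t, 0), c(1, -t, 0),
             c(0, -1, t), c(0, 1, t), c(0, -1, -t), c(0, 1, -t),
             c(t, 0, -1), c(t, 0, 1), c(-t, 0, -1), c(-t, 0, 1))
  v <- v / sqrt(rowSums(v^2))
  f <- rbind(c(1, 12, 6), c(1, 6, 2), c(1, 2, 8), c(1, 8, 11), c(1, 11, 12),
             c(2, 6, 10), c(6, 12, 5), c(12, 11, 3), c(11, 8, 7), c(8, 2, 9),
             c(4, 10, 5), c(4, 5, 3), c(4, 3, 7), c(4, 7, 9), c(4, 9, 10),
             c(5, 10, 6), c(3, 5, 12), c(7, 3, 11), c(9, 7, 8), c(10, 9, 2))
  for (s in seq_len(subdiv)) {
    midcache <- new.env(hash = TRUE)
    nf <- matrix(0L, nrow(f) * 4L, 3L)
    mid <- function(a, b) {
      key <- paste(min(a, b), max(a, b))
      got <- midcache[[key]]
      if (!is.null(got)) return(got)
      p <- (v[a, ] + v[b, ]) / 2
      p <- p / sqrt(sum(p^2))
      v <<- rbind(v, p)
      midcache[[key]] <- nrow(v)
      nrow(v)
    }
    for (j in seq_len(nrow(f))) {
      a <- f[j, 1]; b <- f[j, 2]; c3 <- f[j, 3]
      ab <- mid(a, b); bc <- mid(b, c3); ca <- mid(c3, a)
      nf[(j - 1) * 4 + 1, ] <- c(a, ab, ca)
      nf[(j - 1) * 4 + 2, ] <- c(b, bc, ab)
      nf[(j - 1) * 4 + 3, ] <- c(c3, ca, bc)
      nf[(j - 1) * 4 + 4, ] <- c(ab, bc, ca)
    }
    f <- nf
  }
  tri_mesh(sweep(v * radius, 2, center, "+"), f)
}

# Closed cylinder from p0 to p1 with `nseg` angular segments.
make_cylinder_mesh <- function(p0, p1, radius, nseg = 16L) {
  axis <- p1 - p0
  len <- sqrt(sum(axis^2))
  a <- axis / len
  h <- if (abs(a[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  b1 <- h - a * sum(h * a); b1 <- b1 / sqrt(sum(b1^2))
  b2 <- c(a[2] * b1[3] - a[3] * b1[2],
          a[3] * b1[1] - a[1] * b1[3],
          a[1] * b1[2] - a[2] * b1[1])
  ang <- 2 * pi * (seq_len(nseg) - 1) / nseg
  ring <- outer(cos(ang), b1) + outer(sin(ang), b2)
  v_lo <- sweep(ring * radius, 2, p0, "+")
  v_hi <- sweep(ring * radius, 2, p1, "+")
  v <- rbind(v_lo, v_hi, p0, p1)
  i <- seq_len(nseg); ip <- c(seq_len(nseg)[-1], 1L)
  lo <- i; hi <- i + nseg; lop <- ip; hip <- ip + nseg
  c_lo <- 2L * nseg + 1L; c_hi <- 2L * nseg + 2L
  f <- rbind(cbind(lo, lop, hip), cbind(lo, hip, hi),   # side (outward)
             cbind(c_lo, lop, lo),                       # bottom cap
             cbind(c_hi, hi, hip))                       # top cap
  tri_mesh(v, f)
}

# Merge meshes as separate closed components.
merge_meshes <- function(meshes) {
  off <- 0L; comp <- 0L
  vs <- list(); fs <- list(); cs <- list()
  for (m in meshes) {
    vs[[length(vs) + 1L]] <- m$vertices
    fs[[length(fs) + 1L]] <- m$faces + off
    cs[[length(cs) + 1L]] <- m$components + comp
    off <- off + nrow(m$vertices)
    comp <- comp + max(m$components)
  }
  tri_mesh(do.call(rbind, vs), do.call(rbind, fs), unlist(cs))
}

# Affine rescale so the bounding box maps exactly onto [lo, hi] per axis.
mesh_fit_bbox <- function(mesh, lo, hi) {
  bb <- mesh_bbox(mesh)
  span <- bb[2, ] - bb[1, ]
  span[span == 0] <- 1
  scale <- (hi - lo) / span
  mesh$vertices <- sweep(sweep(mesh$vertices, 2, bb[1, ]), 2, scale, "*")
  mesh$vertices <- sweep(mesh$vertices, 2, lo, "+")
  mesh
}
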