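# Triangle-mesh utilities. Meshes are lists (vertices: n x 3 numeric in mm,
# faces: m x 3 integer, 1-based, counter-clockwise seen from outside), class
# "mesh3". Purpose-built: containment tests and deterministic surface sampling
# are the only operations the exposure measurements need.

#' Construct a triangle mesh
#'
#' @param vertices n x 3 numeric matrix of vertex coordinates (mm).
#' @param faces m x 3 integer matrix of 1-based vertex indices.
#' @return an object of class `mesh3`.
#' @export
mesh3 <- function(vertices, faces) {
  vertices <- as.matrix(vertices)
  faces <- matrix(as.integer(as.matrix(faces)), ncol = 3)
  stopifnot(ncol(vertices) == 3, ncol(faces) == 3)
  if (nrow(faces) > 0 &&
    (min(faces) < 1L || max(faces) > nrow(vertices))) {
    stop("face indices out of range", call. = FALSE)
  }
  structure(list(vertices = vertices, faces = faces), class = "mesh3")
}

#' @export
print.mesh3 <- function(x, ...) {
  cat(sprintf(
    "<mesh3> %d vertices, %d faces, watertight: %s\n",
    nrow(x$vertices), nrow(x$faces), is_watertight(x)
  ))
  invisible(x)
}

#' Watertightness check
#'
#' A mesh is watertight (2-manifold and closed) when every undirected edge is
#' shared by exactly two faces, traversed once in each direction.
#'
#' @param mesh a [mesh3()].
#' @return logical scalar.
#' @export
is_watertight <- function(mesh) {
  f <- mesh$faces
  if (nrow(f) == 0) return(FALSE)
  from <- c(f[, 1], f[, 2], f[, 3])
  to <- c(f[, 2], f[, 3], f[, 1])
  und <- paste(pmin(from, to), pmax(from, to))
  cnt <- table(und)
  if (any(cnt != 2L)) return(FALSE)
  dir <- paste(from, to)
  all(table(dir) == 1L) # each direction exactly once => consistent orientation
}

#' Signed volume of a closed mesh
#'
#' @param mesh a [mesh3()]; positive for outward-oriented watertight meshes.
#' @return volume in mm^3.
#' @export
mesh_volume <- function(mesh) {
  v <- mesh$vertices
  f <- mesh$faces
  a <- v[f[, 1], , drop = FALSE]
  b <- v[f[, 2], , drop = FALSE]
  cc <- v[f[, 3], , drop = FALSE]
  cr <- cbind(
    b[, 2] * cc[, 3] - b[, 3] * cc[, 2],
    b[, 3] * cc[, 1] - b[, 1] * cc[, 3],
    b[, 1] * cc[, 2] - b[, 2] * cc[, 1]
  )
  sum(rowSums(a * cr)) / 6
}

#' Rigidly transform a mesh
#'
#' @param mesh a [mesh3()].
#' @param R 3 x 3 rotation matrix.
#' @param t length-3 translation (mm).
#' @return the transformed mesh; face winding is flipped if `det(R) < 0` so
#'   that outward orientation is preserved under reflections.
#' @export
transform_mesh <- function(mesh, R = diag(3), t = c(0, 0, 0)) {
  v <- mesh$vertices %*% t(R)
  v <- sweep(v, 2, t, "+")
  f <- mesh$faces
  if (det(R) < 0) f <- f[, c(1, 3, 2), drop = FALSE]
  mesh3(v, f)
}

#' Point-in-mesh containment test
#'
#' Parity ray casting against a watertight triangle mesh.
#'
#' @param points n x 3 matrix of query points.
#' @param mesh a watertight [mesh3()].
#' @param require_watertight error (rather than proceed) on open meshes.
#' @return logical vector, `TRUE` where the point is inside.
#' @export
points_in_mesh <- function(points, mesh, require_watertight = TRUE) {
  points <- matrix(as.numeric(points), ncol = 3)
  if (require_watertight && !is_watertight(mesh)) {
    stop("mesh integrity error: containment tests require a watertight mesh",
      call. = FALSE
    )
  }
  points_in_mesh_cpp(points, mesh$vertices, mesh$faces)
}

# Deterministic uniform surface sampling: every face is subdivided into 4^k
# congruent subtriangles (k chosen per face so the longest subtriangle edge is
# at most `step`), and one sample is placed at each subtriangle centroid.
# Deterministic, seed-free, and equivariant under rigid motions.
sample_mesh_surface <- function(mesh, step) {
  v <- mesh$vertices
  f <- mesh$faces
  a <- v[f[, 1], , drop = FALSE]
  b <- v[f[, 2], , drop = FALSE]
  cc <- v[f[, 3], , drop = FALSE]
  maxedge <- pmax(rownorms(b - a), rownorms(cc - b), rownorms(a - cc))
  k <- pmax(0L, ceiling(log2(maxedge / step)))
  out <- vector("list", nrow(f))
  for (lev in sort(unique(k))) {
    idx <- which(k == lev)
    n <- 2L^lev
    grid_up <- expand.grid(i = 0:(n - 1L), j = 0:(n - 1L))
    grid_up <- grid_up[grid_up$i + grid_up$j <= n - 1L, , drop = FALSE]
    bu <- cbind((grid_up$i + 1 / 3) / n, (grid_up$j + 1 / 3) / n)
    if (n > 1L) {
      grid_dn <- expand.grid(i = 0:(n - 2L), j = 0:(n - 2L))
      grid_dn <- grid_dn[grid_dn$i + grid_dn$j <= n - 2L, , drop = FALSE]
      bd <- cbind((grid_dn$i + 2 / 3) / n, (grid_dn$j + 2 / 3) / n)
      bu <- rbind(bu, bd)
    }
    for (fi in idx) {
      u <- b[fi, ] - a[fi, ]
      w <- cc[fi, ] - a[fi, ]
      pts <- matrix(a[fi, ], nrow(bu), 3, byrow = TRUE) +
        outer(bu[, 1], u) + outer(bu[, 2], w)
      out[[fi]] <- cbind(pts, fi)
    }
  }
  m <- do.call(rbind, out)
  list(points = m[, 1:3, drop = FALSE], face = as.integer(m[, 4]))
}

# ---- STL input/output (ASCII and binary little-endian) -----------------------

#' Read an STL file
#'
#' Reads binary or ASCII STL; the dialect is detected from the header and file
#' size. Coincident vertices (exact coordinate match) are merged so that
#' watertightness is recoverable from the soup of facets.
#'
#' @param path file path.
#' @return a [mesh3()].
#' @export
read_stl <- function(path) {
  if (!file.exists(path)) stop("STL file not found: ", path, call. = FALSE)
  sz <- file.info(path)$size
  if (is.na(sz) || sz < 15) stop("STL format error: file too short", call. = FALSE)
  con <- file(path, "rb")
  on.exit(close(con))
  head <- readBin(con, "raw", n = min(84, sz))
  is_binary <- FALSE
  if (sz >= 84) {
    ntri <- readBin(head[81:84], "integer", size = 4, endian = "little")
    if (!is.na(ntri) && sz == 84 + 50 * as.numeric(ntri)) is_binary <- TRUE
  }
  if (is_binary) {
    seek(con, 84)
    ntri <- readBin(head[81:84], "integer", size = 4, endian = "little")
    rec <- readBin(con, "raw", n = 50 * ntri)
    m <- matrix(rec, nrow = 50)
    tri <- vapply(seq_len(ntri), function(i) {
      readBin(m[1:48, i], "numeric", n = 12, size = 4, endian = "little")
    }, numeric(12))
    verts <- matrix(as.numeric(tri[4:12, , drop = FALSE]), ncol = 3, byrow = TRUE)
  } else {
    verts <- tryCatch(
      {
        txt <- readLines(path, warn = FALSE, skipNul = TRUE)
        vl <- grep("^[[:space:]]*vertex[[:space:]]", txt, value = TRUE, useBytes = TRUE)
        if (length(vl) == 0 || length(vl) %% 3 != 0) {
          stop("truncated or malformed ASCII facet list")
        }
        v <- do.call(rbind, lapply(strsplit(trimws(vl), "[[:space:]]+"), function(p) {
          as.numeric(p[2:4])
        }))
        if (any(!is.finite(v))) stop("non-numeric vertex")
        v
      },
      error = function(e) {
        stop("STL format error: ", conditionMessage(e), call. = FALSE)
      },
      warning = function(w) {
        stop("STL format error: unreadable ASCII content", call. = FALSE)
      }
    )
  }
  key <- paste(verts[, 1], verts[, 2], verts[, 3])
  uid <- match(key, unique(key))
  uverts <- verts[!duplicated(key), , drop = FALSE]
  faces <- matrix(uid, ncol = 3, byrow = TRUE)
  mesh3(uverts, faces)
}

#' Write an STL file
#'
#' @param mesh a [mesh3()].
#' @param path output path.
#' @param binary write binary STL (default) or ASCII.
#' @param name solid name recorded in the header.
#' @return `path`, invisibly.
#' @export
write_stl <- function(mesh, path, binary = TRUE, name = "orthosetup") {
  v <- mesh$vertices
  f <- mesh$faces
  a <- v[f[, 1], , drop = FALSE]
  b <- v[f[, 2], , drop = FALSE]
  cc <- v[f[, 3], , drop = FALSE]
  n <- cbind(
    (b[, 2] - a[, 2]) * (cc[, 3] - a[, 3]) - (b[, 3] - a[, 3]) * (cc[, 2] - a[, 2]),
    (b[, 3] - a[, 3]) * (cc[, 1] - a[, 1]) - (b[, 1] - a[, 1]) * (cc[, 3] - a[, 3]),
    (b[, 1] - a[, 1]) * (cc[, 2] - a[, 2]) - (b[, 2] - a[, 2]) * (cc[, 1] - a[, 1])
  )
  len <- rownorms(n)
  len[len == 0] <- 1
  n <- n / len
  if (binary) {
    con <- file(path, "wb")
    on.exit(close(con))
    hdr <- charToRaw(sprintf("%-80s", paste("binary STL", name)))[1:80]
    writeBin(hdr, con)
    writeBin(as.integer(nrow(f)), con, size = 4, endian = "little")
    for (i in seq_len(nrow(f))) {
      writeBin(as.numeric(c(n[i, ], a[i, ], b[i, ], cc[i, ])),
        con,
        size = 4, endian = "little"
      )
      writeBin(as.raw(c(0, 0)), con)
    }
  } else {
    fmt <- function(p) sprintf("%.9g %.9g %.9g", p[1], p[2], p[3])
    lines <- character(0)
    for (i in seq_len(nrow(f))) {
      lines <- c(
        lines,
        sprintf("  facet normal %s", fmt(n[i, ])),
        "    outer loop",
        sprintf("      vertex %s", fmt(a[i, ])),
        sprintf("      vertex %s", fmt(b[i, ])),
        sprintf("      vertex %s", fmt(cc[i, ])),
        "    endloop",
        "  endfacet"
      )
    }
    writeLines(c(sprintf("solid %s", name), lines, sprintf("endsolid %s", name)), path)
  }
  invisible(path)
}

# ---- parametric solids used by the synthetic module and the fixtures --------

#' Axis-aligned box mesh
#'
#' @param lo,hi opposite corners (length-3, mm).
#' @return a watertight [mesh3()] with outward orientation.
#' @export
box_mesh <- function(lo, hi) {
  lo <- as_point3(lo)
  hi <- as_point3(hi)
  stopifnot(all(hi > lo))
  v <- as.matrix(expand.grid(x = c(lo[1], hi[1]), y = c(lo[2], hi[2]), z = c(lo[3], hi[3])))
  # vertex order: 1:(---) 2:(+--) 3:(-+-) 4:(++-) 5:(--+) 6:(+-+) 7:(-++) 8:(+++)
  f <- rbind(
    c(1, 3, 2), c(2, 3, 4), # bottom (z = lo)
    c(5, 6, 7), c(6, 8, 7), # top
    c(1, 2, 5), c(2, 6, 5), # y = lo
    c(3, 7, 4), c(4, 7, 8), # y = hi
    c(1, 5, 3), c(3, 5, 7), # x = lo
    c(2, 4, 6), c(4, 8, 6) # x = hi
  )
  mesh3(v, f)
}

#' Closed surface of revolution
#'
#' Revolves a piecewise-linear radial profile about the z axis. The profile is
#' given apical-to-coronal or vice versa as (radius, z) pairs; an end with
#' radius 0 becomes an apex point, an end with positive radius is closed by a
#' flat disc. Used for the frustum-crown/cone-root synthetic teeth.
#'
#' @param profile_r,profile_z numeric vectors (mm) of equal length >= 2.
#' @param n_seg number of angular segments.
#' @param max_ring_spacing long profile segments are subdivided into extra
#'   rings at most this far apart (mm), keeping facets near-isotropic.
#' @return a watertight [mesh3()].
#' @export
revolve_mesh <- function(profile_r, profile_z, n_seg = 24, max_ring_spacing = 1.5) {
  stopifnot(length(profile_r) == length(profile_z), length(profile_r) >= 2, n_seg >= 3)
  if (any(profile_r < 0)) stop("profile radii must be >= 0", call. = FALSE)
  if (any(profile_r[-c(1, length(profile_r))] <= 0)) {
    stop("only the profile endpoints may have zero radius", call. = FALSE)
  }
  rr <- profile_r[1]
  zz <- profile_z[1]
  for (i in seq_len(length(profile_r) - 1)) {
    len <- sqrt((profile_r[i + 1] - profile_r[i])^2 + (profile_z[i + 1] - profile_z[i])^2)
    nsub <- max(1L, ceiling(len / max_ring_spacing))
    f <- seq_len(nsub) / nsub
    rr <- c(rr, profile_r[i] + f * (profile_r[i + 1] - profile_r[i]))
    zz <- c(zz, profile_z[i] + f * (profile_z[i + 1] - profile_z[i]))
  }
  profile_r <- rr
  profile_z <- zz
  th <- 2 * pi * (0:(n_seg - 1)) / n_seg
  verts <- NULL
  ring_idx <- list() # vertex indices per profile station (length 1 => apex)
  for (i in seq_along(profile_r)) {
    if (profile_r[i] == 0) {
      verts <- rbind(verts, c(0, 0, profile_z[i]))
      ring_idx[[i]] <- nrow(verts)
    } else {
      ring <- cbind(profile_r[i] * cos(th), profile_r[i] * sin(th), profile_z[i])
      start <- if (is.null(verts)) 0 else nrow(verts)
      verts <- rbind(verts, ring)
      ring_idx[[i]] <- start + 1:n_seg
    }
  }
  nxt <- function(j) j %% n_seg + 1
  faces <- NULL
  for (i in seq_len(length(profile_r) - 1)) {
    lo <- ring_idx[[i]]
    hi <- ring_idx[[i + 1]]
    if (length(lo) == 1 && length(hi) == 1) stop("degenerate profile", call. = FALSE)
    if (length(lo) == 1) { # apex at bottom
      for (j in 1:n_seg) faces <- rbind(faces, c(lo, hi[j], hi[nxt(j)]))
    } else if (length(hi) == 1) { # apex at top
      for (j in 1:n_seg) faces <- rbind(faces, c(lo[j], hi, lo[nxt(j)]))
    } else {
      for (j in 1:n_seg) {
        faces <- rbind(
          faces,
          c(lo[j], hi[j], hi[nxt(j)]),
          c(lo[j], hi[nxt(j)], lo[nxt(j)])
        )
      }
    }
  }
  # close flat ends (positive-radius endpoints) with a center-fan cap
  close_cap <- function(ring, z, downward) {
    verts <<- rbind(verts, c(0, 0, z))
    ctr <- nrow(verts)
    for (j in 1:n_seg) {
      tri <- if (downward) c(ctr, ring[nxt(j)], ring[j]) else c(ctr, ring[j], ring[nxt(j)])
      faces <<- rbind(faces, tri)
    }
  }
  # orientation: assume profile_z increasing => bottom cap points down
  if (profile_r[1] > 0) close_cap(ring_idx[[1]], profile_z[1], downward = TRUE)
  nlast <- length(profile_r)
  if (profile_r[nlast] > 0) close_cap(ring_idx[[nlast]], profile_z[nlast], downward = FALSE)
  orient_mesh(mesh3(verts, faces))
}

# Make face windings consistent (BFS over shared edges) and outward
# (positive signed volume). Requires a closed 2-manifold face set.
orient_mesh <- function(mesh) {
  f <- mesh$faces
  nf <- nrow(f)
  edges_of <- function(tri) rbind(tri[c(1, 2)], tri[c(2, 3)], tri[c(3, 1)])
  ekey <- function(e) paste(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]))
  # map undirected edge -> incident faces
  all_e <- do.call(rbind, lapply(seq_len(nf), function(i) cbind(edges_of(f[i, ]), i)))
  keys <- ekey(all_e[, 1:2, drop = FALSE])
  inc <- split(all_e[, 3], keys)
  visited <- rep(FALSE, nf)
  for (seed in seq_len(nf)) {
    if (visited[seed]) next
    queue <- seed
    visited[seed] <- TRUE
    while (length(queue) > 0) {
      i <- queue[[1]]
      queue <- queue[-1]
      ei <- edges_of(f[i, ])
      for (r in 1:3) {
        nb <- setdiff(inc[[ekey(ei[r, , drop = FALSE])]], i)
        for (j in nb) {
          if (visited[j]) next
          ej <- edges_of(f[j, ])
          # consistent orientation: shared edge traversed in opposite directions
          same_dir <- any(ej[, 1] == ei[r, 1] & ej[, 2] == ei[r, 2])
          if (same_dir) f[j, ] <- f[j, c(1, 3, 2)]
          visited[j] <- TRUE
          queue <- c(queue, j)
        }
      }
    }
  }
  m <- mesh3(mesh$vertices, f)
  if (mesh_volume(m) < 0) m$faces <- m$faces[, c(1, 3, 2), drop = FALSE]
  m
}
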