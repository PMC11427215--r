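#' Triangular mesh of the circular domain
#'
#' Builds a structured triangulation of the disk from concentric rings of
#' nodes.  Ring node counts grow proportionally to the ring radius so that
#' the edge length is approximately uniform; consecutive rings are stitched
#' with a two-pointer strip triangulation.  Each ring receives a random
#' angular phase derived from `seed`, so meshes built with different seeds
#' (or edge lengths) do not share element boundaries -- the data-simulation
#' and reconstruction meshes are deliberately distinct discretizations.
#'
#' @param domain an [circular_domain()] object.
#' @param target_edge_length requested edge length in mm; must be positive
#'   and smaller than the radius.
#' @param seed integer seed for the ring phases.
#'
#' @return An object of class `ot_mesh` with node coordinates, triangles
#'   (counter-clockwise), element areas and centroids, the triangle
#'   adjacency table, and the ordered boundary-edge table with outward unit
#'   normals.
#' @export
build_circular_mesh <- function(domain, target_edge_length, seed = 1L) {
  R <- domain$radius
  h <- target_edge_length
  if (!is.numeric(h) || length(h) != 1L || h <= 0 || h >= R)
    stop("target_edge_length must satisfy 0 < target_edge_length < radius")

  n_outer <- max(26L, as.integer(round(2 * pi * R / h)))
  m <- max(1L, as.integer(round(R / h)))
  phases <- local_runif(m, seed) * 2 * pi

  nodes <- matrix(0, nrow = 1L, ncol = 2L)  # center node first
  ring_ids <- vector("list", m)
  ring_ang <- vector("list", m)
  for (i in seq_len(m)) {
    ri <- R * i / m
    ni <- max(6L, as.integer(round(n_outer * i / m)))
    ang <- (phases[i] + 2 * pi * (seq_len(ni) - 1L) / ni) %% (2 * pi)
    ord <- order(ang)
    ang <- ang[ord]
    ids <- nrow(nodes) + seq_len(ni)
    nodes <- rbind(nodes, cbind(ri * cos(ang), ri * sin(ang)))
    ring_ids[[i]] <- ids
    ring_ang[[i]] <- ang
  }

  tris <- vector("list", m)
  # central fan
  O <- ring_ids[[1L]]
  nb <- length(O)
  tris[[1L]] <- cbind(1L, O, O[c(2:nb, 1L)])
  if (m >= 2L) for (i in 2:m) {
    tris[[i]] <- annulus_strip(ring_ids[[i - 1L]], ring_ang[[i - 1L]],
                               ring_ids[[i]], ring_ang[[i]])
  }
  tri <- do.call(rbind, tris)
  storage.mode(tri) <- "integer"
  dimnames(tri) <- NULL

  # enforce counter-clockwise orientation
  sa <- signed_areas(nodes, tri)
  flip <- sa < 0
  if (any(flip)) tri[flip, c(2L, 3L)] <- tri[flip, c(3L, 2L)]
  areas <- abs(sa)
  if (any(areas <= 0))
    stop("mesher produced a degenerate element (zero area)")

  centroids <- (nodes[tri[, 1L], , drop = FALSE] +
                nodes[tri[, 2L], , drop = FALSE] +
                nodes[tri[, 3L], , drop = FALSE]) / 3

  adj <- triangle_adjacency(tri)
  boundary <- boundary_table(nodes, tri, adj, ring_ids[[m]], ring_ang[[m]])

  mesh <- structure(list(
    nodes = nodes,
    triangles = tri,
    areas = areas,
    centroids = centroids,
    adjacency = adj,
    boundary = boundary,
    radius = R,
    target_edge_length = h,
    seed = as.integer(seed)), class = "ot_mesh")
  validate_mesh(mesh)
  mesh
}

# uniform deviates from a private RNG stream; the session RNG is untouched
local_runif <- function(n, seed) {
  state <- get0(".Random.seed", envir = globalenv(), inherits = FALSE)
  on.exit({
    if (is.null(state)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", state, envir = globalenv())
  })
  set.seed(as.integer(seed) %% .Machine$integer.max)
  stats::runif(n)
}

signed_areas <- function(nodes, tri) {
  x1 <- nodes[tri[, 1L], 1L]; y1 <- nodes[tri[, 1L], 2L]
  x2 <- nodes[tri[, 2L], 1L]; y2 <- nodes[tri[, 2L], 2L]
  x3 <- nodes[tri[, 3L], 1L]; y3 <- nodes[tri[, 3L], 2L]
  0.5 * ((x2 - x1) * (y3 - y1) - (x3 - x1) * (y2 - y1))
}

# strip triangulation between two node rings sorted by angle
annulus_strip <- function(I, a, O, b) {
  na <- length(a); nb <- length(b)
  off <- (b - a[1L]) %% (2 * pi)
  j0 <- which.min(off)
  ordO <- c(j0:nb, if (j0 > 1L) 1:(j0 - 1L))
  O <- O[ordO]
  A <- a[1L] + (a - a[1L]) %% (2 * pi)
  B <- a[1L] + off[ordO]
  A_ext <- c(A, A[1L] + 2 * pi)
  B_ext <- c(B, B[1L] + 2 * pi)
  out <- matrix(0L, nrow = na + nb, ncol = 3L)
  i <- 1L; j <- 1L; ti <- 0L; tj <- 0L; t <- 0L
  while (ti < na || tj < nb) {
    t <- t + 1L
    if (ti < na && (tj >= nb || A_ext[i + 1L] <= B_ext[j + 1L])) {
      out[t, ] <- c(I[((i - 1L) %% na) + 1L],
                    I[(i %% na) + 1L],
                    O[((j - 1L) %% nb) + 1L])
      i <- i + 1L; ti <- ti + 1L
    } else {
      out[t, ] <- c(O[((j - 1L) %% nb) + 1L],
                    O[(j %% nb) + 1L],
                    I[((i - 1L) %% na) + 1L])
      j <- j + 1L; tj <- tj + 1L
    }
  }
  out
}

# adjacency across edge e = (tri[k, e], tri[k, e %% 3 + 1]); 0 = boundary
triangle_adjacency <- function(tri) {
  K <- nrow(tri)
  ek <- rep(seq_len(K), times = 3L)
  v1 <- c(tri[, 1L], tri[, 2L], tri[, 3L])
  v2 <- c(tri[, 2L], tri[, 3L], tri[, 1L])
  key <- paste(pmin(v1, v2), pmax(v1, v2))
  sp <- split(seq_along(key), key)
  adj <- matrix(0L, nrow = K, ncol = 3L)
  for (idx in sp) {
    if (length(idx) == 2L) {
      k1 <- ek[idx[1L]]; k2 <- ek[idx[2L]]
      e1 <- (idx[1L] - 1L) %/% K + 1L
      e2 <- (idx[2L] - 1L) %/% K + 1L
      adj[k1, e1] <- k2
      adj[k2, e2] <- k1
    } else if (length(idx) > 2L) {
      stop("non-manifold edge in triangulation")
    }
  }
  adj
}

boundary_table <- function(nodes, tri, adj, outer_ids, outer_ang) {
  K <- nrow(tri)
  nb <- length(outer_ids)
  n1 <- outer_ids
  n2 <- outer_ids[c(2:nb, 1L)]
  t1 <- outer_ang
  t2 <- outer_ang[c(2:nb, 1L)]
  t2 <- ifelse(t2 <= t1, t2 + 2 * pi, t2)
  # locate the triangle owning each boundary edge
  tri_of <- integer(nb); edge_of <- integer(nb)
  for (e in 1:3) {
    a <- tri[, e]; b <- tri[, (e %% 3L) + 1L]
    onb <- which(adj[, e] == 0L)
    if (!length(onb)) next
    key <- paste(pmin(a[onb], b[onb]), pmax(a[onb], b[onb]))
    want <- paste(pmin(n1, n2), pmax(n1, n2))
    hit <- match(want, key)
    ok <- !is.na(hit)
    tri_of[ok] <- onb[hit[ok]]
    edge_of[ok] <- e
  }
  if (any(tri_of == 0L))
    stop("boundary edge without an owning triangle; mesh is inconsistent")
  dx <- nodes[n2, 1L] - nodes[n1, 1L]
  dy <- nodes[n2, 2L] - nodes[n1, 2L]
  len <- sqrt(dx^2 + dy^2)
  # outward normal of the CCW-ordered boundary loop
  nx <- dy / len
  ny <- -dx / len
  data.frame(node1 = n1, node2 = n2, tri = tri_of, edge = edge_of,
             length = len, nx = nx, ny = ny, theta1 = t1, theta2 = t2)
}

#' Validate the mesh invariants
#'
#' Checks element areas, boundary-loop closure, outward unit normals,
#' centroid containment, and that the polygonal boundary area is within 1%
#' of the analytic disk area.  Called by [build_circular_mesh()]; exported
#' for meshes read back from disk.
#'
#' @param mesh an `ot_mesh`.
#' @return `mesh`, invisibly; errors on any violated invariant.
#' @export
validate_mesh <- function(mesh) {
  if (any(mesh$areas <= 0)) stop("mesh has non-positive element areas")
  b <- mesh$boundary
  if (!all(b$node2 == c(b$node1[-1L], b$node1[1L])))
    stop("boundary edges do not form a single closed loop")
  nrm <- sqrt(b$nx^2 + b$ny^2)
  if (max(abs(nrm - 1)) > 1e-12) stop("boundary normals are not unit length")
  # outwardness: normal points away from the origin for a centered disk
  mid <- cbind((mesh$nodes[b$node1, 1L] + mesh$nodes[b$node2, 1L]) / 2,
               (mesh$nodes[b$node1, 2L] + mesh$nodes[b$node2, 2L]) / 2)
  if (any(mid[, 1L] * b$nx + mid[, 2L] * b$ny <= 0))
    stop("boundary normals are not outward")
  ratio <- sum(mesh$areas) / (pi * mesh$radius^2)
  if (ratio < 0.99 || ratio > 1 + 1e-9)
    stop(sprintf("mesh area covers %.4f of the disk; expected in [0.99, 1]",
                 ratio))
  inside <- locate_points(mesh, mesh$centroids)
  if (any(!inside$inside)) stop("an element centroid falls outside the mesh")
  invisible(mesh)
}

#' Locate points in a mesh
#'
#' Finds the containing element of each query point by barycentric
#' coordinates, with a nearest-centroid fallback for points outside the
#' triangulation (reported through the `inside` flag).
#'
#' @param mesh an `ot_mesh`.
#' @param points numeric matrix (n x 2) of query coordinates in mm.
#' @param tol containment tolerance on barycentric coordinates.
#' @return A list with integer vector `element` and logical vector `inside`.
#' @export
locate_points <- function(mesh, points, tol = 1e-9) {
  points <- matrix(points, ncol = 2L)
  tri <- mesh$triangles
  A <- mesh$nodes[tri[, 1L], , drop = FALSE]
  e1 <- mesh$nodes[tri[, 2L], , drop = FALSE] - A
  e2 <- mesh$nodes[tri[, 3L], , drop = FALSE] - A
  det <- e1[, 1L] * e2[, 2L] - e1[, 2L] * e2[, 1L]
  n <- nrow(points)
  element <- integer(n)
  inside <- logical(n)
  for (i in seq_len(n)) {
    dx <- points[i, 1L] - A[, 1L]
    dy <- points[i, 2L] - A[, 2L]
    u <- (dx * e2[, 2L] - dy * e2[, 1L]) / det
    v <- (e1[, 1L] * dy - e1[, 2L] * dx) / det
    margin <- pmin(u, v, 1 - u - v)
    k <- which.max(margin)
    if (margin[k] >= -tol) {
      element[i] <- k
      inside[i] <- TRUE
    } else {
      d2 <- (mesh$centroids[, 1L] - points[i, 1L])^2 +
            (mesh$centroids[, 2L] - points[i, 2L])^2
      element[i] <- which.min(d2)
      inside[i] <- FALSE
    }
  }
  list(element = element, inside = inside)
}

#' @export
print.ot_mesh <- function(x, ...) {
  cat(sprintf(
    "Triangular disk mesh: %d nodes, %d elements, radius %g mm, h = %g mm\n",
    nrow(x$nodes), nrow(x$triangles), x$radius, x$target_edge_length))
  cat(sprintf("  area coverage: %.4f of the disk; %d boundary edges\n",
              sum(x$areas) / (pi * x$radius^2), nrow(x$boundary)))
  invisible(x)
}
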