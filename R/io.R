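#' Mesh serialization
#'
#' Plain structured-text mesh format: a `nodes` section (`x y` per line),
#' an `elements` section (`i j k` node indices), and a `boundary` section
#' (`i j` node pairs in loop order).  Derived quantities (areas, centroids,
#' adjacency, normals) are recomputed on read and the mesh is re-validated.
#'
#' @param mesh an `ot_mesh`.
#' @param path output file.
#' @export
write_mesh <- function(mesh, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# otmc mesh radius=%.17g edge=%.17g seed=%d",
                     mesh$radius, mesh$target_edge_length, mesh$seed), con)
  writeLines(sprintf("nodes %d", nrow(mesh$nodes)), con)
  writeLines(sprintf("%.17g %.17g", mesh$nodes[, 1L], mesh$nodes[, 2L]), con)
  writeLines(sprintf("elements %d", nrow(mesh$triangles)), con)
  writeLines(sprintf("%d %d %d", mesh$triangles[, 1L], mesh$triangles[, 2L],
                     mesh$triangles[, 3L]), con)
  writeLines(sprintf("boundary %d", nrow(mesh$boundary)), con)
  writeLines(sprintf("%d %d", mesh$boundary$node1, mesh$boundary$node2), con)
  invisible(path)
}

#' @rdname write_mesh
#' @return [read_mesh()] returns the `ot_mesh`.
#' @export
read_mesh <- function(path) {
  lines <- readLines(path)
  hdr <- lines[1L]
  get_num <- function(key) {
    m <- regmatches(hdr, regexec(paste0(key, "=([-0-9.eE+]+)"), hdr))[[1L]]
    as.numeric(m[2L])
  }
  radius <- get_num("radius"); edge <- get_num("edge"); seed <- get_num("seed")
  i <- 2L
  stopifnot(startsWith(lines[i], "nodes"))
  n <- as.integer(strsplit(lines[i], " ")[[1L]][2L])
  nodes <- matrix(scan(text = lines[(i + 1L):(i + n)], quiet = TRUE),
                  ncol = 2L, byrow = TRUE)
  i <- i + n + 1L
  stopifnot(startsWith(lines[i], "elements"))
  K <- as.integer(strsplit(lines[i], " ")[[1L]][2L])
  tri <- matrix(as.integer(scan(text = lines[(i + 1L):(i + K)],
                                quiet = TRUE)), ncol = 3L, byrow = TRUE)
  i <- i + K + 1L
  stopifnot(startsWith(lines[i], "boundary"))
  nb <- as.integer(strsplit(lines[i], " ")[[1L]][2L])
  bnd <- matrix(as.integer(scan(text = lines[(i + 1L):(i + nb)],
                                quiet = TRUE)), ncol = 2L, byrow = TRUE)
  rebuild_mesh(nodes, tri, bnd, radius, edge, seed)
}

# reconstruct the derived mesh quantities from the serialized core
rebuild_mesh <- function(nodes, tri, bnd, radius, edge, seed) {
  sa <- signed_areas(nodes, tri)
  flip <- sa < 0
  if (any(flip)) tri[flip, c(2L, 3L)] <- tri[flip, c(3L, 2L)]
  areas <- abs(sa)
  centroids <- (nodes[tri[, 1L], , drop = FALSE] +
                nodes[tri[, 2L], , drop = FALSE] +
                nodes[tri[, 3L], , drop = FALSE]) / 3
  adj <- triangle_adjacency(tri)
  ang <- atan2(nodes[bnd[, 1L], 2L], nodes[bnd[, 1L], 1L]) %% (2 * pi)
  boundary <- boundary_table(nodes, tri, adj, bnd[, 1L], ang)
  mesh <- structure(list(
    nodes = nodes, triangles = tri, areas = areas, centroids = centroids,
    adjacency = adj, boundary = boundary, radius = radius,
    target_edge_length = edge, seed = as.integer(seed)), class = "ot_mesh")
  validate_mesh(mesh)
  mesh
}

#' Field serialization
#'
#' Tab-separated element table (`element`, `mua`, `mus`) with the
#' anisotropy recorded in the header line.
#'
#' @param field an `ot_field`.
#' @param path file path.
#' @export
write_field <- function(field, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# otmc field g=%.17g", field$g), con)
  writeLines("element\tmua\tmus", con)
  writeLines(sprintf("%d\t%.17g\t%.17g", seq_along(field$mua),
                     field$mua, field$mus), con)
  invisible(path)
}

#' @rdname write_field
#' @export
read_field <- function(path) {
  hdr <- readLines(path, n = 1L)
  g <- as.numeric(regmatches(hdr, regexec("g=([-0-9.eE+]+)", hdr))[[1L]][2L])
  tab <- utils::read.delim(path, comment.char = "#")
  optical_field(tab$mua, tab$mus, g = g)
}

#' Measurement serialization
#'
#' Tab-separated table with one row per source-detector pair: amplitude
#' and phase of the complex exitance plus their noise standard deviations.
#'
#' @param meas an `ot_measurement`.
#' @param path file path.
#' @export
write_measurements <- function(meas, path) {
  S <- meas$n_sources; B <- meas$n_detectors
  M2 <- S * B
  amp <- meas$values[1:M2]
  phs <- meas$values[(M2 + 1):(2 * M2)]
  sa <- if (is.null(meas$sigma)) rep(NA_real_, M2) else meas$sigma[1:M2]
  sp <- if (is.null(meas$sigma)) rep(NA_real_, M2) else
    meas$sigma[(M2 + 1):(2 * M2)]
  tab <- data.frame(source = rep(seq_len(S), each = B),
                    detector = rep(seq_len(B), times = S),
                    amplitude = amp, phase = phs,
                    sigma_amplitude = sa, sigma_phase = sp)
  utils::write.table(tab, path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' @rdname write_measurements
#' @export
read_measurements <- function(path) {
  tab <- utils::read.delim(path)
  S <- max(tab$source); B <- max(tab$detector)
  ord <- order(tab$source, tab$detector)
  tab <- tab[ord, ]
  sigma <- c(tab$sigma_amplitude, tab$sigma_phase)
  if (anyNA(sigma)) sigma <- NULL
  measurement_vector(c(tab$amplitude, tab$phase), sigma, S, B)
}

#' Run-configuration files
#'
#' YAML configuration snapshot (every argument of a run, plus the seed) so
#' a saved run can be replayed exactly.
#'
#' @param config named list.
#' @param path file path.
#' @export
write_config <- function(config, path) {
  yaml::write_yaml(config, path)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) yaml::read_yaml(path)

#' Monte Carlo result serialization
#'
#' Writes one source's tallies to a structured text file: the complex
#' exitance per detector (with its standard errors) and, when present, the
#' Jacobian accumulators in sparse coordinate-list layout (detector,
#' element, real, imaginary), for both the path-length (`S_a`) and
#' scatter-count (`S_s`) accumulators.
#'
#' @param mc an `mc_result` from [mc_simulate()].
#' @param path file path.
#' @export
write_mc_result <- function(mc, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# otmc mc_result source=%d P=%.17g seed=%.17g",
                     mc$source_index, mc$P, as.numeric(mc$seed)), con)
  writeLines(sprintf("exitance %d", length(mc$Y)), con)
  writeLines("detector\tre\tim\tse_re\tse_im\tA", con)
  writeLines(sprintf("%d\t%.17g\t%.17g\t%.17g\t%.17g\t%.17g",
                     seq_along(mc$Y), Re(mc$Y), Im(mc$Y),
                     mc$Y_se_re, mc$Y_se_im, mc$A), con)
  for (nm in c("S_a", "S_s")) {
    M <- mc[[nm]]
    if (is.null(M)) next
    nz <- which(M != 0, arr.ind = TRUE)
    writeLines(sprintf("%s %d", nm, nrow(nz)), con)
    writeLines("detector\telement\tre\tim", con)
    if (nrow(nz))
      writeLines(sprintf("%d\t%d\t%.17g\t%.17g", nz[, 1L], nz[, 2L],
                         Re(M[nz]), Im(M[nz])), con)
  }
  invisible(path)
}

#' Write a per-iteration run log
#'
#' @param result an `sgn_result`.
#' @param path file path (tab-separated).
#' @export
write_run_log <- function(result, path) {
  utils::write.table(result$history, path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}
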