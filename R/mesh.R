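#' Labelled triangulated lumen surface mesh
#'
#' Container for the luminal wall surface used by the moving-boundary
#' stiffness stage: node coordinates (m), triangular faces, outward unit
#' normals, a per-node region label (one label per cine-MRI analysis
#' region), and the inlet/outlet boundary-ring node sets which are held
#' fixed during wall motion.
#'
#' @param nodes numeric matrix n x 3 (m).
#' @param faces integer matrix f x 3 (1-based node indices).
#' @param normals numeric matrix n x 3, unit outward normals.
#' @param region character vector length n.
#' @param boundary_rings named list of integer node-index vectors (e.g.
#'   `inlet`, `outlet`) fixed in place.
#' @param rings optional list of integer vectors grouping nodes into
#'   cross-sectional rings (used by slice-based lumen-area evaluation).
#' @return object of class `surface_mesh`.
#' @export
surface_mesh <- function(nodes, faces, normals, region,
                         boundary_rings = list(), rings = NULL) {
  nodes <- as.matrix(nodes); normals <- as.matrix(normals)
  faces <- as.matrix(faces)
  n <- nrow(nodes)
  stopifnot(ncol(nodes) == 3, ncol(normals) == 3, ncol(faces) == 3,
            nrow(normals) == n, length(region) == n)
  nl <- sqrt(rowSums(normals^2))
  if (any(abs(nl - 1) > 1e-6)) normals <- normals / nl
  if (any(is.na(region))) stop("every node must carry a region label")
  if (max(faces) > n || min(faces) < 1) stop("face indices out of range")
  for (r in boundary_rings)
    if (any(r < 1 | r > n)) stop("boundary ring indices out of range")
  structure(list(nodes = nodes, faces = faces, normals = normals,
                 region = as.character(region),
                 boundary_rings = boundary_rings, rings = rings),
            class = "surface_mesh")
}

#' @export
print.surface_mesh <- function(x, ...) {
  cat(sprintf("Surface mesh: %d nodes, %d triangles, regions: %s\n",
              nrow(x$nodes), nrow(x$faces),
              paste(unique(x$region), collapse = ", ")))
  invisible(x)
}

#' All boundary-ring node indices of a mesh
#' @param mesh `surface_mesh`.
#' @return integer vector (possibly empty).
#' @export
boundary_nodes <- function(mesh) {
  unique(unlist(mesh$boundary_rings, use.names = FALSE))
}

#' One-ring vertex adjacency of a triangulated mesh
#' @param mesh `surface_mesh`.
#' @return list of integer neighbour vectors, one per node.
#' @export
vertex_adjacency <- function(mesh) {
  n <- nrow(mesh$nodes)
  f <- mesh$faces
  e <- rbind(f[, c(1, 2)], f[, c(2, 3)], f[, c(3, 1)])
  e <- rbind(e, e[, 2:1])
  adj <- split(e[, 2], factor(e[, 1], levels = seq_len(n)))
  lapply(adj, function(v) sort(unique(v)))
}

#' Area-weighted outward vertex normals from face orientation
#' @param nodes n x 3 coordinates.
#' @param faces f x 3 indices (consistent outward winding).
#' @return n x 3 unit normal matrix.
#' @export
compute_vertex_normals <- function(nodes, faces) {
  n <- nrow(nodes)
  nrm <- matrix(0, n, 3)
  v1 <- nodes[faces[, 2], ] - nodes[faces[, 1], ]
  v2 <- nodes[faces[, 3], ] - nodes[faces[, 1], ]
  fn <- cbind(v1[, 2] * v2[, 3] - v1[, 3] * v2[, 2],
              v1[, 3] * v2[, 1] - v1[, 1] * v2[, 3],
              v1[, 1] * v2[, 2] - v1[, 2] * v2[, 1])
  for (k in 1:3) {
    idx <- faces[, k]
    for (c in 1:3) nrm[, c] <- nrm[, c] +
        as.numeric(tapply(fn[, c], factor(idx, levels = seq_len(n)), sum,
                          default = 0))
  }
  nrm[is.na(nrm)] <- 0
  len <- sqrt(rowSums(nrm^2))
  len[len == 0] <- 1
  nrm / len
}

ring_polygon_area <- function(pts) {
  # enclosed area of a closed 3D ring: project onto the best-fit plane
  ctr <- colMeans(pts)
  q <- sweep(pts, 2, ctr)
  # Newell normal
  np <- nrow(q)
  nx <- ny <- nz <- 0
  for (i in seq_len(np)) {
    j <- if (i == np) 1L else i + 1L
    nx <- nx + (q[i, 2] - q[j, 2]) * (q[i, 3] + q[j, 3])
    ny <- ny + (q[i, 3] - q[j, 3]) * (q[i, 1] + q[j, 1])
    nz <- nz + (q[i, 1] - q[j, 1]) * (q[i, 2] + q[j, 2])
  }
  nrm <- c(nx, ny, nz)
  nrm <- nrm / sqrt(sum(nrm^2))
  # orthonormal in-plane basis
  a <- if (abs(nrm[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  u <- a - sum(a * nrm) * nrm; u <- u / sqrt(sum(u^2))
  v <- c(nrm[2] * u[3] - nrm[3] * u[2],
         nrm[3] * u[1] - nrm[1] * u[3],
         nrm[1] * u[2] - nrm[2] * u[1])
  x <- q %*% u; y <- q %*% v
  o <- order(atan2(y, x))
  x <- x[o]; y <- y[o]
  j <- c(seq_len(np)[-1], 1L)
  abs(sum(x * y[j] - x[j] * y)) / 2
}

#' Write a surface mesh (with optional point data) as legacy ASCII VTK
#'
#' Writes a `POLYDATA` dataset with triangle polygons and optional
#' `POINT_DATA` arrays: integer region ids, scalar stiffness, and a
#' displacement vector field.
#'
#' @param mesh `surface_mesh`.
#' @param path output `.vtk` path.
#' @param stiffness optional per-node stiffness (Pa/m).
#' @param displacement optional n x 3 displacement matrix (m).
#' @export
write_mesh_vtk <- function(mesh, path, stiffness = NULL,
                           displacement = NULL) {
  n <- nrow(mesh$nodes); f <- nrow(mesh$faces)
  con <- file(path, "w")
  on.exit(close(con))
  wr <- function(...) cat(..., "\n", sep = "", file = con)
  wr("# vtk DataFile Version 3.0")
  wr("aortacal lumen surface")
  wr("ASCII")
  wr("DATASET POLYDATA")
  wr(sprintf("POINTS %d double", n))
  utils::write.table(format(mesh$nodes, digits = 10, trim = TRUE,
                            scientific = TRUE),
                     con, row.names = FALSE, col.names = FALSE,
                     quote = FALSE)
  wr(sprintf("POLYGONS %d %d", f, 4 * f))
  utils::write.table(cbind(3L, mesh$faces - 1L), con, row.names = FALSE,
                     col.names = FALSE, quote = FALSE)
  wr(sprintf("POINT_DATA %d", n))
  regs <- unique(mesh$region)
  wr("SCALARS region_id int 1")
  wr("LOOKUP_TABLE default")
  writeLines(as.character(match(mesh$region, regs) - 1L), con)
  wr(sprintf("FIELD region_names 1"))
  wr(sprintf("region_name_table 1 %d string_placeholder", length(regs)))
  writeLines(regs, con)
  if (!is.null(stiffness)) {
    wr("SCALARS stiffness_pa_per_m double 1")
    wr("LOOKUP_TABLE default")
    writeLines(format(stiffness, digits = 10, trim = TRUE), con)
  }
  if (!is.null(displacement)) {
    wr("VECTORS displacement_m double")
    utils::write.table(format(displacement, digits = 10, trim = TRUE,
                              scientific = TRUE),
                       con, row.names = FALSE, col.names = FALSE,
                       quote = FALSE)
  }
  invisible(path)
}

#' Read a legacy ASCII VTK POLYDATA surface written by [write_mesh_vtk()]
#'
#' @param path `.vtk` path.
#' @param region_map optional data.frame `node_id,region` overriding the
#'   embedded region labels (e.g. a sidecar map for an unlabelled STL-origin
#'   surface).
#' @return `surface_mesh` (normals recomputed from face winding; boundary
#'   rings are not stored in VTK and come back empty).
#' @export
read_mesh_vtk <- function(path, region_map = NULL) {
  ln <- readLines(path)
  ip <- grep("^POINTS", ln)[1]
  n <- as.integer(strsplit(ln[ip], "\\s+")[[1]][2])
  pts <- scan(text = ln[(ip + 1):(ip + n)], quiet = TRUE)
  nodes <- matrix(pts, ncol = 3, byrow = TRUE)
  ig <- grep("^POLYGONS", ln)[1]
  f <- as.integer(strsplit(ln[ig], "\\s+")[[1]][2])
  fv <- scan(text = ln[(ig + 1):(ig + f)], quiet = TRUE)
  fm <- matrix(fv, ncol = 4, byrow = TRUE)
  faces <- fm[, 2:4, drop = FALSE] + 1L
  region <- rep("region1", n)
  ir <- grep("^SCALARS region_id", ln)
  if (length(ir)) {
    ids <- as.integer(ln[(ir[1] + 2):(ir[1] + 1 + n)])
    it <- grep("^region_name_table", ln)
    if (length(it)) {
      nregs <- as.integer(strsplit(ln[it[1]], "\\s+")[[1]][3])
      regs <- ln[(it[1] + 1):(it[1] + nregs)]
      region <- regs[ids + 1L]
    } else region <- as.character(ids)
  }
  if (!is.null(region_map)) region[region_map$node_id] <- region_map$region
  surface_mesh(nodes, faces, compute_vertex_normals(nodes, faces), region)
}

#' Write a surface mesh as ASCII STL
#'
#' STL carries no labels; pair it with a `node_id,region` sidecar CSV when
#' region information must survive the round trip.
#' @param mesh `surface_mesh`.
#' @param path output `.stl` path.
#' @export
write_mesh_stl <- function(mesh, path) {
  con <- file(path, "w")
  on.exit(close(con))
  cat("solid lumen\n", file = con)
  v1 <- mesh$nodes[mesh$faces[, 2], , drop = FALSE] -
    mesh$nodes[mesh$faces[, 1], , drop = FALSE]
  v2 <- mesh$nodes[mesh$faces[, 3], , drop = FALSE] -
    mesh$nodes[mesh$faces[, 1], , drop = FALSE]
  fn <- cbind(v1[, 2] * v2[, 3] - v1[, 3] * v2[, 2],
              v1[, 3] * v2[, 1] - v1[, 1] * v2[, 3],
              v1[, 1] * v2[, 2] - v1[, 2] * v2[, 1])
  fn <- fn / pmax(sqrt(rowSums(fn^2)), 1e-300)
  for (i in seq_len(nrow(mesh$faces))) {
    cat(sprintf("facet normal %g %g %g\n outer loop\n", fn[i, 1], fn[i, 2],
                fn[i, 3]), file = con)
    for (k in 1:3) {
      p <- mesh$nodes[mesh$faces[i, k], ]
      cat(sprintf("  vertex %g %g %g\n", p[1], p[2], p[3]), file = con)
    }
    cat(" endloop\nendfacet\n", file = con)
  }
  cat("endsolid lumen\n", file = con)
  invisible(path)
}
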