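#' Regional area compliance
#'
#' `CA = D * Amin`: absolute luminal area change per unit pressure, the
#' quantity that calibrates the wall stiffness of a cine-MRI region.
#'
#' @param di distensibility (1/Pa).
#' @param amin diastolic cross-sectional area (m^2).
#' @return area compliance (m^2/Pa).
#' @export
area_compliance <- function(di, amin) {
  if (any(di < 0) || any(amin < 0)) stop("inputs must be non-negative")
  di * amin
}

#' Local lumen cross-sectional area at mesh nodes
#'
#' Default (`method = "region"`): each node takes its region's
#' representative (diastolic) area, matching how the stiffness regions are
#' calibrated against per-plane cine-MRI measurements. With
#' `method = "slice"` the enclosed area of the node's cross-sectional ring
#' is computed geometrically (requires ring metadata on the mesh).
#'
#' @param mesh `surface_mesh`.
#' @param region_areas named vector of per-region diastolic areas (m^2);
#'   required for `method = "region"`.
#' @param method `"region"` or `"slice"`.
#' @param nodes optional node indices (default all).
#' @return numeric vector of areas (m^2), one per requested node.
#' @export
local_lumen_area <- function(mesh, region_areas = NULL,
                             method = c("region", "slice"), nodes = NULL) {
  method <- match.arg(method)
  if (is.null(nodes)) nodes <- seq_len(nrow(mesh$nodes))
  if (method == "region") {
    if (is.null(region_areas)) stop("region_areas required for method='region'")
    reg <- mesh$region[nodes]
    if (!all(reg %in% names(region_areas)))
      stop("unlabelled node or missing region area: ",
           paste(setdiff(reg, names(region_areas)), collapse = ", "))
    return(unname(region_areas[reg]))
  }
  if (is.null(mesh$rings)) stop("mesh carries no ring metadata for slicing")
  ring_of <- integer(nrow(mesh$nodes))
  for (k in seq_along(mesh$rings)) ring_of[mesh$rings[[k]]] <- k
  ring_area <- vapply(mesh$rings, function(idx)
    ring_polygon_area(mesh$nodes[idx, , drop = FALSE]), numeric(1))
  if (any(ring_of[nodes] == 0)) stop("node not on any ring")
  ring_area[ring_of[nodes]]
}

#' Per-node wall stiffness field from regional area compliance
#'
#' The moving-boundary wall law displaces each wall node along its normal by
#' the transmural pressure divided by a local stiffness coefficient. That
#' coefficient is chosen so a region of lumen area `An` and area compliance
#' `CA` reproduces its measured compliance under a uniform pressure load:
#' `Kn = 2*sqrt(pi*An) / CA`. Nodes on the fixed inlet/outlet rings are
#' stiffened by `boundary_factor` so the boundary does not dilate.
#'
#' @param mesh `surface_mesh`.
#' @param ca_by_region named per-region area compliances (m^2/Pa). A zero
#'   (rigid) region receives the capped maximum stiffness with a warning.
#' @param region_areas named per-region diastolic areas (m^2) for the
#'   `An` term; see [local_lumen_area()].
#' @param boundary_factor stiffness multiplier on boundary-ring nodes
#'   (default 1e3).
#' @param pext external (abluminal) pressure (Pa), normally the diastolic
#'   pressure; stored on the field for the displacement operator.
#' @param k_cap maximum stiffness assigned to rigid regions (Pa/m).
#' @param area_method passed to [local_lumen_area()].
#' @return object of class `stiffness_field`: list with `K` (Pa/m), `An`
#'   (m^2), `ca_by_region`, `pext`, `passes` (smoothing passes applied so
#'   far), `boundary_factor`.
#' @export
stiffness_field <- function(mesh, ca_by_region, region_areas,
                            boundary_factor = 1e3, pext = 0,
                            k_cap = 1e12,
                            area_method = c("region", "slice")) {
  area_method <- match.arg(area_method)
  regs <- unique(mesh$region)
  if (!all(regs %in% names(ca_by_region)))
    stop("missing area compliance for region(s): ",
         paste(setdiff(regs, names(ca_by_region)), collapse = ", "))
  An <- local_lumen_area(mesh, region_areas, method = area_method)
  ca <- unname(ca_by_region[mesh$region])
  K <- numeric(nrow(mesh$nodes))
  rigid <- ca <= 0
  if (any(rigid)) {
    warning("rigid region(s) with zero area compliance: capped stiffness")
    K[rigid] <- k_cap
  }
  K[!rigid] <- 2 * sqrt(pi * An[!rigid]) / ca[!rigid]
  K <- pmin(K, k_cap)
  bn <- boundary_nodes(mesh)
  K[bn] <- K[bn] * boundary_factor
  if (any(!is.finite(K)) || any(K <= 0)) stop("stiffness field not positive finite")
  structure(list(K = K, An = An, ca_by_region = ca_by_region,
                 pext = pext, passes = 0L,
                 boundary_factor = boundary_factor),
            class = "stiffness_field")
}

#' @export
print.stiffness_field <- function(x, ...) {
  cat(sprintf(
    "Stiffness field: %d nodes, K in [%.3g, %.3g] Pa/m, %d smoothing pass(es)\n",
    length(x$K), min(x$K), max(x$K), x$passes))
  invisible(x)
}

#' Smooth a stiffness field by neighbour averaging
#'
#' Each pass replaces every interior node's stiffness by the arithmetic
#' mean of its one-ring neighbours, eliminating the discontinuities between
#' adjacent calibration regions; boundary-ring nodes are frozen. Averaging
#' obeys the discrete maximum principle: no pass creates values outside the
#' input field's range.
#'
#' @param field `stiffness_field`.
#' @param mesh the `surface_mesh` the field lives on.
#' @param passes number of smoothing passes (default 5).
#' @param on `"K"` (default) to smooth the stiffness itself, or
#'   `"compliance"` to smooth `1/K` and invert back.
#' @return the smoothed `stiffness_field`.
#' @export
smooth_field <- function(field, mesh, passes = 5, on = c("K", "compliance")) {
  on <- match.arg(on)
  stopifnot(passes >= 0)
  if (passes == 0) return(field)
  adj <- vertex_adjacency(mesh)
  frozen <- boundary_nodes(mesh)
  free <- setdiff(seq_along(field$K), frozen)
  x <- if (on == "K") field$K else 1 / field$K
  for (p in seq_len(passes)) {
    xin <- x
    for (i in free) x[i] <- mean(xin[adj[[i]]])
  }
  field$K <- if (on == "K") x else 1 / x
  field$passes <- field$passes + as.integer(passes)
  field
}

#' Pressure-driven nodal displacement (moving-boundary wall law)
#'
#' Each wall node moves along its outward normal in proportion to the local
#' transmural pressure: `delta_n = (p_n - pext)/K_n * n_hat`. Positive
#' transmural pressure moves the wall outward; the stiffened boundary rings
#' barely move.
#'
#' @param mesh `surface_mesh`.
#' @param field `stiffness_field` (supplies `K` and `pext`).
#' @param p luminal pressure (Pa): scalar or per-node vector.
#' @return list with `vectors` (n x 3, m), `magnitude` (n, signed along the
#'   normal), and `displaced` (n x 3 displaced coordinates).
#' @export
displace_nodes <- function(mesh, field, p) {
  n <- nrow(mesh$nodes)
  if (length(p) == 1L) p <- rep(p, n)
  if (length(p) != n || any(!is.finite(p))) stop("invalid pressure vector")
  mag <- (p - field$pext) / field$K
  vec <- mesh$normals * mag
  list(vectors = vec, magnitude = mag, displaced = mesh$nodes + vec)
}

#' Write a stiffness/displacement field as flat CSV
#'
#' Columns `node_id,region,K_pa_per_m,ux,uy,uz` (displacement columns zero
#' when no displacement is supplied).
#' @param mesh `surface_mesh`.
#' @param field `stiffness_field`.
#' @param path output path.
#' @param displacement optional n x 3 matrix (m).
#' @export
write_field_csv <- function(mesh, field, path, displacement = NULL) {
  n <- nrow(mesh$nodes)
  if (is.null(displacement)) displacement <- matrix(0, n, 3)
  utils::write.csv(
    data.frame(node_id = seq_len(n), region = mesh$region,
               K_pa_per_m = field$K,
               ux = displacement[, 1], uy = displacement[, 2],
               uz = displacement[, 3]),
    path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
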