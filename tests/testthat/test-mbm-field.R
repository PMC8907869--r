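test_that("area compliance is the distensibility-area product", {
  expect_equal(area_compliance(0, 5e-4), 0)
  expect_equal(area_compliance(2.5e-5, 5e-4), 1.25e-8)
  expect_equal(area_compliance(2 * 2.5e-5, 5e-4),
               2 * area_compliance(2.5e-5, 5e-4))
  expect_equal(area_compliance(2.5e-5, 2 * 5e-4),
               2 * area_compliance(2.5e-5, 5e-4))
  expect_error(area_compliance(-1, 1), "non-negative")
})

test_that("lumen area lookup works per region and by slicing", {
  r <- 0.01
  mesh <- make_cylinder_mesh(r, 0.1, n_circ = 48, n_axial = 10,
                             regions = c("a", "b"))
  # region lookup
  An <- local_lumen_area(mesh, region_areas = c(a = 1e-4, b = 2e-4))
  expect_setequal(unique(An), c(1e-4, 2e-4))
  # step change exactly at the region boundary
  z <- mesh$nodes[, 3]
  expect_true(all(An[z < 0.0499] == 1e-4))
  expect_true(all(An[z > 0.0501] == 2e-4))
  expect_error(local_lumen_area(mesh, region_areas = c(a = 1e-4)),
               "missing region")

  # geometric slicing recovers pi r^2 within 1% at n_circ = 48
  As <- local_lumen_area(mesh, method = "slice")
  expect_lt(max(rel_err(As, pi * r^2)), 0.01)

  # bent tube: ring area still within 3% of the straight cross-section
  tor <- make_torus_mesh(0.008, 0.04, span = pi, n_circ = 48, n_axial = 16)
  At <- local_lumen_area(tor, method = "slice")
  expect_lt(max(rel_err(At, pi * 0.008^2)), 0.03)
})

test_that("stiffness field follows the compliance-calibrated wall law", {
  mesh <- make_cylinder_mesh(0.0126, 0.1, n_circ = 48, n_axial = 10)
  An <- 5e-4; CA <- 1.25e-8
  f <- stiffness_field(mesh, c(wall = CA), c(wall = An))
  interior <- setdiff(seq_len(nrow(mesh$nodes)), boundary_nodes(mesh))
  expect_equal(unique(f$K[interior]), 2 * sqrt(pi * An) / CA)
  expect_lt(rel_err(unique(f$K[interior]), 6.341e6), 1e-3)

  # quadrupling the lumen area doubles the stiffness
  f4 <- stiffness_field(mesh, c(wall = CA), c(wall = 4 * An))
  expect_equal(unique(f4$K[interior]),
               2 * unique(f$K[interior]), tolerance = 1e-12)

  # softer wall: stiffness vanishes as compliance grows
  fbig <- stiffness_field(mesh, c(wall = 1e6), c(wall = An))
  expect_lt(max(fbig$K[interior]), 1e-4)

  # boundary rings are stiffened by the fixation factor
  bn <- boundary_nodes(mesh)
  expect_equal(unique(f$K[bn]), 1e3 * unique(f$K[interior]))

  # rigid region gets the capped maximum with a warning
  expect_warning(fr <- stiffness_field(mesh, c(wall = 0), c(wall = An)),
                 "rigid")
  expect_true(all(fr$K[interior] == max(fr$K[interior])))
})

test_that("neighbour-average smoothing obeys the maximum principle", {
  mesh <- make_cylinder_mesh(0.01, 0.1, n_circ = 20, n_axial = 9,
                             regions = c("a", "b"))
  f <- stiffness_field(mesh, c(a = 1e-8, b = 4e-8),
                       c(a = 3e-4, b = 3e-4))
  # uniform field is a fixed point (no boundary stiffening, truly uniform)
  fu <- stiffness_field(mesh, c(a = 1e-8, b = 1e-8), c(a = 3e-4, b = 3e-4),
                        boundary_factor = 1)
  fu5 <- smooth_field(fu, mesh, passes = 5)
  expect_equal(fu5$K, fu$K, tolerance = 1e-12)

  # zero passes is the identity
  expect_equal(smooth_field(f, mesh, passes = 0)$K, f$K)

  # arbitrary random fields never leave their input range
  adjn <- vertex_adjacency(mesh)
  set.seed(5)
  for (i in 1:5) {
    frand <- f
    frand$K <- stats::runif(length(f$K), 1e5, 1e9)
    sm <- smooth_field(frand, mesh, passes = sample(1:6, 1))
    expect_gte(min(sm$K), min(frand$K) - 1e-6)
    expect_lte(max(sm$K), max(frand$K) + 1e-6)
  }

  # two-region step: the largest neighbour jump shrinks every pass and the
  # frozen boundary rings never move
  jump <- function(K) {
    mx <- 0
    for (i in seq_along(adjn)) mx <- max(mx, abs(K[i] - K[adjn[[i]]]))
    mx
  }
  bn <- boundary_nodes(mesh)
  prev <- f
  jumps <- jump(f$K)
  for (p in 1:5) {
    cur <- smooth_field(prev, mesh, passes = 1)
    expect_equal(cur$K[bn], f$K[bn])
    jumps <- c(jumps, jump(cur$K))
    prev <- cur
  }
  expect_true(all(diff(jumps) < 0))
  expect_equal(prev$passes, 5L)
})

test_that("displacement follows the transmural pressure along normals", {
  mesh <- make_cylinder_mesh(0.01, 0.12, n_circ = 64, n_axial = 12)
  An <- pi * 0.01^2
  CA <- 1.25e-8
  pext <- mmhg_to_pa(72)
  f <- stiffness_field(mesh, c(wall = CA), c(wall = An), pext = pext)

  # zero transmural pressure, zero displacement
  d0 <- displace_nodes(mesh, f, pext)
  expect_true(all(d0$magnitude == 0))

  # negative transmural pressure moves the wall inward
  din <- displace_nodes(mesh, f, pext - 500)
  expect_true(all(din$magnitude < 0))
  rad <- sqrt(rowSums(din$displaced[, 1:2]^2))
  expect_true(all(rad < 0.01))

  expect_error(displace_nodes(mesh, f, c(NA, rep(1, nrow(mesh$nodes) - 1))),
               "pressure")

  # boundary rings stay put relative to the interior
  dup <- displace_nodes(mesh, f, pext + mmhg_to_pa(36))
  bn <- boundary_nodes(mesh)
  interior <- setdiff(seq_len(nrow(mesh$nodes)), bn)
  expect_lte(max(abs(dup$magnitude[bn])),
             stats::median(abs(dup$magnitude[interior])) / 1e3 + 1e-15)
})

test_that("cylinder displacement recovers the prescribed area compliance", {
  # the design identity of the wall law: under a uniform pulse load the
  # enclosed area grows by CA * Ppulse (first-order in dr/r)
  ppulse_pa <- mmhg_to_pa(36)
  for (r in c(0.005, 0.010, 0.015)) {
    amin <- pi * r^2
    # distensibility chosen for ~5% systolic area pulsation
    D <- 0.05 / ppulse_pa
    CA <- area_compliance(D, amin)
    mesh <- make_cylinder_mesh(r, 10 * r, n_circ = 64, n_axial = 12)
    apoly <- local_lumen_area(mesh, method = "slice")[1]
    f <- stiffness_field(mesh, c(wall = CA), c(wall = apoly), pext = 0)
    d <- displace_nodes(mesh, f, ppulse_pa)
    newmesh <- mesh
    newmesh$nodes <- d$displaced
    apost <- local_lumen_area(newmesh, method = "slice")
    interior_rings <- 4:9
    da_sim <- mean(apost[unlist(mesh$rings[interior_rings])]) - apoly
    expect_lt(rel_err(da_sim, CA * ppulse_pa), 0.015)
  }
})

test_that("mesh VTK and field CSV round-trip", {
  mesh <- make_cylinder_mesh(0.01, 0.06, n_circ = 16, n_axial = 4,
                             regions = c("a", "b"))
  f <- stiffness_field(mesh, c(a = 1e-8, b = 2e-8),
                       c(a = 3e-4, b = 3e-4))
  p <- withr::local_tempfile(fileext = ".vtk")
  write_mesh_vtk(mesh, p, stiffness = f$K)
  back <- read_mesh_vtk(p)
  expect_equal(back$nodes, mesh$nodes, tolerance = 1e-8)
  expect_equal(back$faces, mesh$faces)
  expect_equal(back$region, mesh$region)

  pcsv <- withr::local_tempfile(fileext = ".csv")
  d <- displace_nodes(mesh, f, 500)
  write_field_csv(mesh, f, pcsv, d$vectors)
  tab <- utils::read.csv(pcsv)
  expect_equal(nrow(tab), nrow(mesh$nodes))
  expect_equal(tab$K_pa_per_m, f$K, tolerance = 1e-6)

  pstl <- withr::local_tempfile(fileext = ".stl")
  write_mesh_stl(mesh, pstl)
  expect_gt(length(readLines(pstl)), 7 * nrow(mesh$faces))
})
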