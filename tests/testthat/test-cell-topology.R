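test_that("catalog cells satisfy the polyhedral invariants", {
  expected <- list(`4` = c(4, 6, 4), `6` = c(8, 12, 6), `8` = c(6, 12, 8),
                   `12` = c(20, 30, 12), `20` = c(12, 30, 20),
                   `32` = c(60, 90, 32))
  for (g in cell_labels()) {
    cell <- fix_cells(g)
    V <- nrow(cell$vertices); E <- nrow(cell$edges); F <- length(cell$faces)
    expect_equal(c(V, E, F), expected[[as.character(g)]],
                 info = paste("counts, g =", g))
    expect_identical(V - E + F, 2L)
    el <- apply(cell$edges, 1, function(e)
      sqrt(sum((cell$vertices[e[1], ] - cell$vertices[e[2], ])^2)))
    expect_lt(max(abs(el - cell$a_x)), 1e-9)
    ## vertex functionality and face degree
    expect_true(all(tabulate(cell$edges, V) == cell$k))
    face_n <- vapply(cell$faces, length, integer(1))
    if (g == 32) {
      expect_identical(sort(unique(face_n)), c(5L, 6L))
      expect_identical(as.integer(table(face_n)), c(12L, 20L))
    } else {
      expect_true(all(face_n == cell$n))
    }
  }
  expect_error(build_cell(7), "valid labels")
})

test_that("closed-form radii match the geometric route on Platonic cells", {
  for (g in c(4, 6, 8, 12, 20)) {
    cell <- fix_cells(g)
    r_geo <- radii_geometric(cell)
    r_eq <- radii_eq1(cell$n, cell$theta)
    for (f in c("r_in", "r_mid", "r_out"))
      expect_lt(abs(r_geo[[f]] - r_eq[[f]]) / r_eq[[f]], 1e-9)
    expect_true(r_geo$r_in <= r_geo$r_mid && r_geo$r_mid <= r_geo$r_out)
  }
  ## frozen coordinate-oracle values, unit edge
  r <- radii_eq1(3, acos(1 / 3))
  expect_equal(unname(unlist(r)), unname(ref_radii$tetra), tolerance = 1e-9)
  r <- radii_eq1(4, pi / 2)
  expect_equal(unname(unlist(r)), unname(ref_radii$cube), tolerance = 1e-9)
  ## linear scaling in a_x
  r2 <- radii_eq1(5, 2, a_x = 2)
  r1 <- radii_eq1(5, 2, a_x = 1)
  expect_equal(unlist(r2), 2 * unlist(r1), tolerance = 1e-15)
  expect_error(radii_eq1(2, 1), "n")
  expect_error(radii_eq1(4, pi), "theta")
})

test_that("truncated icosahedron radii use the nearer (hexagonal) face class", {
  cell <- fix_cells(32)
  r <- radii_geometric(cell)
  face_dist <- vapply(cell$faces, function(f) {
    fv <- cell$vertices[f, , drop = FALSE]
    ctr <- colMeans(fv)
    sqrt(sum(ctr^2))
  }, numeric(1))
  n_face <- vapply(cell$faces, length, integer(1))
  expect_equal(r$r_in, min(face_dist[n_face == 6]), tolerance = 1e-9)
  expect_gt(min(face_dist[n_face == 5]), r$r_in)
  ## the closed forms presume a single face class; for the hexagonal class
  ## (whose apothem meets a hexagon-hexagon edge) they still apply, and the
  ## geometric route is authoritative overall
  r_hex <- radii_eq1(6, cell$theta[["hex"]])
  expect_equal(r_hex$r_in, min(face_dist[n_face == 6]), tolerance = 1e-9)
})

test_that("aspheric ratios shrink toward 1 across the catalog", {
  ratios <- t(vapply(cell_labels(), function(g) {
    r <- radii_geometric(fix_cells(g))
    c(mid = r$r_mid / r$r_in, out = r$r_out / r$r_in)
  }, numeric(2)))
  ## non-increasing (dual pairs share ratios exactly) and overall decreasing
  expect_true(all(diff(ratios[, "mid"]) <= 1e-4))
  expect_true(all(diff(ratios[, "out"]) <= 1e-4))
  expect_lt(ratios[nrow(ratios), "mid"], 1.1)
  expect_lt(ratios[nrow(ratios), "out"], 1.1)
  expect_gt(ratios[1, "out"], 2)
})

test_that("MEP frames point through face centers with the inradius", {
  cube <- fix_cells(6)
  fr <- mep_frame(cube, 1)
  expect_equal(sqrt(sum(fr$axis^2)), 1, tolerance = 1e-12)
  expect_equal(fr$z_face, 0.5, tolerance = 1e-9)
  expect_equal(fr$period, 1.0, tolerance = 1e-9)
  tet <- fix_cells(4)
  fr0 <- mep_frame(tet, 1)
  fc <- colMeans(tet$vertices[tet$faces[[1]], ])
  expect_gt(sum(fr0$axis * fc), 0)
  ico <- fix_cells(20)
  zf <- vapply(seq_along(ico$faces), function(f) mep_frame(ico, f)$z_face,
               numeric(1))
  expect_lt(diff(range(zf)), 1e-9)
  expect_error(mep_frame(cube, 9), "face_index")
})

test_that("bead-spring discretization counts and neighbor replication", {
  tet <- fix_cells(4)
  bn <- to_bead_network(tet, N = 4)
  expect_identical(nrow(bn$strands), 6L)
  expect_identical(nrow(bn$sites) - nrow(bn$crosslinks), 18L)  # interior beads
  expect_identical(nrow(bn$springs), 24L)
  ## N = 1: springs connect cross-links directly
  bn1 <- to_bead_network(tet, N = 1)
  expect_identical(nrow(bn1$sites), nrow(bn1$crosslinks))
  expect_identical(bn1$springs, bn1$strands)
  expect_error(to_bead_network(tet, N = 4, b = 0.7), "1%")

  ## cube with neighbors: 6 imaged cells, no duplicated shared strands.
  ## Brute-force oracle: 12 home edges + 6 * 12 image edges, deduplicated by
  ## sorted endpoint-midpoint keys.
  cube <- fix_cells(6)
  bnr <- to_bead_network(cube, N = 1, replicate_neighbors = TRUE)
  offs <- rbind(diag(3), -diag(3), 0)
  mids <- NULL
  for (r in seq_len(nrow(offs))) {
    v <- sweep(cube$vertices, 2, offs[r, ], "+")
    m <- (v[cube$edges[, 1], ] + v[cube$edges[, 2], ]) / 2
    mids <- rbind(mids, m)
  }
  n_unique <- nrow(unique(round(mids, 8)))
  expect_identical(nrow(bnr$strands), n_unique)        # 60 for the cube
  expect_identical(sum(!bnr$pinned), 8L)               # home cross-links free
  ## reflection through a face maps the cube onto its neighbor (tessellation)
  img <- cellhop:::.reflect_through_face(cube, 1, cube$vertices)
  fr <- mep_frame(cube, 1)
  shifted <- sweep(cube$vertices, 2, fr$axis * fr$period, "+")
  expect_equal(img[order(img[, 1], img[, 2], img[, 3]), ],
               shifted[order(shifted[, 1], shifted[, 2], shifted[, 3]), ],
               tolerance = 1e-9)
})

test_that("mesh and network writers emit well-formed files", {
  td <- withr::local_tempdir()
  cube <- fix_cells(6)
  off <- file.path(td, "cube.off")
  write_off(cube, off)
  lines <- readLines(off)
  expect_identical(lines[1], "OFF")
  expect_identical(lines[2], "8 6 12")
  vtk <- file.path(td, "cube.vtk")
  write_vtk(cube, vtk)
  expect_true(any(grepl("^POLYGONS 6", readLines(vtk))))
  bn <- to_bead_network(cube, N = 2)
  xyz <- file.path(td, "cube.xyz")
  write_xyz(bn, xyz)
  expect_identical(readLines(xyz)[1], as.character(nrow(bn$sites)))
  side <- jsonlite::read_json(paste0(xyz, ".json"), simplifyVector = TRUE)
  expect_identical(nrow(side$springs), nrow(bn$springs))
})
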