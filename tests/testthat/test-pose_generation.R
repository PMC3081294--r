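test_that("pseudo-normal length follows the mean-volume sphere radius", {
  ## a residue of mean volume 4*pi/3 has a 1 Angstrom sphere radius
  vols <- stats::setNames(rep(4 * pi / 3, 20), residue_types())
  set.seed(5)
  p <- partner_structure(matrix(rnorm(30, sd = 4), 10, 3),
                         sample(residue_types(), 10, replace = TRUE),
                         volumes = vols)
  sv <- pseudo_normals(p)
  expect_true(all(abs(sv$len - 1) < 1e-12))
  ## directions are unit
  expect_true(all(abs(sv$ux^2 + sv$uy^2 + sv$uz^2 - 1) < 1e-9))
})

test_that("pseudo-normals of a spherical cloud point outward", {
  dirs <- voroscore:::.fibonacci_dirs(40)
  p <- partner_structure(dirs * 10, rep("A", 40))
  sv <- pseudo_normals(p)
  ang <- vapply(seq_len(nrow(sv)), function(k) {
    u <- c(sv$ux[k], sv$uy[k], sv$uz[k])
    radial <- dirs[sv$node[k], ]
    acos(min(1, sum(u * radial))) * 180 / pi
  }, 0)
  ## every vector points into the outward hemisphere, and the bulk tracks
  ## the fitted-sphere normal closely; discrete Delaunay neighborhoods
  ## tilt individual vectors by a few tens of degrees at most
  expect_true(all(ang < 90))
  expect_lt(median(ang), 30)
  expect_true(all(ang < 60))
})

test_that("a symmetric interior node's cancelling sum is dropped", {
  g <- as.matrix(expand.grid(0:2, 0:2, 0:2)) * 4
  p <- partner_structure(g, rep("A", 27))
  expect_warning(sv <- pseudo_normals(p), "dropped")
  ctr <- which(g[, 1] == 4 & g[, 2] == 4 & g[, 3] == 4)
  expect_false(ctr %in% sv$node)
})

test_that("pose enumeration counts multiply out and spins tile 360 degrees", {
  tc <- make_toy_complex(fixture_spec(seed = 7, n_residues = 12))
  rv <- pseudo_normals(tc$native$receptor)
  lv <- pseudo_normals(tc$native$ligand)
  p1 <- enumerate_poses(tc$native$receptor, tc$native$ligand, step_deg = 5,
                        rec_vectors = rv[1, ], lig_vectors = lv[1, ])
  expect_equal(nrow(p1), 72)
  expect_equal(sort(unique(p1$spin)), seq(0, 355, by = 5))
  p2 <- enumerate_poses(tc$native$receptor, tc$native$ligand, step_deg = 90,
                        rec_vectors = rv[1:2, ], lig_vectors = lv[1:3, ])
  expect_equal(nrow(p2), 24)
  expect_error(enumerate_poses(tc$native$receptor, tc$native$ligand,
                               step_deg = 7), "divide 360")
})

test_that("paired vectors are exactly anti-parallel in every pose", {
  tc <- make_toy_complex(fixture_spec(seed = 7, n_residues = 12))
  ps <- enumerate_poses(tc$native$receptor, tc$native$ligand, step_deg = 120)
  rv <- attr(ps, "rec_vectors"); lv <- attr(ps, "lig_vectors")
  set.seed(1)
  for (k in sample(nrow(ps), 6)) {
    conf <- realize_pose(ps, k)
    R <- oracle_rigid_rotation(tc$native$ligand$xyz, conf$ligand$xyz)
    v <- c(lv$ux[ps$lv[k]], lv$uy[ps$lv[k]], lv$uz[ps$lv[k]])
    u <- c(rv$ux[ps$ru[k]], rv$uy[ps$ru[k]], rv$uz[ps$ru[k]])
    expect_equal(sum(u * (R %*% v)), -1, tolerance = 1e-9)
  }
})

test_that("the pose stream is deterministic and transforms are recorded", {
  tc <- make_toy_complex(fixture_spec(seed = 7, n_residues = 12))
  ps1 <- enumerate_poses(tc$native$receptor, tc$native$ligand, step_deg = 45)
  ps2 <- enumerate_poses(tc$native$receptor, tc$native$ligand, step_deg = 45)
  expect_identical(as.data.frame(ps1), as.data.frame(ps2))
  c1 <- realize_pose(ps1, 11); c2 <- realize_pose(ps2, 11)
  expect_identical(c1$ligand$xyz, c2$ligand$xyz)
  expect_equal(c1$transform, c(ps1$ru[11], ps1$lv[11], ps1$spin[11]))
})

test_that("ligand-node RMSD matches the direct formula", {
  tc <- make_toy_complex(fixture_spec(seed = 9, n_residues = 12))
  expect_equal(node_rmsd(tc$native, tc$native), 0)
  shifted <- tc$native
  shifted$ligand$xyz <- sweep(shifted$ligand$xyz, 2, c(3, 4, 0), `+`)
  expect_equal(node_rmsd(shifted, tc$native), 5)
  ps <- enumerate_poses(tc$native$receptor, tc$native$ligand, step_deg = 180)
  pose <- realize_pose(ps, 3)
  direct <- sqrt(mean(rowSums((pose$ligand$xyz - tc$native$ligand$xyz)^2)))
  expect_equal(node_rmsd(pose, tc$native), direct)
  bad <- tc$native
  bad$ligand$xyz <- bad$ligand$xyz[-1, , drop = FALSE]
  expect_error(node_rmsd(bad, tc$native), "node counts")
})

test_that("a native pose on the generator manifold is recovered near 10 A", {
  tc <- make_toy_complex(fixture_spec(seed = 13, n_residues = 12))
  rv <- pseudo_normals(tc$native$receptor)
  lv <- pseudo_normals(tc$native$ligand)
  ## declare the native to be an off-grid pose of one vector pair
  off_lig <- tc$native$ligand
  off_lig$xyz <- voroscore:::.pose_ligand_xyz(tc$native$receptor,
                                              tc$native$ligand,
                                              rv[4, ], lv[2, ], 17)
  native <- complex_conformation(tc$native$receptor, off_lig,
                                 provenance = "native")
  ps <- enumerate_poses(tc$native$receptor, tc$native$ligand, step_deg = 5,
                        rec_vectors = rv[4, ], lig_vectors = lv[2, ])
  rmsds <- vapply(seq_len(nrow(ps)), function(k)
    node_rmsd(realize_pose(ps, k), native), 0)
  expect_lt(min(rmsds), 10)
})

test_that("decoy filters reject near-native and contact-free poses", {
  tc <- make_toy_complex(fixture_spec(seed = 17, n_residues = 12,
                                      n_contacts = 14))
  native <- tc$native
  ## candidate poses: ligand rotated about the receptor centroid keeps the
  ## partners in contact for small angles and separates them for large
  ## translations
  rot_pose <- function(theta, axis = c(0, 0, 1), shift = c(0, 0, 0)) {
    R <- voroscore:::.rot_axis_angle(axis, theta)
    ctr <- colMeans(native$receptor$xyz)
    lig <- native$ligand
    lig$xyz <- sweep(sweep(sweep(lig$xyz, 2, ctr) %*% t(R), 2, ctr, `+`),
                     2, shift, `+`)
    complex_conformation(native$receptor, lig)
  }
  poses <- c(
    list(native),                                     # RMSD 0: rejected
    lapply(seq(0.5, 2.4, length.out = 8), rot_pose),  # sliding contact
    lapply(1:3, function(k) rot_pose(0, shift = c(0, 0, 40 + 5 * k))))
  dec <- suppressWarnings(
    build_decoy_set(native, poses, min_area = 150, min_rmsd = 10,
                    per_native = 4, seed = 3))
  ## oracle: recompute both filters directly
  keep <- vapply(poses, function(cf) {
    node_rmsd(cf, native) > 10 &&
      interface_area(tessellate(cf)) >= 150
  }, FALSE)
  expect_false(keep[1])                 # the native itself
  expect_true(all(!keep[10:12]))        # separated poses fail the area floor
  expect_lte(length(dec), 4)
  ## decoys are survivors, labeled, with RMSD recorded
  for (d in dec) {
    expect_equal(d$provenance, "decoy")
    expect_gt(d$rmsd_to_native, 10)
  }
  dec2 <- suppressWarnings(
    build_decoy_set(native, poses, min_area = 150, min_rmsd = 10,
                    per_native = 4, seed = 3))
  expect_equal(vapply(dec, node_rmsd, 0, b = native),
               vapply(dec2, node_rmsd, 0, b = native))
  ## asking for more decoys than survive returns all survivors, warning
  expect_warning(
    all_s <- build_decoy_set(native, poses, min_area = 150, min_rmsd = 10,
                             per_native = 50, seed = 1),
    "survive")
  expect_equal(length(all_s), sum(keep))
})
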