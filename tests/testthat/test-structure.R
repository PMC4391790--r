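test_that("PDB CA parsing honours chain, altloc occupancy and errors", {
  pdb <- withr::local_tempfile(fileext = ".pdb")
  write_test_pdb(pdb)
  tr <- read_ca_trace(pdb, chain = "A")
  expect_equal(tr$length, 3L)
  # altloc B (occupancy 0.6) wins over A (0.4) for residue 2
  expect_equal(unname(tr$coords[2, 1]), 2)
  expect_equal(read_ca_trace(pdb, chain = "B")$length, 1L)
  expect_error(read_ca_trace(pdb, chain = "Z"), "available: A B")
  empty <- withr::local_tempfile(fileext = ".pdb")
  writeLines("END", empty)
  expect_error(read_ca_trace(empty), "ATOM")
})

test_that("PDB writing round-trips a trace to coordinate precision", {
  h <- synth_helix_trace(12)
  pdb <- withr::local_tempfile(fileext = ".pdb")
  write_ca_pdb(h, pdb)
  back <- read_ca_trace(pdb)
  expect_equal(back$coords, h$coords, tolerance = 1e-3)
  expect_equal(back$resno, h$resno)
})

test_that("HST encoding follows the nominal S=1 H=2 G=3 T=4 C=5 table", {
  expect_equal(hst_encode("HHHH")$values, c(2, 2, 2, 2))
  expect_equal(hst_encode("SCGT")$values, c(1, 5, 3, 4))
  expect_equal(dssp_to_hst("EEHH"), c("S", "S", "H", "H"))
  expect_equal(hst_encode(dssp_to_hst("EEHH"))$values, c(1, 1, 2, 2))
  expect_equal(dssp_to_hst("B I "), c("C", "C", "C", "C"))
  expect_error(hst_encode(""), "empty")
})

test_that("HSTD marks S/H run termini with antispike values", {
  expect_equal(hst_differentiate(hst_encode("CHHHHC"))$values,
               c(5, 0.5, 2, 2, 0.5, 5))
  expect_equal(hst_differentiate(hst_encode("SSS"))$values, c(0, 1, 0))
  expect_equal(hst_differentiate(hst_encode("CCCC"))$values, c(5, 5, 5, 5))
  # length-1 runs receive the terminus value once
  expect_equal(hst_differentiate(hst_encode("CSC"))$values, c(5, 0, 5))
  # G/T runs untouched by default, changed when asked
  expect_equal(hst_differentiate(hst_encode("GGTT"))$values, c(3, 3, 4, 4))
  expect_error(hst_differentiate(hst_encode("GG"), letters = "G"),
               "S and H")
})

test_that("HSTD changes exactly the predicted number of positions", {
  set.seed(21)
  for (rep in 1:10) {
    ss <- paste(sample(c("S", "H", "G", "T", "C"), 60, replace = TRUE),
                collapse = "")
    hst <- hst_encode(ss)
    hstd <- hst_differentiate(hst)
    r <- rle(hst$letters)
    sh <- r$values %in% c("S", "H")
    expected_changed <- 2 * sum(sh & r$lengths >= 2) +
      sum(sh & r$lengths == 1)
    expect_equal(sum(hstd$values != hst$values), expected_changed)
  }
})

test_that("centre of gravity is the coordinate mean and is linear", {
  tr <- foldsignal:::new_ca_trace(rbind(c(0, 0, 0), c(2, 0, 0), c(1, 3, 0)))
  expect_equal(center_of_gravity(tr), c(x = 1, y = 1, z = 0))
  one <- foldsignal:::new_ca_trace(rbind(c(1, 2, 3), c(1, 2, 3), c(1, 2, 3)))
  expect_equal(unname(center_of_gravity(one)), c(1, 2, 3))
  shifted <- tr
  shifted$coords <- tr$coords + matrix(c(5, -1, 2), 3, 3, byrow = TRUE)
  expect_equal(center_of_gravity(shifted),
               center_of_gravity(tr) + c(x = 5, y = -1, z = 2))
  w <- center_of_gravity(tr, weights = c(1, 1, 0))
  expect_equal(unname(w), c(1, 0, 0))
})

test_that("triangle areas match base*height/2 and handle degeneracy", {
  tr <- foldsignal:::new_ca_trace(rbind(c(0, 0, 0), c(1, 1, 1), c(4, 0, 0)))
  area <- triangle_area_track(tr, cg = c(0, 3, 0))
  expect_equal(unname(area), 6.0)
  col <- foldsignal:::new_ca_trace(rbind(c(0, 0, 0), c(5, 5, 5), c(2, 0, 0)))
  expect_equal(unname(triangle_area_track(col, cg = c(1, 0, 0))), 0)
  expect_error(triangle_area_track(
    foldsignal:::new_ca_trace(rbind(c(0, 0, 0), c(1, 0, 0)))), "3 residues")
})

test_that("AREA is invariant under rigid motion with CG recomputed", {
  h <- synth_helix_trace(25)
  a0 <- triangle_area_track(h)
  moved <- h
  moved$coords <- random_rigid_transform(h$coords, seed = 13)
  expect_equal(triangle_area_track(moved), a0, tolerance = 1e-9)
})

test_that("helix triangles are smaller than strand triangles about a shared CG", {
  glob <- make_globule()
  mean_h <- mean(triangle_area_track(glob$helix, cg = glob$cg))
  mean_s <- mean(triangle_area_track(glob$strand, cg = glob$cg))
  expect_lt(mean_h, mean_s)
})

test_that("contact maps apply the cutoff inclusively over the full triangle", {
  two <- foldsignal:::new_ca_trace(rbind(c(0, 0, 0), c(7.9, 0, 0),
                                         c(100, 0, 0)))
  cm <- contact_map_from_structure(two, cutoff = 8.0)
  expect_equal(nrow(cm$pairs), 1L)
  expect_equal(unname(cm$pairs[1, ]), c(1L, 2L))
  far <- foldsignal:::new_ca_trace(rbind(c(0, 0, 0), c(8.1, 0, 0),
                                         c(100, 0, 0)))
  expect_equal(nrow(contact_map_from_structure(far, cutoff = 8.0)$pairs), 0L)
  # min_separation excludes near-diagonal pairs
  h <- synth_helix_trace(20)
  cm1 <- contact_map_from_structure(h, min_separation = 1)
  cm3 <- contact_map_from_structure(h, min_separation = 3)
  expect_true(all(cm3$pairs[, 2] - cm3$pairs[, 1] >= 3))
  expect_gt(nrow(cm1$pairs), nrow(cm3$pairs))
})

test_that("superposition recovers rigid motions and matches a numeric oracle", {
  h <- synth_helix_trace(15)
  same <- superpose(h, h)
  expect_equal(same$rmsd, 0, tolerance = 1e-9)
  expect_equal(same$rotation, diag(3), tolerance = 1e-9)

  moved <- h
  moved$coords <- random_rigid_transform(h$coords, seed = 31)
  fit <- superpose(h, moved)
  expect_equal(fit$rmsd, 0, tolerance = 1e-8)

  # one CA displaced by 1 A: Kabsch result checked against a brute-force
  # optimisation over Euler angles + translation
  pert <- h
  pert$coords[8, ] <- pert$coords[8, ] + c(0, 0, 1)
  fit2 <- superpose(h, pert)
  expect_lte(fit2$rmsd, 1 / sqrt(15) + 1e-9)
  oracle <- function(par) {
    cx <- cos(par[1:3]); sx <- sin(par[1:3])
    Rx <- matrix(c(1, 0, 0, 0, cx[1], sx[1], 0, -sx[1], cx[1]), 3)
    Ry <- matrix(c(cx[2], 0, -sx[2], 0, 1, 0, sx[2], 0, cx[2]), 3)
    Rz <- matrix(c(cx[3], sx[3], 0, -sx[3], cx[3], 0, 0, 0, 1), 3)
    moved <- pert$coords %*% t(Rx %*% Ry %*% Rz) +
      matrix(par[4:6], 15, 3, byrow = TRUE)
    sqrt(mean(rowSums((moved - h$coords)^2)))
  }
  best <- stats::optim(rep(0, 6), oracle, method = "BFGS",
                       control = list(maxit = 500, reltol = 1e-14))
  expect_equal(fit2$rmsd, best$value, tolerance = 1e-4)
  expect_error(superpose(h, synth_helix_trace(10)), "differ in length")
})

test_that("DISP vanishes for rigid motions and is symmetric", {
  h <- synth_helix_trace(20)
  expect_equal(max(displacement_track(h, h)), 0, tolerance = 1e-9)
  moved <- h
  moved$coords <- random_rigid_transform(h$coords, seed = 7)
  expect_lt(max(displacement_track(h, moved)), 1e-7)
  hp <- synth_hinge_pair(h, 10, 25)
  d_ab <- displacement_track(hp$A, hp$I)
  d_ba <- displacement_track(hp$I, hp$A)
  expect_equal(unname(d_ab), unname(d_ba), tolerance = 1e-8)
})

test_that("hinge motion gives zero DISP in the fixed domain, chords beyond", {
  h <- synth_helix_trace(30)
  hp <- synth_hinge_pair(h, 15, 10, axis = c(0, 0, 1))
  disp <- displacement_track(hp$A, hp$I, superpose_first = FALSE)
  expect_lt(max(disp[1:15]), 1e-12)
  v <- sweep(hp$A$coords[16:30, ], 2, hp$axis_point)
  r <- sqrt(rowSums((v - outer(as.numeric(v %*% hp$axis), hp$axis))^2))
  expect_equal(unname(disp[16:30]), 2 * r * sin(5 * pi / 180),
               tolerance = 1e-9)
})

test_that("difference tracks are elementwise absolute with NA propagation", {
  expect_equal(difference_track(c(1, 2, 3), c(3, 2, 1)), c(2, 0, 2))
  expect_equal(difference_track(1:4, 1:4), rep(0L, 4))
  expect_equal(difference_track(c(1, NA, 3), c(0, 1, 1)), c(1, NA, 2))
  expect_error(difference_track(1:3, 1:4), "differ in length")
})
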