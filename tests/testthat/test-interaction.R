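test_that("docking box is a cube centred on the residue C-alpha", {
  txt <- pdb_atom_line(1, "CA", "TRP", "A", 56, 10, 10, 10, element = "C")
  st <- read_structure(txt)
  box <- docking_box(st, "A", 56, edge = 14)
  expect_equal(box$center, c(10, 10, 10))
  expect_equal(unname(box$bounds[, "lower"]), c(3, 3, 3))
  expect_equal(unname(box$bounds[, "upper"]), c(17, 17, 17))
  expect_true(box_contains(box, matrix(c(10, 10, 10), 1)))
  expect_true(box_contains(box, matrix(box$center, 1)))
  expect_false(box_contains(box, matrix(c(25, 10, 10), 1)))
  expect_error(docking_box(st, "A", 99), "no C-alpha")
  expect_error(docking_box(st, "A", 56, edge = 0), "positive")
})

test_that("box centre equals the site C-alpha of a generated chain", {
  ens <- generate_ensemble(n_residues = 60, n_conformers = 1, sigma = 0.2,
                           site_residue = 56, seed = 9)
  st <- ens$structures[[1]]
  box <- docking_box(st, "A", 56)
  ca <- st[st$res_number == 56 & st$atom_name == "CA", ]
  expect_equal(box$center, c(ca$x, ca$y, ca$z))
  expect_equal(box$edge, 14)
})

test_that("contact detection honours the distance cutoff", {
  st <- read_structure(paste(
    pdb_atom_line(1, "CA", "ALA", "A", 1, 0, 0, 0, element = "C"),
    pdb_atom_line(2, "CA", "ALA", "A", 2, 20, 0, 0, element = "C"),
    sep = "\n"
  ))
  pose3 <- new_ligand_pose(tibble::tibble(
    atom_name = "C1", element = "C", x = 3, y = 0, z = 0))
  hits <- contact_residues(st, pose3, cutoff = 4)
  expect_equal(hits$res_number, 1L)
  expect_equal(hits$min_distance, 3)

  pose5 <- new_ligand_pose(tibble::tibble(
    atom_name = "C1", element = "C", x = 5, y = 0, z = 0))
  expect_equal(nrow(contact_residues(st, pose5, cutoff = 4)), 0)
})

test_that("planted contacts are recovered exactly and match a brute-force scan", {
  cx <- generate_complex(pocket_residues = c(5, 39, 41, 52, 56),
                         contact_distance = 3.0)
  hits <- contact_residues(cx$structure, cx$pose, cutoff = 4.0)
  expect_setequal(hits$res_number, c(5, 39, 41, 52, 56))
  gt <- cx$ground_truth$contacts
  expect_equal(
    hits$min_distance[order(hits$res_number)],
    gt$min_distance[order(gt$res_number)],
    tolerance = 1e-9
  )
  # independent all-pairs scan
  prot <- cx$structure[cx$structure$element != "H", ]
  lig <- cx$pose[cx$pose$element != "H", ]
  in_contact <- integer(0)
  for (r in unique(prot$res_number)) {
    pr <- prot[prot$res_number == r, ]
    dmin <- Inf
    for (i in seq_len(nrow(pr))) for (j in seq_len(nrow(lig))) {
      d <- sqrt((pr$x[i] - lig$x[j])^2 + (pr$y[i] - lig$y[j])^2 +
                  (pr$z[i] - lig$z[j])^2)
      dmin <- min(dmin, d)
    }
    if (dmin <= 4.0) in_contact <- c(in_contact, r)
  }
  expect_setequal(hits$res_number, in_contact)
})

test_that("contact sets grow monotonically with the cutoff", {
  cx <- generate_complex(pocket_residues = c(10, 30, 50),
                         contact_distance = 3.2, hbond = NULL)
  r35 <- contact_residues(cx$structure, cx$pose, cutoff = 3.5)$res_number
  r45 <- contact_residues(cx$structure, cx$pose, cutoff = 4.5)$res_number
  expect_true(all(r35 %in% r45))
})

test_that("hydrogen bonds require donor typing, distance and angle", {
  cx <- generate_complex(hbond = list(distance = 2.9, angle = 170,
                                      residue = 56))
  hb <- detect_hbonds(cx$structure, cx$pose)
  expect_equal(nrow(hb), 1)
  expect_equal(hb$donor_side, "ligand")
  expect_equal(hb$res_number, 56L)
  expect_equal(hb$distance, 2.9, tolerance = 1e-9)
  expect_equal(hb$angle, 170, tolerance = 1e-6)
  expect_false(hb$distance_only)

  # same geometry at 4.0 A: beyond the distance cutoff
  far <- generate_complex(hbond = list(distance = 4.0, angle = 170,
                                       residue = 56))
  expect_equal(nrow(detect_hbonds(far$structure, far$pose)), 0)

  # bent geometry below the angle threshold
  bent <- generate_complex(hbond = list(distance = 2.9, angle = 100,
                                        residue = 56))
  expect_equal(nrow(detect_hbonds(bent$structure, bent$pose)), 0)
})

test_that("a complex without planted interactions detects nothing", {
  cx <- generate_complex(pocket_residues = integer(0), hbond = NULL)
  expect_equal(nrow(contact_residues(cx$structure, cx$pose, cutoff = 4)), 0)
  expect_equal(nrow(detect_hbonds(cx$structure, cx$pose)), 0)
  expect_equal(nrow(cx$ground_truth$contacts), 0)
})

make_pose <- function(coords, names = NULL) {
  n <- nrow(coords)
  new_ligand_pose(tibble::tibble(
    atom_name = names %||% paste0("C", seq_len(n)),
    element = "C",
    x = coords[, 1], y = coords[, 2], z = coords[, 3]
  ))
}

test_that("pose RMSD measures in-frame binding-mode displacement", {
  set.seed(77)
  coords <- matrix(rnorm(24), ncol = 3)
  a <- make_pose(coords)
  expect_equal(pose_rmsd(a, a), 0)
  b <- make_pose(sweep(coords, 2, c(1, 0, 0), `+`))
  expect_equal(pose_rmsd(a, b), 1, tolerance = 1e-12)
})

test_that("pose RMSD with a group displaced equals the closed form", {
  set.seed(78)
  coords <- matrix(rnorm(30), ncol = 3)
  moved <- coords
  moved[1:4, 3] <- moved[1:4, 3] + 3   # "ring A" shifted 3 A
  a <- make_pose(coords)
  b <- make_pose(moved)
  expect_equal(pose_rmsd(a, b), sqrt(4 * 9 / 10), tolerance = 1e-12)
  groups <- list(ring_A = paste0("C", 1:4), rest = paste0("C", 5:10))
  sr <- substructure_rmsd(a, b, groups)
  expect_equal(sr$rmsd[sr$group == "ring_A"], 3, tolerance = 1e-12)
  expect_equal(sr$rmsd[sr$group == "rest"], 0)
})

test_that("pose RMSD is invariant when both receptor frames move rigidly", {
  set.seed(79)
  coords_a <- matrix(rnorm(27), ncol = 3)
  coords_b <- coords_a + matrix(rnorm(27, sd = 0.5), ncol = 3)
  rec <- matrix(rnorm(60), ncol = 3)
  base <- rmsd_direct <- pose_rmsd(make_pose(coords_a), make_pose(coords_b))
  for (k in 1:3) {
    tf <- random_rigid_transform()
    rec_t <- tf(rec)
    sup <- kabsch_superpose(rec, rec_t)   # receptor b -> receptor a frame
    rmsd_t <- pose_rmsd(make_pose(coords_a), make_pose(tf(coords_b)),
                        superposition = sup)
    expect_equal(rmsd_t, base, tolerance = 1e-9)
  }
})

test_that("substructure RMSDs satisfy the partition identity", {
  set.seed(80)
  for (k in 1:10) {
    n <- 12
    coords <- matrix(rnorm(3 * n), ncol = 3)
    perturbed <- coords + matrix(rnorm(3 * n, sd = runif(1, 0.1, 3)),
                                 ncol = 3)
    a <- make_pose(coords)
    b <- make_pose(perturbed)
    groups <- list(g1 = paste0("C", 1:4), g2 = paste0("C", 5:7),
                   g3 = paste0("C", 8:12))
    sr <- substructure_rmsd(a, b, groups)
    overall <- attr(sr, "overall")
    expect_equal(overall^2,
                 sum(sr$n_atoms * sr$rmsd^2) / sum(sr$n_atoms),
                 tolerance = 1e-9)
  }
})

test_that("pose comparison validates atom mappings and groups", {
  a <- make_pose(matrix(rnorm(9), ncol = 3))
  b <- make_pose(matrix(rnorm(9), ncol = 3), names = c("C1", "C2", "X9"))
  expect_error(pose_rmsd(a, b), "unmatched.*C3")
  expect_error(substructure_rmsd(a, a, list(g = character(0))), "empty")
  expect_error(substructure_rmsd(a, a, list(g = "NOPE")), "unknown atoms")
})
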