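small_receptor <- function(seed = 1) {
  generate_ensemble(n_residues = 40, n_conformers = 1, sigma = 0,
                    site_residue = 20, seed = seed)$structures[[1]]
}

test_that("the mock engine is deterministic for identical input and seed", {
  rec <- small_receptor()
  box <- docking_box(rec, "A", 20, edge = 14)
  lig <- compact_ligand()
  r1 <- mock_dock(rec, lig, box, seed = 5, n_samples = 100)
  r2 <- mock_dock(rec, lig, box, seed = 5, n_samples = 100)
  expect_identical(r1$score, r2$score)
  expect_identical(r1$pose, r2$pose)
  r3 <- mock_dock(rec, lig, box, seed = 6, n_samples = 100)
  expect_false(identical(r1$score, r3$score))
  expect_false(is.unsorted(r1$score))
})

test_that("clashes are penalized relative to clash-free placements", {
  rec <- read_structure(pdb_atom_line(1, "CA", "ALA", "A", 1, 0, 0, 0,
                                      element = "C"))
  lig_clash <- matrix(c(1.5, 0, 0), 1)
  lig_free <- matrix(c(3.0, 0, 0), 1)
  prot <- matrix(0, 1, 3)
  expect_equal(confdock:::mock_score(lig_clash, prot), 10)
  expect_equal(confdock:::mock_score(lig_free, prot), -0.1)
  expect_gt(confdock:::mock_score(lig_clash, prot),
            confdock:::mock_score(lig_free, prot))
})

test_that("grid search best score matches an independent brute-force scorer", {
  rec <- small_receptor(seed = 2)
  box <- docking_box(rec, "A", 20, edge = 6)
  lig <- compact_ligand()
  res <- mock_dock(rec, lig, box, seed = 1, method = "grid", step = 1)
  # enumerate the same grid independently and score with the double loop
  prot <- as.matrix(rec[rec$element != "H", c("x", "y", "z")])
  lx <- as.matrix(lig[, c("x", "y", "z")])
  lc <- sweep(lx, 2, colMeans(lx))
  gx <- seq(box$bounds[1, 1], box$bounds[1, 2], by = 1)
  gy <- seq(box$bounds[2, 1], box$bounds[2, 2], by = 1)
  gz <- seq(box$bounds[3, 1], box$bounds[3, 2], by = 1)
  best <- Inf
  for (x in gx) for (y in gy) for (z in gz) {
    best <- min(best, brute_force_score(sweep(lc, 2, c(x, y, z), `+`), prot))
  }
  expect_equal(res$score[1], best, tolerance = 1e-12)
})

test_that("a ligand larger than the box is rejected", {
  rec <- small_receptor(seed = 3)
  box <- docking_box(rec, "A", 20, edge = 4)
  big <- new_ligand_pose(tibble::tibble(
    atom_name = c("C1", "C2"), element = "C",
    x = c(-5, 5), y = 0, z = 0
  ))
  expect_error(mock_dock(rec, big, box, seed = 1), "larger than box")
})

test_that("external engine configuration errors are distinct and early", {
  rec <- small_receptor(seed = 4)
  box <- docking_box(rec, "A", 20)
  expect_error(
    external_dock(rec, compact_ligand(), box, seed = 1,
                  engine = list(executable = "/no/such/vina")),
    "executable not found: /no/such/vina"
  )
})

canned_vina_output <- function(scores) {
  blocks <- lapply(seq_along(scores), function(k) {
    c(sprintf("MODEL %d", k),
      sprintf("REMARK VINA RESULT:    %6.1f      0.000      0.000",
              scores[k]),
      pdb_atom_line(1, "C1", "LIG", "A", 1, k, 0, 0, element = "C",
                    record = "HETATM"),
      "ENDMDL")
  })
  unlist(blocks)
}

test_that("engine output parsing returns the fixture scores verbatim", {
  scores <- c(-7.1, -6.4, -6.2, -5.9, -5.8, -5.5, -5.2, -5.0, -4.1)
  shuffled <- scores[c(3, 1, 9, 5, 2, 8, 4, 7, 6)]
  res <- parse_vina_output(canned_vina_output(shuffled))
  expect_equal(nrow(res), 9)
  expect_equal(res$score, sort(scores))
  best <- attr(res, "best_pose")
  expect_s3_class(best, "ligand_pose")
  expect_equal(attr(best, "score"), min(scores))
  # pose coordinates travel with their score: model k was written at x = k
  expect_equal(best$x, which(shuffled == min(scores)))
  expect_error(parse_vina_output(c("MODEL 1", "ENDMDL")), "no scored poses")
})

test_that("a scripted external engine round-trips through the adapter", {
  out_fixture <- tempfile(fileext = ".pdbqt")
  writeLines(canned_vina_output(c(-6.5, -6.0)), out_fixture)
  exe <- tempfile(fileext = ".sh")
  writeLines(c(
    "#!/bin/sh",
    "out=''",
    "while [ $# -gt 0 ]; do",
    "  if [ \"$1\" = '--out' ]; then out=$2; shift; fi",
    "  shift",
    "done",
    paste0("cp ", out_fixture, " \"$out\"")
  ), exe)
  Sys.chmod(exe, "0755")
  rec <- small_receptor(seed = 5)
  box <- docking_box(rec, "A", 20)
  res <- external_dock(rec, compact_ligand(), box, seed = 1,
                       engine = list(executable = exe))
  expect_equal(res$score, c(-6.5, -6.0))
})

test_that("ensemble docking aggregates per-conformer and pooled statistics", {
  ens <- generate_ensemble(n_residues = 40, n_conformers = 3, sigma = 0.3,
                           site_residue = 20, seed = 6)
  tab <- ensemble_dock(ens$structures, compact_ligand(),
                       function(s) docking_box(s, "A", 20, edge = 14),
                       engine = list(type = "mock", n_samples = 60),
                       n_repeats = 8, base_seed = 100)
  expect_equal(nrow(tab$records), 24)
  expect_equal(unique(tab$by_conformer$n), 8)
  expect_equal(tab$pooled$n, 24)
  # orchestration never alters engine scores: recompute one cell directly
  box <- docking_box(ens$structures[[2]], "A", 20, edge = 14)
  direct <- mock_dock(ens$structures[[2]], compact_ligand(), box,
                      seed = 100 + 1 * 8 + 2, n_samples = 60)
  expect_equal(
    tab$records$score[tab$records$conformer == "conf02" &
                        tab$records$repeat_index == 3],
    direct$score[1]
  )
})

test_that("aggregation matches hand-computed and streaming references", {
  records <- tibble::tibble(
    conformer = "c1", repeat_index = 1:3, score = c(-5, -6, -7)
  )
  tab <- confdock:::new_affinity_table(records, n_repeats = 3, base_seed = 1)
  expect_equal(tab$by_conformer$mean, -6)
  expect_equal(tab$by_conformer$sd, 1)       # sample SD of {-5,-6,-7}
  w <- welford(records$score)
  expect_equal(tab$pooled$mean, w$mean, tolerance = 1e-12)
  expect_equal(tab$pooled$sd, w$sd, tolerance = 1e-12)
})

test_that("rerunning with the same base seed reproduces the table exactly", {
  ens <- generate_ensemble(n_residues = 30, n_conformers = 2, sigma = 0.2,
                           site_residue = 15, seed = 7)
  args <- list(ens$structures, compact_ligand(),
               function(s) docking_box(s, "A", 15, edge = 12),
               engine = list(type = "mock", n_samples = 40),
               n_repeats = 5, base_seed = 42)
  t1 <- do.call(ensemble_dock, args)
  t2 <- do.call(ensemble_dock, args)
  expect_identical(t1$records, t2$records)
  expect_identical(t1$by_conformer, t2$by_conformer)
})

test_that("histogram frequencies are percentages summing to 100", {
  one <- confdock:::new_affinity_table(
    tibble::tibble(conformer = "c", repeat_index = 1L, score = -6),
    n_repeats = 1, base_seed = 1)
  h1 <- affinity_histogram(one)
  expect_equal(nrow(h1), 1)
  expect_equal(h1$rel_freq_pct, 100)

  two <- confdock:::new_affinity_table(
    tibble::tibble(conformer = "c", repeat_index = 1:4,
                   score = c(-6.1, -6.1, -5.6, -5.6)),
    n_repeats = 4, base_seed = 1)
  h2 <- affinity_histogram(two, bin_width = 0.25)
  expect_equal(sort(h2$rel_freq_pct[h2$count > 0]), c(50, 50))

  set.seed(9)
  scores <- round(rnorm(1000, -6, 0.4), 3)
  tab <- confdock:::new_affinity_table(
    tibble::tibble(conformer = "c", repeat_index = 1:1000, score = scores),
    n_repeats = 1000, base_seed = 1)
  h <- affinity_histogram(tab, bin_width = 0.25)
  expect_equal(sum(h$rel_freq_pct), 100, tolerance = 1e-9)
  # independent binning
  lo <- floor(min(scores) / 0.25) * 0.25
  manual <- table(cut(scores, breaks = c(seq(lo, max(scores) + 0.25,
                                             by = 0.25)), right = FALSE))
  expect_equal(sum(h$count), 1000)
  expect_equal(h$count[h$count > 0],
               unname(as.integer(manual[manual > 0])))
})
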