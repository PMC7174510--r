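write_ensemble_files <- function(dir, n_conformers = 5, seed = 17) {
  ens <- generate_ensemble(
    n_residues = 50, n_conformers = n_conformers,
    sigma = list(core = 0.1, loop = 2, loop_ranges = list(c(15, 25))),
    conformer_scale = seq(0.2, 2, length.out = n_conformers),
    site_residue = 40, seed = seed
  )
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- vapply(names(ens$structures), function(id) {
    p <- file.path(dir, paste0(id, ".pdb"))
    write_structure(ens$structures[[id]], p)
    p
  }, "")
  list(ens = ens, paths = paths)
}

test_that("the diversity workflow writes its four report files", {
  root <- withr::local_tempdir()
  fx <- write_ensemble_files(file.path(root, "in"))
  cfg <- list(
    structures = lapply(fx$paths, function(p) list(path = p, chain = "A")),
    site = c(5, 10, 40),
    out_dir = file.path(root, "out")
  )
  paths <- run_diversity(cfg)
  expect_true(all(file.exists(paths)))

  mp <- jsonlite::read_json(paths[["max_pair"]])
  expect_equal(sort(c(mp$conformer_a, mp$conformer_b)),
               paste0(fx$ens$ground_truth$expected_max_pair, ":A"))

  prof <- utils::read.delim(paths[["zscore_profile"]])
  expect_equal(nrow(prof), 50)
  expect_equal(mean(prof$z), 0, tolerance = 1e-9)

  site <- jsonlite::read_json(paths[["site_report"]])
  expect_equal(site$fraction_below_zero, 1)

  m <- utils::read.delim(paths[["rmsd_matrix"]])
  expect_equal(nrow(m), 5)
})

test_that("a single conformer is rejected before any work is done", {
  root <- withr::local_tempdir()
  fx <- write_ensemble_files(file.path(root, "in"), n_conformers = 5)
  cfg <- list(
    structures = list(list(path = fx$paths[[1]], chain = "A")),
    out_dir = file.path(root, "out")
  )
  expect_error(run_diversity(cfg), ">=2 conformers")
})

test_that("reruns with the same config are byte-identical", {
  root <- withr::local_tempdir()
  fx <- write_ensemble_files(file.path(root, "in"), n_conformers = 3)
  mk_cfg <- function(out) list(
    structures = lapply(fx$paths, function(p) list(path = p, chain = "A")),
    site = c(5, 10),
    out_dir = out
  )
  p1 <- run_diversity(mk_cfg(file.path(root, "out1")))
  p2 <- run_diversity(mk_cfg(file.path(root, "out2")))
  for (k in seq_along(p1)) {
    expect_identical(readLines(p1[[k]]), readLines(p2[[k]]))
  }
})

test_that("the docking workflow writes consistent affinity reports", {
  root <- withr::local_tempdir()
  fx <- write_ensemble_files(file.path(root, "in"), n_conformers = 3)
  lig_path <- file.path(root, "lig.pdb")
  writeLines(c(
    pdb_atom_line(1, "C1", "LIG", "A", 1, 0, 0, 0, element = "C",
                  record = "HETATM"),
    pdb_atom_line(2, "C2", "LIG", "A", 1, 1.5, 0, 0, element = "C",
                  record = "HETATM"),
    pdb_atom_line(3, "N1", "LIG", "A", 1, 0, 1.4, 0, element = "N",
                  record = "HETATM")
  ), lig_path)
  cfg <- list(
    structures = lapply(fx$paths, function(p) list(path = p, chain = "A")),
    ligand = lig_path,
    box = list(chain = "A", residue = 40, edge = 14),
    engine = list(type = "mock", n_samples = 50),
    n_repeats = 10,
    base_seed = 7,
    out_dir = file.path(root, "dock")
  )
  paths <- run_dock(cfg)
  expect_true(all(file.exists(paths)))

  aff <- utils::read.delim(paths[["affinities"]])
  expect_equal(nrow(aff), 30)   # 3 conformers x 10 repeats

  # summary.json must equal recomputation from affinities.tsv
  summ <- jsonlite::read_json(paths[["summary"]], simplifyVector = TRUE)
  by_conf <- aggregate(score ~ conformer, aff, mean)
  expect_equal(summ$by_conformer$mean[order(summ$by_conformer$conformer)],
               by_conf$score[order(by_conf$conformer)], tolerance = 1e-9)
  expect_equal(summ$pooled$mean, mean(aff$score), tolerance = 1e-9)
  expect_equal(summ$pooled$sd, sd(aff$score), tolerance = 1e-9)

  h <- utils::read.delim(paths[["histogram"]])
  expect_equal(sum(h$rel_freq_pct), 100, tolerance = 1e-9)
})

test_that("a missing external engine aborts before any run", {
  root <- withr::local_tempdir()
  fx <- write_ensemble_files(file.path(root, "in"), n_conformers = 3)
  cfg <- list(
    structures = lapply(fx$paths, function(p) list(path = p, chain = "A")),
    ligand = new_ligand_pose(tibble::tibble(
      atom_name = "C1", element = "C", x = 0, y = 0, z = 0)),
    box = list(chain = "A", residue = 40),
    engine = list(type = "external", executable = "/no/such/engine"),
    out_dir = file.path(root, "dock")
  )
  expect_error(run_dock(cfg), "executable not found")
})

test_that("druglikeness reports round-trip through JSON and TSV", {
  root <- withr::local_tempdir()
  prof <- run_druglikeness(SMILES_1A116, out_dir = root)
  j <- jsonlite::read_json(file.path(root, "druglikeness.json"))
  expect_equal(j$mw, prof$mw, tolerance = 1e-9)
  expect_equal(j$hbd, 2)
  expect_equal(j$tpsa, 50.41, tolerance = 1e-6)
  expect_true(j$lipinski_pass)
  tsv <- utils::read.delim(file.path(root, "druglikeness.tsv"))
  expect_equal(tsv$rotatable_bonds, 3)

  benzene <- run_druglikeness("c1ccccc1", out_dir = root)
  expect_equal(benzene$tpsa, 0)
  expect_equal(benzene$hbd + benzene$hba, 0)
  expect_true(benzene$lipinski_pass && benzene$veber_pass)

  expect_error(run_druglikeness("notasmiles((", out_dir = root),
               "parse failure")
})

test_that("config validation catches missing files and bad values", {
  expect_error(read_run_config("/no/such/config.yaml"), "not found")
  expect_error(read_run_config(list(structures = list())), "out_dir")
  expect_error(
    read_run_config(list(out_dir = ".", n_repeats = 0)),
    "n_repeats"
  )
  expect_error(
    read_run_config(list(out_dir = ".",
                         structures = list(list(path = "/nope.pdb")))),
    "/nope.pdb"
  )
})

test_that("YAML configs are accepted", {
  root <- withr::local_tempdir()
  fx <- write_ensemble_files(file.path(root, "in"), n_conformers = 3)
  cfg_path <- file.path(root, "run.yaml")
  yaml::write_yaml(list(
    structures = lapply(unname(fx$paths),
                        function(p) list(path = p, chain = "A")),
    site = c(5, 10),
    out_dir = file.path(root, "out")
  ), cfg_path)
  paths <- run_diversity(cfg_path)
  expect_true(all(file.exists(paths)))
})

test_that("the command-line wrapper computes a druglikeness profile", {
  cli <- system.file("cli", "confdock.R", package = "confdock")
  expect_true(nzchar(cli))
  root <- withr::local_tempdir()
  out <- suppressWarnings(system2(
    "Rscript", c(cli, "druglikeness", "--molecule", shQuote(SMILES_1A116),
                 "--out-dir", root),
    stdout = TRUE, stderr = TRUE
  ))
  expect_equal(attr(out, "status") %||% 0, 0)
  expect_true(file.exists(file.path(root, "druglikeness.json")))
  bad <- suppressWarnings(system2(
    "Rscript", c(cli, "druglikeness", "--molecule", "'notasmiles(('",
                 "--out-dir", root),
    stdout = TRUE, stderr = TRUE
  ))
  expect_equal(attr(bad, "status"), 2)
})
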