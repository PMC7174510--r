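#' Deterministic mock docking engine
#'
#' A seeded stand-in engine for exercising the ensemble-docking
#' orchestration without an external program. Rigid-body placements of the
#' ligand are sampled inside the box (uniform centroid position, uniform
#' random orientation) and scored with a simple clash/contact potential over
#' protein-ligand heavy-atom pairs:
#' `f(d) = +10` for `d < 2` Angstrom (steric clash), `-0.1` for
#' `2 <= d <= 4` (favourable contact), `0` beyond. Lower is better. With
#' `method = "grid"` the centroid is moved over an exhaustive translational
#' grid with no rotation — useful as an enumerable reference configuration.
#'
#' @param receptor A `confdock_structure`.
#' @param ligand A `ligand_pose` providing the ligand geometry.
#' @param box A `docking_box`.
#' @param seed Integer seed; identical input + seed gives identical output.
#' @param n_samples Number of random placements (default 500).
#' @param method `"random"` (default) or `"grid"`.
#' @param step Grid step in Angstrom for `method = "grid"` (default 0.5).
#' @return Tibble of class `dock_result` with columns `pose`, `score`
#'   (kcal/mol-scaled mock units), sorted ascending by score; attribute
#'   `best_pose` holds the best placement as a `ligand_pose`.
#' @export
mock_dock <- function(receptor, ligand, box, seed, n_samples = 500,
                      method = c("random", "grid"), step = 0.5) {
  method <- match.arg(method)
  lig <- pose_heavy(ligand)
  lx <- pose_coords(lig)
  lc <- sweep(lx, 2, colMeans(lx))
  radius <- sqrt(max(rowSums(lc^2)))
  if (2 * radius > box$edge) {
    stop("ligand (diameter ", round(2 * radius, 1),
         " A) larger than box edge ", box$edge, " A", call. = FALSE)
  }
  prot <- dplyr::filter(receptor, .data$group == "protein",
                        .data$element != "H")
  px <- as_coord_matrix(prot[, c("x", "y", "z")])

  if (method == "random") {
    set.seed(seed)
    centers <- cbind(
      stats::runif(n_samples, box$bounds[1, 1], box$bounds[1, 2]),
      stats::runif(n_samples, box$bounds[2, 1], box$bounds[2, 2]),
      stats::runif(n_samples, box$bounds[3, 1], box$bounds[3, 2])
    )
    placements <- lapply(seq_len(n_samples), function(k) {
      sweep(lc %*% t(random_rotation()), 2, centers[k, ], `+`)
    })
  } else {
    gx <- seq(box$bounds[1, 1], box$bounds[1, 2], by = step)
    gy <- seq(box$bounds[2, 1], box$bounds[2, 2], by = step)
    gz <- seq(box$bounds[3, 1], box$bounds[3, 2], by = step)
    centers <- as.matrix(expand.grid(x = gx, y = gy, z = gz))
    placements <- lapply(seq_len(nrow(centers)), function(k) {
      sweep(lc, 2, centers[k, ], `+`)
    })
  }
  scores <- vapply(placements, function(coords) {
    mock_score(coords, px)
  }, numeric(1))

  ord <- order(scores)
  out <- tibble::tibble(pose = seq_along(scores)[ord], score = scores[ord])
  best <- new_ligand_pose(
    tibble::tibble(atom_name = lig$atom_name, element = lig$element,
                   x = placements[[ord[1]]][, 1],
                   y = placements[[ord[1]]][, 2],
                   z = placements[[ord[1]]][, 3]),
    pose_id = paste0("mock_best_seed", seed),
    conformer_id = structure_id(receptor),
    score = scores[ord[1]]
  )
  structure(out, best_pose = best, engine = "mock",
            class = c("dock_result", class(tibble::tibble())))
}

# clash/contact potential over heavy-atom pairs
mock_score <- function(lig_coords, prot_coords) {
  d <- cross_distances(lig_coords, prot_coords)
  sum(10 * (d < 2)) - 0.1 * sum(d >= 2 & d <= 4)
}

#' Run an external docking engine (AutoDock Vina dialect)
#'
#' Writes receptor and ligand as PDBQT, invokes the configured executable
#' with the box centre/size and seed, and parses the scored output poses.
#' The adapter passes coordinates through unmodified: receptor preparation
#' (hydrogens, charges) is the caller's responsibility. The mock engine is
#' never substituted silently — every failure is a distinct error.
#'
#' @param receptor A `confdock_structure`.
#' @param ligand A `ligand_pose`.
#' @param box A `docking_box`.
#' @param seed Integer seed forwarded to the engine.
#' @param engine List with `executable` (path) and optional `extra_args`
#'   character vector.
#' @return A `dock_result` tibble (pose, score in kcal/mol), best first, with
#'   parsed pose coordinates in the `poses` attribute.
#' @export
external_dock <- function(receptor, ligand, box, seed, engine) {
  exe <- engine$executable
  if (is.null(exe) || (!file.exists(exe) && Sys.which(exe) == "")) {
    stop("docking engine executable not found: ",
         exe %||% "<unset>", call. = FALSE)
  }
  dir <- tempfile("dock")
  dir.create(dir)
  on.exit(unlink(dir, recursive = TRUE))
  rec_path <- file.path(dir, "receptor.pdbqt")
  lig_path <- file.path(dir, "ligand.pdbqt")
  out_path <- file.path(dir, "out.pdbqt")
  write_pdbqt(receptor, rec_path)
  write_pdbqt(ligand, lig_path)
  args <- c(
    "--receptor", rec_path, "--ligand", lig_path, "--out", out_path,
    "--center_x", box$center[1], "--center_y", box$center[2],
    "--center_z", box$center[3],
    "--size_x", box$edge, "--size_y", box$edge, "--size_z", box$edge,
    "--seed", seed, engine$extra_args
  )
  status <- suppressWarnings(
    system2(exe, args, stdout = TRUE, stderr = TRUE)
  )
  code <- attr(status, "status") %||% 0
  if (code != 0) {
    stop("docking engine exited with status ", code, ":\n",
         paste(utils::tail(status, 5), collapse = "\n"), call. = FALSE)
  }
  if (!file.exists(out_path)) {
    stop("docking engine produced no output file", call. = FALSE)
  }
  parse_vina_output(readLines(out_path, warn = FALSE))
}

#' Parse AutoDock-Vina-style scored output poses
#'
#' Reads MODEL blocks with `REMARK VINA RESULT` score lines from PDBQT text.
#'
#' @param lines Character vector of output lines (or a path).
#' @return A `dock_result` tibble, best score first, with the parsed
#'   `ligand_pose` list in the `poses` attribute.
#' @export
parse_vina_output <- function(lines) {
  if (length(lines) == 1 && file.exists(lines)) {
    lines <- readLines(lines, warn = FALSE)
  }
  starts <- grep("^MODEL", lines)
  if (length(starts) == 0) starts <- 1
  ends <- c(starts[-1] - 1, length(lines))
  poses <- list()
  scores <- numeric(0)
  for (k in seq_along(starts)) {
    block <- lines[starts[k]:ends[k]]
    sl <- grep("^REMARK VINA RESULT", block, value = TRUE)
    if (length(sl) == 0) next
    score <- as.numeric(strsplit(trimws(sub("^REMARK VINA RESULT:?", "",
                                            sl[1])), "\\s+")[[1]][1])
    atoms <- parse_pose_pdb_lines(block)
    scores <- c(scores, score)
    poses[[length(poses) + 1]] <- new_ligand_pose(
      atoms, pose_id = paste0("pose", k), score = score
    )
  }
  if (length(scores) == 0) {
    stop("no scored poses found in engine output", call. = FALSE)
  }
  ord <- order(scores)
  structure(
    tibble::tibble(pose = seq_along(scores)[ord], score = scores[ord]),
    poses = poses[ord], best_pose = poses[[ord[1]]], engine = "external",
    class = c("dock_result", class(tibble::tibble()))
  )
}

#' Write a structure or ligand pose as PDBQT
#'
#' ATOM records with the PDBQT partial-charge and atom-type columns (charge
#' written as 0.000; the AutoDock type is the element symbol). Preparation
#' pipelines that assign real charges should replace this step.
#'
#' @param x A `confdock_structure` or `ligand_pose`.
#' @param file Output path.
#' @return The path, invisibly.
#' @export
write_pdbqt <- function(x, file) {
  if (inherits(x, "confdock_structure")) {
    at <- dplyr::filter(x, .data$group == "protein")
    lines <- sprintf(
      "ATOM  %5d %-4s%3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f    %6.3f %-2s",
      seq_len(nrow(at)),
      ifelse(nchar(at$atom_name) < 4, paste0(" ", at$atom_name),
             at$atom_name),
      at$res_name, ifelse(at$chain == "", "A", at$chain), at$res_number,
      at$x, at$y, at$z, at$occupancy, 0, 0, at$element
    )
  } else {
    lines <- c("ROOT", sprintf(
      "ATOM  %5d %-4s%3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f    %6.3f %-2s",
      seq_len(nrow(x)),
      ifelse(nchar(x$atom_name) < 4, paste0(" ", x$atom_name), x$atom_name),
      "LIG", "A", 1L, x$x, x$y, x$z, 1, 0, 0, x$element
    ), "ENDROOT", "TORSDOF 0")
  }
  writeLines(lines, file)
  invisible(file)
}

#' Dock one ligand against every conformer of an ensemble, with repeats
#'
#' Orchestrates `n_repeats` docking runs per conformer through a pluggable
#' engine and records the best (lowest) score of each run — the per-repeat
#' statistic behind "mean docking energy +/- SD". The seed of repeat r of
#' conformer c is `base_seed + (c - 1) * n_repeats + (r - 1)`: deterministic
#' and disjoint across (conformer, repeat), so a rerun with the same
#' `base_seed` reproduces the table exactly for a deterministic engine.
#' Failed runs are recorded and skipped with a warning; more than 10%
#' failures abort.
#'
#' @param structures Named list of `confdock_structure` conformers.
#' @param ligand A `ligand_pose`.
#' @param box A `docking_box`, a named list of boxes (one per conformer id),
#'   or a function `structure -> docking_box`.
#' @param engine Engine spec: `list(type = "mock", n_samples = 500)` or
#'   `list(type = "external", executable = "...", extra_args = c())`.
#' @param n_repeats Repeats per conformer (default 100).
#' @param base_seed Base seed of the schedule (default 1).
#' @return An `affinity_table`: list with `records` (tibble: `conformer`,
#'   `repeat_index`, `score`), `by_conformer` (mean, sample SD, n per
#'   conformer) and `pooled` (overall mean, SD, n).
#' @export
ensemble_dock <- function(structures, ligand, box, engine,
                          n_repeats = 100, base_seed = 1) {
  stopifnot(length(structures) >= 1, n_repeats >= 1)
  ids <- names(structures)
  if (is.null(ids)) {
    ids <- vapply(structures, structure_id, "")
    names(structures) <- ids
  }
  boxes <- resolve_boxes(structures, box)
  records <- list()
  n_fail <- 0
  total <- length(ids) * n_repeats
  for (ci in seq_along(ids)) {
    for (r in seq_len(n_repeats)) {
      seed <- base_seed + (ci - 1) * n_repeats + (r - 1)
      res <- tryCatch(
        run_engine(engine, structures[[ci]], ligand, boxes[[ci]], seed),
        error = function(e) e
      )
      if (inherits(res, "error")) {
        n_fail <- n_fail + 1
        warning("run failed (", ids[ci], ", repeat ", r, "): ",
                conditionMessage(res), call. = FALSE)
        if (n_fail > 0.1 * total) {
          stop("more than 10% of docking runs failed; aborting",
               call. = FALSE)
        }
        next
      }
      records[[length(records) + 1]] <- tibble::tibble(
        conformer = ids[ci], repeat_index = r, score = res$score[1]
      )
    }
  }
  new_affinity_table(dplyr::bind_rows(records), n_repeats = n_repeats,
                     base_seed = base_seed)
}

run_engine <- function(engine, receptor, ligand, box, seed) {
  type <- engine$type %||% "mock"
  switch(type,
    mock = mock_dock(receptor, ligand, box, seed,
                     n_samples = engine$n_samples %||% 500,
                     method = engine$method %||% "random",
                     step = engine$step %||% 0.5),
    external = external_dock(receptor, ligand, box, seed, engine),
    stop("unknown engine type '", type, "'", call. = FALSE)
  )
}

resolve_boxes <- function(structures, box) {
  ids <- names(structures)
  if (inherits(box, "docking_box")) {
    stats::setNames(rep(list(box), length(ids)), ids)
  } else if (is.function(box)) {
    stats::setNames(lapply(structures, box), ids)
  } else if (is.list(box)) {
    if (!all(ids %in% names(box))) {
      stop("box list missing conformers: ",
           paste(setdiff(ids, names(box)), collapse = ", "), call. = FALSE)
    }
    box[ids]
  } else {
    stop("box must be a docking_box, list or function", call. = FALSE)
  }
}

new_affinity_table <- function(records, n_repeats, base_seed) {
  by_conf <- records |>
    dplyr::group_by(.data$conformer) |>
    dplyr::summarise(
      mean = mean(.data$score),
      sd = stats::sd(.data$score),   # sample SD (ddof = 1)
      n = dplyr::n(), .groups = "drop"
    )
  pooled <- tibble::tibble(
    mean = mean(records$score),
    sd = stats::sd(records$score),
    n = nrow(records)
  )
  structure(
    list(records = records, by_conformer = by_conf, pooled = pooled),
    n_repeats = n_repeats, base_seed = base_seed,
    class = "affinity_table"
  )
}

#' @export
print.affinity_table <- function(x, ...) {
  cat("<affinity_table> ", nrow(x$records), " runs over ",
      nrow(x$by_conformer), " conformers (",
      attr(x, "n_repeats"), " repeats, base seed ",
      attr(x, "base_seed"), ")\n", sep = "")
  cat(sprintf("  pooled: %.3f +/- %.3f kcal/mol (n = %d)\n",
              x$pooled$mean, x$pooled$sd, x$pooled$n))
  print(x$by_conformer)
  invisible(x)
}

#' @export
tidy.affinity_table <- function(x, ...) x$by_conformer

#' @export
glance.affinity_table <- function(x, ...) {
  dplyr::mutate(x$pooled,
                n_conformers = nrow(x$by_conformer),
                n_repeats = attr(x, "n_repeats"),
                base_seed = attr(x, "base_seed"))
}

#' Relative-frequency histogram of docking affinities
#'
#' Bins the pooled per-run best scores into fixed-width bins aligned to
#' multiples of the bin width; relative frequencies are percentages and sum
#' to 100.
#'
#' @param table An `affinity_table`.
#' @param bin_width Bin width in kcal/mol (default 0.25).
#' @return Tibble with `lower`, `upper`, `mid`, `count`,
#'   `rel_freq_pct`.
#' @export
affinity_histogram <- function(table, bin_width = 0.25) {
  scores <- table$records$score
  if (length(scores) == 0) stop("empty affinity table", call. = FALSE)
  lo <- floor(min(scores) / bin_width) * bin_width
  idx <- pmin(floor((scores - lo) / bin_width),
              ceiling((max(scores) - lo) / bin_width - 1e-9))
  idx <- pmax(idx, 0)
  n_bins <- max(idx) + 1
  counts <- tabulate(idx + 1, nbins = n_bins)
  tibble::tibble(
    lower = lo + bin_width * (seq_len(n_bins) - 1),
    upper = lo + bin_width * seq_len(n_bins),
    mid = lo + bin_width * (seq_len(n_bins) - 0.5),
    count = counts,
    rel_freq_pct = 100 * counts / sum(counts)
  )
}
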