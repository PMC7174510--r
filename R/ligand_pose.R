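#' Construct a ligand pose
#'
#' @param atoms Tibble with columns `atom_name`, `element`, `x`, `y`, `z`
#'   (Angstrom); an optional `graph_index` column maps each heavy atom onto an
#'   atom of a [parse_molecule()] molecular graph.
#' @param pose_id Pose label.
#' @param conformer_id Id of the receptor conformer the pose was docked
#'   against (optional).
#' @param score Engine score in kcal/mol (optional).
#' @return A tibble of class `ligand_pose`.
#' @export
new_ligand_pose <- function(atoms, pose_id = "pose", conformer_id = NULL,
                            score = NULL) {
  stopifnot(all(c("atom_name", "element", "x", "y", "z") %in% names(atoms)))
  if (!all(is.finite(atoms$x) & is.finite(atoms$y) & is.finite(atoms$z))) {
    stop("pose coordinates must be finite", call. = FALSE)
  }
  structure(tibble::as_tibble(atoms),
            pose_id = pose_id, conformer_id = conformer_id, score = score,
            class = c("ligand_pose", class(tibble::tibble())))
}

#' Read a ligand pose from PDB, PDBQT or SDF text
#'
#' PDB and PDBQT coordinate blocks are read from their fixed columns (for
#' PDBQT the partial charge and AutoDock atom-type columns are parsed but
#' only element and coordinates are used). SDF (V2000) blocks are read via
#' ChemmineR.
#'
#' @param input Path or text block.
#' @param format `"auto"` (by extension/content), `"pdb"`, `"pdbqt"` or
#'   `"sdf"`.
#' @param pose_id,conformer_id Labels stored on the pose.
#' @return A `ligand_pose` tibble.
#' @export
read_ligand_pose <- function(input, format = c("auto", "pdb", "pdbqt", "sdf"),
                             pose_id = NULL, conformer_id = NULL) {
  format <- match.arg(format)
  is_file <- length(input) == 1 && !grepl("\n", input) && file.exists(input)
  lines <- if (is_file) readLines(input, warn = FALSE) else
    unlist(strsplit(input, "\n", fixed = TRUE), use.names = FALSE)
  if (format == "auto") {
    ext <- if (is_file) tolower(sub(".*\\.", "", input)) else ""
    format <- if (ext %in% c("pdb", "pdbqt", "sdf")) {
      ext
    } else if (any(grepl("V2000", lines))) {
      "sdf"
    } else "pdb"
  }
  if (is.null(pose_id)) {
    pose_id <- if (is_file) sub("\\.[^.]*$", "", basename(input)) else "pose"
  }
  atoms <- switch(format,
    pdb = ,
    pdbqt = parse_pose_pdb_lines(lines),
    sdf = parse_pose_sdf_lines(lines)
  )
  new_ligand_pose(atoms, pose_id = pose_id, conformer_id = conformer_id)
}

parse_pose_pdb_lines <- function(lines) {
  al <- grep("^(ATOM  |HETATM)", lines, value = TRUE)
  if (length(al) == 0) stop("no coordinate records in pose input",
                            call. = FALSE)
  atom_name <- trimws(substr(al, 13, 16))
  element <- trimws(substr(al, 77, 78))
  # PDBQT puts the AutoDock type in 78-79; fall back to the atom name when
  # the element column is empty or numeric
  element <- ifelse(element == "" | grepl("[0-9.+-]", element),
                    element_from_atom_name(atom_name), element)
  tibble::tibble(
    atom_name = atom_name,
    element = toupper(element),
    x = as.numeric(substr(al, 31, 38)),
    y = as.numeric(substr(al, 39, 46)),
    z = as.numeric(substr(al, 47, 54))
  )
}

parse_pose_sdf_lines <- function(lines) {
  path <- tempfile(fileext = ".sdf")
  writeLines(lines, path)
  on.exit(unlink(path))
  sdf <- ChemmineR::read.SDFset(path)[[1]]
  ab <- ChemmineR::atomblock(sdf)
  element <- gsub("_.*$", "", rownames(ab))
  tibble::tibble(
    atom_name = paste0(element, seq_along(element)),
    element = toupper(element),
    x = ab[, 1], y = ab[, 2], z = ab[, 3]
  )
}

#' @export
print.ligand_pose <- function(x, ...) {
  cat("<ligand_pose> ", attr(x, "pose_id") %||% "", ": ", nrow(x), " atoms",
      sep = "")
  if (!is.null(attr(x, "score"))) {
    cat(sprintf(", score %.2f kcal/mol", attr(x, "score")))
  }
  cat("\n")
  NextMethod()
}

pose_heavy <- function(pose) dplyr::filter(pose, .data$element != "H")

pose_coords <- function(pose) as_coord_matrix(pose[, c("x", "y", "z")])
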