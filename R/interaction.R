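#' Docking box centred on a residue's C-alpha
#'
#' Axis-aligned cube with the given edge, centred exactly on the C-alpha of
#' the chosen residue — the search volume used to re-dock a ligand at a
#' specific site (default edge 14 Angstrom).
#'
#' @param structure A `confdock_structure`.
#' @param chain Chain id.
#' @param residue Author residue number carrying the centre C-alpha.
#' @param edge Cube edge in Angstrom (> 0), default 14.
#' @return An object of class `docking_box`: list with `center` (length-3),
#'   `edge`, and `bounds` (3 x 2 matrix of lower/upper limits).
#' @export
docking_box <- function(structure, chain, residue, edge = 14) {
  if (edge <= 0) stop("edge must be positive", call. = FALSE)
  ca <- dplyr::filter(structure, .data$group == "protein",
                      .data$chain == !!chain,
                      .data$res_number == !!residue,
                      .data$atom_name == "CA")
  if (nrow(ca) == 0) {
    stop("residue ", residue, " of chain ", chain,
         " has no C-alpha", call. = FALSE)
  }
  center <- c(ca$x[1], ca$y[1], ca$z[1])
  bounds <- cbind(center - edge / 2, center + edge / 2)
  dimnames(bounds) <- list(c("x", "y", "z"), c("lower", "upper"))
  structure(list(center = center, edge = edge, bounds = bounds),
            class = "docking_box")
}

#' @export
print.docking_box <- function(x, ...) {
  cat(sprintf("<docking_box> edge %.1f A, center (%.2f, %.2f, %.2f)\n",
              x$edge, x$center[1], x$center[2], x$center[3]))
  invisible(x)
}

#' Test points for containment in a docking box
#' @param box A `docking_box`.
#' @param points N x 3 matrix (or data frame with x, y, z).
#' @return Logical vector.
#' @export
box_contains <- function(box, points) {
  p <- as_coord_matrix(points)
  p[, 1] >= box$bounds[1, 1] & p[, 1] <= box$bounds[1, 2] &
    p[, 2] >= box$bounds[2, 1] & p[, 2] <= box$bounds[2, 2] &
    p[, 3] >= box$bounds[3, 1] & p[, 3] <= box$bounds[3, 2]
}

#' Residues in contact with a ligand pose
#'
#' A residue is in contact when any of its heavy atoms lies within `cutoff`
#' of any ligand heavy atom. The result is sorted by minimum distance — the
#' residue list behind a 2D protein-ligand interaction map.
#'
#' @param structure A `confdock_structure` (protein atoms are used).
#' @param pose A `ligand_pose`.
#' @param cutoff Heavy-atom distance cutoff in Angstrom (default 4.0).
#' @return Tibble with `chain`, `res_number`, `res_name`, `min_distance`,
#'   `n_atom_pairs` (pairs within cutoff), sorted by `min_distance`. Empty
#'   tibble when nothing is within the cutoff.
#' @export
contact_residues <- function(structure, pose, cutoff = 4.0) {
  if (nrow(pose) == 0) stop("empty ligand pose", call. = FALSE)
  prot <- dplyr::filter(structure, .data$group == "protein",
                        .data$element != "H")
  lig <- pose_heavy(pose)
  d <- cross_distances(pose_coords(lig),
                       as_coord_matrix(prot[, c("x", "y", "z")]))
  min_d <- apply(d, 2, min)
  n_in <- colSums(d <= cutoff)
  prot |>
    dplyr::mutate(min_distance = min_d, n_pairs = n_in) |>
    dplyr::group_by(.data$chain, .data$res_number, .data$ins_code,
                    .data$res_name) |>
    dplyr::summarise(min_distance = min(.data$min_distance),
                     n_atom_pairs = sum(.data$n_pairs), .groups = "drop") |>
    dplyr::filter(.data$min_distance <= cutoff) |>
    dplyr::arrange(.data$min_distance) |>
    dplyr::select("chain", "res_number", "res_name", "min_distance",
                  "n_atom_pairs")
}

# |A| x |B| Euclidean distance matrix
cross_distances <- function(a, b) {
  an <- rowSums(a^2); bn <- rowSums(b^2)
  d2 <- outer(an, bn, `+`) - 2 * tcrossprod(a, b)
  d2[d2 < 0] <- 0
  sqrt(d2)
}

#' Detect protein-ligand hydrogen bonds
#'
#' Geometric criterion: donor and acceptor are nitrogen or oxygen heavy atoms
#' on opposite sides of the interface with donor-acceptor distance at most
#' `d_max`. When an explicit hydrogen is present on the donor (within 1.3
#' Angstrom), the D-H...A angle must also be at least `angle_min`; crystal
#' structures usually lack hydrogens, in which case the distance-only
#' criterion applies and the bond is flagged `distance_only = TRUE`.
#'
#' Donor capability on the ligand side can be supplied through a
#' `graph_index` mapping onto a molecular graph (atoms with attached
#' hydrogens); without it, and without explicit hydrogens, every ligand N/O
#' is treated as a potential donor.
#'
#' @param structure A `confdock_structure`.
#' @param pose A `ligand_pose`.
#' @param d_max Donor-acceptor heavy-atom distance cutoff (default 3.5).
#' @param angle_min Minimum D-H...A angle in degrees (default 120), applied
#'   only when an explicit hydrogen is present.
#' @param graph Optional `molgraph` giving ligand hydrogen counts.
#' @return Tibble of class `hbond_table`: `donor_side`, `donor_atom`,
#'   `acceptor_atom`, `res_number`, `res_name`, `distance`, `angle`
#'   (NA when no hydrogen), `distance_only`.
#' @export
detect_hbonds <- function(structure, pose, d_max = 3.5, angle_min = 120,
                          graph = NULL) {
  prot <- dplyr::filter(structure, .data$group == "protein")
  prot_polar <- dplyr::filter(prot, .data$element %in% c("N", "O"))
  lig_polar <- dplyr::filter(pose, .data$element %in% c("N", "O"))
  out <- tibble::tibble(
    donor_side = character(0), donor_atom = character(0),
    acceptor_atom = character(0), res_number = integer(0),
    res_name = character(0), distance = numeric(0), angle = numeric(0),
    distance_only = logical(0)
  )
  if (nrow(prot_polar) == 0 || nrow(lig_polar) == 0) {
    return(structure(out, class = c("hbond_table", class(out))))
  }
  lig_h <- dplyr::filter(pose, .data$element == "H")
  lig_donor_ok <- ligand_donor_flags(lig_polar, lig_h, graph)

  d <- cross_distances(pose_coords(lig_polar),
                       as_coord_matrix(prot_polar[, c("x", "y", "z")]))
  hits <- which(d <= d_max, arr.ind = TRUE)
  rows <- list()
  for (k in seq_len(nrow(hits))) {
    li <- hits[k, 1]; pi <- hits[k, 2]
    dist <- d[li, pi]
    # ligand as donor, protein as acceptor
    if (lig_donor_ok[li]) {
      ang <- donor_angle(c(lig_polar$x[li], lig_polar$y[li], lig_polar$z[li]),
                         lig_h,
                         c(prot_polar$x[pi], prot_polar$y[pi],
                           prot_polar$z[pi]))
      if (is.na(ang$angle) || ang$angle >= angle_min) {
        rows[[length(rows) + 1]] <- tibble::tibble(
          donor_side = "ligand", donor_atom = lig_polar$atom_name[li],
          acceptor_atom = prot_polar$atom_name[pi],
          res_number = prot_polar$res_number[pi],
          res_name = prot_polar$res_name[pi],
          distance = dist, angle = ang$angle,
          distance_only = is.na(ang$angle)
        )
      }
    }
    # protein as donor (no hydrogens in typical crystal structures:
    # distance-only), ligand N/O as acceptor; carbonyl/carboxylate oxygens
    # carry no hydrogen and are never donors, so protein donors are N atoms
    # and hydroxyl-bearing side-chain oxygens
    if (prot_polar$element[pi] == "N" ||
        prot_polar$atom_name[pi] %in% c("OG", "OG1", "OH")) {
      rows[[length(rows) + 1]] <- tibble::tibble(
        donor_side = "protein", donor_atom = prot_polar$atom_name[pi],
        acceptor_atom = lig_polar$atom_name[li],
        res_number = prot_polar$res_number[pi],
        res_name = prot_polar$res_name[pi],
        distance = dist, angle = NA_real_, distance_only = TRUE
      )
    }
  }
  if (length(rows) > 0) out <- dplyr::bind_rows(rows)
  structure(dplyr::arrange(out, .data$distance),
            class = c("hbond_table", class(tibble::tibble())))
}

ligand_donor_flags <- function(lig_polar, lig_h, graph) {
  if (nrow(lig_h) > 0) {
    # donor iff an explicit hydrogen is covalently attached (<= 1.3 A)
    d <- cross_distances(pose_coords(lig_polar), pose_coords(lig_h))
    return(apply(d, 1, min) <= 1.3)
  }
  if (!is.null(graph) && "graph_index" %in% names(lig_polar)) {
    return(graph$atoms$n_h[lig_polar$graph_index] > 0)
  }
  rep(TRUE, nrow(lig_polar))
}

donor_angle <- function(donor_xyz, lig_h, acceptor_xyz) {
  if (nrow(lig_h) == 0) return(list(angle = NA_real_))
  hx <- pose_coords(lig_h)
  dh <- sqrt(rowSums(sweep(hx, 2, donor_xyz)^2))
  att <- which(dh <= 1.3)
  if (length(att) == 0) return(list(angle = NA_real_))
  # best (largest) angle over the attached hydrogens
  angs <- vapply(att, function(i) {
    v1 <- hx[i, ] - donor_xyz   # D -> H  ... angle at H between H->D, H->A
    u1 <- donor_xyz - hx[i, ]
    u2 <- acceptor_xyz - hx[i, ]
    cosang <- sum(u1 * u2) / sqrt(sum(u1^2) * sum(u2^2))
    acos(pmin(pmax(cosang, -1), 1)) * 180 / pi
  }, numeric(1))
  list(angle = max(angs))
}

#' Binding-mode RMSD between two poses of the same ligand
#'
#' Measures how far the ligand's binding mode shifts between two receptor
#' conformers. The receptors are superposed first (pass the
#' `kabsch_superposition` of conformer-b C-alphas onto conformer-a C-alphas);
#' the transform is applied to pose `b` and the RMSD is taken over matched
#' heavy atoms *without* re-fitting the ligand, so a rigid displacement of
#' the whole ligand shows up in full. Set `fit = TRUE` to additionally
#' superpose the ligands (shape comparison instead of binding-mode
#' comparison).
#'
#' @param a,b `ligand_pose` tibbles of the same molecule, atoms matched by
#'   `atom_name`.
#' @param superposition Optional `kabsch_superposition` mapping receptor b
#'   onto receptor a; `NULL` when both poses are already in one frame.
#' @param fit Re-fit the ligand before computing the RMSD (default `FALSE`).
#' @return RMSD in Angstrom (scalar).
#' @export
pose_rmsd <- function(a, b, superposition = NULL, fit = FALSE) {
  m <- match_pose_atoms(a, b)
  xa <- m$a; xb <- m$b
  if (!is.null(superposition)) xb <- apply_superposition(superposition, xb)
  if (fit) {
    return(kabsch_superpose(xa, xb)$rmsd)
  }
  rmsd_inframe(xa, xb)
}

match_pose_atoms <- function(a, b) {
  ha <- pose_heavy(a); hb <- pose_heavy(b)
  j <- match(ha$atom_name, hb$atom_name)
  if (anyNA(j)) {
    stop("atoms of pose a unmatched in pose b: ",
         paste(ha$atom_name[is.na(j)], collapse = ", "), call. = FALSE)
  }
  if (anyDuplicated(ha$atom_name) || anyDuplicated(hb$atom_name)) {
    stop("duplicate atom names prevent an unambiguous atom mapping",
         call. = FALSE)
  }
  list(a = pose_coords(ha), b = pose_coords(hb)[j, , drop = FALSE],
       names = ha$atom_name)
}

#' Per-substructure binding-mode RMSD
#'
#' In-frame RMSD of each named atom group (e.g. `ring_A`, `ring_B`,
#' `guanidine`), after applying the receptor superposition to pose `b`. When
#' the groups partition the heavy atoms, the overall RMSD obeys
#' `overall^2 = sum(n_g * rmsd_g^2) / sum(n_g)`.
#'
#' @param a,b `ligand_pose` tibbles (atoms matched by `atom_name`).
#' @param groups Named list of character vectors of atom names.
#' @param superposition Optional receptor superposition applied to `b`.
#' @return Tibble with `group`, `n_atoms`, `rmsd`; attribute `overall` holds
#'   the all-atom in-frame RMSD.
#' @export
substructure_rmsd <- function(a, b, groups, superposition = NULL) {
  if (length(groups) == 0 || is.null(names(groups))) {
    stop("groups must be a named list of atom-name vectors", call. = FALSE)
  }
  m <- match_pose_atoms(a, b)
  xb <- if (is.null(superposition)) m$b else
    apply_superposition(superposition, m$b)
  res <- purrr::imap(groups, function(atoms, gname) {
    if (length(atoms) == 0) stop("empty group '", gname, "'", call. = FALSE)
    idx <- match(atoms, m$names)
    if (anyNA(idx)) {
      stop("group '", gname, "' lists unknown atoms: ",
           paste(atoms[is.na(idx)], collapse = ", "), call. = FALSE)
    }
    tibble::tibble(group = gname, n_atoms = length(idx),
                   rmsd = rmsd_inframe(m$a[idx, , drop = FALSE],
                                       xb[idx, , drop = FALSE]))
  })
  out <- dplyr::bind_rows(res)
  structure(out, overall = rmsd_inframe(m$a, xb),
            class = c("substructure_rmsd", class(tibble::tibble())))
}
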