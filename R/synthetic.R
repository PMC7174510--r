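#' Generate a synthetic conformer ensemble with known per-residue mobility
#'
#' Builds a self-avoiding C-alpha chain with 3.8 Angstrom consecutive spacing
#' (the physical C-alpha / C-alpha distance of a trans peptide bond), then
#' produces conformers by adding independent isotropic Gaussian displacements
#' with a per-residue standard deviation, followed by a random global rigid
#' transform (rotation + translation) per conformer. The rigid transform
#' carries no structural signal — superposition must remove it — while the
#' sigma profile injects heterogeneous per-residue mobility of the kind a
#' crystal-structure ensemble of a flexible protein shows: a rigid core and
#' mobile loops.
#'
#' Residues are written as ALA except a designated site residue written as
#' TRP, mirroring workflows centred on a binding-site tryptophan.
#'
#' @param n_residues Chain length (default 100).
#' @param n_conformers Number of conformers (default 10).
#' @param sigma Per-residue displacement SD in Angstrom: either a vector of
#'   length `n_residues`, or a named list `list(core = 0.1, loop = 2,
#'   loop_ranges = list(c(20, 35), c(60, 75)))` giving a rigid-core SD, a
#'   loop SD and the loop residue ranges.
#' @param conformer_scale Optional per-conformer multiplier on the
#'   displacement (length `n_conformers`); with distinct scales the
#'   maximum-diversity pair is, in expectation, the two largest scales.
#' @param site_residue Residue written as TRP (default 56).
#' @param seed Integer seed fixing all randomness.
#' @return A list with `structures` (named list of `confdock_structure`),
#'   `traces` (named list of `ca_trace`), and `ground_truth`: a list holding
#'   the per-residue `sigma` tibble, the `conformer_scale` vector and
#'   `expected_max_pair` (ids of the two largest-scale conformers, `NULL`
#'   when scales are not unique).
#' @export
generate_ensemble <- function(n_residues = 100, n_conformers = 10,
                              sigma = list(core = 0.1, loop = 2,
                                           loop_ranges = list(c(20, 35),
                                                              c(60, 75))),
                              conformer_scale = NULL,
                              site_residue = 56, seed = 1) {
  stopifnot(n_residues >= 4, n_conformers >= 1)
  sig <- expand_sigma_profile(sigma, n_residues)
  if (any(sig < 0)) stop("sigma must be >= 0", call. = FALSE)
  if (is.null(conformer_scale)) conformer_scale <- rep(1, n_conformers)
  stopifnot(length(conformer_scale) == n_conformers, all(conformer_scale >= 0))

  set.seed(seed)
  base <- self_avoiding_chain(n_residues)

  ids <- sprintf("conf%02d", seq_len(n_conformers))
  structures <- vector("list", n_conformers)
  for (k in seq_len(n_conformers)) {
    disp <- matrix(stats::rnorm(n_residues * 3), ncol = 3) *
      (sig * conformer_scale[k])
    coords <- base + disp
    rot <- random_rotation()
    shift <- stats::runif(3, -20, 20)
    coords <- sweep(coords %*% t(rot), 2, shift, `+`)
    structures[[k]] <- chain_to_structure(coords, ids[k], site_residue)
  }
  names(structures) <- ids
  traces <- lapply(structures, ca_trace, chain = "A")

  expected_max_pair <- NULL
  ord <- order(conformer_scale, decreasing = TRUE)
  if (n_conformers >= 2 &&
      !any(duplicated(conformer_scale[ord[1:2]])) &&
      conformer_scale[ord[2]] > max(c(0, conformer_scale[ord[-(1:2)]]))) {
    expected_max_pair <- sort(ids[ord[1:2]])
  } else if (n_conformers >= 2 && conformer_scale[ord[1]] >
             conformer_scale[ord[2]] &&
             length(unique(conformer_scale)) == n_conformers) {
    expected_max_pair <- sort(ids[ord[1:2]])
  }

  list(
    structures = structures,
    traces = traces,
    ground_truth = list(
      sigma = tibble::tibble(res_number = seq_len(n_residues), sigma = sig),
      conformer_scale = stats::setNames(conformer_scale, ids),
      expected_max_pair = expected_max_pair,
      site_residue = site_residue
    )
  )
}

expand_sigma_profile <- function(sigma, n_residues) {
  if (is.numeric(sigma)) {
    if (length(sigma) == 1) return(rep(sigma, n_residues))
    if (length(sigma) != n_residues) {
      stop("sigma vector must have length n_residues", call. = FALSE)
    }
    return(sigma)
  }
  sig <- rep(sigma$core, n_residues)
  for (rg in sigma$loop_ranges) {
    if (rg[1] < 1 || rg[2] > n_residues || rg[1] > rg[2]) {
      stop("loop range outside [1, n_residues]", call. = FALSE)
    }
    sig[rg[1]:rg[2]] <- sigma$loop
  }
  sig
}

# random self-avoiding walk with fixed 3.8 A steps; rejects steps closer than
# 3.4 A to any previous bead
self_avoiding_chain <- function(n, step = 3.8, min_sep = 3.4) {
  coords <- matrix(NA_real_, n, 3)
  coords[1, ] <- 0
  for (i in 2:n) {
    for (attempt in 1:200) {
      dir <- stats::rnorm(3)
      dir <- dir / sqrt(sum(dir^2))
      cand <- coords[i - 1, ] + step * dir
      prev <- coords[seq_len(i - 2), , drop = FALSE]
      if (i == 2 || nrow(prev) == 0 ||
          min(sqrt(rowSums(sweep(prev, 2, cand)^2))) >= min_sep) {
        coords[i, ] <- cand
        break
      }
    }
    if (any(is.na(coords[i, ]))) {
      # fall back to continuing straight on; always self-avoiding
      coords[i, ] <- 2 * coords[i - 1, ] - coords[i - 2, ]
    }
  }
  coords
}

chain_to_structure <- function(coords, id, site_residue) {
  n <- nrow(coords)
  res_name <- rep("ALA", n)
  if (!is.na(site_residue) && site_residue >= 1 && site_residue <= n) {
    res_name[site_residue] <- "TRP"
  }
  atoms <- tibble::tibble(
    record = "ATOM",
    atom_name = "CA",
    altloc = "",
    res_name = res_name,
    chain = "A",
    res_number = seq_len(n),
    ins_code = "",
    x = coords[, 1], y = coords[, 2], z = coords[, 3],
    occupancy = 1,
    element = "C",
    group = "protein"
  )
  new_structure(atoms, id = id)
}

#' Generate a toy protein-ligand complex with planted contacts and H-bond
#'
#' Lays the protein C-alphas out on a straight line with 3.8 Angstrom
#' spacing, then places one ligand carbon directly above each pocket residue
#' at exactly the planted contact distance. Non-pocket residues are farther
#' from every ligand atom than the contact cutoff by construction. A planted
#' hydrogen bond adds a ligand donor nitrogen (with an explicit hydrogen at
#' 1.0 Angstrom placed to realize the requested donor-H...acceptor angle) and
#' a protein backbone-style acceptor oxygen at the requested donor-acceptor
#' distance from it.
#'
#' @param n_residues Protein length (default 80).
#' @param pocket_residues Residue numbers receiving a planted contact.
#' @param contact_distance Planted minimum heavy-atom distance (Angstrom,
#'   default 3.0).
#' @param hbond `NULL`, or `list(distance = 2.9, angle = 170, residue = 56)`:
#'   donor-acceptor distance (Angstrom), D-H...A angle (degrees) and the
#'   protein residue carrying the acceptor.
#' @param seed Integer seed (orientation jitter of the hydrogen placement).
#' @return A list with `structure` (`confdock_structure`), `pose`
#'   (`ligand_pose` tibble) and `ground_truth` (planted contact tibble and
#'   H-bond description).
#' @export
generate_complex <- function(n_residues = 80,
                             pocket_residues = c(5, 39, 41, 52, 56),
                             contact_distance = 3.0,
                             hbond = list(distance = 2.9, angle = 170,
                                          residue = 56),
                             seed = 1) {
  if (any(pocket_residues < 1 | pocket_residues > n_residues)) {
    stop("pocket residues outside chain", call. = FALSE)
  }
  if (any(contact_distance <= 0)) {
    stop("planted contact distance must be positive", call. = FALSE)
  }
  set.seed(seed)
  coords <- cbind((seq_len(n_residues) - 1) * 3.8, 0, 0)
  prot <- chain_to_structure(coords, "toy_receptor",
                             site_residue = hbond$residue %||% NA)

  lig_atoms <- tibble::tibble(
    atom_name = character(0), element = character(0),
    x = numeric(0), y = numeric(0), z = numeric(0)
  )
  if (length(pocket_residues) == 0 && is.null(hbond)) {
    # no planted interactions: a single inert atom far from the chain keeps
    # the pose non-empty while guaranteeing empty detections
    lig_atoms <- tibble::tibble(atom_name = "C1", element = "C",
                                x = 0, y = 100, z = 100)
  }
  k <- 0
  for (r in sort(unique(pocket_residues))) {
    k <- k + 1
    lig_atoms <- dplyr::bind_rows(lig_atoms, tibble::tibble(
      atom_name = sprintf("C%d", k), element = "C",
      x = coords[r, 1], y = 0, z = contact_distance
    ))
  }

  gt_hbond <- NULL
  if (!is.null(hbond)) {
    if (hbond$distance <= 0 || hbond$angle <= 0 || hbond$angle > 180) {
      stop("infeasible H-bond geometry", call. = FALSE)
    }
    r <- hbond$residue
    if (r < 1 || r > n_residues) stop("H-bond residue outside chain",
                                      call. = FALSE)
    # acceptor O sits next to the residue CA, offset in -y; the ligand donor
    # N sits hbond$distance away along +z from the acceptor
    acc <- coords[r, ] + c(0, -2.0, 0)
    don <- acc + c(0, 0, hbond$distance)
    # place H at 1.0 A from the donor, in the D-A plane, so the D-H...A
    # angle (at H) equals the requested value exactly: solve for the H-D-A
    # angle phi that yields it
    v <- (acc - don) / hbond$distance          # unit vector D -> A
    w <- c(1, 0, 0)                            # perpendicular to v (v is +z)
    angle_at_h <- function(phi) {
      h <- don + cos(phi) * v + sin(phi) * w
      u1 <- don - h; u2 <- acc - h
      acos(sum(u1 * u2) / sqrt(sum(u1^2) * sum(u2^2))) * 180 / pi
    }
    phi <- if (hbond$angle >= 180) 0 else
      stats::uniroot(function(p) angle_at_h(p) - hbond$angle,
                     c(1e-6, pi / 2))$root
    h <- don + cos(phi) * v + sin(phi) * w
    prot_o <- tibble::tibble(
      record = "ATOM", atom_name = "O", altloc = "",
      res_name = prot$res_name[prot$res_number == r][1],
      chain = "A", res_number = as.integer(r), ins_code = "",
      x = acc[1], y = acc[2], z = acc[3], occupancy = 1,
      element = "O", group = "protein"
    )
    prot <- new_structure(
      dplyr::arrange(dplyr::bind_rows(prot, prot_o),
                     .data$res_number, .data$atom_name),
      id = attr(prot, "id")
    )
    lig_atoms <- dplyr::bind_rows(
      lig_atoms,
      tibble::tibble(atom_name = "N1", element = "N",
                     x = don[1], y = don[2], z = don[3]),
      tibble::tibble(atom_name = "H1", element = "H",
                     x = h[1], y = h[2], z = h[3])
    )
    gt_hbond <- tibble::tibble(
      donor = "N1", acceptor_res = r, distance = hbond$distance,
      angle = hbond$angle
    )
  }

  pose <- new_ligand_pose(lig_atoms, pose_id = "toy_ligand",
                          conformer_id = "toy_receptor")
  contacts <- tibble::tibble(res_number = sort(unique(pocket_residues)),
                             min_distance = contact_distance)
  if (!is.null(hbond)) {
    # the acceptor oxygen of the H-bond residue sits hbond$distance from the
    # ligand donor, which can undercut the planted pocket distance
    if (hbond$residue %in% contacts$res_number) {
      contacts$min_distance[contacts$res_number == hbond$residue] <-
        min(contact_distance, hbond$distance)
    } else {
      contacts <- dplyr::arrange(
        dplyr::bind_rows(contacts,
                         tibble::tibble(res_number = hbond$residue,
                                        min_distance = hbond$distance)),
        .data$res_number
      )
    }
  }
  list(
    structure = prot,
    pose = pose,
    ground_truth = list(contacts = contacts, hbond = gt_hbond)
  )
}
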