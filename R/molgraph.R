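#' Parse a small molecule into a molecular graph
#'
#' Accepts a SMILES string or an SDF (V2000) block/file. SMILES are converted
#' through ChemmineR/ChemmineOB (OpenBabel); SDF blocks are read with
#' ChemmineR. The resulting graph carries, per atom: element, formal charge,
#' attached (implicit + explicit) hydrogen count, aromaticity and ring
#' membership; per bond: order and ring membership. Implicit hydrogens are
#' assigned from standard valences (C 4, N 3, O 2, halogens 1, S 2, P 3)
#' adjusted by formal charge; aromaticity is perceived on 5-7 membered rings
#' with a Hueckel electron count over the Kekule structure.
#'
#' @param input SMILES string, SDF text block, or path to an .sdf/.mol file.
#' @return An object of class `molgraph`: list with tibbles `atoms`
#'   (`element`, `charge`, `n_h`, `aromatic`, `in_ring`, `x`, `y`, `z`) and
#'   `bonds` (`a1`, `a2`, `order`, `in_ring`, `aromatic`), plus the `source`
#'   string.
#' @examples
#' \dontrun{
#' benzene <- parse_molecule("c1ccccc1")
#' sum(benzene$atoms$aromatic)  # 6
#' }
#' @export
parse_molecule <- function(input) {
  stopifnot(is.character(input), length(input) == 1)
  is_file <- !grepl("\n", input) && file.exists(input)
  if (is_file) {
    sdf_lines <- readLines(input, warn = FALSE)
  } else if (grepl("\n", input) || grepl("V2000", input)) {
    sdf_lines <- unlist(strsplit(input, "\n", fixed = TRUE))
  } else {
    sdf_lines <- smiles_to_sdf_lines(input)
  }
  molgraph_from_sdf_lines(sdf_lines, source = if (is_file) input else
    substr(input, 1, 200))
}

smiles_to_sdf_lines <- function(smiles) {
  txt <- tryCatch(
    ChemmineOB::convertFormat("SMI", "SDF", paste0(smiles, "\n")),
    error = function(e) {
      stop("SMILES parse failure for '", smiles, "': ",
           conditionMessage(e), call. = FALSE)
    }
  )
  lines <- unlist(strsplit(txt, "\n", fixed = TRUE))
  n_atoms <- if (length(lines) >= 4) {
    suppressWarnings(as.integer(substr(lines[4], 1, 3)))
  } else NA_integer_
  if (is.na(n_atoms) || n_atoms == 0) {
    stop("SMILES parse failure for '", smiles, "': no atoms produced",
         call. = FALSE)
  }
  lines
}

molgraph_from_sdf_lines <- function(lines, source = "sdf") {
  if (length(lines) < 4) stop("truncated SDF block", call. = FALSE)
  counts <- lines[4]
  n_atoms <- suppressWarnings(as.integer(substr(counts, 1, 3)))
  n_bonds <- suppressWarnings(as.integer(substr(counts, 4, 6)))
  if (is.na(n_atoms) || is.na(n_bonds)) {
    stop("malformed SDF counts line (line 4): '", counts, "'", call. = FALSE)
  }
  if (n_atoms == 0) stop("SDF block contains no atoms", call. = FALSE)
  atom_lines <- lines[5:(4 + n_atoms)]
  x <- as.numeric(substr(atom_lines, 1, 10))
  y <- as.numeric(substr(atom_lines, 11, 20))
  z <- as.numeric(substr(atom_lines, 21, 30))
  element <- trimws(substr(atom_lines, 32, 34))
  if (any(is.na(x) | is.na(y) | is.na(z))) {
    stop("malformed SDF atom line ",
         4 + which(is.na(x) | is.na(y) | is.na(z))[1], call. = FALSE)
  }
  # old-style charge code: 0 none, 1..3 -> +3..+1, 5..7 -> -1..-3
  ccode <- suppressWarnings(as.integer(substr(atom_lines, 37, 39)))
  ccode[is.na(ccode)] <- 0L
  charge <- dplyr::case_when(
    ccode %in% 1:3 ~ 4L - ccode,
    ccode %in% 5:7 ~ 4L - ccode,
    TRUE ~ 0L
  )

  bonds <- tibble::tibble(a1 = integer(0), a2 = integer(0),
                          order = integer(0))
  if (n_bonds > 0) {
    bond_lines <- lines[(5 + n_atoms):(4 + n_atoms + n_bonds)]
    bonds <- tibble::tibble(
      a1 = as.integer(substr(bond_lines, 1, 3)),
      a2 = as.integer(substr(bond_lines, 4, 6)),
      order = as.integer(substr(bond_lines, 7, 9))
    )
  }
  # M CHG property lines override old-style codes
  for (ln in grep("^M  CHG", lines, value = TRUE)) {
    flds <- as.integer(strsplit(trimws(substr(ln, 7, nchar(ln))),
                                "\\s+")[[1]])
    n <- flds[1]
    for (k in seq_len(n)) {
      charge[flds[2 * k]] <- flds[2 * k + 1]
    }
  }

  atoms <- tibble::tibble(
    element = element, charge = charge,
    x = x, y = y, z = z
  )
  build_molgraph(atoms, bonds, source)
}

build_molgraph <- function(atoms, bonds, source) {
  n <- nrow(atoms)
  explicit_h <- integer(n)
  if (nrow(bonds) > 0) {
    if (any(bonds$a1 < 1 | bonds$a1 > n | bonds$a2 < 1 | bonds$a2 > n)) {
      stop("bond references unknown atom", call. = FALSE)
    }
    h_idx <- which(atoms$element == "H")
    for (i in seq_len(nrow(bonds))) {
      if (bonds$a1[i] %in% h_idx) {
        explicit_h[bonds$a2[i]] <- explicit_h[bonds$a2[i]] + 1L
      }
      if (bonds$a2[i] %in% h_idx) {
        explicit_h[bonds$a1[i]] <- explicit_h[bonds$a1[i]] + 1L
      }
    }
  }
  order_sum <- bond_order_sums(nrow(atoms), bonds)
  implicit_h <- pmax(0L, default_valence(atoms$element, atoms$charge) -
                       order_sum)
  implicit_h[atoms$element == "H"] <- 0L
  n_h <- ifelse(explicit_h > 0, explicit_h, implicit_h)
  # an atom with any explicit H keeps only those; mixed cases are rare in
  # V2000 input and resolved in favour of the explicit count

  rings <- perceive_rings(n, bonds)
  bond_in_ring <- logical(nrow(bonds))
  if (nrow(bonds) > 0) bond_in_ring <- rings$bond_in_ring
  atom_in_ring <- rings$atom_in_ring
  arom <- perceive_aromaticity(atoms, bonds, rings$rings)

  atoms <- atoms |>
    dplyr::mutate(
      idx = dplyr::row_number(),
      n_h = as.integer(n_h),
      aromatic = arom$atom,
      in_ring = atom_in_ring,
      .before = 1
    ) |>
    dplyr::select("idx", "element", "charge", "n_h", "aromatic", "in_ring",
                  "x", "y", "z")
  bonds$in_ring <- bond_in_ring
  bonds$aromatic <- arom$bond
  structure(list(atoms = atoms, bonds = bonds, source = source),
            class = "molgraph")
}

bond_order_sums <- function(n, bonds) {
  s <- numeric(n)
  if (nrow(bonds) == 0) return(s)
  ord <- ifelse(bonds$order == 4, 1.5, bonds$order)  # aromatic SDF bonds
  for (i in seq_len(nrow(bonds))) {
    s[bonds$a1[i]] <- s[bonds$a1[i]] + ord[i]
    s[bonds$a2[i]] <- s[bonds$a2[i]] + ord[i]
  }
  round(s)
}

default_valence <- function(element, charge) {
  base <- dplyr::case_when(
    element == "C" ~ 4L,
    element == "N" ~ 3L,
    element == "O" ~ 2L,
    element %in% c("F", "CL", "Cl", "BR", "Br", "I") ~ 1L,
    element == "S" ~ 2L,
    element == "P" ~ 3L,
    element == "B" ~ 3L,
    element %in% c("Si", "SI") ~ 4L,
    element == "H" ~ 1L,
    TRUE ~ 0L
  )
  adj <- dplyr::case_when(
    element %in% c("N", "P") ~ charge,
    element %in% c("O", "S") ~ charge,
    element == "C" ~ -abs(charge),
    TRUE ~ 0L
  )
  pmax(0L, base + adj)
}

# ring membership: a bond is in a ring iff it is not a bridge; rings are
# recovered as the shortest cycle through each non-bridge edge
perceive_rings <- function(n, bonds) {
  atom_in_ring <- logical(n)
  if (nrow(bonds) == 0) {
    return(list(bond_in_ring = logical(0), atom_in_ring = atom_in_ring,
                rings = list()))
  }
  g <- igraph::graph_from_data_frame(
    data.frame(from = bonds$a1, to = bonds$a2),
    directed = FALSE,
    vertices = data.frame(name = seq_len(n))
  )
  br <- igraph::bridges(g)
  bond_in_ring <- !seq_len(nrow(bonds)) %in% as.integer(br)
  rings <- list()
  seen <- character(0)
  for (e in which(bond_in_ring)) {
    g2 <- igraph::delete_edges(g, e)
    sp <- suppressWarnings(igraph::shortest_paths(
      g2, from = as.character(bonds$a1[e]), to = as.character(bonds$a2[e])
    )$vpath[[1]])
    if (length(sp) == 0) next
    ring <- as.integer(igraph::as_ids(sp))
    key <- paste(sort(ring), collapse = "-")
    if (!key %in% seen) {
      seen <- c(seen, key)
      rings[[length(rings) + 1]] <- ring
    }
    atom_in_ring[ring] <- TRUE
  }
  list(bond_in_ring = bond_in_ring, atom_in_ring = atom_in_ring,
       rings = rings)
}

# simplified Hueckel perception on the Kekule structure: a 5-7 membered ring
# of C/N/O/S atoms is aromatic when every atom is conjugated (has a double
# bond to some ring atom, or contributes a lone pair) and the pi electron
# count is 4n+2. Exocyclic double bonds (quinones) contribute no pi electrons
# and block the lone-pair route, which correctly rejects quinoid rings.
perceive_aromaticity <- function(atoms, bonds, rings) {
  n <- nrow(atoms)
  atom_arom <- logical(n)
  bond_arom <- logical(nrow(bonds))
  if (length(rings) == 0) {
    return(list(atom = atom_arom, bond = bond_arom))
  }
  dbl_partner <- vector("list", n)
  for (i in seq_len(nrow(bonds))) {
    if (bonds$order[i] == 2) {
      dbl_partner[[bonds$a1[i]]] <- c(dbl_partner[[bonds$a1[i]]],
                                      bonds$a2[i])
      dbl_partner[[bonds$a2[i]]] <- c(dbl_partner[[bonds$a2[i]]],
                                      bonds$a1[i])
    }
    if (bonds$order[i] == 4) {  # explicit aromatic SDF bond
      atom_arom[bonds$a1[i]] <- TRUE
      atom_arom[bonds$a2[i]] <- TRUE
      bond_arom[i] <- TRUE
    }
  }
  in_any_ring <- logical(n)
  for (ring in rings) in_any_ring[ring] <- TRUE

  for (ring in rings) {
    if (!length(ring) %in% 5:7) next
    if (!all(atoms$element[ring] %in% c("C", "N", "O", "S"))) next
    pi <- 0
    ok <- TRUE
    for (a in ring) {
      partners <- dbl_partner[[a]]
      if (length(partners) > 0 && any(in_any_ring[partners])) {
        pi <- pi + 1
      } else if (length(partners) > 0) {
        ok <- FALSE; break     # exocyclic double bond (quinoid)
      } else if (atoms$element[a] %in% c("N", "O", "S") ||
                 atoms$charge[a] < 0) {
        pi <- pi + 2           # lone-pair donor
      } else {
        ok <- FALSE; break     # sp3 carbon
      }
    }
    if (ok && pi %% 4 == 2) {
      atom_arom[ring] <- TRUE
      ring_set <- ring
      for (i in seq_len(nrow(bonds))) {
        if (bonds$a1[i] %in% ring_set && bonds$a2[i] %in% ring_set) {
          bond_arom[i] <- TRUE
        }
      }
    }
  }
  list(atom = atom_arom, bond = bond_arom)
}

#' @export
print.molgraph <- function(x, ...) {
  heavy <- sum(x$atoms$element != "H")
  cat("<molgraph> ", heavy, " heavy atoms, ", nrow(x$bonds), " bonds, ",
      "formula ", molecular_formula(x), "\n", sep = "")
  invisible(x)
}

#' Molecular formula (Hill order)
#' @param m A `molgraph`.
#' @return Character scalar, e.g. `"C16H16F3N3"`.
#' @export
molecular_formula <- function(m) {
  el <- m$atoms$element
  nh <- sum(m$atoms$n_h) + sum(el == "H")
  counts <- table(el[el != "H"])
  if (nh > 0) counts <- c(counts, H = nh)
  nm <- names(counts)
  hill <- c(intersect(c("C", "H"), nm), sort(setdiff(nm, c("C", "H"))))
  paste0(purrr::map_chr(hill, function(e) {
    k <- counts[[e]]
    paste0(substr(e, 1, 1), tolower(substring(e, 2)),
           if (k > 1) k else "")
  }), collapse = "")
}

#' Named substructure map over a molecular graph
#'
#' Validates named atom groups (1-based atom indices of the graph) used for
#' per-substructure pose comparison, e.g. `ring_A`, `ring_B`, `guanidine`.
#'
#' @param m A `molgraph`.
#' @param ... Named integer vectors of atom indices.
#' @param allow_overlap Permit atoms shared between groups (default `FALSE`).
#' @return Named list of class `substructure_map`.
#' @export
substructure_map <- function(m, ..., allow_overlap = FALSE) {
  groups <- list(...)
  if (length(groups) == 0 || is.null(names(groups)) ||
      any(names(groups) == "")) {
    stop("substructure groups must be named", call. = FALSE)
  }
  all_idx <- unlist(groups)
  if (any(all_idx < 1 | all_idx > nrow(m$atoms))) {
    stop("group atom index outside molecule", call. = FALSE)
  }
  if (!allow_overlap && anyDuplicated(all_idx)) {
    stop("groups overlap; set allow_overlap = TRUE if intended",
         call. = FALSE)
  }
  structure(lapply(groups, as.integer), class = "substructure_map")
}
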