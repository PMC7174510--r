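#' Read a macromolecular structure from PDB-format text
#'
#' Parses PDB ATOM/HETATM records (via bio3d) into a tidy atom table.
#' Only the first MODEL of a multi-model file is read (the workflow targets
#' crystal structures). Alternate locations are resolved to a single
#' conformation per atom: the altloc with the highest occupancy is kept, ties
#' going to altloc "A". Waters (HOH/WAT/DOD) and other HETATM groups never
#' enter the protein chains; they are retained in the same table flagged by
#' the `group` column ("protein", "het" or "water") so ligands stay available
#' for interaction analysis.
#'
#' @param input Path to a PDB file, or a character scalar/vector of PDB-format
#'   text.
#' @param id Structure label, e.g. `"1E96:A"`. Defaults to the file name
#'   without extension, or `"structure"` for raw text input.
#' @return A tibble of class `confdock_structure` with one row per atom and
#'   columns `record`, `atom_name`, `altloc`, `res_name`, `chain`,
#'   `res_number`, `ins_code`, `x`, `y`, `z`, `occupancy`, `element`, `group`,
#'   carrying the structure `id` as an attribute.
#' @export
read_structure <- function(input, id = NULL) {
  src <- resolve_pdb_source(input)
  if (is.null(id)) id <- src$default_id

  if (!any(grepl("^(ATOM  |HETATM)", src$lines))) {
    stop("no ATOM records found in ", src$label, call. = FALSE)
  }
  check_coordinate_fields(src)

  pdb <- tryCatch(
    suppressWarnings(bio3d::read.pdb(src$path, multi = FALSE,
                                     rm.alt = FALSE, verbose = FALSE)),
    error = function(e) {
      stop("failed to parse ", src$label, ": ", conditionMessage(e),
           call. = FALSE)
    }
  )
  at <- pdb$atom
  atoms <- tibble::tibble(
    record = at$type,
    atom_name = at$elety,
    altloc = ifelse(is.na(at$alt), "", at$alt),
    res_name = at$resid,
    chain = ifelse(is.na(at$chain), "", at$chain),
    res_number = as.integer(at$resno),
    ins_code = ifelse(is.na(at$insert), "", at$insert),
    x = at$x, y = at$y, z = at$z,
    occupancy = ifelse(is.na(at$o), 1, at$o),
    element = toupper(ifelse(is.na(at$elesy) | at$elesy == "",
                             element_from_atom_name(at$elety), at$elesy))
  )
  atoms <- resolve_altlocs(atoms)
  atoms$group <- dplyr::case_when(
    atoms$res_name %in% c("HOH", "WAT", "DOD", "H2O") ~ "water",
    atoms$record == "HETATM" ~ "het",
    TRUE ~ "protein"
  )
  if (!is.null(src$cleanup)) unlink(src$path)
  new_structure(atoms, id = id)
}

resolve_pdb_source <- function(input) {
  if (length(input) == 1 && !grepl("\n", input) && file.exists(input)) {
    list(lines = readLines(input, warn = FALSE),
         path = input, cleanup = NULL,
         label = input,
         default_id = sub("\\.[^.]*$", "", basename(input)))
  } else {
    lines <- unlist(strsplit(input, "\n", fixed = TRUE), use.names = FALSE)
    path <- tempfile(fileext = ".pdb")
    writeLines(lines, path)
    list(lines = lines, path = path, cleanup = TRUE,
         label = "PDB text input", default_id = "structure")
  }
}

# fail early, with a line number, on unparseable coordinate fields
check_coordinate_fields <- function(src) {
  idx <- grep("^(ATOM  |HETATM)", src$lines)
  al <- src$lines[idx]
  xyz <- cbind(
    suppressWarnings(as.numeric(substr(al, 31, 38))),
    suppressWarnings(as.numeric(substr(al, 39, 46))),
    suppressWarnings(as.numeric(substr(al, 47, 54)))
  )
  bad <- which(rowSums(!is.finite(xyz)) > 0)
  if (length(bad) > 0) {
    stop("malformed coordinate field at line ", idx[bad[1]], " of ",
         src$label, call. = FALSE)
  }
  invisible(TRUE)
}

# keep one atom per (chain, residue, atom name): highest occupancy, tie -> 'A'
# (then alphabetical, for a deterministic result on files without an 'A')
resolve_altlocs <- function(atoms) {
  atoms |>
    dplyr::group_by(.data$chain, .data$res_number, .data$ins_code,
                    .data$res_name, .data$atom_name, .data$record) |>
    dplyr::arrange(dplyr::desc(.data$occupancy),
                   .data$altloc != "A", .data$altloc,
                   .by_group = TRUE) |>
    dplyr::slice(1) |>
    dplyr::ungroup() |>
    dplyr::arrange(.data$chain, .data$res_number, .data$ins_code)
}

new_structure <- function(atoms, id) {
  structure(atoms, id = id,
            class = c("confdock_structure", class(tibble::tibble())))
}

#' @export
print.confdock_structure <- function(x, ...) {
  cat("<confdock_structure> ", attr(x, "id"), ": ",
      sum(x$group == "protein"), " protein atoms, ",
      sum(x$group == "het"), " het atoms, ",
      sum(x$group == "water"), " waters, chains: ",
      paste(sort(unique(x$chain[x$group == "protein"])), collapse = ", "),
      "\n", sep = "")
  NextMethod()
}

#' Structure id accessor
#' @param structure A `confdock_structure`.
#' @return The id label.
#' @export
structure_id <- function(structure) attr(structure, "id")

element_from_atom_name <- function(atom_name) {
  # PDB convention puts the element in the leading letters of the atom name
  # ("CA" = C-alpha carbon); strip digits/primes and keep a two-letter symbol
  # only for names that start with a known two-letter element
  nm <- gsub("[0-9']", "", atom_name)
  two <- c("CL", "BR", "FE", "ZN", "MG", "MN", "CU", "SE", "NI", "CO")
  first2 <- toupper(substr(nm, 1, 2))
  ifelse(first2 %in% two & nchar(nm) >= 2, first2, toupper(substr(nm, 1, 1)))
}

#' Write a structure as PDB-format text
#'
#' Emits standard fixed-column ATOM/HETATM records with coordinates rounded
#' to 3 decimals (via bio3d).
#'
#' @param structure A `confdock_structure`.
#' @param file Optional path; when `NULL` the text is returned as a character
#'   vector of lines.
#' @return The PDB lines, invisibly.
#' @export
write_structure <- function(structure, file = NULL) {
  path <- file %||% tempfile(fileext = ".pdb")
  if (nrow(structure) == 0) {
    warning("writing empty structure: header-only output", call. = FALSE)
    out <- c(sprintf("REMARK   confdock structure %s (empty)",
                     attr(structure, "id") %||% ""), "END")
    writeLines(out, path)
  } else {
    bio3d::write.pdb(
      file = path,
      xyz = as.numeric(t(as.matrix(structure[, c("x", "y", "z")]))),
      type = structure$record,
      resno = structure$res_number,
      resid = structure$res_name,
      eleno = seq_len(nrow(structure)),
      elety = structure$atom_name,
      chain = ifelse(structure$chain == "", "A", structure$chain),
      insert = ifelse(structure$ins_code == "", NA, structure$ins_code),
      o = structure$occupancy,
      b = rep(0, nrow(structure)),
      elesy = structure$element,
      end = TRUE
    )
    out <- readLines(path, warn = FALSE)
  }
  if (is.null(file)) unlink(path)
  invisible(out)
}

#' Extract the C-alpha trace of one chain
#'
#' @param structure A `confdock_structure`.
#' @param chain Chain identifier. Residues lacking a C-alpha are omitted and
#'   reported in the `gaps` attribute of the result.
#' @return A tibble of class `ca_trace` with columns `chain`, `res_number`,
#'   `ins_code`, `res_name`, `x`, `y`, `z`, ordered by residue number and
#'   insertion code, with attributes `id` and `gaps`.
#' @export
ca_trace <- function(structure, chain) {
  prot <- dplyr::filter(structure, .data$group == "protein")
  chains <- sort(unique(prot$chain))
  if (!chain %in% chains) {
    stop("chain '", chain, "' not found; available chains: ",
         paste(chains, collapse = ", "), call. = FALSE)
  }
  ch <- dplyr::filter(prot, .data$chain == !!chain)
  residues <- dplyr::distinct(ch, .data$res_number, .data$ins_code,
                              .data$res_name)
  cas <- ch |>
    dplyr::filter(.data$atom_name == "CA", .data$element == "C") |>
    dplyr::arrange(.data$res_number, .data$ins_code) |>
    dplyr::select("chain", "res_number", "ins_code", "res_name",
                  "x", "y", "z")
  gaps <- dplyr::anti_join(residues, cas,
                           by = c("res_number", "ins_code", "res_name"))
  structure(cas,
            id = attr(structure, "id"), gaps = gaps,
            class = c("ca_trace", class(tibble::tibble())))
}

#' Map residues common to two C-alpha traces
#'
#' Pairs residues by identical author number and insertion code where the
#' residue names agree. If fewer than half of the residues of the shorter
#' trace can be paired that way (e.g. the entries use different numbering),
#' falls back to a global sequence alignment (identity scoring, affine gaps)
#' and pairs aligned identical residues.
#'
#' @param a,b `ca_trace` tibbles.
#' @return A tibble of class `residue_correspondence` with columns `idx_a`,
#'   `idx_b` (row indices into the traces), `res_number_a`, `res_number_b`,
#'   `res_name`; attribute `method` is `"number-match"` or
#'   `"alignment-fallback"`.
#' @export
map_common_residues <- function(a, b) {
  if (nrow(a) == 0 || nrow(b) == 0) {
    stop("cannot map residues: empty trace", call. = FALSE)
  }
  key_a <- paste(a$res_number, a$ins_code)
  key_b <- paste(b$res_number, b$ins_code)
  j <- match(key_a, key_b)
  ok <- !is.na(j) & a$res_name == b$res_name[ifelse(is.na(j), 1, j)]
  method <- "number-match"
  pairs <- tibble::tibble(idx_a = which(ok), idx_b = j[ok])

  if (nrow(pairs) < 0.5 * min(nrow(a), nrow(b))) {
    method <- "alignment-fallback"
    pairs <- align_traces(a, b)
  }
  if (nrow(pairs) == 0) stop("no common residues", call. = FALSE)
  out <- tibble::tibble(
    idx_a = pairs$idx_a, idx_b = pairs$idx_b,
    res_number_a = a$res_number[pairs$idx_a],
    res_number_b = b$res_number[pairs$idx_b],
    res_name = a$res_name[pairs$idx_a]
  )
  structure(out, method = method,
            class = c("residue_correspondence", class(tibble::tibble())))
}

# global alignment of the one-letter sequences; identical aligned residues
# become pairs
align_traces <- function(a, b) {
  seq_a <- paste(bio3d::aa321(a$res_name), collapse = "")
  seq_b <- paste(bio3d::aa321(b$res_name), collapse = "")
  aln <- Biostrings::pairwiseAlignment(
    seq_a, seq_b, type = "global",
    substitutionMatrix = identity_substitution_matrix(),
    gapOpening = 10, gapExtension = 0.5
  )
  pa <- strsplit(as.character(Biostrings::alignedPattern(aln)), "")[[1]]
  ps <- strsplit(as.character(Biostrings::alignedSubject(aln)), "")[[1]]
  ia <- 0L; ib <- 0L
  idx_a <- integer(0); idx_b <- integer(0)
  for (k in seq_along(pa)) {
    if (pa[k] != "-") ia <- ia + 1L
    if (ps[k] != "-") ib <- ib + 1L
    if (pa[k] != "-" && ps[k] != "-" && pa[k] == ps[k]) {
      idx_a <- c(idx_a, ia); idx_b <- c(idx_b, ib)
    }
  }
  tibble::tibble(idx_a = idx_a, idx_b = idx_b)
}

identity_substitution_matrix <- function() {
  letters24 <- c(LETTERS, "*")
  m <- matrix(-1, length(letters24), length(letters24),
              dimnames = list(letters24, letters24))
  diag(m) <- 2
  m
}

#' Paired coordinate matrices for a residue correspondence
#'
#' @param corr A `residue_correspondence`.
#' @param a,b The `ca_trace` tibbles it was computed from.
#' @return List with N x 3 matrices `a` and `b`.
#' @export
paired_coords <- function(corr, a, b) {
  list(a = as_coord_matrix(a[corr$idx_a, c("x", "y", "z")]),
       b = as_coord_matrix(b[corr$idx_b, c("x", "y", "z")]))
}
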