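#' Molecular weight
#'
#' Sum of standard (IUPAC 2021) atomic weights over all atoms including
#' implicit hydrogens.
#'
#' @param m A `molgraph`.
#' @return Molecular weight in g/mol.
#' @export
mol_weight <- function(m) {
  el <- normalize_element(m$atoms$element)
  w <- atomic_weights()[el]
  if (anyNA(w)) {
    stop("unknown element: ",
         paste(unique(m$atoms$element[is.na(w)]), collapse = ", "),
         call. = FALSE)
  }
  sum(w) + sum(m$atoms$n_h[el != "H"]) * atomic_weights()[["H"]]
}

atomic_weights <- function() {
  c(H = 1.008, B = 10.81, C = 12.011, N = 14.007, O = 15.999,
    F = 18.998403, Na = 22.98977, Mg = 24.305, Si = 28.085, P = 30.973762,
    S = 32.06, Cl = 35.45, K = 39.0983, Ca = 40.078, Fe = 55.845,
    Zn = 65.38, Se = 78.971, Br = 79.904, I = 126.90447)
}

normalize_element <- function(el) {
  paste0(toupper(substr(el, 1, 1)), tolower(substring(el, 2)))
}

#' Hydrogen-bond donor and acceptor counts (Lipinski convention)
#'
#' Donors are nitrogen or oxygen atoms bearing at least one hydrogen (the
#' donor heavy atom is counted, not its hydrogens); acceptors are all
#' nitrogen and oxygen atoms.
#'
#' @param m A `molgraph`.
#' @return Named list with `hbd` and `hba`.
#' @export
hbond_counts <- function(m) {
  no <- m$atoms$element %in% c("N", "O")
  list(hbd = sum(no & m$atoms$n_h > 0), hba = sum(no))
}

#' Rotatable-bond count
#'
#' Counts single, non-ring bonds between two non-terminal heavy atoms,
#' excluding amide-like C-N bonds: a C-N single bond is not rotatable when
#' the carbon carries a double bond to oxygen or nitrogen (amide, amidine,
#' guanidine), whose partial double-bond character hinders rotation.
#'
#' @param m A `molgraph`.
#' @return Integer count.
#' @export
rotatable_bonds <- function(m) {
  atoms <- m$atoms
  bonds <- m$bonds
  if (nrow(bonds) == 0) return(0L)
  heavy_deg <- heavy_degree(m)
  has_cx_double <- vapply(seq_len(nrow(atoms)), function(i) {
    if (atoms$element[i] != "C") return(FALSE)
    db <- bonds[(bonds$a1 == i | bonds$a2 == i) & bonds$order == 2, ]
    if (nrow(db) == 0) return(FALSE)
    other <- ifelse(db$a1 == i, db$a2, db$a1)
    any(atoms$element[other] %in% c("O", "N"))
  }, logical(1))

  rot <- vapply(seq_len(nrow(bonds)), function(i) {
    a <- bonds$a1[i]; b <- bonds$a2[i]
    if (bonds$order[i] != 1 || bonds$in_ring[i]) return(FALSE)
    if (atoms$element[a] == "H" || atoms$element[b] == "H") return(FALSE)
    if (heavy_deg[a] < 2 || heavy_deg[b] < 2) return(FALSE)
    # amide/amidine/guanidine C-N
    if ((atoms$element[a] == "N" && has_cx_double[b]) ||
        (atoms$element[b] == "N" && has_cx_double[a])) {
      return(FALSE)
    }
    TRUE
  }, logical(1))
  sum(rot)
}

heavy_degree <- function(m) {
  deg <- integer(nrow(m$atoms))
  for (i in seq_len(nrow(m$bonds))) {
    a <- m$bonds$a1[i]; b <- m$bonds$a2[i]
    if (m$atoms$element[b] != "H") deg[a] <- deg[a] + 1L
    if (m$atoms$element[a] != "H") deg[b] <- deg[b] + 1L
  }
  deg
}

#' Topological polar surface area (Ertl fragment contributions)
#'
#' Sums the published fragment contributions of nitrogen and oxygen
#' environments (the original N/O parameterization; sulfur and phosphorus
#' contribute zero under this convention). Every N/O atom must match an
#' environment of the contribution table, otherwise an error names the
#' unmatched environment.
#'
#' @param m A `molgraph`.
#' @return TPSA in squared Angstrom.
#' @export
tpsa <- function(m) {
  atoms <- m$atoms
  total <- 0
  for (i in seq_len(nrow(atoms))) {
    if (!atoms$element[i] %in% c("N", "O")) next
    sig <- tpsa_signature(m, i)
    contrib <- ertl_contributions()[[sig]]
    if (is.null(contrib)) {
      stop("no TPSA contribution for ", atoms$element[i],
           " environment '", sig, "'", call. = FALSE)
    }
    total <- total + contrib
  }
  total
}

# environment key: element | charge | nH | in3ring | n_single:n_double:
# n_triple:n_aromatic (heavy-atom bonds; aromatic perception overrides the
# Kekule orders inside aromatic rings)
tpsa_signature <- function(m, i) {
  atoms <- m$atoms; bonds <- m$bonds
  inc <- bonds[bonds$a1 == i | bonds$a2 == i, ]
  if (nrow(inc) > 0) {
    other <- ifelse(inc$a1 == i, inc$a2, inc$a1)
    keep <- atoms$element[other] != "H"
    inc <- inc[keep, ]
  }
  n_ar <- sum(inc$aromatic)
  n_s <- sum(!inc$aromatic & inc$order == 1)
  n_d <- sum(!inc$aromatic & inc$order == 2)
  n_t <- sum(!inc$aromatic & inc$order == 3)
  in3 <- atoms$in_ring[i] && in_three_ring(m, i)
  paste(atoms$element[i], atoms$charge[i], atoms$n_h[i],
        as.integer(in3), paste(n_s, n_d, n_t, n_ar, sep = ":"),
        sep = "|")
}

in_three_ring <- function(m, i) {
  bonds <- m$bonds[m$bonds$in_ring, ]
  nb <- unique(c(bonds$a2[bonds$a1 == i], bonds$a1[bonds$a2 == i]))
  for (a in nb) {
    for (b in nb) {
      if (a < b && any((bonds$a1 == a & bonds$a2 == b) |
                       (bonds$a1 == b & bonds$a2 == a))) {
        return(TRUE)
      }
    }
  }
  FALSE
}

# Ertl, Rohde & Selzer (2000) N/O fragment contributions, keyed as in
# tpsa_signature(): element | charge | nH | in 3-ring | s:d:t:aromatic
ertl_contributions <- function() {
  list(
    # --- nitrogen, neutral ---
    "N|0|0|0|3:0:0:0" = 3.24,   # N(-*)(-*)-*
    "N|0|0|0|1:1:0:0" = 12.36,  # N(-*)=*
    "N|0|0|0|0:0:1:0" = 23.79,  # N#*
    "N|0|0|0|1:2:0:0" = 11.68,  # N(-*)(=*)=* (azide-like)
    "N|0|0|0|0:1:1:0" = 13.60,  # N(=*)#*
    "N|0|0|1|3:0:0:0" = 3.01,   # aziridine N
    "N|0|1|0|2:0:0:0" = 12.03,  # NH(-*)-*
    "N|0|1|1|2:0:0:0" = 21.94,  # aziridine NH
    "N|0|1|0|0:1:0:0" = 23.85,  # NH=*
    "N|0|2|0|1:0:0:0" = 26.02,  # NH2-*
    # --- nitrogen, charged ---
    "N|1|0|0|4:0:0:0" = 0.00,
    "N|1|0|0|2:1:0:0" = 3.01,
    "N|1|0|0|1:0:1:0" = 4.36,
    "N|1|1|0|3:0:0:0" = 4.44,
    "N|1|1|0|1:1:0:0" = 13.97,
    "N|1|2|0|2:0:0:0" = 16.61,
    "N|1|2|0|0:1:0:0" = 25.59,
    "N|1|3|0|1:0:0:0" = 27.64,
    # --- nitrogen, aromatic ---
    "N|0|0|0|0:0:0:2" = 12.89,  # pyridine n
    "N|0|0|0|0:0:0:3" = 4.41,   # fused bridgehead n
    "N|0|0|0|1:0:0:2" = 4.93,   # substituted pyrrole-type n
    "N|0|0|0|0:1:0:2" = 8.39,   # n with exocyclic double bond
    "N|0|1|0|0:0:0:2" = 15.79,  # pyrrole nH
    "N|1|0|0|0:0:0:3" = 4.10,
    "N|1|0|0|1:0:0:2" = 3.88,
    "N|1|1|0|0:0:0:2" = 14.14,
    # --- oxygen ---
    "O|0|0|0|2:0:0:0" = 9.23,   # ether
    "O|0|0|1|2:0:0:0" = 12.53,  # oxirane
    "O|0|0|0|0:1:0:0" = 17.07,  # carbonyl / =O
    "O|0|1|0|1:0:0:0" = 20.23,  # hydroxyl
    "O|-1|0|0|1:0:0:0" = 23.06, # oxyanion
    "O|0|0|0|0:0:0:2" = 13.14   # aromatic o
  )
}

#' Drug-likeness profile with Lipinski and Veber verdicts
#'
#' Computes the standard oral drug-likeness panel: molecular weight, logP
#' (method recorded in the output), hydrogen-bond donors and acceptors
#' (Lipinski convention), rotatable bonds, and Ertl TPSA. The Lipinski
#' verdict requires MW <= 500, logP <= 5, HBD <= 5 and HBA <= 10; the Veber
#' verdict requires rotatable bonds <= 10 and TPSA <= 140.
#'
#' @param m A `molgraph`.
#' @param logp_method `"crippen"` (Wildman-Crippen atomic contributions,
#'   default), `"openbabel"` (OpenBabel's logP through ChemmineOB; requires
#'   the original SMILES/SDF source), or `"none"` (logP reported as NA and
#'   treated as passing the Lipinski logP criterion).
#' @return One-row tibble of class `druglikeness_profile`: `formula`,
#'   `mw`, `logp`, `logp_method`, `hbd`, `hba`, `rotatable_bonds`, `tpsa`,
#'   `lipinski_pass`, `veber_pass`.
#' @export
druglikeness <- function(m, logp_method = c("crippen", "openbabel", "none")) {
  logp_method <- match.arg(logp_method)
  lp <- switch(logp_method,
    crippen = crippen_logp(m),
    openbabel = openbabel_logp(m),
    none = NA_real_
  )
  hb <- hbond_counts(m)
  mw <- mol_weight(m)
  rb <- rotatable_bonds(m)
  ps <- tpsa(m)
  out <- tibble::tibble(
    formula = molecular_formula(m),
    mw = mw,
    logp = lp,
    logp_method = logp_method,
    hbd = hb$hbd,
    hba = hb$hba,
    rotatable_bonds = rb,
    tpsa = ps,
    lipinski_pass = mw <= 500 & (is.na(lp) | lp <= 5) & hb$hbd <= 5 &
      hb$hba <= 10,
    veber_pass = rb <= 10 & ps <= 140
  )
  structure(out, class = c("druglikeness_profile", class(out)))
}

#' @export
print.druglikeness_profile <- function(x, ...) {
  cat(sprintf(
    paste0("<druglikeness> %s  MW %.2f g/mol  logP %.2f (%s)  HBD %d  ",
           "HBA %d  RotB %d  TPSA %.2f A^2\n  Lipinski: %s   Veber: %s\n"),
    x$formula, x$mw, x$logp, x$logp_method, x$hbd, x$hba,
    x$rotatable_bonds, x$tpsa,
    ifelse(x$lipinski_pass, "pass", "FAIL"),
    ifelse(x$veber_pass, "pass", "FAIL")))
  invisible(x)
}
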