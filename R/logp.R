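#' Crippen logP (Wildman-Crippen atomic contributions)
#'
#' Octanol/water partition coefficient estimated with the Wildman & Crippen
#' (1999) atomic contribution scheme: every atom (including hydrogens) is
#' assigned to one of the published atom classes from its element,
#' aromaticity, hybridization and neighbourhood, and the class contributions
#' are summed. The typing covers the classes occurring in ordinary organic
#' drug-like molecules (C, H, N, O, S, P, halogens); an atom that fits no
#' class falls back to its element's published generic class.
#'
#' @param m A `molgraph`.
#' @return logP estimate (dimensionless).
#' @seealso [druglikeness()]
#' @export
crippen_logp <- function(m) {
  sum(crippen_contributions(m)$contribution)
}

#' Per-atom Crippen contributions
#'
#' @param m A `molgraph`.
#' @return Tibble with `idx`, `element`, `type`, `contribution`,
#'   `h_contribution` (contribution of the attached hydrogens).
#' @export
crippen_contributions <- function(m) {
  vals <- crippen_values()
  types <- vapply(seq_len(nrow(m$atoms)), function(i) crippen_type(m, i), "")
  hc <- vapply(seq_len(nrow(m$atoms)), function(i) {
    n_h <- m$atoms$n_h[i]
    if (n_h == 0) return(0)
    n_h * vals[[crippen_h_type(m, i)]]
  }, numeric(1))
  tibble::tibble(
    idx = m$atoms$idx,
    element = m$atoms$element,
    type = types,
    contribution = unname(unlist(vals[types])),
    h_contribution = hc
  ) |>
    dplyr::mutate(contribution = .data$contribution + .data$h_contribution)
}

crippen_values <- function() {
  list(
    C1 = 0.1441, C2 = 0.0000, C3 = -0.2035, C4 = -0.2051, C5 = -0.2783,
    C6 = 0.1551, C7 = 0.0017, C8 = 0.08452, C9 = -0.1444, C10 = -0.0516,
    C11 = 0.1193, C12 = -0.0967, C13 = -0.5443, C14 = 0.0000, C15 = 0.2450,
    C16 = 0.1980, C17 = 0.0000, C18 = 0.1581, C19 = 0.2955, C20 = 0.2713,
    C21 = 0.1360, C22 = 0.4619, C23 = 0.5437, C24 = 0.1893, C25 = -0.8186,
    C26 = 0.2640, C27 = 0.2148, CS = 0.08129,
    H1 = 0.1230, H2 = -0.2677, H3 = 0.2142, H4 = 0.2980, HS = 0.1125,
    N1 = -1.0190, N2 = -0.7096, N3 = -1.0270, N4 = -0.5188, N5 = 0.08387,
    N6 = 0.1836, N7 = -0.3187, N8 = -0.4458, N9 = 0.01508, N10 = -1.9500,
    N11 = -0.3239, N12 = -1.1190, N13 = -0.3396, N14 = 0.2887,
    NS = -0.4806,
    O1 = 0.1552, O2 = -0.2893, O3 = -0.0684, O4 = -0.4195, O5 = 0.0335,
    O6 = -0.3339, O7 = -1.1890, O8 = 0.1788, O9 = -0.1526, O10 = 0.1129,
    O11 = 0.4833, O12 = -1.3260, OS = -0.1188,
    F1 = 0.4202, Cl1 = 0.6895, Br1 = 0.8456, I1 = 0.8857, Hal = -2.9960,
    P1 = 0.8612,
    S1 = 0.6482, S2 = -0.0024, S3 = 0.6237,
    Me1 = -0.3808, Me2 = -0.0025
  )
}

# neighbourhood summary used by the typing rules
crippen_env <- function(m, i) {
  atoms <- m$atoms; bonds <- m$bonds
  inc <- bonds[bonds$a1 == i | bonds$a2 == i, , drop = FALSE]
  other <- integer(0)
  if (nrow(inc) > 0) other <- ifelse(inc$a1 == i, inc$a2, inc$a1)
  keep <- atoms$element[other] != "H"
  inc <- inc[keep, , drop = FALSE]
  other <- other[keep]
  list(
    el = atoms$element[i],
    charge = atoms$charge[i],
    n_h = atoms$n_h[i],
    aromatic = atoms$aromatic[i],
    nb_el = atoms$element[other],
    nb_aromatic = atoms$aromatic[other],
    order = inc$order,
    bond_aromatic = inc$aromatic,
    other = other
  )
}

crippen_type <- function(m, i) {
  e <- crippen_env(m, i)
  switch(e$el,
    C = crippen_type_c(m, i, e),
    N = crippen_type_n(m, i, e),
    O = crippen_type_o(m, i, e),
    H = crippen_h_type(m, i),
    F = "F1", Cl = "Cl1", CL = "Cl1", Br = "Br1", BR = "Br1", I = "I1",
    P = "P1",
    S = crippen_type_s(e),
    Si = "Me1", SI = "Me1", B = "Me1",
    "Me2"
  )
}

crippen_type_c <- function(m, i, e) {
  hetero <- !e$nb_el %in% c("C", "H")
  if (e$aromatic) {
    if (e$n_h > 0) return("C18")
    sub <- which(!e$bond_aromatic)
    ring_nb <- which(e$bond_aromatic)
    if (length(sub) == 0) return("C19")           # aromatic bridgehead
    if (any(e$order[sub] >= 2)) return("C25")     # exocyclic double bond
    sel <- e$nb_el[sub[1]]
    if (e$nb_aromatic[sub[1]]) return("C20")      # biaryl link
    return(switch(sel,
      C = "C21", N = "C22", O = "C23", S = "C24",
      F = "C14", Cl = "C15", CL = "C15", Br = "C16", BR = "C16",
      I = "C17", "C13"))
  }
  if (any(e$order == 3)) return("C7")
  if (any(e$order == 2)) {
    dbl_nb <- e$nb_el[e$order == 2]
    if (any(dbl_nb %in% c("N", "O", "S", "P"))) return("C5")
    if (any(e$nb_aromatic)) return("C26")
    return("C6")
  }
  # sp3
  if (any(e$nb_aromatic)) {
    nb_c <- e$nb_el[e$nb_aromatic][1] == "C"
    if (e$n_h >= 3) return(if (nb_c) "C8" else "C9")
    if (e$n_h == 2) return("C10")
    if (e$n_h == 1) return("C11")
    return("C12")
  }
  if (any(hetero)) {
    if (e$n_h >= 2) return("C3")
    return("C4")
  }
  if (e$n_h >= 2) return("C1")
  "C2"
}

crippen_type_n <- function(m, i, e) {
  if (e$aromatic) {
    if (e$charge > 0) return("N12")
    return("N11")
  }
  if (e$charge > 0) {
    if (any(e$order >= 2)) return("N13")   # iminium / nitro / nitrile-onium
    if (e$n_h == 0) return("N13")          # quaternary ammonium
    return("N10")                          # protonated amine
  }
  if (e$charge < 0) return("N14")
  if (any(e$order == 3)) return("N9")      # nitrile
  if (any(e$order == 2)) {
    if (e$n_h >= 1) return("N5")           # imine NH=
    return("N6")                           # substituted imine =N-
  }
  if (e$n_h >= 2) {
    if (any(e$nb_aromatic)) return("N3")   # aniline-type NH2
    return("N1")
  }
  if (e$n_h == 1) {
    if (any(e$nb_aromatic)) return("N4")
    return("N2")
  }
  if (any(e$nb_aromatic)) return("N8")
  "N7"
}

crippen_type_o <- function(m, i, e) {
  if (e$aromatic) return("O1")
  if (e$charge < 0) {
    # carboxylate / phosphate / nitro oxygens
    att <- e$other[1]
    if (length(att) == 1 && m$atoms$element[att] == "N") return("O5")
    return("O12")
  }
  if (e$n_h > 0) return("O2")              # hydroxyl (alcohol, acid, oxime)
  if (any(e$order == 2)) {
    att <- e$other[e$order == 2][1]
    ael <- m$atoms$element[att]
    if (ael == "N") return("O5")           # N-oxide / nitro oxygen
    if (ael %in% c("S", "P")) return("O6") # sulfoxide/sulfone/phosphoryl
    # carbonyl: aromatic-conjugated or aliphatic
    cnb <- crippen_env(m, att)
    if (any(cnb$nb_aromatic)) return("O10")
    return("O9")
  }
  if (any(e$nb_aromatic)) return("O4")     # aryl ether / phenol-ester O
  "O3"                                     # dialkyl ether
}

crippen_type_s <- function(e) {
  if (e$aromatic) return("S3")                       # thiophene-type s
  if (e$charge != 0 || any(e$order == 2)) return("S2")  # S=O / charged
  "S1"                                               # thiol / sulfide
}

crippen_h_type <- function(m, i) {
  el <- m$atoms$element[i]
  if (el == "H") return("H1")
  if (el %in% c("C", "SI", "Si", "B")) return("H1")
  if (el == "N") return("H3")
  if (el == "O") {
    e <- crippen_env(m, i)
    if (length(e$other) == 1) {
      att <- e$other[1]
      ael <- m$atoms$element[att]
      if (ael == "N") return("H3")                      # N-OH
      if (ael == "C") {
        cenv <- crippen_env(m, att)
        if (any(cenv$order == 2 & cenv$nb_el == "O")) {
          return("H4")                                  # carboxylic acid OH
        }
        if (cenv$aromatic) return("H2")                 # phenol OH
      }
      if (ael %in% c("O", "S", "P")) return("H4")       # peroxide, P-OH...
    }
    return("H2")                                        # alcohol / water
  }
  if (el == "S") return("H2")                           # thiol H
  "HS"
}

#' OpenBabel logP
#'
#' LogP as computed by OpenBabel's contribution model through
#' \pkg{ChemmineOB}. Requires the molecule's source to be re-parseable (the
#' `source` element of the `molgraph`).
#'
#' @param m A `molgraph`.
#' @return logP estimate.
#' @export
openbabel_logp <- function(m) {
  src <- m$source
  sdf <- if (grepl("\n", src) || file.exists(src)) {
    ChemmineR::read.SDFset(src)
  } else {
    ChemmineR::smiles2sdf(src)
  }
  props <- ChemmineR::propOB(sdf)
  as.numeric(props[["logP"]][1])
}
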