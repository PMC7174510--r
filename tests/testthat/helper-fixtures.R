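# shared fixtures and independent oracles

`%||%` <- function(a, b) if (is.null(a)) b else a

# 1A-116: N-(3,5-dimethylphenyl)-N'-(2-trifluoromethylphenyl)guanidine;
# tautomer with one =N-aryl, one N-H and one NH2 (verified through the
# descriptor panel: formula C16H16F3N3, MW 307.32, HBD 2, HBA 3, TPSA 50.41)
SMILES_1A116 <- "NC(=Nc1ccccc1C(F)(F)F)Nc1cc(C)cc(C)c1"

pdb_atom_line <- function(serial, name, res_name, chain, res_no, x, y, z,
                          occ = 1, altloc = " ", element = NULL,
                          record = "ATOM") {
  if (is.null(element)) element <- substr(name, 1, 1)
  sprintf("%-6s%5d %-4s%1s%3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
          record, serial,
          ifelse(nchar(name) < 4, paste0(" ", name), name),
          altloc, res_name, chain, res_no, x, y, z, occ, 0, element)
}

# small alanine-like zig-zag chain (non-collinear) as raw PDB text
tiny_chain_pdb <- function(n = 3, chain = "A", ca_only = TRUE) {
  lines <- character(0)
  s <- 0
  for (i in seq_len(n)) {
    s <- s + 1
    lines <- c(lines, pdb_atom_line(s, "CA", "ALA", chain, i,
                                    3.5 * i, 1.5 * (i %% 2), 1.1 * (i %% 3),
                                    element = "C"))
    if (!ca_only) {
      s <- s + 1
      lines <- c(lines, pdb_atom_line(s, "O", "ALA", chain, i,
                                      3.5 * i, 1.5 * (i %% 2) + 1.2,
                                      1.1 * (i %% 3), element = "O"))
    }
  }
  paste(c(lines, "END"), collapse = "\n")
}

# independent rotational-search oracle for the minimal RMSD of b onto a:
# multi-start quasi-Newton over the axis-angle parametrization, after
# removing the centroids (optimal translation is centroid matching)
oracle_min_rmsd <- function(a, b, n_starts = 12) {
  ac <- sweep(a, 2, colMeans(a))
  bc <- sweep(b, 2, colMeans(b))
  rot_from_axis_angle <- function(p) {
    theta <- sqrt(sum(p^2))
    if (theta < 1e-12) return(diag(3))
    k <- p / theta
    kx <- matrix(c(0, -k[3], k[2], k[3], 0, -k[1], -k[2], k[1], 0),
                 3, 3, byrow = TRUE)
    diag(3) + sin(theta) * kx + (1 - cos(theta)) * (kx %*% kx)
  }
  obj <- function(p) {
    r <- rot_from_axis_angle(p)
    sqrt(mean(rowSums((ac - bc %*% t(r))^2)))
  }
  starts <- rbind(
    c(0, 0, 0),
    matrix(stats::runif(3 * (n_starts - 1), -pi, pi), ncol = 3)
  )
  best <- Inf
  for (i in seq_len(nrow(starts))) {
    res <- stats::optim(starts[i, ], obj, method = "BFGS",
                        control = list(maxit = 500, reltol = 1e-14))
    best <- min(best, res$value)
  }
  best
}

# streaming (Welford) mean and sample SD, independent of stats::sd
welford <- function(x) {
  n <- 0; mean <- 0; m2 <- 0
  for (v in x) {
    n <- n + 1
    delta <- v - mean
    mean <- mean + delta / n
    m2 <- m2 + delta * (v - mean)
  }
  list(mean = mean, sd = if (n > 1) sqrt(m2 / (n - 1)) else NA_real_, n = n)
}

# compact rigid ligand used for docking tests (roughly tetrahedral, ~2 A)
compact_ligand <- function() {
  new_ligand_pose(tibble::tibble(
    atom_name = c("C1", "C2", "C3", "N1", "O1"),
    element = c("C", "C", "C", "N", "O"),
    x = c(0, 1.5, -0.7, -0.7, 0.8),
    y = c(0, 0, 1.3, -1.3, 0.9),
    z = c(0, 0, 0.3, 0.3, -1.1)
  ), pose_id = "compact")
}

# brute-force scorer independent of mock_score: double loop over pairs
brute_force_score <- function(lig_coords, prot_coords) {
  e <- 0
  for (i in seq_len(nrow(lig_coords))) {
    for (j in seq_len(nrow(prot_coords))) {
      d <- sqrt(sum((lig_coords[i, ] - prot_coords[j, ])^2))
      if (d < 2) e <- e + 10 else if (d <= 4) e <- e - 0.1
    }
  }
  e
}

random_rigid_transform <- function() {
  rot <- confdock:::random_rotation()
  shift <- stats::runif(3, -10, 10)
  function(x) sweep(x %*% t(rot), 2, shift, `+`)
}
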