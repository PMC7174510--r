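#' Pairwise C-alpha RMSD matrix of a conformer ensemble
#'
#' For every unordered pair of conformers, maps the common residues, performs
#' a Kabsch superposition on their shared C-alphas and records the minimized
#' RMSD. Each pair is superposed on its own common-residue set, so entries of
#' the matrix may rest on slightly different atom counts; the counts are kept
#' in the `n_common` attribute.
#'
#' @param traces A named list of `ca_trace` tibbles (names become conformer
#'   ids; unnamed lists fall back to the traces' own `id` attributes).
#' @return A symmetric matrix of class `rmsd_matrix` with zero diagonal,
#'   conformer ids as dimnames, and an `n_common` attribute (matrix of paired
#'   C-alpha counts).
#' @export
pairwise_rmsd <- function(traces) {
  if (length(traces) < 2) stop("need at least 2 conformers", call. = FALSE)
  ids <- names(traces)
  if (is.null(ids)) {
    ids <- vapply(traces, function(t) attr(t, "id") %||% "", "")
  }
  if (any(ids == "") || anyDuplicated(ids)) {
    stop("conformers must carry unique ids", call. = FALSE)
  }
  n <- length(traces)
  m <- matrix(0, n, n, dimnames = list(ids, ids))
  nc <- matrix(NA_integer_, n, n, dimnames = list(ids, ids))
  for (i in seq_len(n - 1)) {
    for (j in seq((i + 1), n)) {
      corr <- tryCatch(
        map_common_residues(traces[[i]], traces[[j]]),
        error = function(e) {
          stop("no common residues between '", ids[i], "' and '", ids[j],
               "'", call. = FALSE)
        }
      )
      pc <- paired_coords(corr, traces[[i]], traces[[j]])
      sup <- kabsch_superpose(pc$a, pc$b)
      m[i, j] <- m[j, i] <- sup$rmsd
      nc[i, j] <- nc[j, i] <- sup$n_atoms
    }
  }
  structure(m, n_common = nc, class = c("rmsd_matrix", "matrix", "array"))
}

#' @export
print.rmsd_matrix <- function(x, ...) {
  cat("<rmsd_matrix> pairwise C-alpha RMSD (Angstrom),",
      nrow(x), "conformers\n")
  m <- unclass(x)
  attr(m, "n_common") <- NULL
  print(round(m, 3), ...)
  invisible(x)
}

#' @export
tidy.rmsd_matrix <- function(x, ...) {
  ids <- rownames(x)
  ut <- which(upper.tri(x), arr.ind = TRUE)
  tibble::tibble(
    conformer_a = ids[ut[, 1]],
    conformer_b = ids[ut[, 2]],
    rmsd = x[ut],
    n_common = attr(x, "n_common")[ut]
  )
}

#' Maximum-diversity conformer pair
#'
#' Arg-max over the strict upper triangle of a pairwise RMSD matrix. Ties are
#' broken lexicographically by the ordered id pair (deterministic), with a
#' warning when the maximum is not unique.
#'
#' @param m An `rmsd_matrix`.
#' @return One-row tibble with `conformer_a`, `conformer_b`, `rmsd`.
#' @export
max_diversity_pair <- function(m) {
  long <- tidy.rmsd_matrix(m) |>
    dplyr::arrange(.data$conformer_a, .data$conformer_b)
  top <- max(long$rmsd)
  hits <- dplyr::filter(long, .data$rmsd == top)
  if (nrow(hits) > 1) {
    warning("maximum RMSD is tied between ", nrow(hits),
            " pairs; returning the lexicographically first", call. = FALSE)
  }
  hits[1, c("conformer_a", "conformer_b", "rmsd")]
}

#' Per-residue displacement Z-score profile of a conformer pair
#'
#' After one global Kabsch superposition over all common C-alphas, the
#' displacement of residue i is the distance between its C-alpha in conformer
#' a and its transformed C-alpha in conformer b. Displacements are
#' standardized to Z-scores with the population standard deviation (the
#' profile is a descriptive standardization of a fixed residue set, not a
#' sample estimate), so `mean(z) = 0` and `sd_pop(z) = 1`. Residues with
#' `z < 0` move less than the average residue of the pair — a relatively
#' rigid region.
#'
#' @param a,b `ca_trace` tibbles of the two conformers.
#' @return A tibble of class `zscore_profile` with columns `res_number`,
#'   `res_name`, `displacement` (Angstrom) and `z`, plus attributes
#'   `mean_displacement`, `sd_displacement` (population), `rmsd`,
#'   `conformer_a`, `conformer_b`.
#' @export
zscore_profile <- function(a, b) {
  corr <- map_common_residues(a, b)
  pc <- paired_coords(corr, a, b)
  sup <- kabsch_superpose(pc$a, pc$b)
  b_fit <- apply_superposition(sup, pc$b)
  d <- sqrt(rowSums((pc$a - b_fit)^2))
  mu <- mean(d)
  sigma <- sd_pop(d)
  if (sigma <= 1e-9 * (1 + mu)) {   # all displacements (numerically) equal
    warning("all per-residue displacements equal; Z-scores set to 0",
            call. = FALSE)
    sigma <- 0
    z <- rep(0, length(d))
  } else {
    z <- (d - mu) / sigma
  }
  out <- tibble::tibble(
    res_number = corr$res_number_a,
    res_name = corr$res_name,
    displacement = d,
    z = z
  )
  structure(out,
            mean_displacement = mu, sd_displacement = sigma,
            rmsd = sup$rmsd,
            conformer_a = attr(a, "id"), conformer_b = attr(b, "id"),
            class = c("zscore_profile", class(tibble::tibble())))
}

sd_pop <- function(x) sqrt(mean((x - mean(x))^2))

#' @export
glance.zscore_profile <- function(x, ...) {
  tibble::tibble(
    n_residues = nrow(x),
    mean_displacement = attr(x, "mean_displacement"),
    sd_displacement = attr(x, "sd_displacement"),
    rmsd = attr(x, "rmsd"),
    conformer_a = attr(x, "conformer_a") %||% NA_character_,
    conformer_b = attr(x, "conformer_b") %||% NA_character_
  )
}

#' Binding-site flexibility verdict from a Z-score profile
#'
#' Reports the Z-score of each site residue and the fraction of site residues
#' with `z < 0`. The verdict is `"low-mobility site"` only when every site
#' residue lies below the average mobility of the pair (fraction = 1);
#' otherwise `"mixed or mobile site"`.
#'
#' @param profile A `zscore_profile`.
#' @param site Integer vector of author residue numbers (e.g. the residues in
#'   close contact with a bound ligand).
#' @return A tibble of class `site_flexibility` with one row per site residue
#'   found in the profile, and attributes `fraction_below_zero`, `verdict`,
#'   `missing` (site residues absent from the profile).
#' @export
site_flexibility <- function(profile, site) {
  if (length(site) == 0) stop("site residue set is empty", call. = FALSE)
  site <- unique(as.integer(site))
  rows <- dplyr::filter(profile, .data$res_number %in% site)
  missing <- setdiff(site, rows$res_number)
  if (length(missing) > 0) {
    warning("site residues not in profile: ",
            paste(missing, collapse = ", "), call. = FALSE)
  }
  if (nrow(rows) == 0) stop("no site residues present in profile",
                            call. = FALSE)
  frac <- mean(rows$z < 0)
  verdict <- if (frac == 1) "low-mobility site" else "mixed or mobile site"
  structure(
    tibble::as_tibble(rows[, c("res_number", "res_name", "displacement", "z")]),
    fraction_below_zero = frac, verdict = verdict, missing = missing,
    class = c("site_flexibility", class(tibble::tibble()))
  )
}

#' @export
print.site_flexibility <- function(x, ...) {
  cat("<site_flexibility> fraction z<0:",
      format(attr(x, "fraction_below_zero"), digits = 3),
      "->", attr(x, "verdict"), "\n")
  NextMethod()
}

#' @export
glance.site_flexibility <- function(x, ...) {
  tibble::tibble(
    n_site = nrow(x),
    fraction_below_zero = attr(x, "fraction_below_zero"),
    verdict = attr(x, "verdict"),
    n_missing = length(attr(x, "missing"))
  )
}
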