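# Geometry agreement between levels of theory: optimal-superposition
# (Kabsch) RMSD, RMSDs over stripped substructures, forming-bond
# distance differences, and close vdW contact detection.

#' Minimal RMSD after optimal superposition (Kabsch)
#'
#' Translates both structures' selected atoms to their centroids,
#' factorizes the cross-covariance by SVD, corrects for reflections,
#' and returns the RMSD under the optimal proper rotation. Atom
#' correspondence is positional over `atom_subset`.
#'
#' @param A,B [qc_structure()]s with identical element sequence on the
#'   subset
#' @param atom_subset indices to superpose (default: all atoms)
#' @return minimal RMSD, Angstrom. Degenerate (collinear) subsets are
#'   solved but flagged with a warning.
#' @export
kabsch_rmsd <- function(A, B, atom_subset = seq_len(n_atoms(A))) {
  if (length(atom_subset) < 3L) {
    stop("need at least 3 atoms for a unique superposition")
  }
  if (!identical(A$elements[atom_subset], B$elements[atom_subset])) {
    stop("element sequences differ on the selected subset")
  }
  P <- A$coords[atom_subset, , drop = FALSE]
  Q <- B$coords[atom_subset, , drop = FALSE]
  P <- sweep(P, 2, colMeans(P))
  Q <- sweep(Q, 2, colMeans(Q))
  H <- crossprod(P, Q)
  sv <- svd(H)
  if (sv$d[2] < 1e-10 * max(sv$d[1], 1e-300)) {
    warning("nearly collinear atom subset; rotation is ill-conditioned")
  }
  d <- sign(det(sv$v %*% t(sv$u)))
  D <- diag(c(1, 1, d))
  R <- sv$v %*% D %*% t(sv$u)
  diff <- Q - P %*% t(R)
  sqrt(sum(diff^2) / length(atom_subset))
}

# nucleophile membership in a TS: the connected component containing the
# nucleophile carbon (the forming C-C bond is too long to be perceived)
.nucleophile_atoms <- function(structure, nu_c) {
  bonds <- perceive_bonds(structure)
  .reachable(bonds, nu_c, blocked = integer(0))
}

# R-group membership: atoms reachable from each attachment atom without
# crossing the core
.rgroup_atoms <- function(structure, key_atoms) {
  bonds <- perceive_bonds(structure)
  sort(unique(unlist(lapply(key_atoms$attach, function(a) {
    .reachable(bonds, a, blocked = key_atoms$core)
  }))))
}

#' RMSD between two levels' geometries over a stripped substructure
#'
#' Modes: `full` (all atoms), `no_nucleophile` (TS atoms minus the
#' nucleophile fragment), `no_rgroups` (minus every R-group subtree),
#' `core_only` (the enone core atoms), and `ma_vs_ts` (the MA geometry
#' of level A against the TS geometry of level B with the nucleophile
#' removed). The retained subset is re-aligned on its own.
#'
#' @param reaction a [reaction_record()]
#' @param level_A,level_B level strings
#' @param mode one of `"full"`, `"no_nucleophile"`, `"no_rgroups"`,
#'   `"core_only"`, `"ma_vs_ts"`
#' @param include_h include hydrogens (default TRUE)
#' @return RMSD, Angstrom
#' @export
stripped_rmsd <- function(reaction, level_A, level_B,
                          mode = c("full", "no_nucleophile", "no_rgroups",
                                   "core_only", "ma_vs_ts"),
                          include_h = TRUE) {
  mode <- match.arg(mode)
  ka <- reaction$key_atoms
  if (mode == "ma_vs_ts") {
    A <- get_record(reaction, level_A, "MA")$structure
    B <- get_record(reaction, level_B, "TS")$structure
    nu <- .nucleophile_atoms(B, ka$nu_c)
    keep_B <- setdiff(seq_len(n_atoms(B)), nu)
    # MA atoms are the TS minus nucleophile, in shared order
    if (length(keep_B) != n_atoms(A)) {
      stop("MA atom count does not match TS-minus-nucleophile subset")
    }
    sel_A <- seq_len(n_atoms(A))
    if (!include_h) {
      hmask <- A$elements[sel_A] != "H"
      sel_A <- sel_A[hmask]; keep_B <- keep_B[hmask]
    }
    if (length(sel_A) < 3L) stop("retained subset has fewer than 3 atoms")
    # reuse kabsch on a re-indexed copy of B
    Bsub <- qc_structure(B$elements[keep_B], B$coords[keep_B, , drop = FALSE],
                         role = B$role, net_charge = B$net_charge,
                         label = B$label)
    Asub <- qc_structure(A$elements[sel_A], A$coords[sel_A, , drop = FALSE],
                         role = A$role, net_charge = A$net_charge,
                         label = A$label)
    return(kabsch_rmsd(Asub, Bsub))
  }
  A <- get_record(reaction, level_A, "TS")$structure
  B <- get_record(reaction, level_B, "TS")$structure
  keep <- switch(mode,
    full = seq_len(n_atoms(A)),
    no_nucleophile = setdiff(seq_len(n_atoms(A)),
                             .nucleophile_atoms(A, ka$nu_c)),
    no_rgroups = setdiff(seq_len(n_atoms(A)), .rgroup_atoms(A, ka)),
    core_only = ka$core)
  if (!include_h) keep <- keep[A$elements[keep] != "H"]
  if (length(keep) < 3L) stop("retained subset has fewer than 3 atoms")
  kabsch_rmsd(A, B, atom_subset = keep)
}

#' Forming C-C bond distance difference between two levels
#'
#' Distances between the nucleophile carbon and the beta-carbon in each
#' level's TS, and the signed difference `d_B - d_A`.
#'
#' @param reaction a [reaction_record()]
#' @param level_A,level_B level strings
#' @return named numeric vector `c(d_A =, d_B =, delta =)`, Angstrom
#' @export
bond_forming_delta <- function(reaction, level_A, level_B) {
  ka <- reaction$key_atoms
  dist_at <- function(level) {
    s <- get_record(reaction, level, "TS")$structure
    sqrt(sum((s$coords[ka$nu_c, ] - s$coords[ka$beta_c, ])^2))
  }
  d_A <- dist_at(level_A)
  d_B <- dist_at(level_B)
  c(d_A = d_A, d_B = d_B, delta = d_B - d_A)
}

#' Close van der Waals contacts
#'
#' All non-bonded, non-geminal atom pairs matching the element filter
#' whose distance is below `factor` times the sum of their vdW radii
#' (e.g. factor 0.9 with Bondi carbons flags C-C pairs under 3.06 A).
#'
#' @param structure a [qc_structure()]
#' @param elements_filter length-2 character vector of element symbols,
#'   or NULL for all pairs
#' @param factor threshold factor in (0, 1]
#' @param bonds connectivity (for the bonded/geminal exclusion)
#' @return data frame with columns `i`, `j`, `distance`, `vdw_sum`,
#'   `ratio`; attribute `factor`
#' @export
vdw_contacts <- function(structure, elements_filter = c("C", "C"),
                         factor = 0.9, bonds = perceive_bonds(structure)) {
  if (factor <= 0 || factor > 1) stop("factor must be in (0, 1]")
  n <- n_atoms(structure)
  el <- structure$elements
  rv <- vdw_radius(el)
  d <- as.matrix(stats::dist(structure$coords))
  gd <- .graph_distances(bonds, n)
  out <- data.frame(i = integer(0), j = integer(0), distance = numeric(0),
                    vdw_sum = numeric(0), ratio = numeric(0))
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      if (!is.null(elements_filter)) {
        ok <- (el[i] == elements_filter[1] && el[j] == elements_filter[2]) ||
          (el[i] == elements_filter[2] && el[j] == elements_filter[1])
        if (!ok) next
      }
      if (is.finite(gd[i, j]) && gd[i, j] <= 2) next  # bonded or geminal
      vsum <- rv[i] + rv[j]
      if (d[i, j] < factor * vsum) {
        out <- rbind(out, data.frame(i = i, j = j, distance = d[i, j],
                                     vdw_sum = vsum,
                                     ratio = d[i, j] / vsum))
      }
    }
  }
  attr(out, "factor") <- factor
  out
}

#' Summarize RMSD / bond-distance distributions
#'
#' Means and fractions below thresholds for a set of per-reaction
#' geometry comparisons, plus histogram bin counts.
#'
#' @param rmsd numeric vector of RMSDs (Angstrom)
#' @param delta_d numeric vector of signed bond-forming distance
#'   differences (Angstrom); optional
#' @param rmsd_threshold RMSD success threshold (default 2)
#' @param delta_threshold absolute bond-distance threshold (default 0.3)
#' @param bin_width histogram bin width (default 0.1)
#' @return list with `mean_rmsd`, `frac_rmsd_below` (percent),
#'   `mean_delta_d`, `frac_delta_below` (percent), and histogram counts
#' @export
summarize_distributions <- function(rmsd, delta_d = NULL,
                                    rmsd_threshold = 2.0,
                                    delta_threshold = 0.3,
                                    bin_width = 0.1) {
  if (!length(rmsd)) stop("empty report list")
  breaks <- seq(0, max(rmsd, rmsd_threshold) + bin_width, by = bin_width)
  h <- graphics::hist(rmsd, breaks = breaks, plot = FALSE)
  out <- list(mean_rmsd = mean(rmsd),
              frac_rmsd_below = 100 * mean(rmsd < rmsd_threshold),
              rmsd_hist = list(breaks = h$breaks, counts = h$counts))
  if (!is.null(delta_d)) {
    out$mean_delta_d <- mean(delta_d)
    out$frac_delta_below <- 100 * mean(abs(delta_d) < delta_threshold)
  }
  out
}
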