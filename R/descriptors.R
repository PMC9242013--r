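# Interpretable physical-organic descriptors used as ML features:
# Gasteiger (PEOE) partial charges, Kier-Hall electrotopological state
# indices, Sterimol L/B1/B5, percent buried volume, and Shrake-Rupley
# solvent-accessible surface area. All geometric descriptors use the
# Bondi vdW radii from the constants table and deterministic point sets
# (no RNG), so results are bit-reproducible.

# ---- connectivity -----------------------------------------------------------

#' Perceive covalent bonds from interatomic distances
#'
#' Two atoms are bonded when their distance is below
#' `tolerance * (r_cov_i + r_cov_j)` (Cordero covalent radii).
#'
#' @param structure a [qc_structure()]
#' @param tolerance multiplicative slack on the covalent-radius sum
#' @return integer matrix with columns `i`, `j` (each row one bond,
#'   `i < j`) and attribute `n` (atom count)
#' @export
perceive_bonds <- function(structure, tolerance = 1.2) {
  n <- n_atoms(structure)
  rc <- covalent_radius(structure$elements)
  d <- as.matrix(stats::dist(structure$coords))
  thr <- outer(rc, rc, "+") * tolerance
  hit <- which(d < thr & upper.tri(d), arr.ind = TRUE)
  bonds <- matrix(as.integer(hit), ncol = 2)
  colnames(bonds) <- c("i", "j")
  attr(bonds, "n") <- n
  bonds
}

# adjacency list from a bond matrix
.adjacency <- function(bonds, n = attr(bonds, "n")) {
  adj <- vector("list", n)
  for (k in seq_len(nrow(bonds))) {
    i <- bonds[k, 1]; j <- bonds[k, 2]
    adj[[i]] <- c(adj[[i]], j)
    adj[[j]] <- c(adj[[j]], i)
  }
  adj
}

# BFS graph distances (number of bonds) from each atom; Inf if disconnected
.graph_distances <- function(bonds, n = attr(bonds, "n")) {
  adj <- .adjacency(bonds, n)
  d <- matrix(Inf, n, n)
  diag(d) <- 0
  for (s in seq_len(n)) {
    queue <- s
    while (length(queue)) {
      v <- queue[1]; queue <- queue[-1]
      for (w in adj[[v]]) {
        if (d[s, w] > d[s, v] + 1) {
          d[s, w] <- d[s, v] + 1
          queue <- c(queue, w)
        }
      }
    }
  }
  d
}

# atoms reachable from `start` without passing through any atom in `blocked`
.reachable <- function(bonds, start, blocked, n = attr(bonds, "n")) {
  adj <- .adjacency(bonds, n)
  seen <- rep(FALSE, n)
  seen[blocked] <- NA           # NA marks walls
  queue <- start
  out <- integer(0)
  while (length(queue)) {
    v <- queue[1]; queue <- queue[-1]
    if (!isFALSE(seen[v])) next
    seen[v] <- TRUE
    out <- c(out, v)
    queue <- c(queue, adj[[v]])
  }
  sort(out)
}

# ---- PEOE (Gasteiger-Marsili) charges --------------------------------------

# electronegativity polynomials chi(q) = a + b q + c q^2 per atom type
.peoe_params <- list(
  H      = c(7.17, 6.24, -0.56),
  C.sp3  = c(7.98, 9.18, 1.88),
  C.sp2  = c(8.79, 9.32, 1.51),
  C.sp   = c(10.39, 9.45, 0.73),
  N.sp3  = c(11.54, 10.82, 1.36),
  N.sp2  = c(12.87, 11.15, 0.85),
  N.sp   = c(15.68, 11.70, -0.27),
  O.sp3  = c(14.18, 12.92, 1.39),
  O.sp2  = c(17.07, 13.79, 0.47),
  F      = c(14.66, 13.85, 2.31),
  Cl     = c(11.00, 9.69, 1.35),
  Br     = c(10.08, 8.47, 1.16),
  I      = c(9.90, 7.96, 0.96),
  S      = c(10.14, 9.13, 1.38)
)

# degree-based hybridization assignment (heuristic, matches the common
# typing for the organic elements this pipeline sees)
.peoe_type <- function(elements, degree) {
  vapply(seq_along(elements), function(i) {
    el <- elements[i]; dg <- degree[i]
    switch(el,
      H = "H", F = "F", Cl = "Cl", Br = "Br", I = "I", S = "S",
      C = if (dg >= 4) "C.sp3" else if (dg == 3) "C.sp2" else "C.sp",
      N = if (dg >= 3) "N.sp3" else if (dg == 2) "N.sp2" else "N.sp",
      O = if (dg >= 2) "O.sp3" else "O.sp2",
      el)
  }, "")
}

#' Gasteiger (PEOE) partial charges
#'
#' Iterative partial equalization of orbital electronegativity: in
#' iteration k each bond transfers
#' `(chi_acceptor - chi_donor) / chi_plus(donor) * damping^k` electrons
#' from the less to the more electronegative atom, with `chi_plus` the
#' donor's cation electronegativity (20.02 for H). Net charge is
#' conserved exactly; initial charges default to formal charges when
#' supplied, else the net charge spread uniformly.
#'
#' @param structure a [qc_structure()]
#' @param bonds connectivity from [perceive_bonds()]
#' @param n_iter damped iterations (default 8)
#' @param damping geometric damping base (default 0.5)
#' @param formal_charges optional per-atom seed charges summing to the
#'   structure's net charge
#' @return numeric per-atom charges (e)
#' @export
peoe_charges <- function(structure, bonds = perceive_bonds(structure),
                         n_iter = 8L, damping = 0.5,
                         formal_charges = NULL) {
  n <- n_atoms(structure)
  degree <- tabulate(c(bonds[, 1], bonds[, 2]), nbins = n)
  types <- .peoe_type(structure$elements, degree)
  bad <- !types %in% names(.peoe_params)
  if (any(bad)) {
    stop("no PEOE parameters for element(s): ",
         paste(unique(structure$elements[bad]), collapse = ", "),
         call. = FALSE)
  }
  par <- do.call(rbind, .peoe_params[types])
  chi_plus <- rowSums(par)
  chi_plus[structure$elements == "H"] <- 20.02
  q <- if (is.null(formal_charges)) {
    rep(structure$net_charge / n, n)
  } else {
    if (abs(sum(formal_charges) - structure$net_charge) > 1e-8) {
      stop("formal charges must sum to the net charge")
    }
    as.numeric(formal_charges)
  }
  for (k in seq_len(n_iter)) {
    chi <- par[, 1] + par[, 2] * q + par[, 3] * q^2
    dq <- numeric(n)
    f <- damping^k
    for (b in seq_len(nrow(bonds))) {
      i <- bonds[b, 1]; j <- bonds[b, 2]
      if (chi[i] == chi[j]) next
      if (chi[j] > chi[i]) { don <- i; acc <- j } else { don <- j; acc <- i }
      t <- (chi[acc] - chi[don]) / chi_plus[don] * f
      dq[don] <- dq[don] + t
      dq[acc] <- dq[acc] - t
    }
    q <- q + dq
  }
  q
}

# ---- Kier-Hall EState indices ----------------------------------------------

.valence_electrons <- c(H = 1, B = 3, C = 4, N = 5, O = 6, F = 7,
                        Si = 4, P = 5, S = 6, Cl = 7, Br = 7, I = 7)
.principal_n <- c(H = 1, B = 2, C = 2, N = 2, O = 2, F = 2,
                  Si = 3, P = 3, S = 3, Cl = 3, Br = 4, I = 5)

#' Kier-Hall electrotopological state (EState) indices
#'
#' For each heavy atom the intrinsic state
#' `I = ((2/n)^2 * delta_v + 1) / delta` (n the principal quantum
#' number, `delta` the heavy-atom degree, `delta_v` the valence
#' connectivity) is perturbed by `sum_j (I_i - I_j) / d_ij^2` with
#' `d_ij` the topological distance in bonds plus one. Hydrogens enter
#' only through the hydrogen counts; their entries in the result are NA.
#' An isolated heavy atom (degree 0) falls back to its free-atom
#' intrinsic state (`delta := 1`) with a logged message.
#'
#' @param structure a [qc_structure()]
#' @param bonds connectivity from [perceive_bonds()]
#' @return numeric per-atom vector; NA for hydrogens
#' @export
estate_indices <- function(structure, bonds = perceive_bonds(structure)) {
  n <- n_atoms(structure)
  el <- structure$elements
  heavy <- which(el != "H")
  if (!length(heavy)) return(rep(NA_real_, n))
  adj <- .adjacency(bonds, n)
  h_count <- vapply(seq_len(n), function(i) sum(el[adj[[i]]] == "H"), 0)
  delta <- vapply(seq_len(n), function(i) sum(el[adj[[i]]] != "H"), 0)
  zv <- .valence_electrons[el]
  pn <- .principal_n[el]
  if (anyNA(zv) || anyNA(pn)) {
    stop("no EState parameters for element(s): ",
         paste(unique(el[is.na(zv) | is.na(pn)]), collapse = ", "))
  }
  delta_v <- zv - h_count
  # Kier-Hall higher-period scaling: (Zv - h)/(Z - Zv - 1)
  z_all <- c(H = 1, B = 5, C = 6, N = 7, O = 8, F = 9, Si = 14, P = 15,
             S = 16, Cl = 17, Br = 35, I = 53)[el]
  hi <- pn > 2
  delta_v[hi] <- (zv[hi] - h_count[hi]) / (z_all[hi] - zv[hi] - 1)
  dly <- delta
  iso <- heavy[delta[heavy] == 0]
  if (length(iso)) {
    message("estate_indices: isolated heavy atom(s) at index ",
            paste(iso, collapse = ", "), "; using free-atom intrinsic state")
    dly[iso] <- 1
  }
  I <- ((2 / pn)^2 * delta_v + 1) / dly
  # heavy-atom topological distances
  gd <- .graph_distances(bonds, n)
  S <- rep(NA_real_, n)
  for (i in heavy) {
    js <- setdiff(heavy, i)
    d <- gd[i, js] + 1
    ok <- is.finite(d)
    S[i] <- I[i] + sum((I[i] - I[js][ok]) / d[ok]^2)
  }
  S
}

# ---- Sterimol ---------------------------------------------------------------

#' Sterimol steric parameters L, B1, B5
#'
#' The substituent is every atom reachable from `sub_atom` without
#' crossing `attach_atom`. With the axis running from the attachment
#' atom through the substituent's first atom: `L` is the maximal extent
#' of the substituent vdW spheres along the axis (measured from the
#' attachment atom), `B5` the maximal perpendicular extent, and `B1`
#' the minimal perpendicular half-width over all rotations about the
#' axis (minimum of the support function of the projected spheres).
#'
#' @param structure a [qc_structure()]
#' @param attach_atom index of the atom the substituent hangs from
#' @param sub_atom index of the substituent's first atom
#' @param bonds connectivity (for the substituent traversal)
#' @param radii per-atom vdW radii; default Bondi
#' @param angle_step B1 rotational scan resolution, degrees
#' @return named numeric vector `c(L =, B1 =, B5 =)`, Angstrom
#' @export
sterimol <- function(structure, attach_atom, sub_atom,
                     bonds = perceive_bonds(structure),
                     radii = vdw_radius(structure$elements),
                     angle_step = 0.02) {
  p <- structure$coords
  axis <- p[sub_atom, ] - p[attach_atom, ]
  nrm <- sqrt(sum(axis^2))
  if (nrm < 1e-9) stop("attach->sub vector is zero")
  u <- axis / nrm
  sub_set <- .reachable(bonds, sub_atom, blocked = attach_atom)
  sub_set <- setdiff(sub_set, attach_atom)
  if (!length(sub_set)) stop("substituent atom set is empty")
  rel <- sweep(p[sub_set, , drop = FALSE], 2, p[attach_atom, ])
  r <- radii[sub_set]
  proj <- drop(rel %*% u)
  L <- max(proj + r)
  perp <- rel - outer(proj, u)
  # orthonormal basis of the perpendicular plane
  ref <- if (abs(u[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  e1 <- ref - sum(ref * u) * u; e1 <- e1 / sqrt(sum(e1^2))
  e2 <- c(u[2] * e1[3] - u[3] * e1[2],
          u[3] * e1[1] - u[1] * e1[3],
          u[1] * e1[2] - u[2] * e1[1])
  q <- cbind(drop(perp %*% e1), drop(perp %*% e2))
  B5 <- max(sqrt(rowSums(q^2)) + r)
  theta <- seq(0, 360 - angle_step, by = angle_step) * pi / 180
  dirs <- cbind(cos(theta), sin(theta))
  support <- dirs %*% t(q)                      # n_theta x n_atoms
  B1 <- min(apply(sweep(support, 2, r, "+"), 1, max))
  c(L = L, B1 = B1, B5 = B5)
}

# deterministic molecule-fixed rotation. Grid/point-set integrals
# (buried volume, SASA) are evaluated after rotating coordinates into a
# frame built from the molecule's own coordinate covariance, with signs
# fixed by the atom-index-weighted projections (intrinsic to the
# molecule, so the integrals are invariant under rigid motions of the
# input up to floating-point noise).
.canonical_rotation <- function(coords) {
  n <- nrow(coords)
  if (n < 2L) return(diag(3))
  X <- sweep(coords, 2, colMeans(coords))
  R <- eigen(crossprod(X) / n, symmetric = TRUE)$vectors
  s <- drop(crossprod(R, colSums(X * seq_len(n))))
  flip <- s < 0 & abs(s) > 1e-9
  R[, flip] <- -R[, flip]
  if (det(R) < 0) {
    k <- which.min(abs(s))
    R[, k] <- -R[, k]
  }
  R
}

# ---- percent buried volume --------------------------------------------------

# in-sphere integration grid, memoized (the same 3.5 A / 0.05 A grid is
# reused for every atom of every reaction)
.pbv_cache <- new.env(parent = emptyenv())
.pbv_grid <- function(R, grid_spacing) {
  key <- sprintf("%.6g_%.6g", R, grid_spacing)
  hit <- get0(key, envir = .pbv_cache)
  if (!is.null(hit)) return(hit)
  g <- seq(-R + grid_spacing / 2, R - grid_spacing / 2, by = grid_spacing)
  pts <- as.matrix(expand.grid(x = g, y = g, z = g))
  pts <- pts[rowSums(pts^2) <= R^2, , drop = FALSE]
  assign(key, pts, envir = .pbv_cache)
  pts
}

#' Percent buried volume
#'
#' Fraction (as a percentage) of a probe sphere of radius
#' `sphere_radius` centered on `center_atom` that lies inside the
#' scaled vdW spheres of the molecule's atoms, by deterministic uniform
#' grid integration.
#'
#' @param structure a [qc_structure()]
#' @param center_atom index of the sphere center atom
#' @param sphere_radius probe-sphere radius, Angstrom (default 3.5)
#' @param radii_scale vdW radius scale factor (default 1.17)
#' @param grid_spacing integration grid pitch, Angstrom (default 0.05)
#' @param radii per-atom vdW radii; default Bondi
#' @return buried volume, percent of the probe sphere
#' @export
percent_buried_volume <- function(structure, center_atom,
                                  sphere_radius = 3.5, radii_scale = 1.17,
                                  grid_spacing = 0.05,
                                  radii = vdw_radius(structure$elements)) {
  if (sphere_radius <= 0) stop("sphere_radius must be positive")
  center <- structure$coords[center_atom, ]
  R <- sphere_radius
  pts <- .pbv_grid(R, grid_spacing)
  covered <- rep(FALSE, nrow(pts))
  rs <- radii * radii_scale
  rel <- sweep(structure$coords, 2, center) %*%
    .canonical_rotation(structure$coords)
  keep <- sqrt(rowSums(rel^2)) <= R + rs       # atoms that can reach the sphere
  for (a in which(keep)) {
    d2 <- (pts[, 1] - rel[a, 1])^2 + (pts[, 2] - rel[a, 2])^2 +
      (pts[, 3] - rel[a, 3])^2
    covered <- covered | d2 <= rs[a]^2
  }
  100 * sum(covered) / nrow(pts)
}

# ---- SASA -------------------------------------------------------------------

# deterministic golden-spiral point set on the unit sphere
.golden_spiral <- function(n) {
  i <- seq_len(n) - 0.5
  phi <- acos(1 - 2 * i / n)
  theta <- pi * (1 + sqrt(5)) * i
  cbind(sin(phi) * cos(theta), sin(phi) * sin(theta), cos(phi))
}

#' Shrake-Rupley solvent-accessible surface area
#'
#' Each atom's sphere of radius `r_vdw + probe` is sampled with a
#' deterministic golden-spiral point set; points falling inside any
#' other atom's probe-inflated sphere are inaccessible. Per-atom areas
#' sum to the total.
#'
#' @param structure a [qc_structure()]
#' @param probe probe radius, Angstrom (default 1.4)
#' @param n_points sample points per atom (default 960; minimum 10)
#' @param radii per-atom vdW radii; default Bondi
#' @return list with `atom_area` (numeric vector, A^2) and `total`
#' @export
sasa <- function(structure, probe = 1.4, n_points = 960L,
                 radii = vdw_radius(structure$elements)) {
  if (probe < 0) stop("probe must be non-negative")
  if (n_points < 10L) stop("n_points must be at least 10")
  n <- n_atoms(structure)
  pts <- .golden_spiral(n_points)
  p <- structure$coords %*% .canonical_rotation(structure$coords)
  ri <- radii + probe
  d <- as.matrix(stats::dist(p))
  area <- numeric(n)
  for (i in seq_len(n)) {
    nbr <- which(d[i, ] < ri[i] + ri & seq_len(n) != i)
    sp <- sweep(pts * ri[i], 2, p[i, ], "+")
    acc <- rep(TRUE, n_points)
    for (j in nbr) {
      d2 <- (sp[, 1] - p[j, 1])^2 + (sp[, 2] - p[j, 2])^2 +
        (sp[, 3] - p[j, 3])^2
      acc <- acc & d2 > ri[j]^2
    }
    area[i] <- 4 * pi * ri[i]^2 * sum(acc) / n_points
  }
  list(atom_area = area, total = sum(area))
}

# ---- descriptor bundle ------------------------------------------------------

#' Compute the full descriptor set for one record
#'
#' Bundles every descriptor family for a species: per-atom Mulliken
#' (from the record), PEOE and EState values, Sterimol parameters for
#' each R-group attachment, percent buried volume and SASA at the key
#' atoms. The dispersion slot is a pass-through hook for externally
#' supplied per-atom values (flagged experimental; no internal formula).
#'
#' @param rec a [qm_record()]
#' @param key_atoms key-atom list as in [reaction_record()]; indices
#'   must be valid for this record's structure
#' @param bonds optional precomputed connectivity
#' @param dispersion optional externally supplied per-atom dispersion
#'   descriptor values
#' @return object of class `descriptor_set`
#' @export
descriptor_set <- function(rec, key_atoms, bonds = NULL, dispersion = NULL) {
  s <- rec$structure
  if (is.null(bonds)) bonds <- perceive_bonds(s)
  peoe <- peoe_charges(s, bonds)
  est <- estate_indices(s, bonds)
  sa <- sasa(s)
  ster <- lapply(key_atoms$attach, function(a) {
    core_nb <- intersect(.adjacency(bonds, n_atoms(s))[[a]], key_atoms$core)
    if (!length(core_nb)) return(c(L = NA_real_, B1 = NA_real_, B5 = NA_real_))
    sterimol(s, attach_atom = core_nb[1], sub_atom = a, bonds = bonds)
  })
  if (!is.null(dispersion) && length(dispersion) != n_atoms(s)) {
    stop("dispersion must be one value per atom")
  }
  structure(list(
    mulliken = rec$mulliken,
    peoe = peoe,
    estate = est,
    sterimol = ster,
    pbv = stats::setNames(
      vapply(c(key_atoms$beta_c,
               if (s$role == "TS") key_atoms$nu_c else integer(0)),
             function(a) percent_buried_volume(s, a), 0),
      c("beta_c", if (s$role == "TS") "nu_c" else character(0))),
    sasa_atom = sa$atom_area,
    sasa_total = sa$total,
    dispersion = dispersion,
    level = rec$level,
    role = s$role), class = "descriptor_set")
}
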