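# Independent oracles used by the unit and acceptance tests. These are
# deliberately separate code paths from the package implementation:
# brute-force scans, Monte-Carlo integration, and closed forms written
# from the textbook expressions.

# random rigid motion of a coordinate matrix
random_rigid_motion <- function(coords, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  q <- stats::rnorm(4); q <- q / sqrt(sum(q^2))
  R <- quat_to_rot(q)
  t <- stats::rnorm(3, sd = 5)
  sweep(coords %*% t(R), 2, t, "+")
}

quat_to_rot <- function(q) {
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  rbind(c(1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y)),
        c(2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x)),
        c(2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)))
}

# brute-force minimal RMSD: random quaternion grid + Nelder-Mead
# refinement of the best candidates
oracle_rmsd <- function(P, Q, n_grid = 2000, n_refine = 5) {
  P <- sweep(P, 2, colMeans(P))
  Q <- sweep(Q, 2, colMeans(Q))
  rmsd_q <- function(q) {
    q <- q / sqrt(sum(q^2))
    sqrt(mean(rowSums((Q - P %*% t(quat_to_rot(q)))^2)))
  }
  qs <- matrix(stats::rnorm(4 * n_grid), ncol = 4)
  vals <- apply(qs, 1, rmsd_q)
  best <- order(vals)[seq_len(n_refine)]
  mins <- vapply(best, function(i) {
    stats::optim(qs[i, ], rmsd_q, method = "Nelder-Mead",
                 control = list(maxit = 2000, reltol = 1e-14))$value
  }, 0)
  min(mins)
}

# dense rotational-scan Sterimol oracle (0.1 degree grid), written
# directly from the geometric definition
oracle_sterimol <- function(coords, radii, attach, sub, sub_set) {
  u <- coords[sub, ] - coords[attach, ]
  u <- u / sqrt(sum(u^2))
  rel <- sweep(coords[sub_set, , drop = FALSE], 2, coords[attach, ])
  r <- radii[sub_set]
  proj <- drop(rel %*% u)
  L <- max(proj + r)
  perp <- rel - outer(proj, u)
  ref <- if (abs(u[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  e1 <- ref - sum(ref * u) * u; e1 <- e1 / sqrt(sum(e1^2))
  e2 <- c(u[2] * e1[3] - u[3] * e1[2], u[3] * e1[1] - u[1] * e1[3],
          u[1] * e1[2] - u[2] * e1[1])
  a <- drop(perp %*% e1); b <- drop(perp %*% e2)
  B5 <- max(sqrt(a^2 + b^2) + r)
  th <- seq(0, 2 * pi, length.out = 3601)[-3601]
  widths <- vapply(th, function(t) max(a * cos(t) + b * sin(t) + r), 0)
  c(L = L, B1 = min(widths), B5 = B5)
}

# Monte-Carlo buried-volume oracle
oracle_pbv_mc <- function(coords, radii_scaled, center, R, n = 1e7,
                          seed = 99, chunk = 1e6) {
  set.seed(seed)
  hit <- 0; tot <- 0
  while (tot < n) {
    m <- min(chunk, n - tot)
    pts <- matrix(stats::runif(3 * m, -R, R), ncol = 3)
    pts <- pts[rowSums(pts^2) <= R^2, , drop = FALSE]
    covered <- rep(FALSE, nrow(pts))
    for (a in seq_len(nrow(coords))) {
      d2 <- (pts[, 1] - (coords[a, 1] - center[1]))^2 +
        (pts[, 2] - (coords[a, 2] - center[2]))^2 +
        (pts[, 3] - (coords[a, 3] - center[3]))^2
      covered <- covered | d2 <= radii_scaled[a]^2
    }
    hit <- hit + sum(covered); tot <- tot + nrow(pts)
  }
  100 * hit / tot
}

# spreadsheet-style RRHO free energy, written independently from the
# same textbook partition functions (1 atm standard state + molar
# correction), for cross-checking rrho_thermo / activation_barrier
oracle_rrho_G <- function(elements, coords, freqs, E_hartree, T = 298.15,
                          conc = 1.0) {
  h <- 6.62607015e-34; kB <- 1.380649e-23; c_cm <- 2.99792458e10
  NAv <- 6.02214076e23; Rj <- 8.31446261815324
  amu <- 1.66053906660e-27
  kcal <- function(J_per_mol) J_per_mol / 4184
  m <- deltabarrier::atomic_mass(elements) * amu
  M <- sum(m)
  freqs <- freqs[freqs > 0]
  # translation
  qt <- (2 * pi * M * kB * T / h^2)^1.5 * kB * T / 101325
  S <- Rj * (log(qt) + 2.5)
  U <- 1.5 * Rj * T
  # rotation
  n <- length(elements)
  if (n > 1) {
    com <- colSums(coords * m) / M
    x <- sweep(coords, 2, com) * 1e-10
    Imat <- matrix(0, 3, 3)
    for (i in seq_len(n)) {
      r2 <- sum(x[i, ]^2)
      Imat <- Imat + m[i] * (diag(3) * r2 - outer(x[i, ], x[i, ]))
    }
    ev <- sort(eigen(Imat)$values)
    if (n == 2 || ev[1] / ev[3] < 1e-8) {
      qr <- 8 * pi^2 * ev[3] * kB * T / h^2
      S <- S + Rj * (log(qr) + 1)
      U <- U + Rj * T
    } else {
      qr <- sqrt(pi * prod(ev)) * (8 * pi^2 * kB * T / h^2)^1.5
      S <- S + Rj * (log(qr) + 1.5)
      U <- U + 1.5 * Rj * T
    }
  }
  # vibrations (pure RRHO, no damping: caller uses cutoff = 0)
  zpe <- 0
  for (nu in freqs) {
    x <- h * c_cm * nu / (kB * T)
    zpe <- zpe + NAv * h * c_cm * nu / 2
    U <- U + Rj * T * x / (exp(x) - 1)
    S <- S + Rj * (x / (exp(x) - 1) - log(1 - exp(-x)))
  }
  H <- E_hartree * 627.5094740631 + kcal(zpe + U + Rj * T)
  G <- H - T * kcal(S)
  G + kcal(Rj * T * log(conc * 1000 * Rj * T / 101325))
}

# small shared fixtures ------------------------------------------------------

water_structure <- function() {
  qc_structure(c("O", "H", "H"),
               rbind(c(0, 0, 0.1173), c(0, 0.7572, -0.4692),
                     c(0, -0.7572, -0.4692)),
               role = "MA", label = "water fixture")
}

# a tiny diatomic + triatomic reaction with hand-set energetics; thermal
# contributions are real RRHO terms, checked against oracle_rrho_G
toy_reaction <- function(dE_kcal = 10, e_shift = 0) {
  hk <- deltabarrier::qc_constants$hartree_kcal
  ma <- qm_record(qc_structure(c("C", "O"), rbind(c(0, 0, 0), c(1.13, 0, 0)),
                               role = "MA", label = "toy MA"),
                  level = "SQM", e_elec = -113.3 + e_shift,
                  frequencies = 2143)
  nuc <- qm_record(water_structure(), level = "SQM",
                   e_elec = -76.4 + e_shift,
                   frequencies = c(1595, 3657, 3756))
  nuc$structure$role <- "nucleophile"
  ts_el <- c("C", "O", "O", "H", "H")
  ts_xyz <- rbind(c(0, 0, 0), c(1.13, 0, 0), c(0, 0, 2.2),
                  c(0.76, 0, 2.79), c(-0.76, 0, 2.79))
  ts <- qm_record(qc_structure(ts_el, ts_xyz, role = "TS",
                               label = "toy TS"),
                  level = "SQM",
                  e_elec = -113.3 - 76.4 + dE_kcal / hk + e_shift,
                  frequencies = c(-500, 300, 800, 1595, 2100, 3657, 3756,
                                  450, 120))
  reaction_record("toy", list(SQM = list(MA = ma, nucleophile = nuc,
                                         TS = ts)),
                  key_atoms = list(nu_c = 3L, beta_c = 1L, carbonyl_o = 2L,
                                   core = c(1L, 2L), attach = integer(0)))
}
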