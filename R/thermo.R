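# Ideal-gas rigid-rotor harmonic-oscillator (RRHO) thermochemistry with
# quasiharmonic vibrational entropy, and bimolecular activation barriers.
#
# Conventions (all configurable where noted):
#   * symmetry number sigma = 1 for every species (documented bias)
#   * frequency scaling factor 1.0 by default
#   * quasiharmonic scheme: Grimme damped free-rotor interpolation with a
#     100 cm^-1 cutoff and Head-Gordon damping 1/(1+(nu0/nu)^4);
#     Truhlar frequency-raising available as an option
#   * TS records: the single imaginary mode is dropped from all
#     vibrational sums; extra imaginary modes are a hard error
#   * standard state: 1 atm gas converted to a molar concentration via
#     the additive term RT ln(c RT / p0)

# per-mode harmonic-oscillator entropy, cal/(mol K); nu in cm^-1
.s_ho <- function(nu, T) {
  cc <- qc_constants
  x <- cc$h * cc$c_cm * nu / (cc$kB * T)
  r_cal <- cc$R_kcal * 1000
  r_cal * (x / (exp(x) - 1) - log1p(-exp(-x)))
}

# per-mode free-rotor entropy with Grimme's averaged-moment damping
.s_fr <- function(nu, T) {
  cc <- qc_constants
  mu <- cc$h / (8 * pi^2 * cc$c_cm * nu)            # kg m^2
  mu_p <- mu * cc$grimme_Bav / (mu + cc$grimme_Bav)
  r_cal <- cc$R_kcal * 1000
  r_cal * (0.5 + log(sqrt(8 * pi^3 * mu_p * cc$kB * T) / cc$h))
}

# Head-Gordon damping weight: -> 1 for nu >> cutoff, -> 0 for nu << cutoff
.qh_weight <- function(nu, cutoff) 1 / (1 + (cutoff / nu)^4)

#' Quasiharmonic vibrational entropy
#'
#' Per-mode entropies interpolated between the harmonic-oscillator and
#' free-rotor expressions with the damping function
#' `w(nu) = 1/(1 + (cutoff/nu)^4)`; the mode contributes
#' `w * S_HO + (1 - w) * S_FR` (Grimme scheme). With
#' `scheme = "truhlar"` each frequency below the cutoff is instead
#' raised to the cutoff inside the harmonic expression.
#'
#' @param frequencies real (positive) wavenumbers, cm^-1
#' @param T temperature, K
#' @param cutoff damping center / raising threshold, cm^-1 (default 100)
#' @param scheme `"grimme"` (default) or `"truhlar"`
#' @return vibrational entropy, cal/(mol K)
#' @export
quasiharmonic_entropy <- function(frequencies, T = 298.15, cutoff = 100,
                                  scheme = c("grimme", "truhlar")) {
  scheme <- match.arg(scheme)
  if (cutoff < 0) stop("cutoff must be non-negative")
  if (T <= 0) stop("temperature must be positive")
  frequencies <- frequencies[frequencies > 0 | !length(frequencies)]
  if (!length(frequencies)) return(0)
  if (any(frequencies <= 0)) stop("quasiharmonic entropy needs real modes")
  if (scheme == "truhlar") {
    return(sum(.s_ho(pmax(frequencies, cutoff), T)))
  }
  if (cutoff == 0) return(sum(.s_ho(frequencies, T)))
  w <- .qh_weight(frequencies, cutoff)
  sum(w * .s_ho(frequencies, T) + (1 - w) * .s_fr(frequencies, T))
}

# principal moments of inertia, kg m^2, from elements + coords (Angstrom)
.inertia_moments <- function(elements, coords) {
  cc <- qc_constants
  m <- atomic_mass(elements) * cc$amu
  xyz <- coords * 1e-10
  com <- colSums(xyz * m) / sum(m)
  xyz <- sweep(xyz, 2, com)
  x <- xyz[, 1]; y <- xyz[, 2]; z <- xyz[, 3]
  I <- matrix(c(sum(m * (y^2 + z^2)), -sum(m * x * y), -sum(m * x * z),
                -sum(m * x * y), sum(m * (x^2 + z^2)), -sum(m * y * z),
                -sum(m * x * z), -sum(m * y * z), sum(m * (x^2 + y^2))),
              3, 3)
  sort(eigen(I, symmetric = TRUE, only.values = TRUE)$values)
}

#' RRHO / quasiharmonic thermochemistry for one record
#'
#' Ideal-gas rigid-rotor harmonic-oscillator partition-function
#' thermochemistry at 1 atm, with the vibrational entropy additionally
#' evaluated under the quasiharmonic scheme, and the composite free
#' energy `G_qh` referenced to the requested molar standard state.
#'
#' `G_qh = E + ZPE + U_trans + U_rot + U_vib + RT - T S_qh + RT ln(c RT/p0)`
#' where `E` is the solvent single-point energy when present, else the
#' gas-phase electronic energy ([composite_energy()]).
#'
#' For a TS-role record the single imaginary mode is excluded from all
#' vibrational sums; more than one imaginary mode (or any, for a
#' minimum) is an error surfaced by [check_role_frequencies()].
#'
#' @param rec a [qm_record()]
#' @param T temperature, K
#' @param conc standard-state concentration, mol/L; `NULL` keeps 1 atm
#' @param qh_cutoff quasiharmonic cutoff, cm^-1
#' @param qh_scheme `"grimme"` or `"truhlar"`
#' @param freq_scale harmonic frequency scaling factor
#' @return object of class `thermo_result`: list with `ZPE`, `U_trans`,
#'   `U_rot`, `U_vib`, `H`, `G_qh` (kcal/mol), `S_trans`, `S_rot`,
#'   `S_vib_rrho`, `S_vib_qh` (cal/(mol K)), `T`, `standard_state`
#' @export
rrho_thermo <- function(rec, T = 298.15, conc = 1.0, qh_cutoff = 100,
                        qh_scheme = "grimme", freq_scale = 1.0) {
  stopifnot(inherits(rec, "qm_record"))
  if (T <= 0) stop("temperature must be positive")
  cc <- qc_constants
  s <- rec$structure
  n <- n_atoms(s)
  check_role_frequencies(rec)
  freqs <- rec$frequencies * freq_scale
  freqs <- freqs[freqs > 0]                 # TS imaginary mode dropped
  moments <- if (n > 1L) .inertia_moments(s$elements, s$coords) else rep(0, 3)
  linear <- n == 2L || (n > 2L && moments[1] / max(moments[3], 1e-99) < 1e-8)
  n_expected <- if (n == 1L) 0L else if (linear) 3L * n - 5L else 3L * n - 6L
  if (n_expected > 0L && !length(freqs)) {
    stop("polyatomic record has no frequencies; cannot compute thermochemistry",
         call. = FALSE)
  }

  r_kcal <- cc$R_kcal
  r_cal <- r_kcal * 1000
  mass_kg <- sum(atomic_mass(s$elements)) * cc$amu

  # translation (Sackur-Tetrode at 1 atm)
  q_t <- (2 * pi * mass_kg * cc$kB * T / cc$h^2)^1.5 * (cc$kB * T / cc$atm_Pa)
  S_trans <- r_cal * (log(q_t) + 2.5)
  U_trans <- 1.5 * r_kcal * T

  # rotation
  if (n == 1L) {
    S_rot <- 0; U_rot <- 0
  } else if (linear) {
    I <- moments[3]
    q_r <- 8 * pi^2 * I * cc$kB * T / cc$h^2      # sigma = 1
    S_rot <- r_cal * (log(q_r) + 1)
    U_rot <- r_kcal * T
  } else {
    q_r <- sqrt(pi) * sqrt((8 * pi^2 * cc$kB * T / cc$h^2)^3 * prod(moments))
    S_rot <- r_cal * (log(q_r) + 1.5)
    U_rot <- 1.5 * r_kcal * T
  }

  # vibrations
  if (length(freqs)) {
    x <- cc$h * cc$c_cm * freqs / (cc$kB * T)
    ZPE <- sum(cc$NA_avogadro * cc$h * cc$c_cm * freqs / 2) / cc$J_per_kcal
    U_vib <- r_kcal * T * sum(x / (exp(x) - 1))
    S_vib_rrho <- sum(.s_ho(freqs, T))
    S_vib_qh <- quasiharmonic_entropy(freqs, T, cutoff = qh_cutoff,
                                      scheme = qh_scheme)
  } else {
    ZPE <- 0; U_vib <- 0; S_vib_rrho <- 0; S_vib_qh <- 0
  }

  E <- composite_energy(rec) * cc$hartree_kcal
  H <- E + ZPE + U_trans + U_rot + U_vib + r_kcal * T
  S_tot <- (S_trans + S_rot + S_vib_qh) / 1000     # kcal/(mol K)
  G <- H - T * S_tot
  ss <- "1 atm"
  if (!is.null(conc)) {
    G <- G + standard_state_correction(T, conc)
    ss <- sprintf("%g mol/L", conc)
  }
  structure(list(ZPE = ZPE, U_trans = U_trans, U_rot = U_rot, U_vib = U_vib,
                 S_trans = S_trans, S_rot = S_rot,
                 S_vib_rrho = S_vib_rrho, S_vib_qh = S_vib_qh,
                 H = H, G_qh = G, T = T, standard_state = ss),
            class = "thermo_result")
}

#' @export
print.thermo_result <- function(x, ...) {
  cat(sprintf("<thermo_result> T=%.2f K, %s: H=%.4f, G_qh=%.4f kcal/mol\n",
              x$T, x$standard_state, x$H, x$G_qh))
  invisible(x)
}

#' Standard-state correction from 1 atm to a molar concentration
#'
#' The additive free-energy term `RT ln(c RT / p0)` that converts the
#' 1 atm ideal-gas standard state to a concentration standard state of
#' `conc` mol/L (about +1.89 kcal/mol for 1 mol/L at 298.15 K).
#'
#' @param T temperature, K
#' @param conc target concentration, mol/L
#' @return correction, kcal/mol
#' @export
standard_state_correction <- function(T = 298.15, conc = 1.0) {
  if (T <= 0) stop("temperature must be positive")
  if (conc <= 0) stop("concentration must be positive")
  cc <- qc_constants
  # c RT / p0 with c in mol/m^3
  ratio <- (conc * 1000) * cc$R_J * T / cc$atm_Pa
  cc$R_kcal * T * log(ratio)
}

#' Bimolecular activation barrier for one reaction
#'
#' `dG_act = G_qh(TS) - G_qh(MA) - G_qh(nucleophile)` with every species
#' evaluated at the same temperature and molar standard state, using the
#' solvent single-point energy when present. The TS record must carry
#' exactly one imaginary mode.
#'
#' @param reaction a [reaction_record()]
#' @param level level-of-theory string
#' @inheritParams rrho_thermo
#' @return object of class `barrier_record`: list with `reaction_id`,
#'   `level`, `dG_act` (kcal/mol), `T`, `standard_state`
#' @export
activation_barrier <- function(reaction, level, T = 298.15, conc = 1.0,
                               qh_cutoff = 100, qh_scheme = "grimme",
                               freq_scale = 1.0) {
  stopifnot(inherits(reaction, "reaction_record"))
  th <- lapply(c(MA = "MA", nucleophile = "nucleophile", TS = "TS"),
               function(role) {
                 rec <- get_record(reaction, level, role)
                 rrho_thermo(rec, T = T, conc = conc, qh_cutoff = qh_cutoff,
                             qh_scheme = qh_scheme, freq_scale = freq_scale)
               })
  dG <- th$TS$G_qh - th$MA$G_qh - th$nucleophile$G_qh
  if (!is.finite(dG)) stop("non-finite activation barrier")
  structure(list(reaction_id = reaction$reaction_id, level = level,
                 dG_act = dG, T = T, standard_state = th$TS$standard_state),
            class = "barrier_record")
}

#' @export
print.barrier_record <- function(x, ...) {
  cat(sprintf("<barrier_record> %s @ %s: dG_act = %.3f kcal/mol (%g K, %s)\n",
              x$reaction_id, x$level, x$dG_act, x$T, x$standard_state))
  invisible(x)
}

#' Compute barriers for a list of reactions
#'
#' @param reactions list of [reaction_record()]s
#' @param level level-of-theory string
#' @inheritParams rrho_thermo
#' @return data frame with columns `reaction_id`, `level`, `dG_act`
#' @export
compute_barriers <- function(reactions, level, T = 298.15, conc = 1.0,
                             qh_cutoff = 100, qh_scheme = "grimme",
                             freq_scale = 1.0) {
  rows <- lapply(reactions, function(rx) {
    b <- activation_barrier(rx, level, T = T, conc = conc,
                            qh_cutoff = qh_cutoff, qh_scheme = qh_scheme,
                            freq_scale = freq_scale)
    data.frame(reaction_id = b$reaction_id, level = b$level,
               dG_act = b$dG_act, stringsAsFactors = FALSE)
  })
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}
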