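# Synthetic-data generators. Two layers:
#
#  * generate_reactions(): fabricates a desk-scale analogue of the
#    enumerated nitro-Michael dataset -- an alpha,beta-unsaturated
#    carbonyl core with four variable R positions, a nitronate
#    nucleophile, and transition states with the forming C-C bond --
#    at two pseudo-levels of theory ("SQM" = perturbed geometry and
#    biased energies, "DFT" = reference), written in the same XYZ /
#    qclog / manifest formats qm_io reads. No electronic structure is
#    run: energies and frequencies are internally consistent fabrications
#    and every generated file passes the pipeline's validators.
#
#  * generate_feature_table(): draws a correlated-Gaussian feature table
#    with a sparse additive signal on top of an SQM-like baseline
#    barrier, the stochastic world in which the delta-learning recovery
#    properties are tested. Ground truth is recorded for both.

# substituent vocabulary: geometry template + scalar "size" and
# "electron-withdrawing" scores that drive the planted energy bias
.substituents <- list(
  H    = list(size = 0.0, en = 0.0),
  Me   = list(size = 1.0, en = -0.2),
  F    = list(size = 0.3, en = 1.0),
  Cl   = list(size = 0.8, en = 0.8),
  OH   = list(size = 0.5, en = 0.7),
  NH2  = list(size = 0.6, en = 0.4)
)

# local orthonormal frame completing unit vector u
.frame <- function(u) {
  w <- if (abs(u[3]) < 0.9) c(0, 0, 1) else c(1, 0, 0)
  v <- c(u[2] * w[3] - u[3] * w[2], u[3] * w[1] - u[1] * w[3],
         u[1] * w[2] - u[2] * w[1])
  v <- v / sqrt(sum(v^2))
  w <- c(u[2] * v[3] - u[3] * v[2], u[3] * v[1] - u[1] * v[3],
         u[1] * v[2] - u[2] * v[1])
  list(v = v, w = w)
}

# atoms of one substituent attached at core position `pc` along unit
# direction `u`; returns list(elements, coords, bonds_local)
.build_substituent <- function(name, pc, u) {
  fr <- .frame(u)
  v <- fr$v; w <- fr$w
  at <- function(b, du) pc + b * du
  switch(name,
    H = list(el = "H", xyz = rbind(at(1.09, u)), bonds = matrix(0L, 0, 2)),
    F = list(el = "F", xyz = rbind(at(1.35, u)), bonds = matrix(0L, 0, 2)),
    Cl = list(el = "Cl", xyz = rbind(at(1.77, u)), bonds = matrix(0L, 0, 2)),
    Me = {
      cpos <- at(1.50, u)
      hs <- t(vapply(c(pi / 3, pi, 5 * pi / 3), function(th) {
        cpos + 1.09 * (0.333 * u + 0.943 * (cos(th) * v + sin(th) * w))
      }, numeric(3)))
      list(el = c("C", "H", "H", "H"), xyz = rbind(cpos, hs),
           bonds = cbind(1, 2:4))
    },
    OH = {
      # hydroxyl H points out of the core plane to avoid clashes with
      # neighbouring substituents in the crude template geometry
      opos <- at(1.40, u)
      h <- opos + 0.96 * (0.25 * u + 0.968 * w)
      list(el = c("O", "H"), xyz = rbind(opos, h), bonds = cbind(1, 2))
    },
    NH2 = {
      npos <- at(1.40, u)
      h1 <- npos + 1.01 * (0.375 * u + 0.927 * w)
      h2 <- npos + 1.01 * (0.375 * u - 0.927 * w)
      list(el = c("N", "H", "H"), xyz = rbind(npos, h1, h2),
           bonds = cbind(1, 2:3))
    },
    stop("unknown substituent: ", name))
}

# Michael-acceptor geometry with R1..R4; returns structure pieces plus
# the intended bond graph and attachment indices
.build_ma <- function(subs) {
  core_el <- c("C", "C", "C", "O")
  core_xyz <- rbind(c(0, 0, 0),        # C1, beta-carbon
                    c(1.34, 0, 0),     # C2, alpha-carbon
                    c(2.08, 1.22, 0),  # C3, carbonyl carbon
                    c(3.29, 1.37, 0))  # O4
  dirs <- list(R1 = c(-0.5, 0.866, 0),
               R2 = c(-0.5, -0.866, 0),
               R3 = c(0.4907, -0.8713, 0),
               R4 = c(-0.342, 0.94, 0))
  anchor <- c(R1 = 1L, R2 = 1L, R3 = 2L, R4 = 3L)
  el <- core_el; xyz <- core_xyz
  bonds <- rbind(c(1, 2), c(2, 3), c(3, 4))
  attach <- integer(0)
  for (k in seq_along(dirs)) {
    nm <- names(dirs)[k]
    sb <- .build_substituent(subs[k], core_xyz[anchor[nm], ], dirs[[nm]])
    base <- length(el)
    el <- c(el, sb$el)
    xyz <- rbind(xyz, sb$xyz)
    attach <- c(attach, base + 1L)
    bonds <- rbind(bonds, c(anchor[nm], base + 1L))
    if (nrow(sb$bonds)) bonds <- rbind(bonds, sb$bonds + base)
  }
  list(elements = el, coords = xyz, bonds = bonds, attach = attach)
}

# nitronate nucleophile (CH2=NO2-), local frame: C at origin, N on +x
.build_nucleophile <- function() {
  el <- c("C", "N", "O", "O", "H", "H")
  xyz <- rbind(c(0, 0, 0), c(1.35, 0, 0),
               c(1.975, 1.0825, 0), c(1.975, -1.0825, 0),
               c(-0.54, 0.935, 0), c(-0.54, -0.935, 0))
  bonds <- rbind(c(1, 2), c(2, 3), c(2, 4), c(1, 5), c(1, 6))
  list(elements = el, coords = xyz, bonds = bonds)
}

# place the nucleophile above the beta-carbon at forming distance d
.place_nucleophile <- function(nu, beta_pos, d) {
  # local x -> +z (N away from the MA plane), local y -> +x, local z -> +y
  Rm <- cbind(c(0, 0, 1), c(1, 0, 0), c(0, 1, 0))
  xyz <- nu$coords %*% t(Rm)
  sweep(xyz, 2, beta_pos + c(0, 0, d), "+")
}

# deterministic fabricated frequencies: 3N-6 modes in [120, 3200] cm^-1
.fab_frequencies <- function(n_atoms) {
  nm <- max(0L, 3L * n_atoms - 6L)
  if (nm == 0L) return(numeric(0))
  fr <- 120 + (3200 - 120) * (seq_len(nm) - 0.5) / nm
  sort(fr * stats::runif(nm, 0.97, 1.03))
}

# TS modes: reactant modes survive, five new low intermolecular modes
# appear, and one mode becomes the imaginary reaction coordinate
# (3(n1+n2)-7 = (3n1-6) + (3n2-6) + 5), keeping ZPE nearly additive
.fab_ts_frequencies <- function(freq_ma, freq_nu) {
  c(-stats::runif(1, 400, 600), sort(c(freq_ma, freq_nu,
                                       stats::runif(5, 80, 400))))
}

# fabricated Mulliken charges summing to the net charge
.fab_mulliken <- function(elements, net_charge, o_shift = 0) {
  base <- c(C = 0.06, H = 0.06, O = -0.35, N = 0.12, F = -0.22,
            Cl = -0.12)[elements]
  base[is.na(base)] <- 0
  base[elements == "O"] <- base[elements == "O"] + o_shift
  base + (net_charge - sum(base)) / length(elements)
}

#' Generate a synthetic reaction dataset on disk
#'
#' Writes, for each reaction, MA / nucleophile / TS species at two
#' pseudo-levels of theory (`"SQM"`, `"DFT"`) as qclog files plus TS
#' XYZ files, a manifest CSV, and a ground-truth JSON sidecar. The
#' planted world: DFT is the reference; the SQM electronic barrier is
#' the DFT barrier plus a sparse additive bias in the substituents'
#' size/electron-withdrawing scores plus Gaussian noise `sigma`; SQM
#' geometries are the DFT geometry plus isotropic Gaussian coordinate
#' noise, with the forming C-C bond shorter by `bond_offset`. TSs carry
#' exactly one planted imaginary mode, minima none.
#'
#' @param n_reactions number of reactions
#' @param out_dir output directory (created if needed)
#' @param seed integer seed; the generator is fully deterministic
#' @param noise_sd geometric noise SD per coordinate, Angstrom
#'   (default 0.1)
#' @param bond_offset SQM minus DFT forming-bond distance, Angstrom
#'   (default -0.04, i.e. the DFT distance is 0.04 longer)
#' @param sigma barrier-bias noise SD, kcal/mol (default 0.5)
#' @param lit_fraction fraction of reactions tagged `"literature"`
#' @param vocabulary substituent names to draw from
#' @return list with `manifest_path`, `manifest` (data frame),
#'   `sidecar_path`, `ground_truth` (list per reaction)
#' @export
generate_reactions <- function(n_reactions, out_dir = tempfile("rxns"),
                               seed = 1L, noise_sd = 0.1,
                               bond_offset = -0.04, sigma = 0.5,
                               lit_fraction = 0,
                               vocabulary = names(.substituents)) {
  stopifnot(n_reactions >= 1)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  set.seed(seed)
  nu <- .build_nucleophile()
  d_dft <- 2.10
  d_sqm <- d_dft + bond_offset
  rows <- list(); truth <- list()
  e_nu_dft <- -245.300000
  e_nu_sqm <- -240.100000
  for (r in seq_len(n_reactions)) {
    id <- sprintf("rxn%04d", r)
    subs <- sample(vocabulary, 4, replace = TRUE)
    ma <- .build_ma(subs)
    n_ma <- length(ma$elements)
    # planted energetics (kcal/mol); the electronic barrier draw is
    # offset so that after the ~+13 kcal/mol bimolecular entropy
    # penalty the free-energy barriers span the usual DFT range
    dE_dft <- stats::runif(1, -8, 25)
    size_sc <- vapply(subs, function(s) .substituents[[s]]$size, 0)
    en_sc <- vapply(subs, function(s) .substituents[[s]]$en, 0)
    g_bias <- unname(3.2 * size_sc[1] + 3.2 * size_sc[2] - 2.2 * en_sc[3] +
                       1.6 * en_sc[4])
    eps <- stats::rnorm(1, 0, sigma)
    bias <- g_bias + eps
    e_ma_dft <- -300 - 0.5 * n_ma + stats::rnorm(1, 0, 0.005)
    e_ma_sqm <- e_ma_dft * 0.98
    hk <- qc_constants$hartree_kcal
    e_ts_dft <- e_ma_dft + e_nu_dft + dE_dft / hk
    e_ts_sqm <- e_ma_sqm + e_nu_sqm + (dE_dft + bias) / hk
    en_total <- sum(en_sc)

    # geometries
    ts_dft_xyz <- rbind(ma$coords, .place_nucleophile(nu, ma$coords[1, ],
                                                      d_dft))
    ts_sqm_xyz <- rbind(ma$coords, .place_nucleophile(nu, ma$coords[1, ],
                                                      d_sqm))
    ts_el <- c(ma$elements, nu$elements)
    jitter <- function(xyz) xyz + stats::rnorm(length(xyz), 0, noise_sd)
    geoms <- list(
      DFT = list(MA = ma$coords, nucleophile = nu$coords, TS = ts_dft_xyz),
      SQM = list(MA = jitter(ma$coords), nucleophile = jitter(nu$coords),
                 TS = jitter(ts_sqm_xyz)))
    energies <- list(
      DFT = c(MA = e_ma_dft, nucleophile = e_nu_dft, TS = e_ts_dft),
      SQM = c(MA = e_ma_sqm, nucleophile = e_nu_sqm, TS = e_ts_sqm))
    elements <- list(MA = ma$elements, nucleophile = nu$elements, TS = ts_el)
    charges <- c(MA = 0L, nucleophile = -1L, TS = -1L)

    ka_txt <- .format_key_atoms(list(
      nu_c = n_ma + 1L, beta_c = 1L, carbonyl_o = 4L,
      core = c(1L, 2L, 3L, 4L), attach = ma$attach))
    tag <- if (stats::runif(1) < lit_fraction) "literature" else "unassigned"

    freq_seed <- list(MA = .fab_frequencies(n_ma),
                      nucleophile = .fab_frequencies(length(nu$elements)))
    freq_seed$TS <- .fab_ts_frequencies(freq_seed$MA, freq_seed$nucleophile)
    for (lev in c("DFT", "SQM")) {
      for (role in c("MA", "nucleophile", "TS")) {
        s <- qc_structure(elements[[role]], geoms[[lev]][[role]],
                          role = role, net_charge = charges[[role]],
                          label = paste(id, lev, role, sep = "_"))
        freqs <- freq_seed[[role]] * if (lev == "DFT") 1 else 1.01
        mull <- .fab_mulliken(elements[[role]], charges[[role]],
                              o_shift = -0.04 * en_total)
        rec <- qm_record(s, level = lev, e_elec = energies[[lev]][[role]],
                         e_spe = energies[[lev]][[role]] - 0.002,
                         frequencies = freqs, mulliken = mull)
        fname <- sprintf("%s_%s_%s.qclog", id, lev, role)
        write_qm_log(rec, file.path(out_dir, fname))
        if (role == "TS") {
          write_xyz(s, file.path(out_dir, sprintf("%s_%s_TS.xyz", id, lev)))
        }
        rows[[length(rows) + 1L]] <- data.frame(
          reaction_id = id, level = lev, role = role, path = fname,
          key_atoms = if (role == "TS") ka_txt else "",
          split_tag = tag, stringsAsFactors = FALSE)
      }
    }
    truth[[id]] <- list(substituents = subs, size_scores = unname(size_sc),
                        en_scores = unname(en_sc), dE_dft = dE_dft,
                        g_bias = g_bias, eps = eps, sigma = sigma,
                        d_form = c(DFT = d_dft, SQM = d_sqm),
                        n_ma_atoms = n_ma,
                        bonds_ma = ma$bonds,
                        attach = ma$attach, split_tag = tag)
  }
  manifest <- do.call(rbind, rows)
  manifest_path <- file.path(out_dir, "manifest.csv")
  save_manifest(manifest, manifest_path)
  sidecar_path <- file.path(out_dir, "ground_truth.json")
  jsonlite::write_json(truth, sidecar_path, auto_unbox = TRUE, digits = NA)
  list(manifest_path = manifest_path, manifest = manifest,
       sidecar_path = sidecar_path, ground_truth = truth, out_dir = out_dir)
}

#' Generate a synthetic feature table with a planted sparse signal
#'
#' Features are correlated Gaussians (AR(1) correlation `rho`), the
#' baseline barrier is drawn uniformly over 7.83-42.38 kcal/mol (the
#' span of semi-empirical nitro-Michael barriers) independently of the
#' features (so the baseline carries information the features do not --
#' the regime where delta learning helps), and the target is
#' `y = baseline + sum(coefs * x[, active]) + eps`,
#' `eps ~ N(0, sigma)`. With the default `sigma = 0.5` kcal/mol the
#' irreducible MAE floor is `sigma * sqrt(2/pi) ~ 0.40` kcal/mol. The
#' baseline also enters the feature matrix as `barrier_SQM` (the "All"
#' subset convention). Optionally plants a highly correlated feature
#' pair to exercise pruning.
#'
#' @param n rows (reactions)
#' @param n_features Gaussian features (excluding the barrier column)
#' @param active indices of causal features
#' @param coefs coefficients of the active features, kcal/mol per SD
#' @param sigma target noise SD, kcal/mol (default 0.5)
#' @param rho AR(1) feature correlation (default 0.3)
#' @param planted_pair optional `c(i, j, r)`: make feature j correlate
#'   with feature i at level r
#' @param seed integer seed
#' @return a [feature_table()] with attribute `"ground_truth"`
#' @export
generate_feature_table <- function(n, n_features = 30L,
                                   active = c(3L, 7L, 12L, 20L),
                                   coefs = c(1.5, -1.0, 0.8, 0.6),
                                   sigma = 0.5, rho = 0.3,
                                   planted_pair = NULL, seed = 1L) {
  stopifnot(length(active) == length(coefs), all(active <= n_features))
  set.seed(seed)
  S <- rho^abs(outer(seq_len(n_features), seq_len(n_features), "-"))
  X <- matrix(stats::rnorm(n * n_features), n) %*% chol(S)
  if (!is.null(planted_pair)) {
    i <- planted_pair[1]; j <- planted_pair[2]; r <- planted_pair[3]
    X[, j] <- r * X[, i] + sqrt(1 - r^2) * stats::rnorm(n)
  }
  colnames(X) <- sprintf("f%02d", seq_len(n_features))
  baseline <- stats::runif(n, 7.83, 42.38)
  g <- drop(X[, active, drop = FALSE] %*% coefs)
  eps <- stats::rnorm(n, 0, sigma)
  y <- baseline + g + eps
  x <- cbind(X, barrier_SQM = baseline)
  rownames(x) <- sprintf("rxn%04d", seq_len(n))
  ft <- feature_table(x, y = y, baseline = baseline, level = "SQM",
                      subset = "All")
  attr(ft, "ground_truth") <- list(
    active = colnames(X)[active], coefs = coefs, sigma = sigma,
    eps = eps, g = g)
  ft
}
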