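# File IO: XYZ structures, quantum-chemistry log files, and reaction
# manifests.
#
# The native log dialect ("qclog") is a minimal line-oriented format so
# that fixtures and tests never depend on proprietary program output:
#
#   #QCLOG 1
#   label  my_species
#   role   TS
#   charge -1
#   energy -250.123456         # Hartree; may repeat, LAST wins
#   spe    -250.234567         # optional solvent single-point, Hartree
#   begin geometry             # Angstrom; may repeat, LAST wins
#   C 0.000 0.000 0.000
#   end geometry
#   begin frequencies          # cm^-1, whitespace-separated, signed
#   -512.3 45.0 1200.0
#   end frequencies
#   begin mulliken             # e, one value per atom in order
#   -0.35 0.35
#   end mulliken
#
# Real Gaussian-style logs are supported through the same parser
# registry (`format = "gaussian"`), so an archive of program output can
# be ingested without changing downstream code.

#' Read an XYZ file
#'
#' Standard XYZ dialect: atom-count line, comment line, then
#' `element x y z` rows. The comment line is preserved as the label.
#'
#' @param path file path
#' @param role role to assign (default `"unknown"`)
#' @param net_charge net charge to assign (XYZ does not carry one)
#' @return a [qc_structure()]
#' @export
read_xyz <- function(path, role = "unknown", net_charge = 0L) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  if (length(lines) < 2L) stop("XYZ parse error at line 1: file too short")
  n <- suppressWarnings(as.integer(trimws(lines[1])))
  if (is.na(n) || n < 1L) {
    stop("XYZ parse error at line 1: malformed atom count '", lines[1], "'")
  }
  if (length(lines) < n + 2L) {
    stop(sprintf("XYZ parse error: expected %d atom rows, found %d",
                 n, length(lines) - 2L))
  }
  label <- lines[2]
  elements <- character(n)
  coords <- matrix(NA_real_, n, 3)
  for (i in seq_len(n)) {
    ln <- n_line <- i + 2L
    tok <- strsplit(trimws(lines[ln]), "\\s+")[[1]]
    if (length(tok) < 4L) {
      stop(sprintf("XYZ parse error at line %d: expected 'element x y z'", ln))
    }
    xyz <- suppressWarnings(as.numeric(tok[2:4]))
    if (anyNA(xyz)) {
      stop(sprintf("XYZ parse error at line %d: non-numeric coordinate", ln))
    }
    elements[i] <- tok[1]
    coords[i, ] <- xyz
  }
  qc_structure(elements, coords, role = role, net_charge = net_charge,
               label = label)
}

#' Write an XYZ file
#' @param s a [qc_structure()]
#' @param path output path
#' @param digits coordinate precision
#' @return `path`, invisibly
#' @export
write_xyz <- function(s, path, digits = 8) {
  stopifnot(inherits(s, "qc_structure"))
  fmt <- sprintf("%%-3s %%.%df %%.%df %%.%df", digits, digits, digits)
  rows <- sprintf(fmt, s$elements, s$coords[, 1], s$coords[, 2], s$coords[, 3])
  writeLines(c(as.character(n_atoms(s)), s$label, rows), path)
  invisible(path)
}

# ---- qm log parser registry -------------------------------------------------

.qm_parsers <- new.env(parent = emptyenv())

#' Register a quantum-chemistry log parser
#'
#' Parsers are functions `(path, level) -> qm_record`. The built-in
#' formats are `"qclog"` (the native dialect) and `"gaussian"`.
#'
#' @param name format name
#' @param fun parser function
#' @return `name`, invisibly
#' @export
register_qm_parser <- function(name, fun) {
  stopifnot(is.function(fun))
  assign(name, fun, envir = .qm_parsers)
  invisible(name)
}

#' Read a quantum-chemistry log file
#'
#' Dispatches to a registered parser. Both built-in parsers keep the
#' LAST geometry and LAST electronic energy in the file (matching how
#' optimization logs print intermediate steps), store imaginary modes as
#' negative wavenumbers, and parse a Mulliken block when present.
#' A frequency count differing from 3N-6 (nonlinear) / 3N-5 (linear)
#' gives a warning, not an error, since projection conventions vary.
#'
#' @param path file path
#' @param level level-of-theory string stored on the record
#' @param format parser name, default `"qclog"`
#' @return a [qm_record()]
#' @export
read_qm_log <- function(path, level, format = "qclog") {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  fun <- get0(format, envir = .qm_parsers)
  if (is.null(fun)) stop("unknown log format: ", format, call. = FALSE)
  rec <- fun(path, level)
  .warn_mode_count(rec, path)
  rec
}

.warn_mode_count <- function(rec, path) {
  n <- n_atoms(rec$structure)
  nf <- length(rec$frequencies)
  if (n < 2L || nf == 0L) return(invisible(rec))
  if (!nf %in% c(3 * n - 6, 3 * n - 5)) {
    warning(sprintf("%s: %d frequencies for %d atoms (expected 3N-6=%d or 3N-5=%d)",
                    path, nf, n, 3 * n - 6, 3 * n - 5), call. = FALSE)
  }
  invisible(rec)
}

.parse_qclog <- function(path, level) {
  lines <- readLines(path, warn = FALSE)
  header <- list(label = basename(path), role = "unknown", charge = 0L)
  energy <- NA_real_
  spe <- NA_real_
  geom_lines <- NULL
  freq <- numeric(0)
  mull <- NULL
  i <- 1L
  while (i <= length(lines)) {
    ln <- sub("#.*$", "", lines[i])
    ln <- trimws(ln)
    i <- i + 1L
    if (!nzchar(ln)) next
    tok <- strsplit(ln, "\\s+")[[1]]
    key <- tok[1]
    if (key == "begin") {
      block <- tok[2]
      body <- character(0)
      while (i <= length(lines) &&
             !grepl(paste0("^\\s*end\\s+", block), lines[i])) {
        body <- c(body, lines[i])
        i <- i + 1L
      }
      if (i > length(lines)) {
        stop(sprintf("%s: unterminated '%s' block", path, block), call. = FALSE)
      }
      i <- i + 1L  # skip the 'end' line
      if (block == "geometry") {
        geom_lines <- body          # last block wins
      } else if (block == "frequencies") {
        freq <- as.numeric(unlist(strsplit(trimws(body), "\\s+")))
      } else if (block == "mulliken") {
        mull <- as.numeric(unlist(strsplit(trimws(body), "\\s+")))
      }
    } else if (key == "energy") {
      energy <- as.numeric(tok[2])  # last wins
    } else if (key == "spe") {
      spe <- as.numeric(tok[2])
    } else if (key %in% c("label", "role")) {
      header[[key]] <- tok[2]
    } else if (key == "charge") {
      header$charge <- as.integer(tok[2])
    }
  }
  if (!is.finite(energy)) {
    stop(sprintf("%s: no electronic energy found", path), call. = FALSE)
  }
  if (is.null(geom_lines) || length(geom_lines) == 0L) {
    stop(sprintf("%s: no geometry block found", path), call. = FALSE)
  }
  tok <- strsplit(trimws(geom_lines), "\\s+")
  elements <- vapply(tok, `[[`, "", 1L)
  coords <- t(vapply(tok, function(t) as.numeric(t[2:4]), numeric(3)))
  s <- qc_structure(elements, coords, role = header$role,
                    net_charge = header$charge, label = header$label)
  qm_record(s, level = level, e_elec = energy, e_spe = spe,
            frequencies = freq, mulliken = mull)
}

#' Write a record in the native qclog dialect
#' @param rec a [qm_record()]
#' @param path output path
#' @return `path`, invisibly
#' @export
write_qm_log <- function(rec, path) {
  stopifnot(inherits(rec, "qm_record"))
  s <- rec$structure
  out <- c("#QCLOG 1",
           paste("label", s$label),
           paste("role", s$role),
           paste("charge", s$net_charge),
           sprintf("energy %.10f", rec$e_elec))
  if (is.finite(rec$e_spe)) out <- c(out, sprintf("spe %.10f", rec$e_spe))
  out <- c(out, "begin geometry",
           sprintf("%-3s %.8f %.8f %.8f", s$elements,
                   s$coords[, 1], s$coords[, 2], s$coords[, 3]),
           "end geometry")
  if (length(rec$frequencies)) {
    out <- c(out, "begin frequencies",
             paste(sprintf("%.4f", rec$frequencies), collapse = " "),
             "end frequencies")
  }
  if (!is.null(rec$mulliken)) {
    out <- c(out, "begin mulliken",
             paste(sprintf("%.6f", rec$mulliken), collapse = " "),
             "end mulliken")
  }
  writeLines(out, path)
  invisible(path)
}

# Gaussian-style text output: last "Standard orientation" (or "Input
# orientation") geometry, last "SCF Done" energy, "Frequencies --" rows,
# and the last "Mulliken charges" block.
.atomic_numbers <- c(H = 1, He = 2, B = 5, C = 6, N = 7, O = 8, F = 9,
                     Ne = 10, Na = 11, Mg = 12, Si = 14, P = 15, S = 16,
                     Cl = 17, K = 19, Br = 35, I = 53)

.parse_gaussian <- function(path, level) {
  lines <- readLines(path, warn = FALSE)
  scf <- grep("SCF Done:", lines, value = TRUE)
  if (!length(scf)) stop(sprintf("%s: no 'SCF Done' energy", path), call. = FALSE)
  energy <- as.numeric(sub(".*=\\s*([-0-9.]+)\\s+.*", "\\1", scf[length(scf)]))
  ori <- grep("(Standard|Input) orientation:", lines)
  if (!length(ori)) stop(sprintf("%s: no orientation block", path), call. = FALSE)
  start <- ori[length(ori)] + 5L
  end <- start
  while (end <= length(lines) && !grepl("^\\s*-{5,}", lines[end])) end <- end + 1L
  rows <- strsplit(trimws(lines[start:(end - 1L)]), "\\s+")
  z <- vapply(rows, function(r) as.integer(r[2]), integer(1))
  elements <- names(.atomic_numbers)[match(z, .atomic_numbers)]
  coords <- t(vapply(rows, function(r) as.numeric(r[4:6]), numeric(3)))
  freq <- numeric(0)
  for (ln in grep("Frequencies --", lines, value = TRUE)) {
    freq <- c(freq, as.numeric(strsplit(trimws(
      sub(".*Frequencies --", "", ln)), "\\s+")[[1]]))
  }
  mull <- NULL
  mstart <- grep("^ *Mulliken charges", lines)
  if (length(mstart)) {
    ms <- mstart[length(mstart)] + 2L
    vals <- numeric(length(elements))
    for (k in seq_along(elements)) {
      tok <- strsplit(trimws(lines[ms + k - 1L]), "\\s+")[[1]]
      vals[k] <- as.numeric(tok[3])
    }
    mull <- vals
  }
  chg <- 0L
  cline <- grep("Charge =", lines, value = TRUE)
  if (length(cline)) {
    chg <- as.integer(sub(".*Charge =\\s*(-?[0-9]+).*", "\\1", cline[1]))
  }
  s <- qc_structure(elements, coords, role = "unknown", net_charge = chg,
                    label = basename(path))
  qm_record(s, level = level, e_elec = energy, frequencies = freq,
            mulliken = mull)
}

register_qm_parser("qclog", .parse_qclog)
register_qm_parser("gaussian", .parse_gaussian)

# ---- manifests --------------------------------------------------------------

# key_atoms disk encoding (0-based):
#   "nu_c=12;beta_c=0;carbonyl_o=3;core=0,1,2,3;attach=4,6,8,10"
.parse_key_atoms <- function(txt) {
  parts <- strsplit(strsplit(txt, ";")[[1]], "=")
  vals <- lapply(parts, function(p) as.integer(strsplit(p[2], ",")[[1]]) + 1L)
  names(vals) <- vapply(parts, `[[`, "", 1L)
  vals
}

.format_key_atoms <- function(ka) {
  paste(vapply(names(ka), function(nm) {
    paste0(nm, "=", paste(ka[[nm]] - 1L, collapse = ","))
  }, ""), collapse = ";")
}

#' Load a reaction manifest
#'
#' The manifest is a CSV (columns `reaction_id`, `level`, `role`, `path`,
#' `key_atoms`, `split_tag`) or an equivalent JSON array; one row per
#' species file. Paths are resolved relative to the manifest location.
#' Atom indices in `key_atoms` are 0-based on disk and converted to
#' R's 1-based indexing on load.
#'
#' Reactions whose files are missing or unreadable are dropped with a
#' per-reaction entry in the `errors` attribute (a data frame of
#' `reaction_id`, `message`); the remaining reactions load normally.
#'
#' @param path manifest file (`.csv` or `.json`)
#' @param format log-file format for [read_qm_log()]
#' @return list of [reaction_record()]s with attribute `"errors"`
#' @export
load_manifest <- function(path, format = "qclog") {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  dir <- dirname(path)
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    df <- jsonlite::fromJSON(path)
  } else {
    df <- utils::read.csv(path, stringsAsFactors = FALSE)
  }
  need <- c("reaction_id", "level", "role", "path", "key_atoms", "split_tag")
  if (!all(need %in% names(df))) {
    stop("manifest must have columns: ", paste(need, collapse = ", "))
  }
  ids <- unique(df$reaction_id)
  dup <- unique(df$reaction_id[duplicated(
    df[, c("reaction_id", "level", "role")])])
  if (length(dup)) {
    stop("duplicate reaction_id/level/role rows in manifest: ",
         paste(dup, collapse = ", "), call. = FALSE)
  }
  reactions <- list()
  errors <- data.frame(reaction_id = character(0), message = character(0),
                       stringsAsFactors = FALSE)
  for (id in ids) {
    sub <- df[df$reaction_id == id, , drop = FALSE]
    res <- tryCatch({
      records <- list()
      for (k in seq_len(nrow(sub))) {
        f <- file.path(dir, sub$path[k])
        if (!file.exists(f)) stop("missing file: ", sub$path[k], call. = FALSE)
        rec <- read_qm_log(f, level = sub$level[k], format = format)
        rec$structure$role <- sub$role[k]
        records[[sub$level[k]]][[sub$role[k]]] <- rec
      }
      ka_txt <- sub$key_atoms[nzchar(sub$key_atoms)][1]
      if (is.na(ka_txt)) stop("no key_atoms given", call. = FALSE)
      tag <- sub$split_tag[1]
      if (is.na(tag) || !nzchar(tag)) tag <- "unassigned"
      reaction_record(id, records, .parse_key_atoms(ka_txt), split_tag = tag)
    }, error = function(e) e)
    if (inherits(res, "error")) {
      errors <- rbind(errors, data.frame(reaction_id = id,
                                         message = conditionMessage(res),
                                         stringsAsFactors = FALSE))
    } else {
      reactions[[id]] <- res
    }
  }
  if (nrow(errors)) {
    warning(sprintf("%d reaction(s) failed to load; see attr(x, 'errors')",
                    nrow(errors)), call. = FALSE)
  }
  attr(reactions, "errors") <- errors
  reactions
}

#' Save a manifest data frame
#'
#' Writes the tabular manifest (as produced by the fixtures generator)
#' back to CSV; content round-trips through [load_manifest()].
#'
#' @param df manifest data frame
#' @param path output `.csv` path
#' @return `path`, invisibly
#' @export
save_manifest <- function(df, path) {
  utils::write.csv(df, path, row.names = FALSE, quote = TRUE)
  invisible(path)
}
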