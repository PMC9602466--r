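# PDB / PDBQT fixed-column parsing.
#
# A hand-rolled reader is used deliberately: docking workflows emit PDBQT, a
# PDB dialect whose occupancy/temperature columns are replaced by partial
# charge and an AutoDock atom type, and pose files hold multiple MODEL
# blocks. Generic PDB readers reject or mangle those columns; here both
# dialects share one tolerant fixed-width path that reports the offending
# line number on malformed input.

AD_ELEMENT_MAP <- c(
  A = "C", C = "C", N = "N", "NA" = "N", OA = "O", O = "O", SA = "S", S = "S",
  HD = "H", HS = "H", H = "H", F = "F", Cl = "Cl", CL = "Cl", Br = "Br",
  BR = "Br", I = "I", P = "P", Mg = "Mg", MG = "Mg", Mn = "Mn", MN = "Mn",
  Zn = "Zn", ZN = "Zn", Ca = "Ca", CA = "Ca", Fe = "Fe", FE = "Fe"
)

parse_atom_line <- function(line, lineno, pdbqt) {
  num <- function(from, to, what) {
    v <- suppressWarnings(as.numeric(substr(line, from, to)))
    if (is.na(v)) {
      abort(sprintf("line %d: malformed %s field in ATOM/HETATM record.", lineno, what))
    }
    v
  }
  if (nchar(line) < 54) {
    abort(sprintf("line %d: truncated ATOM/HETATM record.", lineno))
  }
  atom_name <- trimws(substr(line, 13, 16))
  elem <- trimws(substr(line, 77, 78))
  charge <- NA_real_
  if (pdbqt) {
    charge <- suppressWarnings(as.numeric(substr(line, 67, 76)))
    ad_type <- trimws(substr(line, 78, 79))
    if (nzchar(ad_type) && ad_type %in% names(AD_ELEMENT_MAP)) {
      elem <- unname(AD_ELEMENT_MAP[ad_type])
    }
  }
  if (!nzchar(elem) || !grepl("^[A-Za-z]", elem)) {
    # fall back to the first letter of the atom name (strip leading digits)
    elem <- sub("^[0-9]*", "", atom_name)
    elem <- substr(elem, 1, ifelse(grepl("^(Cl|Br|CL|BR)", elem), 2, 1))
  }
  elem <- paste0(toupper(substr(elem, 1, 1)), tolower(substring(elem, 2)))
  tibble(
    serial = suppressWarnings(as.integer(substr(line, 7, 11))),
    atom_name = atom_name,
    element = elem,
    chain = trimws(substr(line, 22, 22)),
    residue_name = trimws(substr(line, 18, 20)),
    residue_number = as.integer(num(23, 26, "residue number")),
    x = num(31, 38, "x"), y = num(39, 46, "y"), z = num(47, 54, "z"),
    partial_charge = charge
  )
}

#' Read a receptor structure (PDB or PDBQT)
#'
#' Parses ATOM/HETATM records; PDBQT partial-charge and atom-type columns
#' are recognised automatically (or forced via `format`). Waters are
#' dropped by default.
#'
#' @param path structure file.
#' @param format `"auto"`, `"pdb"` or `"pdbqt"`.
#' @param drop_waters remove HOH/WAT residues.
#' @return a tibble of atoms (class `bbb_receptor`) with a `residue_key`
#'   column `"<chain>:<residue_name>:<residue_number>"`.
#' @export
read_receptor <- function(path, format = c("auto", "pdb", "pdbqt"),
                          drop_waters = TRUE) {
  format <- match.arg(format)
  if (!file.exists(path)) abort(sprintf("file not found: %s", path))
  lines <- readLines(path, warn = FALSE)
  pdbqt <- switch(format,
    pdbqt = TRUE, pdb = FALSE,
    auto = grepl("\\.pdbqt$", path, ignore.case = TRUE) ||
      any(grepl("^(ROOT|TORSDOF|BRANCH)", lines))
  )
  sel <- grep("^(ATOM|HETATM)", lines)
  if (!length(sel)) abort("no ATOM/HETATM records found.")
  atoms <- bind_rows(lapply(sel, function(i) parse_atom_line(lines[i], i, pdbqt)))
  if (drop_waters) {
    atoms <- atoms[!atoms$residue_name %in% c("HOH", "WAT"), , drop = FALSE]
  }
  atoms$residue_key <- paste(atoms$chain, atoms$residue_name, atoms$residue_number, sep = ":")
  class(atoms) <- c("bbb_receptor", class(atoms))
  atoms
}

#' Read a set of docked poses
#'
#' Multi-model PDBQT (Vina output) or SDF. One pose per MODEL / SDF record;
#' pose rank follows file order (rank 1 = best). Vina scores are picked up
#' from `REMARK VINA RESULT` lines when present.
#'
#' @param path pose file (`.pdbqt` or `.sdf`).
#' @param ligand_id identifier for the ligand; defaults to the file stem.
#' @return tibble with one row per pose: `ligand_id`, `pose_rank`, `score`,
#'   `atoms` (list of tibbles `element,x,y,z`), and for SDF input `mol`
#'   (list of `bbb_mol` carrying full chemistry).
#' @export
read_pose_set <- function(path, ligand_id = NULL) {
  if (!file.exists(path)) abort(sprintf("file not found: %s", path))
  if (is.null(ligand_id)) ligand_id <- sub("\\.[^.]*$", "", basename(path))
  if (grepl("\\.sdf$", path, ignore.case = TRUE)) {
    mols <- read_mol_sdf(path)
    if (!length(mols)) abort("no records found in pose SDF.")
    return(tibble(
      ligand_id = ligand_id,
      pose_rank = seq_along(mols),
      score = NA_real_,
      atoms = purrr::map(mols, function(m) {
        setNames(m$atoms[, c("elem", "x", "y", "z")], c("element", "x", "y", "z"))
      }),
      mol = unname(mols)
    ))
  }
  lines <- readLines(path, warn = FALSE)
  model_starts <- grep("^MODEL", lines)
  if (!length(model_starts)) {
    model_starts <- 1L
    model_ends <- length(lines)
  } else {
    model_ends <- c(model_starts[-1] - 1L, length(lines))
  }
  poses <- lapply(seq_along(model_starts), function(k) {
    block_idx <- model_starts[k]:model_ends[k]
    sel <- block_idx[grepl("^(ATOM|HETATM)", lines[block_idx])]
    if (!length(sel)) return(NULL)
    atoms <- bind_rows(lapply(sel, function(i) parse_atom_line(lines[i], i, pdbqt = TRUE)))
    score_ln <- grep("^REMARK VINA RESULT", lines[block_idx], value = TRUE)
    score <- if (length(score_ln)) {
      suppressWarnings(as.numeric(strsplit(trimws(sub("^REMARK VINA RESULT:", "", score_ln[1])), "\\s+")[[1]][1]))
    } else NA_real_
    list(atoms = atoms[, c("element", "x", "y", "z")], score = score)
  })
  poses <- poses[!vapply(poses, is.null, TRUE)]
  if (!length(poses)) abort("no poses with atoms found in file.")
  tibble(
    ligand_id = ligand_id,
    pose_rank = seq_along(poses),
    score = vapply(poses, function(p) p$score, 0),
    atoms = purrr::map(poses, "atoms")
  )
}

#' Contact residues of a docked pose
#'
#' A receptor residue is a contact iff any of its heavy atoms lies within
#' `cutoff` of any ligand heavy atom. Hydrogens on either side are ignored.
#'
#' @param pose_atoms tibble `element,x,y,z` (one pose), or a one-row slice
#'   of [read_pose_set()] output.
#' @param receptor output of [read_receptor()].
#' @param cutoff heavy-atom distance cutoff in angstrom (default 4.0).
#' @return sorted character vector of residue keys.
#' @export
contact_residues <- function(pose_atoms, receptor, cutoff = 4.0) {
  stopifnot(cutoff > 0)
  if (is.data.frame(pose_atoms) && "atoms" %in% names(pose_atoms)) {
    stopifnot(nrow(pose_atoms) == 1L)
    pose_atoms <- pose_atoms$atoms[[1]]
  }
  lig <- pose_atoms[pose_atoms$element != "H", , drop = FALSE]
  if (nrow(lig) == 0L) abort("pose has no heavy atoms.")
  rec <- receptor[receptor$element != "H", , drop = FALSE]
  lm <- as.matrix(lig[, c("x", "y", "z")])
  rm_ <- as.matrix(rec[, c("x", "y", "z")])
  # squared-distance matrix via cross product expansion
  d2 <- outer(rowSums(lm^2), rep(1, nrow(rm_))) +
    outer(rep(1, nrow(lm)), rowSums(rm_^2)) - 2 * lm %*% t(rm_)
  hit <- apply(d2 <= cutoff^2 + 1e-9, 2, any)
  sort(unique(rec$residue_key[hit]))
}

#' Residue contact frequency across ligands
#'
#' Counts, for every residue, the number of distinct ligands contacting it
#' (a residue touched several times by the same ligand counts once).
#'
#' @param contacts tibble with columns `ligand_id` and `residue_key`
#'   (one row per contact), or a list of per-ligand residue-key vectors.
#' @return tibble `residue_key`, `count`, sorted by decreasing count.
#' @export
residue_frequency <- function(contacts) {
  if (is.list(contacts) && !is.data.frame(contacts)) {
    contacts <- bind_rows(purrr::imap(contacts, function(keys, id) {
      tibble(ligand_id = id, residue_key = keys)
    }))
  }
  stopifnot(nrow(contacts) >= 1L, all(c("ligand_id", "residue_key") %in% names(contacts)))
  contacts %>%
    dplyr::distinct(.data$ligand_id, .data$residue_key) %>%
    dplyr::count(.data$residue_key, name = "count") %>%
    arrange(desc(.data$count), .data$residue_key)
}

#' Build the frequency-ranked residue schema
#'
#' Takes the top `k` residues by contact count (default 62 — the number of
#' binding-site residues retained for the residue fingerprint). Ties are
#' broken deterministically by chain then residue number, ascending. If
#' fewer than `k` residues were observed the schema is shortened with a
#' warning.
#'
#' @param freq output of [residue_frequency()].
#' @param k schema size.
#' @return character vector of residue keys (class `bbb_residue_schema`),
#'   in rank order.
#' @export
build_residue_schema <- function(freq, k = 62L) {
  stopifnot(k >= 1L)
  if (!nrow(freq)) abort("empty residue frequency table.")
  parts <- strsplit(freq$residue_key, ":", fixed = TRUE)
  chain <- vapply(parts, `[`, "", 1)
  resno <- as.integer(vapply(parts, `[`, "", 3))
  ord <- order(-freq$count, chain, resno)
  keys <- freq$residue_key[ord]
  if (length(keys) < k) {
    warn(sprintf("only %d residues observed; schema shortened from %d.", length(keys), k))
    k <- length(keys)
  }
  structure(keys[seq_len(k)], class = "bbb_residue_schema")
}

#' Residue-contact fingerprint of a pose
#'
#' Bit `i` (0-based) is set iff schema residue `i+1` is a contact of the
#' pose at the given cutoff.
#'
#' @param pose_atoms,receptor,cutoff as in [contact_residues()].
#' @param schema a [build_residue_schema()] result.
#' @return `bit_fp` of length `length(schema)`, schema id `"residue/<k>"`.
#' @export
residue_fingerprint <- function(pose_atoms, receptor, schema, cutoff = 4.0) {
  stopifnot(length(schema) >= 1L)
  hits <- contact_residues(pose_atoms, receptor, cutoff)
  bit_fp(which(schema %in% hits) - 1L, length(schema),
         sprintf("residue/%d", length(schema)))
}

#' Write / read a residue schema as plain text
#'
#' One residue key per line, rank order preserved; round-trips bit-exactly.
#'
#' @param schema `bbb_residue_schema`.
#' @param path file.
#' @export
write_residue_schema <- function(schema, path) {
  writeLines(unclass(schema), path)
  invisible(path)
}

#' @rdname write_residue_schema
#' @export
read_residue_schema <- function(path) {
  structure(readLines(path, warn = FALSE), class = "bbb_residue_schema")
}

#' Default docking-grid configuration
#'
#' Grid parameters carried as configuration for an external docking wrapper:
#' box centre (160, 145.4, 142.88) angstrom with a 40 angstrom edge, the
#' transmembrane substrate-binding channel of P-glycoprotein (PDB 6fn1).
#'
#' @return list with `center` (named numeric xyz) and `box_edge`.
#' @export
docking_config <- function() {
  list(center = c(x = 160, y = 145.4, z = 142.88), box_edge = 40)
}
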