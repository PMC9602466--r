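#' Internal molecule representation
#'
#' A `bbb_mol` holds the atom table (element, coordinates, formal charge,
#' hydrogen count), the bond table (1-based atom indices, integer bond
#' order), and the aromatic rings perceived from the connection table. It is
#' built from SDF blocks (Open Babel output or files on disk); hydrogens may
#' be explicit or implicit — `nh` always stores the total hydrogen count of
#' a heavy atom and `heavy` flags non-hydrogen atoms.
#'
#' @name bbb_mol
#' @keywords internal
NULL

DEFAULT_VALENCE <- c(
  B = 3, C = 4, N = 3, O = 2, F = 1, Si = 4, P = 3, S = 2,
  Cl = 1, Br = 1, I = 1
)

implicit_h <- function(elem, charge, bond_order_sum) {
  v <- unname(DEFAULT_VALENCE[elem])
  if (is.na(v)) return(0L)          # metals, noble gases: no implicit H
  v <- v + charge                    # N+ -> 4, O- -> 1, N- -> 2, C- -> 3
  if (elem %in% c("S", "P") && bond_order_sum > v) {
    # hypervalent sulfur / phosphorus (sulfone, phosphate)
    v <- if (elem == "S") min(6, bond_order_sum) else min(5, bond_order_sum)
  }
  max(0L, as.integer(round(v - bond_order_sum)))
}

#' Build a `bbb_mol` from a raw molfile block
#'
#' The atom/bond tables are read from the V2000 fixed-width text directly
#' (generic SDF readers mis-handle zero-bond records such as single-atom
#' molecules); a ChemmineR SDF object, when supplied, is used only for
#' ring/aromaticity perception.
#' @noRd
mol_from_chemmine <- function(sdf, block_lines, title = "") {
  counts <- block_lines[4]
  n <- suppressWarnings(as.integer(substr(counts, 1, 3)))
  nb <- suppressWarnings(as.integer(substr(counts, 4, 6)))
  if (is.na(n) || is.na(nb)) abort("malformed molfile counts line.")
  atom_lines <- block_lines[4 + seq_len(n)]
  bond_lines <- if (nb > 0) block_lines[4 + n + seq_len(nb)] else character()
  elem <- trimws(substr(atom_lines, 32, 34))
  xyz <- vapply(atom_lines, function(l) {
    c(as.numeric(substr(l, 1, 10)), as.numeric(substr(l, 11, 20)), as.numeric(substr(l, 21, 30)))
  }, numeric(3))
  # legacy molfile charge codes: 1:+3 2:+2 3:+1 5:-1 6:-2 7:-3
  code_map <- c(`1` = 3, `2` = 2, `3` = 1, `5` = -1, `6` = -2, `7` = -3)
  charge_code <- suppressWarnings(as.integer(substr(atom_lines, 37, 39)))
  charge <- ifelse(charge_code %in% names(code_map),
    code_map[as.character(charge_code)], 0
  )
  charge[is.na(charge)] <- 0
  chg_lines <- grep("^M  CHG", block_lines, value = TRUE)
  if (length(chg_lines)) {
    charge <- rep(0, n)
    for (ln in chg_lines) {
      f <- as.integer(strsplit(trimws(substring(ln, 7)), "\\s+")[[1]])
      for (j in seq_len(f[1])) charge[f[2 * j]] <- f[2 * j + 1]
    }
  }
  bonds <- if (nb == 0) {
    tibble(a1 = integer(), a2 = integer(), order = integer())
  } else {
    tibble(
      a1 = as.integer(substr(bond_lines, 1, 3)),
      a2 = as.integer(substr(bond_lines, 4, 6)),
      order = as.integer(substr(bond_lines, 7, 9))
    )
  }
  # aromatic molfile bond order 4 -> treat as order 1.5 for valence purposes
  bo <- ifelse(bonds$order == 4L, 1.5, bonds$order)
  bo_sum <- rep(0, n)
  exp_h <- rep(0L, n)
  for (i in seq_len(nrow(bonds))) {
    bo_sum[bonds$a1[i]] <- bo_sum[bonds$a1[i]] + bo[i]
    bo_sum[bonds$a2[i]] <- bo_sum[bonds$a2[i]] + bo[i]
    if (elem[bonds$a2[i]] == "H") exp_h[bonds$a1[i]] <- exp_h[bonds$a1[i]] + 1L
    if (elem[bonds$a1[i]] == "H") exp_h[bonds$a2[i]] <- exp_h[bonds$a2[i]] + 1L
  }
  nh <- vapply(seq_len(n), function(i) {
    if (elem[i] == "H") return(0L)
    exp_h[i] + implicit_h(elem[i], charge[i], bo_sum[i])
  }, 0L)
  atoms <- tibble(
    idx = seq_len(n), elem = elem,
    x = xyz[1, ], y = xyz[2, ], z = xyz[3, ],
    charge = as.numeric(charge), nh = nh, heavy = elem != "H"
  )
  rings <- if (is.null(sdf) || nrow(bonds) < 3L) {
    list(RINGS = list(), AROMATIC = logical())
  } else {
    tryCatch(
      suppressWarnings(ChemmineR::rings(sdf, upper = 10, type = "all", arom = TRUE)),
      error = function(e) list(RINGS = list(), AROMATIC = logical())
    )
  }
  arom <- list()
  if (length(rings$RINGS)) {
    keep <- which(as.logical(rings$AROMATIC))
    arom <- lapply(rings$RINGS[keep], function(r) {
      as.integer(gsub("^.*_", "", r))
    })
  }
  structure(
    list(atoms = atoms, bonds = bonds, arom_rings = arom, title = title),
    class = "bbb_mol"
  )
}

#' @export
print.bbb_mol <- function(x, ...) {
  cat(sprintf(
    "<bbb_mol '%s': %d atoms (%d heavy), %d bonds, %d aromatic ring(s)>\n",
    x$title, nrow(x$atoms), sum(x$atoms$heavy), nrow(x$bonds),
    length(x$arom_rings)
  ))
  invisible(x)
}

#' Read molecules from an SDF file
#'
#' Parses every record of a (multi-record) SDF file into the package's
#' internal molecule representation, keeping coordinates, formal charges and
#' perceived aromatic rings.
#'
#' @param path SDF file.
#' @return list of `bbb_mol`, named by record title where available.
#' @export
read_mol_sdf <- function(path) {
  lines <- readLines(path, warn = FALSE)
  sdfset <- tryCatch(
    suppressWarnings(ChemmineR::read.SDFset(path)),
    error = function(e) NULL
  )
  ends <- grep("^\\$\\$\\$\\$", lines)
  starts <- c(1L, head(ends, -1) + 1L)
  if (length(ends) == 0L) { starts <- 1L; ends <- length(lines) }
  out <- vector("list", length(starts))
  for (i in seq_along(starts)) {
    block <- lines[starts[i]:ends[i]]
    title <- trimws(block[1])
    sdf_i <- if (!is.null(sdfset) && i <= length(sdfset)) sdfset[[i]] else NULL
    out[[i]] <- mol_from_chemmine(sdf_i, block, title)
  }
  names(out) <- vapply(out, function(m) m$title, "")
  out
}

sdf_text_to_mols <- function(text) {
  f <- tempfile(fileext = ".sdf")
  on.exit(unlink(f))
  writeLines(text, f)
  read_mol_sdf(f)
}

#' Parse SMILES into molecule objects
#'
#' Converts SMILES through Open Babel to SDF connection tables (no 3D
#' coordinates) and parses them. Unparseable entries are returned as `NULL`
#' with a warning; a batch is never aborted by a single bad SMILES.
#'
#' @param smiles character vector.
#' @param ids optional identifiers (defaults to names or seq_along).
#' @return named list of `bbb_mol` (or `NULL` for failures).
#' @export
smiles_to_mols <- function(smiles, ids = NULL) {
  if (is.null(ids)) ids <- names(smiles) %||% as.character(seq_along(smiles))
  stopifnot(length(ids) == length(smiles))
  out <- setNames(vector("list", length(smiles)), ids)
  # one molecule per obabel record, titles carry the id through
  txt <- ob_run(c("-ismi", "-osdf", "-e"), stdin_text = paste(smiles, ids))
  if (length(txt)) {
    mols <- sdf_text_to_mols(txt)
    hit <- match(names(mols), ids)
    for (k in seq_along(mols)) if (!is.na(hit[k])) out[[hit[k]]] <- mols[[k]]
  }
  failed <- names(out)[vapply(out, is.null, TRUE)]
  if (length(failed)) {
    warn(paste0("could not parse ", length(failed), " SMILES: ",
                paste(head(failed, 5), collapse = ", ")))
  }
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Serialize a molecule back to a V2000 molfile block
#'
#' @param mol `bbb_mol`.
#' @param keep optional integer vector of atom indices to keep (bonds are
#'   subset accordingly); defaults to all atoms.
#' @return character vector of molfile lines (without the `$$$$` record
#'   separator).
#' @export
mol_to_molfile <- function(mol, keep = NULL) {
  atoms <- mol$atoms
  bonds <- mol$bonds
  if (!is.null(keep)) {
    keep <- sort(unique(as.integer(keep)))
    remap <- setNames(seq_along(keep), keep)
    atoms <- atoms[atoms$idx %in% keep, , drop = FALSE]
    bonds <- bonds[bonds$a1 %in% keep & bonds$a2 %in% keep, , drop = FALSE]
    bonds$a1 <- as.integer(remap[as.character(bonds$a1)])
    bonds$a2 <- as.integer(remap[as.character(bonds$a2)])
  }
  n <- nrow(atoms)
  b <- nrow(bonds)
  hdr <- c(mol$title, "  bbbfp", "", sprintf("%3d%3d  0  0  0  0  0  0  0  0999 V2000", n, b))
  atom_lines <- vapply(seq_len(n), function(i) {
    sprintf(
      "%10.4f%10.4f%10.4f %-3s 0  0  0  0  0  0  0  0  0  0  0  0",
      atoms$x[i], atoms$y[i], atoms$z[i], atoms$elem[i]
    )
  }, "")
  bond_lines <- if (b) {
    vapply(seq_len(b), function(i) {
      sprintf("%3d%3d%3d  0  0  0  0", bonds$a1[i], bonds$a2[i], bonds$order[i])
    }, "")
  } else character()
  chg <- atoms$idx
  charged <- which(atoms$charge != 0)
  prop <- character()
  if (length(charged)) {
    # at most 8 entries per M CHG line
    for (grp in split(charged, ceiling(seq_along(charged) / 8))) {
      prop <- c(prop, paste0(
        "M  CHG", sprintf("%3d", length(grp)),
        paste0(vapply(grp, function(i) sprintf("%4d%4d", match(i, atoms$idx), as.integer(atoms$charge[i])), ""), collapse = "")
      ))
    }
  }
  c(hdr, atom_lines, bond_lines, prop, "M  END")
}

#' Heavy-atom graph of a molecule
#'
#' @param mol `bbb_mol`.
#' @return an igraph with vertex attribute `aidx` (atom index in the
#'   molecule) and edge attribute `order`.
#' @export
mol_heavy_graph <- function(mol) {
  heavy <- mol$atoms$idx[mol$atoms$heavy]
  bonds <- mol$bonds[mol$bonds$a1 %in% heavy & mol$bonds$a2 %in% heavy, , drop = FALSE]
  g <- igraph::make_empty_graph(n = length(heavy), directed = FALSE)
  igraph::V(g)$aidx <- heavy
  if (nrow(bonds)) {
    ix <- match(bonds$a1, heavy)
    jx <- match(bonds$a2, heavy)
    g <- igraph::add_edges(g, rbind(ix, jx))
    igraph::E(g)$order <- bonds$order
  }
  g
}

#' Canonical SMILES through Open Babel
#'
#' @param smiles character vector of SMILES.
#' @param strip_stereo drop stereo descriptors and isotopes (the default;
#'   stereoisomers are treated as one compound throughout the package).
#' @return character vector; `NA` for entries that failed to parse.
#' @export
canonical_smiles <- function(smiles, strip_stereo = TRUE) {
  ids <- paste0("m", seq_along(smiles))
  args <- c("-ismi", "-ocan", "-e")
  if (strip_stereo) args <- c(args, "-xi")
  out <- ob_run(args, stdin_text = paste(smiles, ids))
  res <- setNames(rep(NA_character_, length(smiles)), ids)
  for (ln in out) {
    parts <- strsplit(trimws(ln), "\\s+")[[1]]
    if (length(parts) >= 2 && parts[2] %in% ids) res[parts[2]] <- parts[1]
    }
  unname(res)
}

#' Canonical SMILES of a molecule object (or a subset of its atoms)
#' @noRd
mol_canonical_smiles <- function(mol, keep = NULL) {
  txt <- c(mol_to_molfile(mol, keep), "$$$$")
  out <- ob_run(c("-isdf", "-ocan", "-xi"), stdin_text = txt)
  if (!length(out)) return(NA_character_)
  strsplit(trimws(out[1]), "\\s+")[[1]][1]
}
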