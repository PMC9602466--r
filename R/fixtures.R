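# Deterministic synthetic fixtures: idealized residue templates, engineered
# ligand fragments, and labelled SMILES libraries with planted signal.
# Geometry is synthetic by design (template internal coordinates, not real
# structure fragments); every generator records its inputs so ground truth
# is machine-readable.

RESIDUE_TEMPLATES <- list(
  GLY = rbind(
    N = c(-1.458, 0, 0), CA = c(0, 0, 0), C = c(0.55, 1.42, 0), O = c(1.78, 1.50, 0)
  ),
  ALA = rbind(
    N = c(-1.458, 0, 0), CA = c(0, 0, 0), C = c(0.55, 1.42, 0), O = c(1.78, 1.50, 0),
    CB = c(0, -1.53, 0)
  ),
  LEU = rbind(
    N = c(-1.458, 0, 0), CA = c(0, 0, 0), C = c(0.55, 1.42, 0), O = c(1.78, 1.50, 0),
    CB = c(0, -1.53, 0), CG = c(0.80, -2.62, 0.30),
    CD1 = c(0.55, -3.95, 1.00), CD2 = c(2.25, -2.33, -0.15)
  ),
  SER = rbind(
    N = c(-1.458, 0, 0), CA = c(0, 0, 0), C = c(0.55, 1.42, 0), O = c(1.78, 1.50, 0),
    CB = c(0, -1.53, 0), OG = c(0.66, -2.63, 0.52), HG = c(0.66, -2.63, 1.49)
  ),
  ASP = rbind(
    N = c(-1.458, 0, 0), CA = c(0, 0, 0), C = c(0.55, 1.42, 0), O = c(1.78, 1.50, 0),
    CB = c(0, -1.53, 0), CG = c(0.10, -3.02, 0.20),
    OD1 = c(1.15, -3.62, 0.20), OD2 = c(-0.98, -3.68, 0.20)
  ),
  LYS = rbind(
    N = c(-1.458, 0, 0), CA = c(0, 0, 0), C = c(0.55, 1.42, 0), O = c(1.78, 1.50, 0),
    CB = c(0, -1.53, 0), CG = c(0.76, -2.81, 0), CD = c(0.02, -4.12, 0),
    CE = c(0.80, -5.39, 0), NZ = c(0.06, -6.68, 0)
  ),
  PHE = rbind(
    N = c(-1.458, 0, 0), CA = c(0, 0, 0), C = c(0.55, 1.42, 0), O = c(1.78, 1.50, 0),
    CB = c(0, -1.53, 0), CG = c(0, -2.90, 0),
    CD1 = c(1.20, -3.60, 0), CD2 = c(-1.20, -3.60, 0),
    CE1 = c(1.20, -4.99, 0), CE2 = c(-1.20, -4.99, 0), CZ = c(0, -5.68, 0)
  )
)

PHE_RING_CENTROID <- c(0, -4.29, 0)
ASP_CARBOXYLATE_MID <- c(0.085, -3.65, 0.20)

rot_x <- function(theta) {
  c_ <- cos(theta); s_ <- sin(theta)
  matrix(c(1, 0, 0, 0, c_, -s_, 0, s_, c_), 3, 3, byrow = TRUE)
}

#' Place a template residue in space
#'
#' Rigidly moves an idealized residue template so that `anchor` (an atom
#' name, or `"ring"` / `"carboxylate"` for the PHE centroid and ASP
#' carboxylate midpoint) lands on `anchor_pos` after applying `rotation`.
#'
#' @param resname template name (GLY, ALA, LEU, SER, ASP, LYS, PHE).
#' @param anchor anchor point name.
#' @param anchor_pos length-3 target position.
#' @param rotation 3x3 rotation matrix.
#' @return tibble `atom_name`, `element`, `x`, `y`, `z`.
#' @export
place_residue <- function(resname, anchor, anchor_pos, rotation = diag(3)) {
  tpl <- RESIDUE_TEMPLATES[[resname]]
  if (is.null(tpl)) abort(sprintf("no template for residue '%s'.", resname))
  a0 <- switch(anchor,
    ring = PHE_RING_CENTROID,
    carboxylate = ASP_CARBOXYLATE_MID,
    {
      if (!anchor %in% rownames(tpl)) abort(sprintf("no atom '%s' in %s.", anchor, resname))
      tpl[anchor, ]
    }
  )
  moved <- t(rotation %*% t(sweep(tpl, 2, a0))) + rep(anchor_pos, each = nrow(tpl))
  tibble(
    atom_name = rownames(tpl),
    element = substr(rownames(tpl), 1, 1),
    x = moved[, 1], y = moved[, 2], z = moved[, 3]
  )
}

pdb_lines <- function(residues) {
  # residues: list of list(resname, resno, atoms tibble)
  serial <- 0L
  out <- character()
  for (r in residues) {
    for (i in seq_len(nrow(r$atoms))) {
      serial <- serial + 1L
      out <- c(out, sprintf(
        "ATOM  %5d %-4s %3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
        serial, r$atoms$atom_name[i], r$resname, "A", r$resno,
        r$atoms$x[i], r$atoms$y[i], r$atoms$z[i], 1.00, 0.00, r$atoms$element[i]
      ))
    }
  }
  c(out, "END")
}

# ligand fragments: atoms (element, dx, dy, dz relative to the station
# anchor), bonds (i, j, order), charges (atom index -> formal charge)
LIGAND_FRAGMENTS <- list(
  methane = list(
    atoms = rbind(C = c(0, 0, 0)),
    bonds = NULL, charges = NULL
  ),
  ethanol = list(
    atoms = rbind(
      O = c(0, 0, 0), H = c(0, 0, -0.97), C2 = c(1.17, 0, 0.75), C1 = c(2.17, 0, 1.85)
    ),
    bonds = cbind(c(1, 1, 3), c(2, 3, 4), c(1, 1, 1)), charges = NULL
  ),
  acetone = list(
    atoms = rbind(
      O = c(0, 0, 0), C2 = c(0, 0, 1.22),
      C1 = c(1.29, 0, 1.97), C3 = c(-1.29, 0, 1.97)
    ),
    bonds = cbind(c(1, 2, 2), c(2, 3, 4), c(2, 1, 1)), charges = NULL
  ),
  methylammonium = list(
    atoms = rbind(N = c(0, 0, 0), C = c(0, 0, 1.50)),
    bonds = cbind(1, 2, 1), charges = c(N = 1)
  ),
  acetate = list(
    atoms = rbind(
      O1 = c(0, 0, 0), C = c(0.55, 0, 1.12), O2 = c(1.70, 0, 0.64),
      CM = c(0.55, 0, 2.62)
    ),
    bonds = cbind(c(1, 2, 2), c(2, 3, 4), c(1, 2, 1)), charges = c(O1 = -1)
  ),
  benzene = list(
    atoms = {
      th <- seq(0, by = pi / 3, length.out = 6)
      m <- cbind(1.39 * cos(th), 1.39 * sin(th), 0)
      rownames(m) <- paste0("C", 1:6)
      m
    },
    bonds = cbind(1:6, c(2:6, 1), rep(c(2, 1), 3)), charges = NULL
  ),
  benzene_tilted = list(
    atoms = {
      # plane normal tilted 75 degrees from z
      u <- c(cos(75 * pi / 180), 0, -sin(75 * pi / 180))
      v <- c(0, 1, 0)
      th <- seq(0, by = pi / 3, length.out = 6)
      m <- t(vapply(th, function(t_) 1.39 * (cos(t_) * u + sin(t_) * v), numeric(3)))
      rownames(m) <- paste0("C", 1:6)
      m
    },
    bonds = cbind(1:6, c(2:6, 1), rep(c(2, 1), 3)), charges = NULL
  )
)

# one engineered station per interaction type: residue placement, ligand
# fragment placement, and the implied ground-truth type set
STATIONS <- list(
  Hydrophobic = list(
    residue = "LEU", anchor = "CD1", lig = "methane", lig_offset = c(0, 0, 4.0),
    implied = "Hydrophobic"
  ),
  HBDonor = list(
    residue = "GLY", anchor = "O", lig = "ethanol", lig_offset = c(0, 0, 2.9),
    implied = c("HBDonor", "VdWContact")
  ),
  HBAcceptor = list(
    residue = "SER", anchor = "OG", lig = "acetone", lig_offset = c(0, 0, 2.9),
    implied = c("HBAcceptor", "VdWContact")
  ),
  Cationic = list(
    residue = "ASP", anchor = "carboxylate", lig = "methylammonium",
    lig_offset = c(0, 0, 4.2), implied = "Cationic"
  ),
  Anionic = list(
    residue = "LYS", anchor = "NZ", lig = "acetate", lig_offset = c(0, 0, 4.2),
    implied = "Anionic"
  ),
  CationPi = list(
    residue = "PHE", anchor = "ring", lig = "methylammonium",
    lig_offset = c(0, 0, 4.0), implied = "CationPi"
  ),
  PiCation = list(
    residue = "LYS", anchor = "NZ", lig = "benzene", lig_offset = c(0, 0, -4.0),
    rotation = "up", implied = "PiCation"
  ),
  PiStacking = list(
    residue = "PHE", anchor = "ring", lig = "benzene_tilted",
    lig_offset = c(0, 0, 6.2), implied = "PiStacking"
  ),
  VdWContact = list(
    residue = "GLY", anchor = "O", lig = "methane", lig_offset = c(0, 0, 2.92),
    implied = "VdWContact"
  )
)

fragment_molfile_parts <- function(frag, shift) {
  at <- frag$atoms
  tibble(
    element = sub("[0-9]*$", "", rownames(at)),
    x = at[, 1] + shift[1], y = at[, 2] + shift[2], z = at[, 3] + shift[3],
    charge = {
      ch <- rep(0, nrow(at))
      if (!is.null(frag$charges)) ch[match(names(frag$charges), rownames(at))] <- frag$charges
      ch
    }
  )
}

#' Build a toy protein-ligand complex realizing chosen interaction types
#'
#' For every requested interaction type, one engineered residue/fragment
#' pair is placed at its own station (stations 28 angstrom apart, so
#' stations cannot cross-talk); the geometry at each station satisfies its
#' type's thresholds with a safety margin. The pose is a single
#' (multi-fragment) SDF record; the receptor is PDB text. Hydrogen-bond
#' stations necessarily also satisfy the van der Waals contact criterion
#' (donor-acceptor pairs sit inside the Bondi radius sum), so their ground
#' truth includes `VdWContact`.
#'
#' @param types character subset of [interaction_types()] (empty for a
#'   no-contact complex).
#' @param seed recorded in the file headers (generation is deterministic).
#' @return list: `receptor_pdb` (lines), `pose_sdf` (lines), `truth`
#'   (tibble `type`, `residue_key`), `spec` (the request).
#' @export
make_toy_complex <- function(types = character(), seed = 1L) {
  bad <- setdiff(types, interaction_types())
  if (length(bad)) abort(sprintf("unknown interaction type(s): %s", paste(bad, collapse = ", ")))
  types <- interaction_types()[interaction_types() %in% types]
  residues <- list()
  lig_atoms <- list()
  lig_bonds <- list()
  truth <- list()
  if (!length(types)) {
    residues[[1]] <- list(
      resname = "GLY", resno = 1L,
      atoms = place_residue("GLY", "CA", c(0, 0, 0))
    )
    lig_atoms[[1]] <- fragment_molfile_parts(LIGAND_FRAGMENTS$methane, c(0, 0, 30))
  }
  for (s in seq_along(types)) {
    st <- STATIONS[[types[s]]]
    origin <- c(28 * (s - 1), 0, 0)
    rot <- if (identical(st$rotation, "up")) rot_x(pi / 2) else diag(3)
    anchor_pos <- origin
    lig_shift <- origin + st$lig_offset
    if (types[s] == "PiCation") {
      # ligand ring at the origin plane, LYS NZ 4 angstrom above it
      anchor_pos <- origin + c(0, 0, 4.0)
      lig_shift <- origin
    }
    residues[[length(residues) + 1L]] <- list(
      resname = st$residue, resno = s,
      atoms = place_residue(st$residue, st$anchor, anchor_pos, rot)
    )
    n_before <- sum(vapply(lig_atoms, nrow, 0L))
    lig_atoms[[length(lig_atoms) + 1L]] <- fragment_molfile_parts(
      LIGAND_FRAGMENTS[[st$lig]], lig_shift
    )
    fb <- LIGAND_FRAGMENTS[[st$lig]]$bonds
    if (!is.null(fb)) {
      lig_bonds[[length(lig_bonds) + 1L]] <- cbind(fb[, 1] + n_before, fb[, 2] + n_before, fb[, 3])
    }
    truth[[length(truth) + 1L]] <- tibble(
      type = st$implied, residue_key = paste("A", st$residue, s, sep = ":")
    )
  }
  atoms <- bind_rows(lig_atoms)
  bonds <- if (length(lig_bonds)) do.call(rbind, lig_bonds) else matrix(numeric(), ncol = 3)
  n <- nrow(atoms)
  b <- nrow(bonds)
  sdf <- c(
    sprintf("toy_pose seed=%d", seed), "  bbbfp fixtures", "",
    sprintf("%3d%3d  0  0  0  0  0  0  0  0999 V2000", n, b),
    vapply(seq_len(n), function(i) {
      sprintf(
        "%10.4f%10.4f%10.4f %-3s 0  0  0  0  0  0  0  0  0  0  0  0",
        atoms$x[i], atoms$y[i], atoms$z[i], atoms$element[i]
      )
    }, ""),
    if (b) vapply(seq_len(b), function(i) {
      sprintf("%3d%3d%3d  0  0  0  0", as.integer(bonds[i, 1]), as.integer(bonds[i, 2]), as.integer(bonds[i, 3]))
    }, "") else character(),
    {
      ch <- which(atoms$charge != 0)
      if (length(ch)) {
        sprintf(
          "M  CHG%3d%s", length(ch),
          paste0(vapply(ch, function(i) sprintf("%4d%4d", i, as.integer(atoms$charge[i])), ""), collapse = "")
        )
      } else character()
    },
    "M  END", "$$$$"
  )
  pdb <- c(
    sprintf("REMARK   1 bbbfp toy complex seed=%d types=%s", seed,
            paste(types, collapse = "+")),
    pdb_lines(residues)
  )
  truth_tbl <- if (length(truth)) bind_rows(truth) else {
    tibble(type = character(), residue_key = character())
  }
  list(receptor_pdb = pdb, pose_sdf = sdf, truth = truth_tbl,
       spec = list(types = types, seed = seed))
}

#' Write a toy complex to a directory
#'
#' @param complex [make_toy_complex()] output.
#' @param dir output directory (created if needed).
#' @return paths of the written files, invisibly.
#' @export
write_toy_complex <- function(complex, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  rp <- file.path(dir, "receptor.pdb")
  pp <- file.path(dir, "pose_1.sdf")
  tp <- file.path(dir, "truth.json")
  writeLines(complex$receptor_pdb, rp)
  writeLines(complex$pose_sdf, pp)
  jsonlite::write_json(
    list(types = complex$spec$types, seed = complex$spec$seed,
         truth = complex$truth),
    tp, auto_unbox = TRUE, digits = NA
  )
  invisible(c(receptor = rp, pose = pp, truth = tp))
}

#' Random synthetic complex for geometric-oracle testing
#'
#' Samples residues from the template set with random rigid placements
#' around randomly chosen ligand fragments at interaction-scale distances
#' (2.5-9 angstrom). No ground truth is attached — these complexes exist to
#' compare the typed detector against brute-force re-derivation.
#'
#' @param seed RNG seed.
#' @param n_residues number of residues to place.
#' @return list with `receptor` (parsed receptor tibble), `mol`
#'   (`bbb_mol` pose) plus the raw text (`receptor_pdb`, `pose_sdf`).
#' @export
make_random_complex <- function(seed = 1L, n_residues = 4L) {
  withr::with_seed(seed, {
    frag_names <- sample(names(LIGAND_FRAGMENTS), 2L)
    lig_atoms <- list(); lig_bonds <- list()
    shift2 <- c(stats::runif(1, 4, 7), stats::runif(1, -2, 2), stats::runif(1, -2, 2))
    shifts <- list(c(0, 0, 0), shift2)
    for (k in 1:2) {
      frag <- LIGAND_FRAGMENTS[[frag_names[k]]]
      n_before <- sum(vapply(lig_atoms, nrow, 0L))
      lig_atoms[[k]] <- fragment_molfile_parts(frag, shifts[[k]])
      if (!is.null(frag$bonds)) {
        lig_bonds[[length(lig_bonds) + 1L]] <-
          cbind(frag$bonds[, 1] + n_before, frag$bonds[, 2] + n_before, frag$bonds[, 3])
      }
    }
    atoms <- bind_rows(lig_atoms)
    residues <- lapply(seq_len(n_residues), function(i) {
      rn <- sample(names(RESIDUE_TEMPLATES), 1)
      u <- stats::rnorm(3); u <- u / sqrt(sum(u^2))
      d <- stats::runif(1, 2.5, 9)
      center <- colMeans(atoms[, c("x", "y", "z")])
      ang <- stats::runif(3, 0, 2 * pi)
      R <- rot_x(ang[1]) %*%
        matrix(c(cos(ang[2]), -sin(ang[2]), 0, sin(ang[2]), cos(ang[2]), 0, 0, 0, 1), 3, 3) %*%
        rot_x(ang[3])
      list(resname = rn, resno = i,
           atoms = place_residue(rn, "CA", unlist(center) + d * u, R))
    })
  })
  bonds <- if (length(lig_bonds)) do.call(rbind, lig_bonds) else matrix(numeric(), ncol = 3)
  n <- nrow(atoms); b <- nrow(bonds)
  sdf <- c(
    sprintf("random_pose seed=%d", seed), "  bbbfp fixtures", "",
    sprintf("%3d%3d  0  0  0  0  0  0  0  0999 V2000", n, b),
    vapply(seq_len(n), function(i) sprintf(
      "%10.4f%10.4f%10.4f %-3s 0  0  0  0  0  0  0  0  0  0  0  0",
      atoms$x[i], atoms$y[i], atoms$z[i], atoms$element[i]
    ), ""),
    if (b) vapply(seq_len(b), function(i) sprintf(
      "%3d%3d%3d  0  0  0  0", as.integer(bonds[i, 1]), as.integer(bonds[i, 2]), as.integer(bonds[i, 3])
    ), "") else character(),
    {
      ch <- which(atoms$charge != 0)
      if (length(ch)) sprintf(
        "M  CHG%3d%s", length(ch),
        paste0(vapply(ch, function(i) sprintf("%4d%4d", i, as.integer(atoms$charge[i])), ""), collapse = "")
      ) else character()
    },
    "M  END", "$$$$"
  )
  pdb <- c(sprintf("REMARK   1 bbbfp random complex seed=%d", seed), pdb_lines(residues))
  rec_file <- tempfile(fileext = ".pdb"); pose_file <- tempfile(fileext = ".sdf")
  writeLines(pdb, rec_file); writeLines(sdf, pose_file)
  out <- list(
    receptor = read_receptor(rec_file), mol = read_mol_sdf(pose_file)[[1]],
    receptor_pdb = pdb, pose_sdf = sdf
  )
  unlink(c(rec_file, pose_file))
  out
}

#' Synthetic per-ligand contact records with known frequencies
#'
#' Draws, for each synthetic substrate, a random subset of a residue pool
#' (each residue kept with probability 0.5, at least one kept) and returns
#' both the contact records and the implied ground-truth frequency table.
#'
#' @param n_substrates number of ligands.
#' @param residue_pool character vector of residue keys.
#' @param seed RNG seed.
#' @return list: `contacts` (tibble `ligand_id`, `residue_key`), `truth`
#'   (tibble `residue_key`, `count`).
#' @export
make_substrate_contacts <- function(n_substrates, residue_pool, seed = 1L) {
  stopifnot(n_substrates >= 1L, length(residue_pool) >= 1L)
  rows <- withr::with_seed(seed, {
    lapply(seq_len(n_substrates), function(i) {
      keep <- residue_pool[stats::runif(length(residue_pool)) < 0.5]
      if (!length(keep)) keep <- sample(residue_pool, 1L)
      tibble(ligand_id = sprintf("lig%03d", i), residue_key = keep)
    })
  })
  contacts <- bind_rows(rows)
  truth <- contacts %>%
    dplyr::distinct(.data$ligand_id, .data$residue_key) %>%
    dplyr::count(.data$residue_key, name = "count") %>%
    arrange(desc(.data$count), .data$residue_key)
  list(contacts = contacts, truth = truth)
}

SCAFFOLD_POOL <- c(
  benzene = "c1ccc(%s)cc1",
  pyridine = "c1ccnc(%s)c1",
  cyclohexane = "C1CCC(%s)CC1",
  naphthalene = "c1ccc2cc(%s)ccc2c1",
  thiophene = "c1cc(%s)sc1",
  furan = "c1cc(%s)oc1",
  piperidine = "C1CCN(%s)CC1",
  pyrimidine = "c1cnc(%s)nc1",
  tetrahydropyran = "C1CCOC(%s)C1",
  cyclopentane = "C1CCC(%s)C1"
)

POSITIVE_SUBSTITUENTS <- c("CC(=O)O", "CCC(=O)O", "C(=O)O", "CC(C)C(=O)O")
NEGATIVE_SUBSTITUENTS <- c("C", "CC", "CCC", "Cl", "C(C)C")

# planted permeation probability per scaffold pool entry: spans permeable
# (>0.6), neutral ([0.4,0.6]) and non-permeable (<0.4) categories
SCAFFOLD_POOL_FRACTION <- c(
  benzene = 1.0, pyridine = 0.9, cyclohexane = 0.8, naphthalene = 0.7,
  thiophene = 0.6, furan = 0.5, piperidine = 0.4, pyrimidine = 0.3,
  tetrahydropyran = 0.1, cyclopentane = 0.0
)

#' Synthetic labelled SMILES library with planted substructure signal
#'
#' Molecules are scaffolds from a fixed 10-member pool decorated with one
#' substituent; the planted rule labels carboxylic-acid-bearing molecules
#' permeable, and each scaffold receives positives at a fixed planted
#' fraction (1.0 down to 0.0 across the pool, spanning the permeable /
#' neutral / non-permeable categories). Scaffold assignment and planted
#' labels are deterministic, so the scaffold partition and per-scaffold
#' positive fractions are identical across seeds; the seed drives only the
#' substituent choice within a class and the label-noise mask.
#'
#' @param n library size.
#' @param noise fraction of labels flipped (in \[0, 0.5)).
#' @param seed RNG seed.
#' @return list: `library` (tibble `id`, `smiles`, `label`), `truth`
#'   (tibble `id`, `scaffold_name`, `planted_label`, `flipped`, plus the
#'   per-scaffold planted fraction in `attr(truth, "scaffold_fraction")`).
#' @export
make_labeled_library <- function(n = 200L, noise = 0, seed = 1L) {
  stopifnot(n >= 2L, noise >= 0, noise < 0.5)
  idx <- seq_len(n)
  pool_n <- length(SCAFFOLD_POOL)
  scaffold_name <- names(SCAFFOLD_POOL)[(idx - 1L) %% pool_n + 1L]
  occurrence <- (idx - 1L) %/% pool_n + 1L
  frac <- SCAFFOLD_POOL_FRACTION[scaffold_name]
  # Bresenham-style spreading: after any number of occurrences a scaffold's
  # positive count is floor(occurrences * fraction), so the realized
  # fraction is always within 1/occurrences of the planted one
  planted <- as.integer(floor(occurrence * frac) - floor((occurrence - 1L) * frac) == 1L)
  out <- withr::with_seed(seed, {
    sub <- ifelse(
      planted == 1L,
      sample(POSITIVE_SUBSTITUENTS, n, replace = TRUE),
      sample(NEGATIVE_SUBSTITUENTS, n, replace = TRUE)
    )
    flipped <- stats::runif(n) < noise
    list(sub = sub, flipped = flipped)
  })
  smiles <- sprintf(unname(SCAFFOLD_POOL[scaffold_name]), out$sub)
  label <- ifelse(out$flipped, 1L - planted, planted)
  truth <- tibble(
    id = sprintf("lib%04d", idx), scaffold_name = scaffold_name,
    planted_label = planted, flipped = out$flipped
  )
  attr(truth, "scaffold_fraction") <- SCAFFOLD_POOL_FRACTION
  list(
    library = tibble(id = sprintf("lib%04d", idx), smiles = smiles, label = label),
    truth = truth
  )
}
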