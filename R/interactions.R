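#' The fixed 9-type interaction schema
#'
#' Order is fixed and serialized with every interaction fingerprint:
#' Hydrophobic, HBDonor, HBAcceptor, Cationic, Anionic, CationPi, PiCation,
#' PiStacking, VdWContact. Donor/acceptor and cation/pi directions are named
#' from the ligand's point of view (HBDonor = ligand donates the hydrogen
#' bond; CationPi = ligand cation over a protein ring).
#'
#' @return character vector of length 9.
#' @export
interaction_types <- function() {
  c(
    "Hydrophobic", "HBDonor", "HBAcceptor", "Cationic", "Anionic",
    "CationPi", "PiCation", "PiStacking", "VdWContact"
  )
}

#' Default geometric thresholds for interaction typing
#'
#' Distances in angstrom, angles in degrees. These are the package defaults
#' for every typed contact: hydrophobic carbon pairs at 4.5; hydrogen bonds
#' at 3.5 with a D-H...A angle of at least 130 degrees when an explicit
#' hydrogen is available (distance-only otherwise); salt bridges at 4.5
#' between charge centres; cation-pi at 4.5 with the cation within 30
#' degrees of the ring normal; pi-stacking face-to-face at 5.5 within 30
#' degrees plane angle or edge-to-face at 6.5 with plane angle 50-90; and
#' van der Waals contacts at the Bondi radius sum plus `vdw_tolerance`.
#'
#' @return named list of thresholds.
#' @export
default_interaction_config <- function() {
  list(
    hydrophobic_max = 4.5,
    hbond_max = 3.5,
    hbond_angle_min = 130,
    ionic_max = 4.5,
    cation_pi_max = 4.5,
    cation_pi_angle_max = 30,
    pi_stack_ftf_max = 5.5,
    pi_stack_ftf_angle_max = 30,
    pi_stack_etf_max = 6.5,
    pi_stack_etf_angle = c(50, 90),
    vdw_tolerance = 0.0
  )
}

#' Bondi van der Waals radii (angstrom)
#'
#' @param elements character vector of element symbols.
#' @return numeric vector of radii; unlisted elements fall back to 1.70.
#' @export
vdw_radius <- function(elements) {
  tbl <- c(
    H = 1.20, C = 1.70, N = 1.55, O = 1.52, F = 1.47, Si = 2.10, P = 1.80,
    S = 1.80, Cl = 1.75, Br = 1.85, I = 1.98, He = 1.40, Ne = 1.54,
    Ar = 1.88, Kr = 2.02, Xe = 2.16, Zn = 1.39, Mg = 1.73
  )
  r <- unname(tbl[elements])
  r[is.na(r)] <- 1.70
  r
}

empty_features <- function() {
  list(
    hydrophobic = tibble(x = numeric(), y = numeric(), z = numeric(), atom = integer()),
    donors = tibble(x = numeric(), y = numeric(), z = numeric(), atom = integer(), h = list()),
    acceptors = tibble(x = numeric(), y = numeric(), z = numeric(), atom = integer()),
    cations = tibble(x = numeric(), y = numeric(), z = numeric(), atom = integer()),
    anions = tibble(x = numeric(), y = numeric(), z = numeric(), atom = integer()),
    rings = list(),
    atoms = tibble(element = character(), x = numeric(), y = numeric(), z = numeric())
  )
}

plane_fit <- function(coords) {
  centroid <- colMeans(coords)
  sv <- svd(sweep(coords, 2, centroid))
  normal <- sv$v[, 3]
  normal <- normal / sqrt(sum(normal^2))
  list(centroid = centroid, normal = normal)
}

#' Perceive pharmacophoric features of a ligand pose
#'
#' Assigns chemistry-aware feature sets from the molecule's connection
#' table and 3D coordinates: hydrogen-bond donors (N/O carrying at least
#' one hydrogen, explicit hydrogens kept for angle checks), acceptors
#' (O, and trivalent non-cationic N that is not a pyrrole-type NH),
#' cation and anion centres (formally charged heavy atoms), hydrophobes
#' (uncharged C/S/Cl/Br/I with no N/O or charged neighbour), and aromatic
#' rings with centroid and unit normal.
#'
#' @param mol `bbb_mol` with 3D coordinates (e.g. an SDF pose).
#' @return feature-set list (`hydrophobic`, `donors`, `acceptors`,
#'   `cations`, `anions`, `rings`, `atoms`).
#' @export
perceive_ligand_features <- function(mol) {
  stopifnot(inherits(mol, "bbb_mol"))
  at <- mol$atoms
  if (all(abs(at$z) < 1e-12) && all(abs(at$x) < 1e-12) && all(abs(at$y) < 1e-12) &&
      nrow(at) > 1) {
    abort("molecule has no coordinates; interaction typing needs a 3D pose.")
  }
  fs <- empty_features()
  nbrs <- function(i) {
    c(mol$bonds$a2[mol$bonds$a1 == i], mol$bonds$a1[mol$bonds$a2 == i])
  }
  heavy <- which(at$heavy)
  arom_atoms <- unique(unlist(mol$arom_rings))
  pt <- function(i) tibble(x = at$x[i], y = at$y[i], z = at$z[i], atom = i)

  for (i in heavy) {
    el <- at$elem[i]
    nb <- nbrs(i)
    nb_heavy <- nb[at$heavy[nb]]
    nb_h <- nb[!at$heavy[nb]]
    if (el %in% c("N", "O") && at$nh[i] >= 1L) {
      d <- pt(i)
      d$h <- list(cbind(at$x[nb_h], at$y[nb_h], at$z[nb_h]))
      fs$donors <- bind_rows(fs$donors, d)
    }
    bo_sum <- sum(ifelse(
      mol$bonds$order[mol$bonds$a1 == i | mol$bonds$a2 == i] == 4L, 1.5,
      mol$bonds$order[mol$bonds$a1 == i | mol$bonds$a2 == i]
    )) + at$nh[i]
    if (el == "O" && at$charge[i] <= 0) {
      fs$acceptors <- bind_rows(fs$acceptors, pt(i))
    }
    if (el == "N" && at$charge[i] <= 0 && bo_sum <= 3 &&
        !(i %in% arom_atoms && at$nh[i] >= 1L)) {
      fs$acceptors <- bind_rows(fs$acceptors, pt(i))
    }
    if (at$charge[i] > 0) fs$cations <- bind_rows(fs$cations, pt(i))
    if (at$charge[i] < 0) fs$anions <- bind_rows(fs$anions, pt(i))
    if (el %in% c("C", "S", "Cl", "Br", "I") && at$charge[i] == 0 &&
        !any(at$elem[nb_heavy] %in% c("N", "O")) &&
        !any(at$charge[nb_heavy] != 0)) {
      fs$hydrophobic <- bind_rows(fs$hydrophobic, pt(i))
    }
  }
  fs$rings <- lapply(mol$arom_rings, function(r) {
    co <- as.matrix(at[r, c("x", "y", "z")])
    c(plane_fit(co), list(members = r))
  })
  fs$atoms <- tibble(
    element = at$elem[heavy], x = at$x[heavy], y = at$y[heavy], z = at$z[heavy]
  )
  fs
}

# Template chemistry of the standard amino acids. Receptor files carry no
# bond orders, so features are assigned by residue and atom name.
RESIDUE_CHEM <- list(
  donor_atoms = list(
    SER = "OG", THR = "OG1", TYR = "OH", CYS = "SG", ASN = "ND2",
    GLN = "NE2", LYS = "NZ", ARG = c("NE", "NH1", "NH2"), TRP = "NE1",
    HIS = c("ND1", "NE2"), HIP = c("ND1", "NE2")
  ),
  acceptor_atoms = list(
    ASP = c("OD1", "OD2"), GLU = c("OE1", "OE2"), ASN = "OD1", GLN = "OE1",
    SER = "OG", THR = "OG1", TYR = "OH", HIS = c("ND1", "NE2"), MET = "SD"
  ),
  cation_atoms = list(LYS = "NZ", ARG = "CZ", HIP = "ND1", HSP = "ND1"),
  anion_pairs = list(ASP = c("OD1", "OD2"), GLU = c("OE1", "OE2")),
  ring_atoms = list(
    PHE = list(c("CG", "CD1", "CD2", "CE1", "CE2", "CZ")),
    TYR = list(c("CG", "CD1", "CD2", "CE1", "CE2", "CZ")),
    HIS = list(c("CG", "ND1", "CD2", "CE1", "NE2")),
    HIP = list(c("CG", "ND1", "CD2", "CE1", "NE2")),
    TRP = list(
      c("CG", "CD1", "NE1", "CE2", "CD2"),
      c("CD2", "CE2", "CZ2", "CH2", "CZ3", "CE3")
    )
  ),
  hydrophobe_atoms = list(
    ALA = "CB", VAL = c("CB", "CG1", "CG2"), LEU = c("CB", "CG", "CD1", "CD2"),
    ILE = c("CB", "CG1", "CG2", "CD1"), MET = c("CB", "CG", "SD", "CE"),
    PHE = c("CB", "CG", "CD1", "CD2", "CE1", "CE2", "CZ"),
    TYR = c("CB", "CG", "CD1", "CD2", "CE1", "CE2"),
    TRP = c("CB", "CG", "CE3", "CZ3", "CH2", "CZ2"),
    PRO = c("CB", "CG"), LYS = c("CB", "CG", "CD"), ARG = c("CB", "CG"),
    GLU = c("CB", "CG"), ASP = "CB", ASN = "CB", GLN = c("CB", "CG"),
    THR = "CG2", CYS = c("CB", "SG"), HIS = "CB", HIP = "CB"
  )
)

STANDARD_RESIDUES <- c(
  "ALA", "ARG", "ASN", "ASP", "CYS", "GLN", "GLU", "GLY", "HIS", "HIP",
  "HSP", "ILE", "LEU", "LYS", "MET", "PHE", "PRO", "SER", "THR", "TRP",
  "TYR", "VAL"
)

#' Perceive features of every receptor residue
#'
#' Template-based assignment by residue and atom name: LYS/ARG (and
#' protonated histidine HIP/HSP) contribute cation centres, ASP/GLU anion
#' centres at the carboxylate midpoint, PHE/TYR/TRP/HIS aromatic rings,
#' backbone N/O plus polar side chains donors/acceptors, and
#' aliphatic/aromatic carbons hydrophobes. Residues with unknown names are
#' skipped with a warning.
#'
#' @param receptor output of [read_receptor()].
#' @return named list (by residue key) of feature sets as in
#'   [perceive_ligand_features()].
#' @export
perceive_residue_features <- function(receptor) {
  out <- list()
  skipped <- character()
  for (key in unique(receptor$residue_key)) {
    res <- receptor[receptor$residue_key == key, , drop = FALSE]
    rn <- res$residue_name[1]
    if (!rn %in% STANDARD_RESIDUES) {
      skipped <- c(skipped, key)
      next
    }
    fs <- empty_features()
    co <- function(names_) {
      res[res$atom_name %in% names_, c("x", "y", "z"), drop = FALSE]
    }
    grab <- function(names_) {
      m <- co(names_)
      if (nrow(m)) tibble(x = m$x, y = m$y, z = m$z, atom = NA_integer_) else NULL
    }
    hres <- res[res$element == "H", , drop = FALSE]
    add_donor <- function(names_) {
      m <- res[res$atom_name %in% names_, , drop = FALSE]
      for (i in seq_len(nrow(m))) {
        if (nrow(hres)) {
          dh <- sqrt((hres$x - m$x[i])^2 + (hres$y - m$y[i])^2 + (hres$z - m$z[i])^2)
          hm <- as.matrix(hres[dh < 1.3, c("x", "y", "z")])
        } else hm <- matrix(numeric(), ncol = 3)
        fs$donors <<- bind_rows(fs$donors, tibble(
          x = m$x[i], y = m$y[i], z = m$z[i], atom = NA_integer_, h = list(hm)
        ))
      }
    }
    if (rn != "PRO") add_donor("N")
    add_donor(RESIDUE_CHEM$donor_atoms[[rn]] %||% character())
    acc <- grab(c("O", "OXT", RESIDUE_CHEM$acceptor_atoms[[rn]] %||% character()))
    if (!is.null(acc)) fs$acceptors <- acc
    cat_ <- grab(RESIDUE_CHEM$cation_atoms[[rn]] %||% character())
    if (!is.null(cat_)) fs$cations <- cat_
    ap <- RESIDUE_CHEM$anion_pairs[[rn]]
    if (!is.null(ap)) {
      m <- co(ap)
      if (nrow(m) == 2L) {
        fs$anions <- tibble(
          x = mean(m$x), y = mean(m$y), z = mean(m$z), atom = NA_integer_
        )
      } else if (nrow(m) > 0L) {
        fs$anions <- tibble(x = m$x, y = m$y, z = m$z, atom = NA_integer_)
      }
    }
    hyd <- grab(RESIDUE_CHEM$hydrophobe_atoms[[rn]] %||% character())
    if (!is.null(hyd)) fs$hydrophobic <- hyd
    for (ring_names in RESIDUE_CHEM$ring_atoms[[rn]] %||% list()) {
      m <- co(ring_names)
      if (nrow(m) >= 5L) {
        fs$rings <- c(fs$rings, list(c(plane_fit(as.matrix(m)), list(members = ring_names))))
      }
    }
    hv <- res[res$element != "H", , drop = FALSE]
    fs$atoms <- tibble(element = hv$element, x = hv$x, y = hv$y, z = hv$z)
    out[[key]] <- fs
  }
  if (length(skipped)) {
    warn(paste0(
      "skipped ", length(skipped), " residue(s) with non-standard names: ",
      paste(head(skipped, 5), collapse = ", ")
    ))
  }
  out
}

vec_angle <- function(u, v) {
  cosang <- sum(u * v) / sqrt(sum(u^2) * sum(v^2))
  acos(pmin(1, pmax(-1, cosang))) * 180 / pi
}

dist3 <- function(p, q) sqrt(sum((p - q)^2))

hbond_geometry_ok <- function(donor_xyz, donor_h, acceptor_xyz, cfg) {
  d <- dist3(donor_xyz, acceptor_xyz)
  if (d > cfg$hbond_max) return(NULL)
  angle <- NA_real_
  if (!is.null(donor_h) && nrow(donor_h) > 0L) {
    angles <- apply(donor_h, 1, function(h) {
      vec_angle(donor_xyz - h, acceptor_xyz - h)
    })
    angle <- max(angles)
    if (angle < cfg$hbond_angle_min) return(NULL)
  }
  list(distance = d, angle = angle)
}

#' Detect typed protein-ligand interactions
#'
#' All-pairs geometric evaluation of the ligand feature set against every
#' residue feature set under the configured thresholds (see
#' [default_interaction_config()]). Returns one row per interaction event.
#'
#' @param lig_feats [perceive_ligand_features()] output.
#' @param res_feats [perceive_residue_features()] output (named list).
#' @param config threshold list; defaults to [default_interaction_config()].
#' @return tibble: `type`, `residue_key`, `distance`, `angle` (NA where not
#'   applicable).
#' @export
detect_interactions <- function(lig_feats, res_feats,
                                config = default_interaction_config()) {
  cfg <- utils::modifyList(default_interaction_config(), config)
  ev <- list()
  add <- function(type, key, distance, angle = NA_real_) {
    ev[[length(ev) + 1L]] <<- tibble(
      type = type, residue_key = key, distance = distance, angle = angle
    )
  }
  xyz <- function(row) c(row$x, row$y, row$z)
  for (key in names(res_feats)) {
    rf <- res_feats[[key]]

    for (i in seq_len(nrow(lig_feats$hydrophobic))) {
      p <- xyz(lig_feats$hydrophobic[i, ])
      for (j in seq_len(nrow(rf$hydrophobic))) {
        d <- dist3(p, xyz(rf$hydrophobic[j, ]))
        if (d <= cfg$hydrophobic_max) add("Hydrophobic", key, d)
      }
    }
    for (i in seq_len(nrow(lig_feats$donors))) {
      p <- xyz(lig_feats$donors[i, ])
      for (j in seq_len(nrow(rf$acceptors))) {
        g <- hbond_geometry_ok(p, lig_feats$donors$h[[i]], xyz(rf$acceptors[j, ]), cfg)
        if (!is.null(g)) add("HBDonor", key, g$distance, g$angle)
      }
    }
    for (j in seq_len(nrow(rf$donors))) {
      p <- xyz(rf$donors[j, ])
      for (i in seq_len(nrow(lig_feats$acceptors))) {
        g <- hbond_geometry_ok(p, rf$donors$h[[j]], xyz(lig_feats$acceptors[i, ]), cfg)
        if (!is.null(g)) add("HBAcceptor", key, g$distance, g$angle)
      }
    }
    for (i in seq_len(nrow(lig_feats$cations))) {
      p <- xyz(lig_feats$cations[i, ])
      for (j in seq_len(nrow(rf$anions))) {
        d <- dist3(p, xyz(rf$anions[j, ]))
        if (d <= cfg$ionic_max) add("Cationic", key, d)
      }
      for (ring in rf$rings) {
        d <- dist3(p, ring$centroid)
        if (d <= cfg$cation_pi_max) {
          ang <- vec_angle(ring$normal, p - ring$centroid)
          ang <- min(ang, 180 - ang)
          if (ang <= cfg$cation_pi_angle_max) add("CationPi", key, d, ang)
        }
      }
    }
    for (i in seq_len(nrow(lig_feats$anions))) {
      p <- xyz(lig_feats$anions[i, ])
      for (j in seq_len(nrow(rf$cations))) {
        d <- dist3(p, xyz(rf$cations[j, ]))
        if (d <= cfg$ionic_max) add("Anionic", key, d)
      }
    }
    for (j in seq_len(nrow(rf$cations))) {
      p <- xyz(rf$cations[j, ])
      for (ring in lig_feats$rings) {
        d <- dist3(p, ring$centroid)
        if (d <= cfg$cation_pi_max) {
          ang <- vec_angle(ring$normal, p - ring$centroid)
          ang <- min(ang, 180 - ang)
          if (ang <= cfg$cation_pi_angle_max) add("PiCation", key, d, ang)
        }
      }
    }
    for (lr in lig_feats$rings) {
      for (rr in rf$rings) {
        d <- dist3(lr$centroid, rr$centroid)
        plane_ang <- vec_angle(lr$normal, rr$normal)
        plane_ang <- min(plane_ang, 180 - plane_ang)
        ftf <- d <= cfg$pi_stack_ftf_max && plane_ang <= cfg$pi_stack_ftf_angle_max
        etf <- d <= cfg$pi_stack_etf_max &&
          plane_ang >= cfg$pi_stack_etf_angle[1] &&
          plane_ang <= cfg$pi_stack_etf_angle[2]
        if (ftf || etf) add("PiStacking", key, d, plane_ang)
      }
    }
    if (nrow(lig_feats$atoms) && nrow(rf$atoms)) {
      rl <- vdw_radius(lig_feats$atoms$element)
      rr_ <- vdw_radius(rf$atoms$element)
      for (i in seq_len(nrow(lig_feats$atoms))) {
        p <- c(lig_feats$atoms$x[i], lig_feats$atoms$y[i], lig_feats$atoms$z[i])
        for (j in seq_len(nrow(rf$atoms))) {
          d <- dist3(p, c(rf$atoms$x[j], rf$atoms$y[j], rf$atoms$z[j]))
          if (d <= rl[i] + rr_[j] + cfg$vdw_tolerance) add("VdWContact", key, d)
        }
      }
    }
  }
  if (!length(ev)) {
    return(tibble(
      type = character(), residue_key = character(),
      distance = numeric(), angle = numeric()
    ))
  }
  bind_rows(ev)
}

#' Interaction-type fingerprint (9 bits)
#'
#' Bit `i` is set iff at least one event of type `interaction_types()[i+1]`
#' occurs anywhere in the complex — one bit per type, complex-level.
#'
#' @param events [detect_interactions()] output.
#' @return `bit_fp` of length 9, schema `"itype/9"`.
#' @export
interaction_fingerprint <- function(events) {
  types <- interaction_types()
  bit_fp(which(types %in% unique(events$type)) - 1L, length(types), "itype/9")
}

#' Full interaction typing of a pose file against a receptor
#'
#' Convenience pipeline: read an SDF pose, perceive both feature sets,
#' detect events and emit the 9-bit fingerprint.
#'
#' @param pose_sdf path to an SDF pose (bond orders required).
#' @param receptor_path PDB/PDBQT receptor file.
#' @param config threshold overrides.
#' @return list with `events` (tibble) and `fp` (`bit_fp`).
#' @export
interaction_profile <- function(pose_sdf, receptor_path,
                                config = default_interaction_config()) {
  mol <- read_mol_sdf(pose_sdf)[[1]]
  rec <- read_receptor(receptor_path)
  lig <- perceive_ligand_features(mol)
  res <- perceive_residue_features(rec)
  events <- detect_interactions(lig, res, config)
  list(events = events, fp = interaction_fingerprint(events))
}
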