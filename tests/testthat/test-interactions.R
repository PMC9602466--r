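test_that("ligand feature perception matches chemistry-derived expectations", {
  etn <- embed_and_optimize_3d("CC[NH3+]", "ethylammonium")$mol
  f <- perceive_ligand_features(etn)
  expect_identical(nrow(f$cations), 1L)
  expect_identical(nrow(f$donors), 1L)
  expect_length(f$rings, 0)

  benz <- embed_and_optimize_3d("c1ccccc1", "benzene")$mol
  f <- perceive_ligand_features(benz)
  expect_length(f$rings, 1)
  expect_identical(nrow(f$hydrophobic), 6L)
  expect_identical(nrow(f$donors), 0L)
  expect_identical(nrow(f$acceptors), 0L)
  expect_equal(sqrt(sum(f$rings[[1]]$normal^2)), 1, tolerance = 1e-9)

  ace <- embed_and_optimize_3d("CC(=O)[O-]", "acetate")$mol
  f <- perceive_ligand_features(ace)
  expect_identical(nrow(f$anions), 1L)
  expect_identical(nrow(f$acceptors), 2L)
})

test_that("residue feature templates assign the documented chemistry", {
  asp <- place_residue("ASP", "CA", c(0, 0, 0))
  phe <- place_residue("PHE", "CA", c(20, 0, 0))
  f <- withr::local_tempfile(fileext = ".pdb")
  writeLines(c(
    bbbfp:::pdb_lines(list(
      list(resname = "ASP", resno = 1, atoms = asp),
      list(resname = "PHE", resno = 2, atoms = phe)
    ))
  ), f)
  rec <- read_receptor(f)
  feats <- perceive_residue_features(rec)
  aspf <- feats[["A:ASP:1"]]
  expect_identical(nrow(aspf$anions), 1L)
  od <- asp[asp$atom_name %in% c("OD1", "OD2"), ]
  expect_equal(aspf$anions$x, mean(od$x))  # carboxylate midpoint
  expect_equal(aspf$anions$y, mean(od$y))
  phef <- feats[["A:PHE:2"]]
  expect_length(phef$rings, 1)
  expect_length(phef$rings[[1]]$members, 6)
})

test_that("waters and unknown residues are skipped with a warning", {
  f <- withr::local_tempfile(fileext = ".pdb")
  writeLines(c(
    "ATOM      1  CA  GLY A   1       0.000   0.000   0.000  1.00  0.00           C",
    "HETATM    2  O   LIG A   9       5.000   0.000   0.000  1.00  0.00           O"
  ), f)
  rec <- read_receptor(f)
  expect_warning(feats <- perceive_residue_features(rec), "LIG")
  expect_identical(names(feats), "A:GLY:1")
  # waters are already dropped at parse time
  writeLines(c(
    "ATOM      1  CA  GLY A   1       0.000   0.000   0.000  1.00  0.00           C",
    "HETATM    2  O   HOH A 101       5.000   0.000   0.000  1.00  0.00           O"
  ), f)
  expect_identical(unique(read_receptor(f)$residue_name), "GLY")
})

# constructed feature sets for threshold tests, no molecules involved
feat_with <- function(slot, tbl_or_ring) {
  fs <- bbbfp:::empty_features()
  if (slot == "rings") fs$rings <- tbl_or_ring else fs[[slot]] <- tbl_or_ring
  fs
}
pointf <- function(x, y, z) tibble::tibble(x = x, y = y, z = z, atom = NA_integer_)
donorf <- function(x, y, z, h = NULL) {
  tibble::tibble(x = x, y = y, z = z, atom = NA_integer_,
                 h = list(if (is.null(h)) matrix(numeric(), ncol = 3) else h))
}
ringf <- function(centroid, normal) {
  list(list(centroid = centroid, normal = normal / sqrt(sum(normal^2)), members = 1:6))
}

test_that("hydrogen-bond detection applies distance then angle", {
  acceptor <- feat_with("acceptors", pointf(0, 0, 0))
  # 2.9 angstrom, D-H...A near 170 degrees -> event
  h <- matrix(c(0, 0.05, 1.95), ncol = 3)
  lig <- feat_with("donors", donorf(0, 0, 2.9, h))
  ev <- detect_interactions(lig, list("A:GLY:1" = acceptor))
  expect_identical(ev$type, "HBDonor")
  expect_gt(ev$angle, 160)
  # 3.6 angstrom -> no event regardless of angle
  lig_far <- feat_with("donors", donorf(0, 0, 3.6, matrix(c(0, 0, 2.65), ncol = 3)))
  expect_identical(nrow(detect_interactions(lig_far, list("A:GLY:1" = acceptor))), 0L)
  # bad angle (90 degrees) -> no event
  h_bad <- matrix(c(2.0, 0, 2.9), ncol = 3)
  lig_bad <- feat_with("donors", donorf(0, 0, 2.9, h_bad))
  expect_identical(nrow(detect_interactions(lig_bad, list("A:GLY:1" = acceptor))), 0L)
  # no hydrogen available -> distance-only fallback fires
  lig_noh <- feat_with("donors", donorf(0, 0, 2.9))
  expect_identical(detect_interactions(lig_noh, list("A:GLY:1" = acceptor))$type, "HBDonor")
})

test_that("pi-stacking accepts face-to-face and edge-to-face geometries", {
  res_ring <- list("A:PHE:1" = feat_with("rings", ringf(c(0, 0, 0), c(0, 0, 1))))
  # parallel rings, centroids 3.8 apart, plane angle 0 -> face-to-face
  lig <- feat_with("rings", ringf(c(0, 0, 3.8), c(0, 0, 1)))
  ev <- detect_interactions(lig, res_ring)
  expect_identical(ev$type, "PiStacking")
  # perpendicular at 6.0 -> edge-to-face
  lig_t <- feat_with("rings", ringf(c(0, 0, 6.0), c(1, 0, 0)))
  expect_identical(detect_interactions(lig_t, res_ring)$type, "PiStacking")
  # perpendicular but too far
  lig_far <- feat_with("rings", ringf(c(0, 0, 6.9), c(1, 0, 0)))
  expect_identical(nrow(detect_interactions(lig_far, res_ring)), 0L)
  # intermediate plane angle (40 degrees) matches neither band at 6.0
  n40 <- c(sin(40 * pi / 180), 0, cos(40 * pi / 180))
  lig_mid <- feat_with("rings", ringf(c(0, 0, 6.0), n40))
  expect_identical(nrow(detect_interactions(lig_mid, res_ring)), 0L)
})

test_that("ionic and cation-pi events respect distance and axis angle", {
  res <- list("A:ASP:1" = feat_with("anions", pointf(0, 0, 0)))
  lig <- feat_with("cations", pointf(0, 0, 4.4))
  expect_identical(detect_interactions(lig, res)$type, "Cationic")
  lig_far <- feat_with("cations", pointf(0, 0, 4.6))
  expect_identical(nrow(detect_interactions(lig_far, res)), 0L)
  ringres <- list("A:PHE:1" = feat_with("rings", ringf(c(0, 0, 0), c(0, 0, 1))))
  on_axis <- feat_with("cations", pointf(0, 0, 4.0))
  expect_identical(detect_interactions(on_axis, ringres)$type, "CationPi")
  off_axis <- feat_with("cations", pointf(3.5, 0, 1.5))  # ~67 degrees off normal
  expect_identical(nrow(detect_interactions(off_axis, ringres)), 0L)
})

test_that("interaction fingerprint sets one bit per observed type", {
  none <- interaction_fingerprint(tibble::tibble(
    type = character(), residue_key = character(),
    distance = numeric(), angle = numeric()
  ))
  expect_identical(none$set_bits, integer())
  expect_identical(none$length, 9L)
  two <- interaction_fingerprint(tibble::tibble(
    type = c("Hydrophobic", "HBDonor", "HBDonor"),
    residue_key = "A:GLY:1", distance = 3, angle = NA_real_
  ))
  expect_identical(two$set_bits, c(0L, 1L))
  # monotone: adding an event never clears a bit; removing all events of a
  # type clears exactly that bit
  ev <- tibble::tibble(
    type = c("Cationic", "PiStacking"), residue_key = "A:X:1",
    distance = 4, angle = NA_real_
  )
  fp_both <- interaction_fingerprint(ev)
  fp_one <- interaction_fingerprint(ev[1, ])
  expect_true(all(fp_one$set_bits %in% fp_both$set_bits))
  expect_identical(setdiff(fp_both$set_bits, fp_one$set_bits),
                   which(interaction_types() == "PiStacking") - 1L)
})

test_that("toy complexes reproduce their planted interaction types exactly", {
  for (ty in interaction_types()) {
    cx <- make_toy_complex(ty)
    dir <- withr::local_tempdir()
    paths <- write_toy_complex(cx, dir)
    prof <- interaction_profile(paths["pose"], paths["receptor"])
    expect_setequal(unique(prof$events$type), unique(cx$truth$type))
    want_bits <- which(interaction_types() %in% cx$truth$type) - 1L
    expect_identical(prof$fp$set_bits, sort(want_bits))
  }
  # all nine at once
  cx <- make_toy_complex(interaction_types())
  dir <- withr::local_tempdir()
  paths <- write_toy_complex(cx, dir)
  prof <- interaction_profile(paths["pose"], paths["receptor"])
  expect_identical(prof$fp$set_bits, 0:8)
  # empty spec: ligand far from the pocket
  cx0 <- make_toy_complex(character())
  paths0 <- write_toy_complex(cx0, withr::local_tempdir())
  prof0 <- interaction_profile(paths0["pose"], paths0["receptor"])
  expect_identical(nrow(prof0$events), 0L)
  expect_identical(prof0$fp$set_bits, integer())
})

test_that("typed detection equals the brute-force oracle on random complexes", {
  for (seed in 1:50) {
    rc <- make_random_complex(seed = seed)
    lig <- perceive_ligand_features(rc$mol)
    res <- suppressWarnings(perceive_residue_features(rc$receptor))
    got <- detect_interactions(lig, res)
    want <- oracle_detect(lig, res)
    expect_identical(event_signature(got), event_signature(want),
                     info = sprintf("seed %d", seed))
  }
})

test_that("rigid rotation and translation leave all events invariant", {
  rot <- function(fs, R, t) {
    move_tbl <- function(tb) {
      if (!nrow(tb)) return(tb)
      m <- t(R %*% t(as.matrix(tb[, c("x", "y", "z")]))) +
        rep(t, each = nrow(tb))
      tb$x <- m[, 1]; tb$y <- m[, 2]; tb$z <- m[, 3]
      if ("h" %in% names(tb)) {
        tb$h <- lapply(tb$h, function(hm) {
          if (is.null(hm) || nrow(hm) == 0) return(hm)
          t(R %*% t(hm)) + rep(t, each = nrow(hm))
        })
      }
      tb
    }
    fs$hydrophobic <- move_tbl(fs$hydrophobic)
    fs$donors <- move_tbl(fs$donors)
    fs$acceptors <- move_tbl(fs$acceptors)
    fs$cations <- move_tbl(fs$cations)
    fs$anions <- move_tbl(fs$anions)
    fs$atoms <- move_tbl(fs$atoms)
    fs$rings <- lapply(fs$rings, function(r) {
      r$centroid <- as.vector(R %*% r$centroid + t)
      r$normal <- as.vector(R %*% r$normal)
      r
    })
    fs
  }
  th <- 0.61; ph <- 1.13
  R <- matrix(c(cos(th), -sin(th), 0, sin(th), cos(th), 0, 0, 0, 1), 3, 3) %*%
    matrix(c(1, 0, 0, 0, cos(ph), -sin(ph), 0, sin(ph), cos(ph)), 3, 3)
  tvec <- c(11.1, -5.3, 2.9)
  for (seed in c(2, 9, 23)) {
    rc <- make_random_complex(seed = seed)
    lig <- perceive_ligand_features(rc$mol)
    res <- suppressWarnings(perceive_residue_features(rc$receptor))
    base <- detect_interactions(lig, res)
    moved <- detect_interactions(rot(lig, R, tvec), lapply(res, rot, R = R, t = tvec))
    expect_identical(event_signature(base), event_signature(moved))
    ord <- order(base$type, base$residue_key, base$distance)
    ord2 <- order(moved$type, moved$residue_key, moved$distance)
    expect_equal(base$distance[ord], moved$distance[ord2], tolerance = 1e-6)
  }
})
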