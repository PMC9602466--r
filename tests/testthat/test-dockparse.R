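toy_pocket <- function() {
  cx <- make_toy_complex(c("Hydrophobic", "Cationic", "HBAcceptor"))
  dir <- withr::local_tempdir(.local_envir = parent.frame())
  write_toy_complex(cx, dir)
}

test_that("receptor parsing extracts residue keys from PDB", {
  paths <- toy_pocket()
  rec <- read_receptor(paths["receptor"])
  expect_identical(length(unique(rec$residue_key)), 3L)
  expect_setequal(unique(rec$residue_name), c("LEU", "ASP", "SER"))
  expect_true(all(is.finite(rec$x)))
})

test_that("PDBQT columns populate partial charges and atom types", {
  lines <- c(
    "ATOM      1  N   LYS A  10      10.000  10.000  10.000  1.00  0.00    -0.350 N ",
    "ATOM      2  CA  LYS A  10      11.400  10.000  10.000  1.00  0.00     0.176 C ",
    "ATOM      3  C1  LYS A  10      12.400  11.000  10.000  1.00  0.00     0.050 A "
  )
  f <- withr::local_tempfile(fileext = ".pdbqt")
  writeLines(lines, f)
  rec <- read_receptor(f, format = "pdbqt")
  expect_equal(rec$partial_charge, c(-0.350, 0.176, 0.050))
  expect_identical(rec$element, c("N", "C", "C"))  # AD type A -> aromatic carbon
})

test_that("malformed fixed-width records error with their line number", {
  f <- withr::local_tempfile(fileext = ".pdb")
  writeLines(c(
    "ATOM      1  N   GLY A   1      10.000  10.000  10.000  1.00  0.00           N",
    "ATOM      2  CA  GLY A   1      bad     10.000  10.000  1.00  0.00           C"
  ), f)
  expect_error(read_receptor(f), "line 2")
  writeLines("ATOM      1  N   GLY A   1      10.0", f)
  expect_error(read_receptor(f), "line 1")
})

test_that("multi-model PDBQT pose sets parse with ranks and scores", {
  qt <- c(
    "MODEL 1", "REMARK VINA RESULT:    -7.5  0.000  0.000",
    "ATOM      1  C1  LIG A   1      10.000  10.000  10.000  1.00  0.00     0.123 C ",
    "ATOM      2  O1  LIG A   1      11.200  10.000  10.000  1.00  0.00    -0.350 OA",
    "ENDMDL",
    "MODEL 2", "REMARK VINA RESULT:    -7.1  1.2  2.2",
    "ATOM      1  C1  LIG A   1      12.000  10.000  10.000  1.00  0.00     0.123 C ",
    "ENDMDL",
    "MODEL 3", "REMARK VINA RESULT:    -6.8  2.0  3.1",
    "ATOM      1  C1  LIG A   1      14.000  10.000  10.000  1.00  0.00     0.123 C ",
    "ENDMDL"
  )
  f <- withr::local_tempfile(fileext = ".pdbqt")
  writeLines(qt, f)
  ps <- read_pose_set(f, "lig1")
  expect_identical(ps$pose_rank, 1:3)
  expect_equal(ps$score, c(-7.5, -7.1, -6.8))
  # coordinates round-trip exactly at PDB precision
  expect_identical(ps$atoms[[1]]$x, c(10.0, 11.2))
  expect_identical(ps$atoms[[1]]$element, c("C", "O"))
  writeLines("REMARK nothing", f)
  expect_error(read_pose_set(f), "no poses|no ATOM")
})

test_that("single-record SDF pose files yield one pose with chemistry", {
  cx <- make_toy_complex("Hydrophobic")
  dir <- withr::local_tempdir()
  paths <- write_toy_complex(cx, dir)
  ps <- read_pose_set(paths["pose"])
  expect_identical(nrow(ps), 1L)
  expect_s3_class(ps$mol[[1]]$atoms, "tbl_df")
})

test_that("contact detection respects the distance cutoff exactly", {
  rec_lines <- c(
    "ATOM      1  CD1 LEU A   1       0.000   0.000   0.000  1.00  0.00           C",
    "ATOM      2  CA  GLY A   2      20.000   0.000   0.000  1.00  0.00           C"
  )
  f <- withr::local_tempfile(fileext = ".pdb")
  writeLines(rec_lines, f)
  rec <- read_receptor(f)
  near <- tibble::tibble(element = "C", x = 3.5, y = 0, z = 0)
  far <- tibble::tibble(element = "C", x = 4.6, y = 0, z = 0)
  expect_identical(contact_residues(near, rec, cutoff = 4), "A:LEU:1")
  expect_identical(contact_residues(far, rec, cutoff = 4), character())
  expect_error(contact_residues(tibble::tibble(
    element = "H", x = 0, y = 0, z = 0
  ), rec), "heavy")
})

test_that("contact residues match the brute-force oracle on random complexes", {
  for (seed in 1:50) {
    rc <- make_random_complex(seed = seed)
    pa <- pose_atoms_of(rc$mol)
    expect_identical(
      contact_residues(pa, rc$receptor, cutoff = 4.0),
      oracle_contact_residues(pa, rc$receptor, cutoff = 4.0),
      info = sprintf("seed %d", seed)
    )
  }
})

test_that("enlarging the cutoff never removes a contact", {
  for (seed in c(3, 17, 29)) {
    rc <- make_random_complex(seed = seed)
    pa <- pose_atoms_of(rc$mol)
    small <- contact_residues(pa, rc$receptor, cutoff = 3.5)
    big <- contact_residues(pa, rc$receptor, cutoff = 5.5)
    expect_true(all(small %in% big))
  }
})

test_that("residue frequency counts distinct ligands only", {
  contacts <- tibble::tibble(
    ligand_id = c("l1", "l1", "l2", "l3", "l3"),
    residue_key = c("A:LEU:1", "A:LEU:1", "A:LEU:1", "A:LEU:1", "A:SER:2")
  )
  fr <- residue_frequency(contacts)
  expect_identical(fr$count[fr$residue_key == "A:LEU:1"], 3L)
  expect_identical(fr$count[fr$residue_key == "A:SER:2"], 1L)
  sc <- make_substrate_contacts(7, paste0("A:GLY:", 1:9), seed = 5)
  expect_identical(residue_frequency(sc$contacts), sc$truth)
})

test_that("schema building ranks by count with deterministic tie-breaks", {
  fr <- tibble::tibble(
    residue_key = c("A:LEU:30", "A:SER:12", "A:ASP:7"),
    count = c(3L, 2L, 1L)
  )
  expect_identical(unclass(build_residue_schema(fr, k = 2)), c("A:LEU:30", "A:SER:12"))
  tie <- tibble::tibble(residue_key = c("A:LEU:30", "A:SER:12"), count = c(3L, 3L))
  expect_identical(unclass(build_residue_schema(tie, k = 1)), "A:SER:12")
  expect_warning(sch <- build_residue_schema(fr, k = 62), "shortened")
  expect_length(sch, 3)
  expect_error(build_residue_schema(fr[0, ], k = 2), "empty")
})

test_that("residue fingerprints set exactly the schema bits in contact", {
  paths <- toy_pocket()
  rec <- read_receptor(paths["receptor"])
  pose <- read_pose_set(paths["pose"])
  schema <- structure(
    sort(unique(rec$residue_key)), class = "bbb_residue_schema"
  )
  fp <- residue_fingerprint(pose[1, ], rec, schema)
  expect_identical(fp$length, 3L)
  hits <- contact_residues(pose[1, ], rec)
  expect_identical(fp$set_bits, which(schema %in% hits) - 1L)
  # a far-away pose gives the all-zero fingerprint
  far <- tibble::tibble(element = "C", x = 500, y = 500, z = 500)
  expect_identical(residue_fingerprint(far, rec, schema)$set_bits, integer())
})

test_that("residue schema serialization round-trips bit-exactly", {
  schema <- structure(
    c("A:LEU:30", "A:SER:12", "B:ASP:7"), class = "bbb_residue_schema"
  )
  f <- withr::local_tempfile(fileext = ".txt")
  write_residue_schema(schema, f)
  back <- read_residue_schema(f)
  expect_identical(unclass(back), unclass(schema))
})

test_that("plain-PDB parsing agrees with an independent PDB reader", {
  skip_if_not_installed("bio3d")
  paths <- toy_pocket()
  rec <- read_receptor(paths["receptor"])
  ref <- bio3d::read.pdb(paths[["receptor"]])
  expect_equal(nrow(rec), nrow(ref$atom))
  expect_equal(rec$x, ref$atom$x)
  expect_equal(rec$residue_number, ref$atom$resno)
  expect_equal(rec$residue_name, ref$atom$resid)
})

test_that("docking grid configuration carries the receptor box", {
  cfg <- docking_config()
  expect_equal(unname(cfg$center), c(160, 145.4, 142.88))
  expect_gt(cfg$box_edge, 0)
})
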