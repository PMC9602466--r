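#' Standardize a table of molecules
#'
#' Applies the library-preparation pipeline to a table of SMILES: salt
#' stripping (largest contiguous fragment retained), charge neutralization
#' where chemically valid (carboxylates/phenolates protonated, ammoniums
#' deprotonated; quaternary nitrogens stay charged), stereo/isotope removal,
#' and canonical SMILES generation. Unparseable entries become rejection
#' rows, they never abort the batch. Single-heavy-atom species (noble gases,
#' bare ions, water) are flagged `excluded`.
#'
#' @param tbl data frame with columns `id`, `smiles` and optionally `label`
#'   (1/0/NA for permeable / non-permeable / unknown).
#' @return tibble with columns `id`, `smiles`, `smiles_canonical`, `label`,
#'   `n_heavy`, `status` (`"ok"`, `"rejected"`, `"excluded"`) and `reason`.
#' @examples
#' \dontrun{
#' standardize_molecules(tibble::tibble(
#'   id = c("a", "b"), smiles = c("CC(=O)[O-].[Na+]", "CCO")
#' ))
#' }
#' @export
standardize_molecules <- function(tbl) {
  stopifnot(is.data.frame(tbl), all(c("id", "smiles") %in% names(tbl)))
  tbl <- as_tibble(tbl)
  if (!"label" %in% names(tbl)) tbl$label <- NA_integer_
  if (anyDuplicated(tbl$id)) abort("molecule ids must be unique.")
  n <- nrow(tbl)
  res <- tibble(
    id = as.character(tbl$id), smiles = tbl$smiles,
    smiles_canonical = NA_character_, label = tbl$label,
    n_heavy = NA_integer_, status = "rejected", reason = "unparseable SMILES"
  )
  ok_in <- !is.na(tbl$smiles) & nzchar(trimws(tbl$smiles))
  res$reason[!ok_in] <- "empty SMILES"
  if (!any(ok_in)) return(res)

  tags <- paste0("s", seq_len(n))
  out <- ob_run(
    c("-ismi", "-ocan", "-r", "--neutralize", "-xi", "-e"),
    stdin_text = paste(tbl$smiles[ok_in], tags[ok_in])
  )
  for (ln in out) {
    parts <- strsplit(trimws(ln), "\\s+")[[1]]
    if (length(parts) >= 2) {
      i <- match(parts[2], tags)
      if (!is.na(i)) {
        res$smiles_canonical[i] <- parts[1]
        res$status[i] <- "ok"
        res$reason[i] <- NA_character_
      }
    }
  }
  got <- which(res$status == "ok")
  if (length(got)) {
    mols <- smiles_to_mols(res$smiles_canonical[got], ids = res$id[got])
    nh <- vapply(mols, function(m) if (is.null(m)) NA_integer_ else sum(m$atoms$heavy), 0L)
    res$n_heavy[got] <- nh
    single <- got[!is.na(nh) & nh <= 1L]
    res$status[single] <- "excluded"
    res$reason[single] <- "single heavy atom"
    bad <- got[is.na(nh)]
    res$status[bad] <- "rejected"
    res$reason[bad] <- "standardized SMILES failed to re-parse"
  }
  res
}

#' Standardize one SMILES string
#'
#' Single-molecule convenience wrapper around [standardize_molecules()].
#'
#' @param smiles a SMILES string.
#' @param id identifier for the returned record.
#' @return one-row tibble (see [standardize_molecules()]).
#' @export
parse_and_standardize <- function(smiles, id = "mol1") {
  stopifnot(is.character(smiles), length(smiles) == 1L)
  standardize_molecules(tibble(id = id, smiles = smiles))
}

#' Is a standardized record a single-heavy-atom species?
#'
#' Monatomic entries (noble gases, bare element ions, water after salt
#' stripping) carry no organic substructure and are excluded from the
#' library.
#'
#' @param record one-row tibble from [standardize_molecules()].
#' @return logical.
#' @export
is_excluded_single_atom <- function(record) {
  stopifnot("n_heavy" %in% names(record), nrow(record) == 1L)
  !is.na(record$n_heavy) && record$n_heavy == 1L
}

# --- circular fingerprint ---------------------------------------------------

ecfp_atom_invariant <- function(mol, i, g_deg) {
  a <- mol$atoms[i, ]
  anum <- match(a$elem, c(
    "H", "He", "Li", "Be", "B", "C", "N", "O", "F", "Ne", "Na", "Mg", "Al",
    "Si", "P", "S", "Cl", "Ar", "K", "Ca", "Br", "I"
  ))
  if (is.na(anum)) anum <- 0L
  in_ring <- any(vapply(mol$arom_rings, function(r) i %in% r, TRUE))
  c(anum, g_deg, a$nh, round(a$charge) + 8, as.integer(in_ring))
}

#' Extended-connectivity (circular) fingerprint, radius 2
#'
#' Implements the iterative neighbourhood-hashing algorithm: each heavy atom
#' starts from an invariant tuple (atomic number, heavy degree, hydrogen
#' count, formal charge, ring membership); two update rounds fold in the
#' sorted (bond order, neighbour identifier) pairs; all identifiers from
#' radii 0-2 are hashed onto `nbits` bits. Deterministic for a given
#' connection table.
#'
#' @param mol `bbb_mol` (2D connection table is sufficient).
#' @param nbits fingerprint length, default 1024.
#' @return `bit_fp` of schema `"ecfp4/<nbits>"`.
#' @export
ecfp4 <- function(mol, nbits = 1024L) {
  stopifnot(inherits(mol, "bbb_mol"))
  if (length(nbits) != 1L || is.na(nbits) || nbits <= 0) {
    abort("`nbits` must be a positive integer.")
  }
  heavy <- mol$atoms$idx[mol$atoms$heavy]
  bonds <- mol$bonds[mol$bonds$a1 %in% heavy & mol$bonds$a2 %in% heavy, , drop = FALSE]
  nbr <- lapply(heavy, function(i) {
    up <- bonds[bonds$a1 == i, c("a2", "order")]
    dn <- bonds[bonds$a2 == i, c("a1", "order")]
    names(up) <- names(dn) <- c("j", "order")
    rbind(up, dn)
  })
  names(nbr) <- heavy
  deg <- vapply(nbr, nrow, 0L)
  ids <- vapply(seq_along(heavy), function(k) {
    hash31(ecfp_atom_invariant(mol, heavy[k], deg[k]))
  }, 0)
  all_ids <- ids
  for (r in 1:2) {
    new_ids <- vapply(seq_along(heavy), function(k) {
      nb <- nbr[[k]]
      if (nrow(nb) == 0L) return(hash31(c(r, ids[k])))
      pairs <- cbind(nb$order, ids[match(nb$j, heavy)])
      pairs <- pairs[order(pairs[, 1], pairs[, 2]), , drop = FALSE]
      hash31(c(r, ids[k], as.vector(t(pairs))))
    }, 0)
    ids <- new_ids
    all_ids <- c(all_ids, ids)
  }
  bit_fp(unique(all_ids %% nbits), nbits, sprintf("ecfp4/%d", nbits))
}

#' Circular fingerprints for a standardized table
#'
#' @param tbl tibble with `id` and `smiles_canonical` columns (rows with
#'   `status != "ok"` are skipped if a `status` column is present).
#' @param nbits fingerprint length.
#' @return tibble `id`, `fp` (list of `bit_fp`).
#' @export
ecfp4_table <- function(tbl, nbits = 1024L) {
  if ("status" %in% names(tbl)) tbl <- tbl[tbl$status == "ok", , drop = FALSE]
  mols <- smiles_to_mols(tbl$smiles_canonical, ids = tbl$id)
  keep <- !vapply(mols, is.null, TRUE)
  tibble(
    id = tbl$id[keep],
    fp = purrr::map(mols[keep], ecfp4, nbits = nbits)
  )
}

# --- deduplication ----------------------------------------------------------

#' Group duplicate molecules by fingerprint similarity
#'
#' Single-linkage grouping of molecules whose pairwise Tanimoto similarity
#' reaches `threshold` (default 1: exact circular-fingerprint duplicates,
#' which is how stereoisomers collapse once stereo is stripped). The group
#' representative is the lexicographically smallest canonical SMILES — a
#' deterministic stand-in for manual inspection.
#'
#' @param fp_tbl tibble with columns `id`, `fp`, and optionally
#'   `smiles_canonical` (used for representative selection).
#' @param threshold similarity threshold in (0, 1].
#' @return tibble with one row per group: `group`, `representative_id`,
#'   `member_ids` (list), `n_members`.
#' @export
dedup_groups <- function(fp_tbl, threshold = 1.0) {
  if (!is.data.frame(fp_tbl) || nrow(fp_tbl) == 0L) {
    return(tibble(
      group = integer(), representative_id = character(),
      member_ids = list(), n_members = integer()
    ))
  }
  stopifnot(threshold > 0, threshold <= 1)
  n <- nrow(fp_tbl)
  edges <- integer()
  if (n > 1L) {
    for (i in seq_len(n - 1L)) {
      for (j in (i + 1L):n) {
        if (tanimoto(fp_tbl$fp[[i]], fp_tbl$fp[[j]]) >= threshold) {
          edges <- c(edges, i, j)
        }
      }
    }
  }
  g <- igraph::make_empty_graph(n = n, directed = FALSE)
  if (length(edges)) g <- igraph::add_edges(g, edges)
  comp <- igraph::components(g)$membership
  smi <- if ("smiles_canonical" %in% names(fp_tbl)) fp_tbl$smiles_canonical else fp_tbl$id
  out <- lapply(sort(unique(comp)), function(cc) {
    m <- which(comp == cc)
    rep_i <- m[order(smi[m], fp_tbl$id[m])][1]
    tibble(
      group = cc, representative_id = fp_tbl$id[rep_i],
      member_ids = list(fp_tbl$id[m]), n_members = length(m)
    )
  })
  bind_rows(out)
}

# --- 3D preparation ---------------------------------------------------------

#' Embed and force-field optimize a 3D conformer
#'
#' Generates 3D coordinates with Open Babel and refines them by
#' steepest-descent minimization under the MMFF94 force field (up to
#' `max_steps` steps, 5000 by default). Molecules that cannot be embedded or
#' parameterized — or whose result contains non-finite or colliding
#' coordinates (closer than 0.7 angstrom) — are flagged rather than raised,
#' and are dropped from the prepared library.
#'
#' @param smiles one SMILES string.
#' @param id molecule identifier.
#' @param max_steps maximum minimization steps.
#' @return list with `ok` (logical), `mol` (`bbb_mol` with conformer or
#'   `NULL`), `reason`.
#' @export
embed_and_optimize_3d <- function(smiles, id = "mol1", max_steps = 5000L) {
  stopifnot(is.character(smiles), length(smiles) == 1L)
  out <- ob_run(
    c("-ismi", "-osdf", "--gen3d", "--minimize", "--sd",
      "--steps", as.character(max_steps), "--ff", "MMFF94"),
    stdin_text = paste(smiles, id)
  )
  fail <- function(reason) list(ok = FALSE, mol = NULL, reason = reason)
  if (!length(out) || !any(grepl("V2000", out))) {
    return(fail("3D embedding failed"))
  }
  mols <- tryCatch(sdf_text_to_mols(out), error = function(e) NULL)
  if (is.null(mols) || !length(mols) || is.null(mols[[1]])) {
    return(fail("3D embedding failed"))
  }
  mol <- mols[[1]]
  co <- as.matrix(mol$atoms[mol$atoms$heavy, c("x", "y", "z")])
  if (!all(is.finite(co))) return(fail("non-finite coordinates"))
  if (nrow(co) > 1L) {
    d <- stats::dist(co)
    if (min(d) <= 0.7) return(fail("atom clash below 0.7 angstrom"))
    if (all(abs(co) < 1e-8)) return(fail("degenerate all-zero coordinates"))
  }
  list(ok = TRUE, mol = mol, reason = NA_character_)
}

#' Prepare a standardized library in 3D
#'
#' Runs [embed_and_optimize_3d()] over all `status == "ok"` rows and writes
#' an SDF library plus a CSV audit log with one row per exclusion.
#'
#' @param std_tbl output of [standardize_molecules()].
#' @param sdf_path,audit_path output files (`NULL` to skip writing).
#' @param max_steps see [embed_and_optimize_3d()].
#' @return tibble `id`, `ok`, `reason`, `mol` (list column).
#' @export
prepare_library_3d <- function(std_tbl, sdf_path = NULL, audit_path = NULL,
                               max_steps = 5000L) {
  ok_rows <- std_tbl[std_tbl$status == "ok", , drop = FALSE]
  res <- purrr::map2(
    ok_rows$smiles_canonical, ok_rows$id,
    function(s, i) embed_and_optimize_3d(s, i, max_steps)
  )
  out <- tibble(
    id = ok_rows$id,
    ok = vapply(res, function(r) r$ok, TRUE),
    reason = vapply(res, function(r) r$reason, ""),
    mol = purrr::map(res, "mol")
  )
  if (!is.null(sdf_path)) {
    blocks <- unlist(lapply(which(out$ok), function(i) {
      c(mol_to_molfile(out$mol[[i]]), "$$$$")
    }))
    writeLines(blocks %||% character(), sdf_path)
  }
  if (!is.null(audit_path)) {
    audit <- bind_rows(
      std_tbl[std_tbl$status != "ok", c("id", "status", "reason")],
      tibble(id = out$id[!out$ok], status = "neglected", reason = out$reason[!out$ok])
    )
    write.csv(audit, audit_path, row.names = FALSE)
  }
  out
}
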