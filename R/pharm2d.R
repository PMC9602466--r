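#' Topological 2-point/3-point pharmacophore fingerprint schema
#'
#' Six feature families — hydrogen-bond donor (HD), acceptor (HA), aromatic
#' ring (AR), hydrophobe (HY), basic group (BG), acidic group (AG) — are
#' combined into 2-point pairs and 3-point triangles whose topological
#' (bond-count) distances are assigned to bins. A fingerprint bit is one
#' equivalence class of (family assignment, binned distance assignment)
#' under permutation of the points, i.e. one distinguishable 2- or 3-point
#' pharmacophore; triangle classes must admit integer distances satisfying
#' the triangle inequality somewhere inside their bins.
#'
#' The default schema uses 13 distance bins over bond counts —
#' 1, 2, 3-4, 5, 6, 7-10, 11-12, 13, 14-19, 20-24, 25-26, 27, 28+ — which
#' the enumeration resolves into exactly 39,971 classes (273 pairs +
#' 39,698 triangles). The bin edges are calibrated so the bit space matches
#' that size; pairs closer than the lowest edge are discarded.
#'
#' @param bins two-column matrix (`lo`, `hi`) of inclusive integer distance
#'   ranges; the last bin may be open (`hi = Inf`).
#' @param families character vector of family codes (order fixes the
#'   encoding).
#' @param min_points,max_points pharmacophore sizes to enumerate (2 and 2-3
#'   supported).
#' @param total_bits expected size; if non-`NULL` the enumeration is
#'   validated against it at first use.
#' @return schema list (class `pharm2d_schema`).
#' @export
pharm_schema <- function(bins = default_pharm_bins(),
                         families = c("AG", "AR", "BG", "HA", "HD", "HY"),
                         min_points = 2L, max_points = 3L,
                         total_bits = NULL) {
  stopifnot(
    is.matrix(bins), ncol(bins) == 2L, nrow(bins) >= 1L,
    all(bins[, 1] <= bins[, 2]), !is.unsorted(bins[, 1]),
    min_points == 2L, max_points %in% c(2L, 3L),
    length(families) >= 1L, !anyDuplicated(families)
  )
  structure(
    list(
      bins = bins, families = families,
      min_points = as.integer(min_points), max_points = as.integer(max_points),
      total_bits = total_bits
    ),
    class = "pharm2d_schema"
  )
}

#' @rdname pharm_schema
#' @export
default_pharm_bins <- function() {
  cbind(
    lo = c(1, 2, 3, 5, 6, 7, 11, 13, 14, 20, 25, 27, 28),
    hi = c(1, 2, 4, 5, 6, 10, 12, 13, 19, 24, 26, 27, Inf)
  )
}

#' @rdname pharm_schema
#' @export
default_pharm_schema <- function() {
  pharm_schema(total_bits = 39971L)
}

#' @export
print.pharm2d_schema <- function(x, ...) {
  cat(sprintf(
    "<pharm2d schema: %d families, %d bins, %d-%d points%s>\n",
    length(x$families), nrow(x$bins), x$min_points, x$max_points,
    if (!is.null(x$total_bits)) sprintf(", %d bits", x$total_bits) else ""
  ))
  invisible(x)
}

# triangle admissibility of binned distances: the class is kept iff integer
# distances inside the three bins can satisfy the triangle inequality
bins_triangle_ok <- function(bins, i, j, k) {
  lo <- bins[, 1]
  hi <- bins[, 2]
  (lo[k] <= hi[i] + hi[j]) & (lo[i] <= hi[j] + hi[k]) & (lo[j] <= hi[i] + hi[k])
}

pharm_key <- function(f1, f2, f3 = NULL, b12, b13 = NULL, b23 = NULL) {
  if (is.null(f3)) {
    sprintf("P%d.%d.%02d", f1, f2, b12)
  } else {
    sprintf("T%d.%d.%d.%02d.%02d.%02d", f1, f2, f3, b12, b13, b23)
  }
}

# generate every canonical class key of the schema, in index order
pharm_all_keys <- function(schema) {
  nf <- length(schema$families)
  B <- nrow(schema$bins)
  keys <- character()
  # pairs: f1 <= f2, any bin
  for (f1 in seq_len(nf)) {
    for (f2 in f1:nf) {
      keys <- c(keys, pharm_key(f1, f2, b12 = seq_len(B)))
    }
  }
  if (schema$max_points >= 3L) {
    grid <- expand.grid(b12 = seq_len(B), b13 = seq_len(B), b23 = seq_len(B))
    ok <- bins_triangle_ok(schema$bins, grid$b12, grid$b13, grid$b23)
    grid <- grid[ok, , drop = FALSE]
    tri_keys <- character()
    for (f1 in seq_len(nf)) {
      for (f2 in f1:nf) {
        for (f3 in f2:nf) {
          if (f1 < f2 && f2 < f3) {
            g <- grid
          } else if (f1 == f2 && f2 == f3) {
            g <- grid[grid$b12 <= grid$b13 & grid$b13 <= grid$b23, , drop = FALSE]
          } else if (f1 == f2) {
            # points 1,2 interchangeable: canonical has b13 <= b23
            g <- grid[grid$b13 <= grid$b23, , drop = FALSE]
          } else {
            # points 2,3 interchangeable: canonical has b12 <= b13
            g <- grid[grid$b12 <= grid$b13, , drop = FALSE]
          }
          if (nrow(g)) {
            tri_keys <- c(tri_keys, pharm_key(f1, f2, f3, g$b12, g$b13, g$b23))
          }
        }
      }
    }
    keys <- c(keys, tri_keys)
  }
  keys
}

pharm_index_env <- function(schema) {
  tag <- paste(
    paste(schema$families, collapse = ","),
    paste(schema$bins[, 1], schema$bins[, 2], collapse = ";"),
    schema$max_points, schema$total_bits %||% "free",
    sep = "|"
  )
  cached <- the$pharm_cache
  if (!is.null(cached) && identical(cached$tag, tag)) return(cached)
  keys <- pharm_all_keys(schema)
  if (!is.null(schema$total_bits) && length(keys) != schema$total_bits) {
    abort(sprintf(
      "schema is inconsistent: enumeration yields %d classes but total_bits is %d.",
      length(keys), schema$total_bits
    ))
  }
  env <- new.env(hash = TRUE, size = length(keys) * 2L)
  for (i in seq_along(keys)) env[[keys[i]]] <- i - 1L
  cached <- list(tag = tag, keys = keys, env = env, n = length(keys))
  the$pharm_cache <- cached
  cached
}

#' Exhaustively enumerate the pharmacophore bit space
#'
#' Counts every admissible canonical (family, binned-distance) class of the
#' schema for 2 points and — when enabled — 3 points with the binned
#' triangle-inequality filter. For the default schema the count is the
#' fingerprint length, 39,971.
#'
#' @param schema a [pharm_schema()].
#' @return integer class count.
#' @examples
#' \dontrun{
#' enumerate_bit_space(default_pharm_schema()) # 39971
#' }
#' @export
enumerate_bit_space <- function(schema = default_pharm_schema()) {
  pharm_index_env(schema)$n
}

# --- feature detection ------------------------------------------------------

#' Detect 2D pharmacophore features of a molecule
#'
#' Graph-pattern feature assignment on the connection table (no conformer
#' needed): HD = N/O bearing a hydrogen; HA = O (non-cationic) or trivalent
#' non-cationic N that is not a pyrrole-type NH; AR = one feature per
#' aromatic ring (all ring atoms); HY = uncharged C/S/halogen with no N/O
#' or charged neighbour, one feature per atom; BG = sp3 amine nitrogen not
#' adjacent to a carbonyl (or any positively charged nitrogen); AG =
#' carboxylic/sulfonic/phosphonic acid group (the central atom with its
#' oxygens). Duplicate matches of one family on an identical atom set are
#' collapsed.
#'
#' @param mol `bbb_mol` (a 2D connection table suffices).
#' @return tibble `family`, `atoms` (list of integer atom-index vectors).
#' @export
detect_pharm_features <- function(mol) {
  stopifnot(inherits(mol, "bbb_mol"))
  at <- mol$atoms
  feats <- list()
  add <- function(family, atoms) {
    feats[[length(feats) + 1L]] <<- tibble(family = family, atoms = list(sort(atoms)))
  }
  nbrs <- function(i) {
    c(mol$bonds$a2[mol$bonds$a1 == i], mol$bonds$a1[mol$bonds$a2 == i])
  }
  bond_order <- function(i, j) {
    b <- mol$bonds[(mol$bonds$a1 == i & mol$bonds$a2 == j) |
      (mol$bonds$a1 == j & mol$bonds$a2 == i), ]
    if (nrow(b)) b$order[1] else 0L
  }
  arom_atoms <- unique(unlist(mol$arom_rings))
  heavy <- which(at$heavy)
  for (i in heavy) {
    el <- at$elem[i]
    nb <- nbrs(i)
    nb_heavy <- nb[at$heavy[nb]]
    bo_sum <- sum(ifelse(
      mol$bonds$order[mol$bonds$a1 == i | mol$bonds$a2 == i] == 4L, 1.5,
      mol$bonds$order[mol$bonds$a1 == i | mol$bonds$a2 == i]
    )) + at$nh[i]
    if (el %in% c("N", "O") && at$nh[i] >= 1L) add("HD", i)
    if (el == "O" && at$charge[i] <= 0) add("HA", i)
    if (el == "N" && at$charge[i] <= 0 && bo_sum <= 3 &&
        !(i %in% arom_atoms && at$nh[i] >= 1L)) {
      add("HA", i)
    }
    if (el %in% c("C", "S", "Cl", "Br", "I") && at$charge[i] == 0 &&
        length(nb_heavy) >= 1L &&
        !any(at$elem[nb_heavy] %in% c("N", "O")) &&
        !any(at$charge[nb_heavy] != 0)) {
      add("HY", i)
    }
    # basic: positively charged N, or sp3 amine not adjacent to a carbonyl
    if (el == "N") {
      if (at$charge[i] > 0) {
        add("BG", i)
      } else if (!(i %in% arom_atoms) &&
                 all(vapply(nb_heavy, function(j) bond_order(i, j), 0L) == 1L)) {
        amide <- any(vapply(nb_heavy, function(j) {
          at$elem[j] == "C" && any(vapply(
            nbrs(j), function(k) at$elem[k] == "O" && bond_order(j, k) == 2L, TRUE
          ))
        }, TRUE))
        if (!amide) add("BG", i)
      }
    }
    # acidic: C/S/P centre bonded to =O and -O(H/-)
    if (el %in% c("C", "S", "P")) {
      os <- nb_heavy[at$elem[nb_heavy] == "O"]
      if (length(os) >= 2L) {
        has_dbl <- any(vapply(os, function(j) bond_order(i, j) == 2L, TRUE))
        hydroxy <- os[vapply(os, function(j) {
          bond_order(i, j) == 1L && (at$nh[j] >= 1L || at$charge[j] < 0)
        }, TRUE)]
        if (has_dbl && length(hydroxy)) add("AG", c(i, os))
      }
    }
  }
  for (r in mol$arom_rings) add("AR", r)
  if (!length(feats)) {
    return(tibble(family = character(), atoms = list()))
  }
  out <- bind_rows(feats)
  out$key <- paste(out$family, vapply(out$atoms, paste, "", collapse = ","))
  out <- out[!duplicated(out$key), c("family", "atoms")]
  out
}

canonical_triplet_key <- function(f, b12, b13, b23) {
  # f: family indices of the three points; distances binned
  perms <- list(c(1, 2, 3), c(1, 3, 2), c(2, 1, 3), c(2, 3, 1), c(3, 1, 2), c(3, 2, 1))
  d <- c(b12, b13, b23)
  pair_slot <- function(a, b) {
    s <- sort(c(a, b))
    if (s[1] == 1 && s[2] == 2) 1L else if (s[1] == 1) 2L else 3L
  }
  best <- NULL
  for (p in perms) {
    key <- pharm_key(
      f[p[1]], f[p[2]], f[p[3]],
      d[pair_slot(p[1], p[2])], d[pair_slot(p[1], p[3])], d[pair_slot(p[2], p[3])]
    )
    if (is.null(best) || key < best) best <- key
  }
  best
}

bin_distance <- function(d, bins) {
  hit <- which(d >= bins[, 1] & d <= bins[, 2])
  if (length(hit)) hit[1] else NA_integer_
}

#' Pharmacophore fingerprint of one molecule
#'
#' Every 2- and 3-subset of distinct feature instances is encoded: the
#' topological distance between two features is the minimum bond-path
#' length between their atom sets; distances are binned, the class is
#' canonicalized under point permutation, and the corresponding bit set.
#' Pairs closer than the lowest bin edge (overlapping or fused features)
#' are discarded.
#'
#' @param mol `bbb_mol`.
#' @param schema a [pharm_schema()]; the calibrated default has 39,971 bits.
#' @param features optional precomputed [detect_pharm_features()] table.
#' @return `bit_fp` of schema `"pharm2d/<bits>"`.
#' @export
molecule_bits <- function(mol, schema = default_pharm_schema(),
                          features = NULL) {
  cache <- pharm_index_env(schema)
  if (is.null(features)) features <- detect_pharm_features(mol)
  nfeat <- nrow(features)
  fp_id <- sprintf("pharm2d/%d", cache$n)
  if (nfeat < 2L) return(bit_fp(integer(), cache$n, fp_id))
  if (length(unlist(features$atoms)) &&
      max(unlist(features$atoms)) > nrow(mol$atoms)) {
    abort("feature references an atom index outside the molecule.")
  }
  g <- mol_heavy_graph(mol)
  vmap <- match(seq_len(nrow(mol$atoms)), igraph::V(g)$aidx)
  dmat <- igraph::distances(g)
  fam_idx <- match(features$family, schema$families)
  if (anyNA(fam_idx)) abort("feature family outside the schema.")
  # pairwise feature distances (min over member atoms), binned
  fd <- matrix(NA_integer_, nfeat, nfeat)
  for (i in seq_len(nfeat - 1L)) {
    vi <- vmap[features$atoms[[i]]]
    for (j in (i + 1L):nfeat) {
      vj <- vmap[features$atoms[[j]]]
      d <- suppressWarnings(min(dmat[vi, vj, drop = FALSE]))
      if (!is.finite(d) || d < schema$bins[1, 1]) next
      fd[i, j] <- fd[j, i] <- bin_distance(d, schema$bins)
    }
  }
  bits <- integer()
  env <- cache$env
  for (i in seq_len(nfeat - 1L)) {
    for (j in (i + 1L):nfeat) {
      b <- fd[i, j]
      if (is.na(b)) next
      ff <- sort(c(fam_idx[i], fam_idx[j]))
      idx <- env[[pharm_key(ff[1], ff[2], b12 = b)]]
      if (!is.null(idx)) bits <- c(bits, idx)
    }
  }
  if (schema$max_points >= 3L && nfeat >= 3L) {
    combs <- utils::combn(nfeat, 3L)
    for (cix in seq_len(ncol(combs))) {
      tri <- combs[, cix]
      b12 <- fd[tri[1], tri[2]]
      b13 <- fd[tri[1], tri[3]]
      b23 <- fd[tri[2], tri[3]]
      if (is.na(b12) || is.na(b13) || is.na(b23)) next
      key <- canonical_triplet_key(fam_idx[tri], b12, b13, b23)
      idx <- env[[key]]
      if (!is.null(idx)) bits <- c(bits, idx)
    }
  }
  bit_fp(unique(bits), cache$n, fp_id)
}

#' Pharmacophore fingerprints for a table of molecules
#'
#' @param tbl tibble with `id` and `smiles_canonical` (or `smiles`).
#' @param schema a [pharm_schema()].
#' @return tibble `id`, `fp`.
#' @export
pharm2d_table <- function(tbl, schema = default_pharm_schema()) {
  smi_col <- if ("smiles_canonical" %in% names(tbl)) "smiles_canonical" else "smiles"
  if ("status" %in% names(tbl)) tbl <- tbl[tbl$status == "ok", , drop = FALSE]
  mols <- smiles_to_mols(tbl[[smi_col]], ids = as.character(tbl$id))
  keep <- !vapply(mols, is.null, TRUE)
  tibble(
    id = tbl$id[keep],
    fp = purrr::map(mols[keep], molecule_bits, schema = schema)
  )
}
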