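# Independent oracle implementations used to cross-check the package's
# geometric and statistical operations. These deliberately re-derive every
# rule with plain loops, separately from the implementation code paths.

oracle_contact_residues <- function(pose_atoms, receptor, cutoff = 4.0) {
  lig <- pose_atoms[pose_atoms$element != "H", , drop = FALSE]
  rec <- receptor[receptor$element != "H", , drop = FALSE]
  keys <- character()
  for (i in seq_len(nrow(lig))) {
    for (j in seq_len(nrow(rec))) {
      d <- sqrt((lig$x[i] - rec$x[j])^2 + (lig$y[i] - rec$y[j])^2 +
                  (lig$z[i] - rec$z[j])^2)
      if (d <= cutoff) keys <- c(keys, rec$residue_key[j])
    }
  }
  sort(unique(keys))
}

oracle_angle <- function(u, v) {
  acos(max(-1, min(1, sum(u * v) / sqrt(sum(u^2) * sum(v^2))))) * 180 / pi
}

# naive all-pairs re-derivation of every geometric interaction test
oracle_detect <- function(lig, res_list, cfg = default_interaction_config()) {
  d3 <- function(p, q) sqrt(sum((p - q)^2))
  row_xyz <- function(tb, i) c(tb$x[i], tb$y[i], tb$z[i])
  out <- list()
  push <- function(type, key) out[[length(out) + 1L]] <<- c(type, key)
  for (key in names(res_list)) {
    rf <- res_list[[key]]
    for (i in seq_len(nrow(lig$hydrophobic))) for (j in seq_len(nrow(rf$hydrophobic))) {
      if (d3(row_xyz(lig$hydrophobic, i), row_xyz(rf$hydrophobic, j)) <= cfg$hydrophobic_max) {
        push("Hydrophobic", key)
      }
    }
    hb <- function(dxyz, hmat, axyz) {
      if (d3(dxyz, axyz) > cfg$hbond_max) return(FALSE)
      if (is.null(hmat) || nrow(hmat) == 0L) return(TRUE)
      any(apply(hmat, 1, function(h) {
        oracle_angle(dxyz - h, axyz - h) >= cfg$hbond_angle_min
      }))
    }
    for (i in seq_len(nrow(lig$donors))) for (j in seq_len(nrow(rf$acceptors))) {
      if (hb(row_xyz(lig$donors, i), lig$donors$h[[i]], row_xyz(rf$acceptors, j))) {
        push("HBDonor", key)
      }
    }
    for (j in seq_len(nrow(rf$donors))) for (i in seq_len(nrow(lig$acceptors))) {
      if (hb(row_xyz(rf$donors, j), rf$donors$h[[j]], row_xyz(lig$acceptors, i))) {
        push("HBAcceptor", key)
      }
    }
    for (i in seq_len(nrow(lig$cations))) {
      for (j in seq_len(nrow(rf$anions))) {
        if (d3(row_xyz(lig$cations, i), row_xyz(rf$anions, j)) <= cfg$ionic_max) {
          push("Cationic", key)
        }
      }
      for (ring in rf$rings) {
        d <- d3(row_xyz(lig$cations, i), ring$centroid)
        if (d <= cfg$cation_pi_max) {
          a <- oracle_angle(ring$normal, row_xyz(lig$cations, i) - ring$centroid)
          if (min(a, 180 - a) <= cfg$cation_pi_angle_max) push("CationPi", key)
        }
      }
    }
    for (i in seq_len(nrow(lig$anions))) for (j in seq_len(nrow(rf$cations))) {
      if (d3(row_xyz(lig$anions, i), row_xyz(rf$cations, j)) <= cfg$ionic_max) {
        push("Anionic", key)
      }
    }
    for (j in seq_len(nrow(rf$cations))) for (ring in lig$rings) {
      d <- d3(row_xyz(rf$cations, j), ring$centroid)
      if (d <= cfg$cation_pi_max) {
        a <- oracle_angle(ring$normal, row_xyz(rf$cations, j) - ring$centroid)
        if (min(a, 180 - a) <= cfg$cation_pi_angle_max) push("PiCation", key)
      }
    }
    for (lr in lig$rings) for (rr in rf$rings) {
      d <- d3(lr$centroid, rr$centroid)
      a <- oracle_angle(lr$normal, rr$normal)
      a <- min(a, 180 - a)
      if ((d <= cfg$pi_stack_ftf_max && a <= cfg$pi_stack_ftf_angle_max) ||
          (d <= cfg$pi_stack_etf_max && a >= cfg$pi_stack_etf_angle[1] &&
             a <= cfg$pi_stack_etf_angle[2])) {
        push("PiStacking", key)
      }
    }
    for (i in seq_len(nrow(lig$atoms))) for (j in seq_len(nrow(rf$atoms))) {
      d <- d3(
        c(lig$atoms$x[i], lig$atoms$y[i], lig$atoms$z[i]),
        c(rf$atoms$x[j], rf$atoms$y[j], rf$atoms$z[j])
      )
      if (d <= vdw_radius(lig$atoms$element[i]) + vdw_radius(rf$atoms$element[j]) +
            cfg$vdw_tolerance) {
        push("VdWContact", key)
      }
    }
  }
  if (!length(out)) {
    return(data.frame(type = character(), residue_key = character()))
  }
  df <- as.data.frame(do.call(rbind, out), stringsAsFactors = FALSE)
  names(df) <- c("type", "residue_key")
  df
}

# sorted event multiset signature, for comparing detectors
event_signature <- function(df) {
  sort(paste(df$type, df$residue_key, sep = "|"))
}

oracle_metrics <- function(tp, tn, fp, fn) {
  tot <- tp + tn + fp + fn
  acc <- (tp + tn) / tot
  prec <- if (tp + fp == 0) 0 else tp / (tp + fp)
  rec <- if (tp + fn == 0) 0 else tp / (tp + fn)
  f1 <- if (prec + rec == 0) 0 else 2 * prec * rec / (prec + rec)
  den <- (tp + fp) * (tp + fn) * (tn + fp) * (tn + fn)
  mcc <- if (den == 0) 0 else (tp * tn - fp * fn) / sqrt(den)
  c(accuracy = acc, precision = prec, recall = rec, f1 = f1, mcc = mcc)
}

# recursive (non-iterative) re-derivation of circular-fingerprint atom
# identifiers, sharing only the hash primitive with the implementation
oracle_ecfp_ids <- function(mol) {
  heavy <- mol$atoms$idx[mol$atoms$heavy]
  neighbors <- function(i) {
    up <- mol$bonds[mol$bonds$a1 == i & mol$bonds$a2 %in% heavy, c("a2", "order")]
    dn <- mol$bonds[mol$bonds$a2 == i & mol$bonds$a1 %in% heavy, c("a1", "order")]
    names(up) <- names(dn) <- c("j", "order")
    rbind(up, dn)
  }
  invariant <- function(i) {
    a <- mol$atoms[i, ]
    anum <- match(a$elem, c(
      "H", "He", "Li", "Be", "B", "C", "N", "O", "F", "Ne", "Na", "Mg", "Al",
      "Si", "P", "S", "Cl", "Ar", "K", "Ca", "Br", "I"
    ))
    if (is.na(anum)) anum <- 0L
    in_ring <- any(vapply(mol$arom_rings, function(r) i %in% r, TRUE))
    deg <- nrow(neighbors(i))
    c(anum, deg, a$nh, round(a$charge) + 8, as.integer(in_ring))
  }
  id_at <- function(i, r) {
    if (r == 0) return(bbbfp:::hash31(invariant(i)))
    nb <- neighbors(i)
    if (nrow(nb) == 0L) return(bbbfp:::hash31(c(r, id_at(i, r - 1))))
    pairs <- cbind(nb$order, vapply(nb$j, function(j) id_at(j, r - 1), 0))
    pairs <- pairs[order(pairs[, 1], pairs[, 2]), , drop = FALSE]
    bbbfp:::hash31(c(r, id_at(i, r - 1), as.vector(t(pairs))))
  }
  unlist(lapply(0:2, function(r) vapply(heavy, function(i) id_at(i, r), 0)))
}

pose_atoms_of <- function(mol) {
  stats::setNames(mol$atoms[, c("elem", "x", "y", "z")], c("element", "x", "y", "z"))
}
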