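#' Sentinel returned for molecules without rings
#' @export
ACYCLIC <- "ACYCLIC"

#' Bemis-Murcko scaffold of a molecule
#'
#' The scaffold keeps every ring system and every linker connecting two
#' rings, and removes terminal side chains. Operationally the scaffold atom
#' set is the 2-core of the heavy-atom graph (iterated removal of
#' degree-one atoms) plus any atom attached to the core by a double or
#' triple bond (so exocyclic carbonyls and the like keep their valence).
#' Acyclic molecules have an empty 2-core and map to the [ACYCLIC] sentinel.
#'
#' @param mol a `bbb_mol`, or a SMILES string.
#' @return canonical scaffold SMILES, or [ACYCLIC].
#' @examples
#' \dontrun{
#' murcko_scaffold("Cc1ccccc1") # toluene -> benzene
#' murcko_scaffold("CCCCCC")    # -> "ACYCLIC"
#' }
#' @export
murcko_scaffold <- function(mol) {
  if (is.character(mol)) {
    mol <- smiles_to_mols(mol)[[1]]
    if (is.null(mol)) abort("SMILES failed to parse.")
  }
  stopifnot(inherits(mol, "bbb_mol"))
  g <- mol_heavy_graph(mol)
  if (igraph::vcount(g) == 0L) return(ACYCLIC)
  core <- igraph::V(g)$aidx[igraph::coreness(g) >= 2]
  if (length(core) == 0L) return(ACYCLIC)
  # retain atoms multiply bonded to the core (exocyclic =O, =N, etc.)
  multi <- mol$bonds[mol$bonds$order >= 2L, , drop = FALSE]
  extra <- c(
    multi$a2[multi$a1 %in% core & !multi$a2 %in% core],
    multi$a1[multi$a2 %in% core & !multi$a1 %in% core]
  )
  extra <- extra[mol$atoms$heavy[extra]]
  keep <- sort(unique(c(core, extra)))
  mol_canonical_smiles(mol, keep = keep)
}

#' Group molecules by scaffold and score permeation probability
#'
#' One group per distinct canonical scaffold SMILES; acyclic molecules are
#' collected in a separate [ACYCLIC] group that is excluded from scaffold
#' statistics. The permeation probability of a scaffold is the fraction of
#' its labelled members that are permeable; members with unknown label count
#' towards membership but not towards the probability.
#'
#' @param tbl tibble with `id`, `smiles_canonical` (or `smiles`), and
#'   optionally `label` (1 permeable / 0 non-permeable / NA unknown).
#' @return tibble: `scaffold_smiles`, `member_ids` (list), `n_members`,
#'   `n_pos`, `n_neg`, `probability`, `category`.
#' @export
group_by_scaffold <- function(tbl) {
  stopifnot(is.data.frame(tbl), "id" %in% names(tbl))
  smi_col <- if ("smiles_canonical" %in% names(tbl)) "smiles_canonical" else "smiles"
  if (!smi_col %in% names(tbl)) abort("need a `smiles` or `smiles_canonical` column.")
  if (!"label" %in% names(tbl)) tbl$label <- NA_integer_
  mols <- smiles_to_mols(tbl[[smi_col]], ids = as.character(tbl$id))
  scaf <- vapply(mols, function(m) {
    if (is.null(m)) NA_character_ else murcko_scaffold(m)
  }, "")
  d <- tibble(id = as.character(tbl$id), label = tbl$label, scaffold = scaf)
  d <- d[!is.na(d$scaffold), , drop = FALSE]
  d %>%
    group_by(.data$scaffold) %>%
    summarise(
      member_ids = list(.data$id),
      n_members = n(),
      n_pos = sum(.data$label == 1, na.rm = TRUE),
      n_neg = sum(.data$label == 0, na.rm = TRUE),
      .groups = "drop"
    ) %>%
    mutate(
      probability = ifelse(.data$n_pos + .data$n_neg > 0,
        .data$n_pos / (.data$n_pos + .data$n_neg), NA_real_
      ),
      category = purrr::map_chr(.data$probability, categorize_scaffold)
    ) %>%
    dplyr::rename(scaffold_smiles = "scaffold") %>%
    arrange(desc(.data$n_members), .data$scaffold_smiles)
}

#' Categorize a scaffold by permeation probability
#'
#' Probability above 0.6 is `permeable`, below 0.4 `non_permeable`, and the
#' closed interval \[0.4, 0.6\] — including both boundaries — is `neutral`.
#'
#' @param probability number in \[0, 1\] (NA allowed: returns `"unknown"`).
#' @return one of `"permeable"`, `"neutral"`, `"non_permeable"`, `"unknown"`.
#' @export
categorize_scaffold <- function(probability) {
  if (is.na(probability)) return("unknown")
  if (probability < 0 || probability > 1) {
    abort("`probability` must lie in [0, 1].")
  }
  if (probability > 0.6) "permeable"
  else if (probability < 0.4) "non_permeable"
  else "neutral"
}

#' Summary statistics of a scaffold grouping
#'
#' @param groups output of [group_by_scaffold()].
#' @param top_k how many of the largest groups to list.
#' @return list with `n_groups`, `singleton_fraction`, `category_counts`
#'   (named vector over permeable/neutral/non_permeable/unknown), and
#'   `top_groups` (tibble).
#' @export
scaffold_summary <- function(groups, top_k = 10L) {
  stopifnot(nrow(groups) >= 1L)
  scaff <- groups[groups$scaffold_smiles != ACYCLIC, , drop = FALSE]
  cats <- c("permeable", "neutral", "non_permeable", "unknown")
  cc <- setNames(integer(length(cats)), cats)
  tabs <- table(scaff$category)
  cc[names(tabs)] <- as.integer(tabs)
  list(
    n_groups = nrow(scaff),
    n_acyclic = sum(groups$scaffold_smiles == ACYCLIC),
    singleton_fraction = if (nrow(scaff)) mean(scaff$n_members == 1L) else NA_real_,
    category_counts = cc,
    top_groups = head(scaff[order(-scaff$n_members), ], top_k)
  )
}

#' Write the scaffold table to CSV
#'
#' @param groups output of [group_by_scaffold()].
#' @param path output file.
#' @export
write_scaffold_csv <- function(groups, path) {
  out <- groups %>%
    mutate(member_ids = vapply(.data$member_ids, paste, "", collapse = " ")) %>%
    select("scaffold_smiles", "n_members", "n_pos", "n_neg", "probability", "category")
  write.csv(out, path, row.names = FALSE)
  invisible(path)
}
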