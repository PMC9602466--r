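#' Bit fingerprints
#'
#' A `bit_fp` is a schema-tagged sparse bit vector: the 0-based indices of
#' the set bits, the total length, and a schema identifier naming the bit
#' layout (e.g. `"ecfp4/1024"`, `"residue/62"`, `"itype/9"`,
#' `"pharm2d/39971"`). All fingerprint generators in the package return this
#' type and all consumers (Tanimoto, concatenation, the benchmark matrix
#' builder) accept it.
#'
#' @param set_bits integer vector of 0-based bit indices (any order,
#'   duplicates tolerated).
#' @param length total number of bits; positive integer.
#' @param schema_id character scalar tagging the bit layout.
#' @return An object of class `bit_fp`.
#' @examples
#' fp <- bit_fp(c(3, 1), 8, "demo/8")
#' fp$set_bits
#' @export
bit_fp <- function(set_bits, length, schema_id = "unknown") {
  if (length(length) != 1L || is.na(length) || length <= 0) {
    abort("`length` must be a positive integer.")
  }
  set_bits <- sort(unique(as.integer(set_bits)))
  if (any(set_bits < 0L) || any(set_bits >= length)) {
    abort("set bit indices must lie in [0, length).")
  }
  structure(
    list(set_bits = set_bits, length = as.integer(length), schema_id = schema_id),
    class = "bit_fp"
  )
}

#' @export
print.bit_fp <- function(x, ...) {
  cat(sprintf(
    "<bit_fp %s: %d/%d bits set>\n", x$schema_id,
    length(x$set_bits), x$length
  ))
  invisible(x)
}

#' @export
format.bit_fp <- function(x, ...) {
  sprintf("<fp %s %d/%d>", x$schema_id, length(x$set_bits), x$length)
}

is_bit_fp <- function(x) inherits(x, "bit_fp")

#' Tanimoto similarity between two bit fingerprints
#'
#' \eqn{T(A,B) = |A \cap B| / |A \cup B|}. Two all-zero fingerprints are
#' defined to have similarity 1.
#'
#' @param a,b `bit_fp` objects of equal length.
#' @return A number in \[0, 1\].
#' @examples
#' tanimoto(bit_fp(c(1, 2, 3), 8), bit_fp(c(2, 3, 4), 8))
#' @export
tanimoto <- function(a, b) {
  stopifnot(is_bit_fp(a), is_bit_fp(b))
  if (a$length != b$length) {
    abort("fingerprint lengths differ; Tanimoto is undefined.")
  }
  ni <- length(intersect(a$set_bits, b$set_bits))
  nu <- length(union(a$set_bits, b$set_bits))
  if (nu == 0L) return(1)
  ni / nu
}

#' Concatenate fingerprints of one molecule
#'
#' Lengths add; set bits of later fingerprints are offset by the cumulative
#' length of the earlier ones, in the order given. This is the feature-merge
#' used when a connectivity fingerprint is combined with the docking-derived
#' fingerprints.
#'
#' @param fps list of `bit_fp` objects.
#' @return A single `bit_fp` whose schema id joins the inputs with `"+"`.
#' @examples
#' concat_features(list(bit_fp(0, 4, "a"), bit_fp(0, 2, "b")))
#' @export
concat_features <- function(fps) {
  stopifnot(is.list(fps), length(fps) >= 1L, all(vapply(fps, is_bit_fp, TRUE)))
  offsets <- cumsum(c(0L, vapply(fps, function(f) f$length, 0L)))
  total <- offsets[length(offsets)]
  bits <- unlist(purrr::map2(
    fps, offsets[-length(offsets)],
    function(f, off) f$set_bits + off
  ))
  bit_fp(bits, total, paste(vapply(fps, function(f) f$schema_id, ""), collapse = "+"))
}

#' Dense 0/1 matrix from a list-column of fingerprints
#'
#' @param fps list of `bit_fp` of identical length and schema.
#' @param drop_empty drop columns that are zero for every row (useful before
#'   model fitting on very long sparse fingerprints).
#' @return integer matrix, one row per fingerprint.
#' @export
fp_matrix <- function(fps, drop_empty = FALSE) {
  stopifnot(length(fps) >= 1L, all(vapply(fps, is_bit_fp, TRUE)))
  len <- unique(vapply(fps, function(f) f$length, 0L))
  if (length(len) != 1L) abort("fingerprints have differing lengths.")
  m <- matrix(0L, nrow = length(fps), ncol = len)
  for (i in seq_along(fps)) {
    b <- fps[[i]]$set_bits
    if (length(b)) m[i, b + 1L] <- 1L
  }
  colnames(m) <- paste0("bit_", seq_len(len) - 1L)
  if (drop_empty) m <- m[, colSums(m) > 0L, drop = FALSE]
  m
}

#' Write / read sparse fingerprint tables
#'
#' The interchange format between pipeline stages is a two-column CSV:
#' `id` and `set_bits` (space-separated 0-based indices). A `length` and
#' `schema_id` are carried in a `# schema:` comment on the first line.
#'
#' @param tbl tibble with columns `id` and `fp` (list of `bit_fp`).
#' @param path file to write.
#' @return `write_fp_csv()` returns `path` invisibly; `read_fp_csv()`
#'   returns a tibble with columns `id` and `fp`.
#' @export
write_fp_csv <- function(tbl, path) {
  stopifnot(all(c("id", "fp") %in% names(tbl)))
  len <- unique(vapply(tbl$fp, function(f) f$length, 0L))
  sch <- unique(vapply(tbl$fp, function(f) f$schema_id, ""))
  if (length(len) != 1L || length(sch) != 1L) {
    abort("all fingerprints in a table must share one schema.")
  }
  lines <- c(
    sprintf("# schema: %s length: %d", sch, len),
    "id,set_bits",
    vapply(seq_len(nrow(tbl)), function(i) {
      paste0(tbl$id[[i]], ",", paste(tbl$fp[[i]]$set_bits, collapse = " "))
    }, "")
  )
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_fp_csv
#' @export
read_fp_csv <- function(path) {
  lines <- readLines(path, warn = FALSE)
  hdr <- regmatches(lines[1], regexec("# schema: (\\S+) length: (\\d+)", lines[1]))[[1]]
  if (length(hdr) != 3L) abort("missing '# schema:' header line.")
  sch <- hdr[2]
  len <- as.integer(hdr[3])
  body <- lines[-(1:2)]
  body <- body[nzchar(body)]
  ids <- sub(",.*$", "", body)
  bits <- sub("^[^,]*,", "", body)
  tibble(
    id = ids,
    fp = purrr::map(bits, function(s) {
      v <- if (nzchar(trimws(s))) as.integer(strsplit(trimws(s), " +")[[1]]) else integer()
      bit_fp(v, len, sch)
    })
  )
}
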