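#' One-hot encodings of sequence windows
#'
#' Two binary representations feed the network. The *general* encoding maps
#' each base to a length-4 unit row vector in the fixed column order
#' A, U, C, G, so an N-nucleotide window becomes an N x 4 matrix. The
#' *merged-seq* encoding first pairs each base with its dot-bracket symbol
#' (`.`, `(`, `)`), giving 4 x 3 = 12 possible pairs, then one-hot encodes
#' the pairs into an N x 12 matrix. Columns of the merged encoding are
#' ordered base-major: `A.`, `A(`, `A)`, `U.`, `U(`, `U)`, `C.`, `C(`,
#' `C)`, `G.`, `G(`, `G)`; the base order A, U, C, G matches the 4-letter
#' case and the symbol order is `.`, `(`, `)`. Rows run 5' to 3'.
#'
#' @param residues a single RNA sequence (A/C/G/U).
#' @return A binary matrix, rows = positions, one 1 per row; column names
#'   give the alphabet; attribute `encoding_kind` is `"general"` or
#'   `"merged"`.
#' @examples
#' encode_general("AUCG")
#' encode_merged(merge_sequence("GAC", "(.)"))
#' @export
encode_general <- function(residues) {
  base_order <- c("A", "U", "C", "G")
  sym <- strsplit(normalize_residues(residues), "")[[1]]
  idx <- match(sym, base_order)
  if (anyNA(idx)) {
    abort(paste0("non-canonical residue '", sym[which(is.na(idx))[1]],
                 "' cannot be one-hot encoded"))
  }
  m <- matrix(0L, nrow = length(sym), ncol = 4L,
              dimnames = list(NULL, base_order))
  m[cbind(seq_along(idx), idx)] <- 1L
  attr(m, "encoding_kind") <- "general"
  m
}

#' @rdname encode_general
#' @param structure dot-bracket string of the same length as `residues`.
#' @return `merge_sequence()` returns a `merged_seq`: a character vector of
#'   two-character (base, symbol) pairs with the originals kept as
#'   attributes.
#' @export
merge_sequence <- function(residues, structure) {
  residues <- normalize_residues(residues)
  if (nchar(residues) != nchar(structure)) {
    abort(paste0("sequence length ", nchar(residues),
                 " and structure length ", nchar(structure), " differ"))
  }
  parse_dot_bracket(structure)
  pairs <- paste0(strsplit(residues, "")[[1]], strsplit(structure, "")[[1]])
  structure(pairs, class = "merged_seq",
            residues = residues, db = structure)
}

merged_alphabet <- function() {
  paste0(rep(c("A", "U", "C", "G"), each = 3), c(".", "(", ")"))
}

#' @rdname encode_general
#' @param merged a `merged_seq` from [merge_sequence()].
#' @export
encode_merged <- function(merged) {
  if (!inherits(merged, "merged_seq")) {
    abort("encode_merged() expects the result of merge_sequence()")
  }
  alpha <- merged_alphabet()
  idx <- match(unclass(merged), alpha)
  m <- matrix(0L, nrow = length(merged), ncol = 12L,
              dimnames = list(NULL, alpha))
  m[cbind(seq_along(idx), idx)] <- 1L
  attr(m, "encoding_kind") <- "merged"
  m
}

#' Decode a one-hot matrix back to its window
#'
#' Inverse of the encoders: recovers the residue string (and, for the
#' merged encoding, the dot-bracket string). Errors if any row is not
#' exactly one-hot.
#'
#' @param m an encoded matrix from [encode_general()] or [encode_merged()].
#' @return For a 4-column matrix, the residue string; for a 12-column
#'   matrix, a list with `residues` and `structure`.
#' @export
decode_matrix <- function(m) {
  if (!all(m %in% c(0, 1)) || any(rowSums(m) != 1)) {
    abort("matrix is not one-hot: every row must contain a single 1")
  }
  if (ncol(m) == 4L) {
    paste(c("A", "U", "C", "G")[max.col(m)], collapse = "")
  } else if (ncol(m) == 12L) {
    pairs <- merged_alphabet()[max.col(m)]
    list(
      residues = paste(substr(pairs, 1, 1), collapse = ""),
      structure = paste(substr(pairs, 2, 2), collapse = "")
    )
  } else {
    abort("expected 4 (general) or 12 (merged) columns")
  }
}

#' Encode a whole window set for the network
#'
#' Maps every window of a set to its one-hot matrix and stacks them into a
#' 3-D array `n x positions x alphabet`, the input shape the network
#' consumes, together with the label vector.
#'
#' @param ds validated tibble of windows.
#' @param kind `"general"` (N x 4) or `"merged"` (N x 12).
#' @param structures for `kind = "merged"`, a tibble with `id` and
#'   `structure` columns ([read_structures()] / [fold_windows()] output)
#'   covering every window id.
#' @return List with `x` (3-D array), `y` (integer labels) and `ids`.
#' @export
encode_dataset <- function(ds, kind = c("general", "merged"), structures = NULL) {
  kind <- match.arg(kind)
  validate_windows(ds)
  n <- nrow(ds)
  rows <- 2L * ds$xi[1] + 1L
  if (kind == "general") {
    mats <- lapply(ds$residues, encode_general)
  } else {
    if (is.null(structures)) {
      abort("merged encoding needs structures (see fold_windows / read_structures)")
    }
    s <- structures$structure[match(ds$id, structures$id)]
    if (anyNA(s)) {
      abort(paste0("no structure for record '", ds$id[which(is.na(s))[1]], "'"))
    }
    mats <- Map(function(r, st) encode_merged(merge_sequence(r, st)),
                ds$residues, s)
  }
  cols <- ncol(mats[[1]])
  x <- array(0L, dim = c(n, rows, cols),
             dimnames = list(NULL, NULL, colnames(mats[[1]])))
  for (i in seq_len(n)) x[i, , ] <- mats[[i]]
  list(x = x, y = ds$label, ids = ds$id, encoding = kind)
}
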