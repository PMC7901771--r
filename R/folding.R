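#' Parse dot-bracket secondary structure
#'
#' Validates a dot-bracket string — `.` for an unpaired nucleotide, `(` for
#' a 5'-side paired nucleotide and `)` for its 3'-side partner — and derives
#' the induced base-pair index set. Brackets must balance; pairs are nested
#' by construction of the notation (no pseudoknots are representable).
#'
#' @param s dot-bracket string.
#' @return An object of class `dot_bracket`: a list with `symbols` (the
#'   string), `length`, and `pairs`, an integer matrix with columns `i`, `j`
#'   of 0-based paired indices (i < j), ordered by `i`.
#' @examples
#' parse_dot_bracket("((...))")$pairs
#' @export
parse_dot_bracket <- function(s) {
  if (!is.character(s) || length(s) != 1L || nchar(s) == 0L) {
    abort("dot-bracket string must be a single non-empty string")
  }
  sym <- strsplit(s, "")[[1]]
  bad <- which(!sym %in% c(".", "(", ")"))
  if (length(bad) > 0) {
    abort(paste0("character '", sym[bad[1]], "' at index ", bad[1] - 1L,
                 " is not one of '.', '(', ')'"))
  }
  stack <- integer(0)
  pairs <- matrix(integer(0), ncol = 2, dimnames = list(NULL, c("i", "j")))
  for (k in seq_along(sym)) {
    if (sym[k] == "(") {
      stack <- c(stack, k)
    } else if (sym[k] == ")") {
      if (length(stack) == 0) {
        abort(paste0("unbalanced ')' at index ", k - 1L))
      }
      pairs <- rbind(pairs, c(stack[length(stack)] - 1L, k - 1L))
      stack <- stack[-length(stack)]
    }
  }
  if (length(stack) > 0) {
    abort(paste0("unbalanced '(' at index ", stack[1] - 1L))
  }
  pairs <- pairs[order(pairs[, 1]), , drop = FALSE]
  structure(
    list(symbols = s, length = length(sym), pairs = pairs),
    class = "dot_bracket"
  )
}

#' @export
print.dot_bracket <- function(x, ...) {
  cat("<dot_bracket> length ", x$length, ", ", nrow(x$pairs), " pair(s)\n",
      x$symbols, "\n", sep = "")
  invisible(x)
}

#' Fold sequences with an external thermodynamic folder
#'
#' Calls an RNAfold-compatible command on each sequence and returns the
#' minimum-free-energy dot-bracket line (the trailing energy annotation is
#' stripped; suboptimal structures are ignored). The command must accept
#' FASTA on stdin and print, per record, a sequence line followed by the
#' structure line — RNAfold's default plain-text dialect.
#'
#' @param residues character vector of RNA sequences.
#' @param folder_cmd the folder executable, default `"RNAfold"`.
#' @param args extra command-line arguments (default `"--noPS"` to suppress
#'   PostScript drawings).
#' @return character vector of dot-bracket strings, one per sequence.
#' @seealso [fold_nussinov()] for the built-in deterministic fallback.
#' @export
fold_external <- function(residues, folder_cmd = "RNAfold", args = "--noPS") {
  if (Sys.which(folder_cmd) == "") {
    abort(paste0(
      "external folder '", folder_cmd, "' not found on PATH; ",
      "use fold_nussinov() or precomputed structures instead"
    ))
  }
  fa <- tempfile(fileext = ".fa")
  on.exit(unlink(fa), add = TRUE)
  writeLines(as.character(rbind(paste0(">q", seq_along(residues)), residues)), fa)
  out <- suppressWarnings(
    system2(folder_cmd, args = c(args, shQuote(fa)), stdout = TRUE, stderr = FALSE)
  )
  status <- attr(out, "status")
  if (!is.null(status) && status != 0) {
    abort(paste0("'", folder_cmd, "' exited with status ", status,
                 "; use fold_nussinov() or precomputed structures instead"))
  }
  structs <- character(length(residues))
  idx <- 0L
  i <- 1L
  while (i <= length(out)) {
    if (startsWith(out[i], ">")) {
      if (i + 2L > length(out)) {
        abort(paste0("unparseable '", folder_cmd, "' output: truncated record"))
      }
      idx <- idx + 1L
      structs[idx] <- strip_energy(out[i + 2L])
      i <- i + 3L
    } else {
      i <- i + 1L
    }
  }
  if (idx != length(residues)) {
    abort(paste0("unparseable '", folder_cmd, "' output: expected ",
                 length(residues), " records, found ", idx))
  }
  for (k in seq_along(residues)) {
    if (nchar(structs[k]) != nchar(residues[k])) {
      abort(paste0("folder returned structure of length ", nchar(structs[k]),
                   " for sequence of length ", nchar(residues[k])))
    }
    parse_dot_bracket(structs[k])
  }
  structs
}

#' Fold sequences by Nussinov maximum pairing
#'
#' A deterministic built-in folder: dynamic programming that maximizes the
#' number of nested canonical base pairs (AU, UA, GC, CG and the GU/UG
#' wobble) subject to a minimum loop length — a pair (i, j) is allowed only
#' when `j - i > min_loop`. It makes no thermodynamic claim; it exists so
#' that merged-seq pipelines are reproducible without an external folder.
#'
#' Ties are broken by a fixed traceback rule: leaving position i unpaired is
#' preferred over pairing it, and among equal-scoring partners the smallest
#' j wins, so outputs are fully deterministic.
#'
#' @param residues character vector of RNA sequences (A/C/G/U; T accepted
#'   and normalized).
#' @param min_loop minimum number of unpaired positions enclosed by a pair
#'   (default 3).
#' @return character vector of dot-bracket strings.
#' @examples
#' fold_nussinov("GGGAAAACCC")
#' @export
fold_nussinov <- function(residues, min_loop = 3L) {
  residues <- normalize_residues(residues)
  if (any(nchar(residues) == 0L)) {
    abort("cannot fold an empty sequence")
  }
  vapply(residues, nussinov_one, "", min_loop = as.integer(min_loop),
         USE.NAMES = FALSE)
}

can_pair <- function(a, b) {
  paste0(a, b) %in% c("AU", "UA", "GC", "CG", "GU", "UG")
}

nussinov_one <- function(seq, min_loop) {
  b <- strsplit(seq, "")[[1]]
  n <- length(b)
  if (n <= min_loop + 1L) {
    return(strrep(".", n))
  }
  M <- matrix(0L, n, n)
  for (span in (min_loop + 1L):(n - 1L)) {
    for (i in 1:(n - span)) {
      j <- i + span
      best <- M[i + 1L, j]                       # i unpaired
      for (k in (i + min_loop + 1L):j) {         # i pairs k, split at k
        if (can_pair(b[i], b[k])) {
          inner <- if (k - i > 1L) M[i + 1L, k - 1L] else 0L
          rest <- if (k < j) M[k + 1L, j] else 0L
          best <- max(best, 1L + inner + rest)
        }
      }
      M[i, j] <- best
    }
  }
  sym <- rep(".", n)
  # iterative traceback with explicit stack; prefers "i unpaired", then smallest k
  stack <- list(c(1L, n))
  while (length(stack) > 0) {
    ij <- stack[[length(stack)]]
    stack[[length(stack)]] <- NULL
    i <- ij[1]; j <- ij[2]
    if (j - i <= min_loop) next
    if (M[i, j] == M[i + 1L, j]) {
      stack[[length(stack) + 1L]] <- c(i + 1L, j)
      next
    }
    for (k in (i + min_loop + 1L):j) {
      if (can_pair(b[i], b[k])) {
        inner <- if (k - i > 1L) M[i + 1L, k - 1L] else 0L
        rest <- if (k < j) M[k + 1L, j] else 0L
        if (M[i, j] == 1L + inner + rest) {
          sym[i] <- "("
          sym[k] <- ")"
          if (k - i > 1L) stack[[length(stack) + 1L]] <- c(i + 1L, k - 1L)
          if (k < j) stack[[length(stack) + 1L]] <- c(k + 1L, j)
          break
        }
      }
    }
  }
  paste(sym, collapse = "")
}

#' Fold a window set
#'
#' Convenience wrapper mapping a window tibble to a structure tibble using
#' the chosen folder.
#'
#' @param ds validated tibble of windows.
#' @param folder `"nussinov"` or `"external"`.
#' @param ... passed to [fold_nussinov()] or [fold_external()].
#' @return A tibble with columns `id`, `residues`, `structure`.
#' @export
fold_windows <- function(ds, folder = c("nussinov", "external"), ...) {
  folder <- match.arg(folder)
  validate_windows(ds)
  structure_str <- switch(folder,
    nussinov = fold_nussinov(ds$residues, ...),
    external = fold_external(ds$residues, ...)
  )
  tibble::tibble(id = ds$id, residues = ds$residues, structure = structure_str)
}
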