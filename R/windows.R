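#' Labeled uridine-centered sequence windows
#'
#' A window set is an ordinary tibble with one row per candidate site and
#' columns `id` (character, unique), `residues` (character over A/C/G/U),
#' `xi` (integer flank length), `label` (integer, 1 = pseudouridine site,
#' 0 = non-site) and optionally `species` (free text such as "HS", "SC",
#' "MM"). Every window spans `2 * xi + 1` nucleotides with a uridine at the
#' central position, i.e. at 0-based index `xi`; all windows in one set
#' share the same `xi`.
#'
#' `psi_windows()` builds and validates such a tibble from its columns;
#' `validate_windows()` checks an existing data frame and returns it
#' (invisibly) or aborts with the offending record named.
#'
#' @param id character vector of record identifiers.
#' @param residues character vector of RNA sequences. `T`/lower case are
#'   normalized to `U`/upper case; any other letter is rejected.
#' @param label integer/numeric vector of 0/1 class labels.
#' @param species optional character vector of species tags.
#' @return A tibble of validated windows.
#' @examples
#' psi_windows("w1", "ACGUACGUACUACGUACGUAC", 1)
#' @export
psi_windows <- function(id, residues, label, species = NA_character_) {
  residues <- normalize_residues(residues)
  n <- length(residues)
  ds <- tibble::tibble(
    id = as.character(id),
    residues = residues,
    xi = as.integer((nchar(residues) - 1L) %/% 2L),
    label = as.integer(label),
    species = rep_len(as.character(species), n)
  )
  validate_windows(ds)
  ds
}

normalize_residues <- function(residues) {
  chartr("Tt", "Uu", toupper(as.character(residues)))
}

#' @rdname psi_windows
#' @param ds a data frame of windows as described above.
#' @export
validate_windows <- function(ds) {
  need <- c("id", "residues", "xi", "label")
  miss <- setdiff(need, names(ds))
  if (length(miss) > 0) {
    abort(paste0("window set lacks column(s): ", paste(miss, collapse = ", ")))
  }
  if (nrow(ds) == 0) {
    return(invisible(ds))
  }
  len <- nchar(ds$residues)
  bad <- which(len != 2L * ds$xi + 1L | len %% 2L == 0L)
  if (length(bad) > 0) {
    abort(paste0(
      "record '", ds$id[bad[1]], "': length ", len[bad[1]],
      " is not 2*xi+1 with xi = ", ds$xi[bad[1]]
    ))
  }
  if (length(unique(ds$xi)) != 1L) {
    abort("all windows in a set must share the same xi (mixed window lengths)")
  }
  foreign <- regexpr("[^ACGU]", ds$residues)
  bad <- which(foreign > 0)
  if (length(bad) > 0) {
    abort(paste0(
      "record '", ds$id[bad[1]], "': disallowed character '",
      substr(ds$residues[bad[1]], foreign[bad[1]], foreign[bad[1]]),
      "' at position ", foreign[bad[1]],
      " (only A, C, G, U are accepted; ambiguity codes are rejected)"
    ))
  }
  center <- substr(ds$residues, ds$xi + 1L, ds$xi + 1L)
  bad <- which(center != "U")
  if (length(bad) > 0) {
    abort(paste0(
      "record '", ds$id[bad[1]], "': central position (index ", ds$xi[bad[1]],
      ", 0-based) is '", center[bad[1]], "', not U"
    ))
  }
  if (!all(ds$label %in% c(0L, 1L))) {
    abort("labels must be 0 (non-site) or 1 (pseudouridine site)")
  }
  invisible(ds)
}

#' Read a labeled window set
#'
#' Reads uridine-centered windows from FASTA (labels carried in the header
#' as a `label=0` / `label=1` token, pipe- or space-delimited) or from a
#' two-column whitespace-delimited text file (`sequence label` per line,
#' optional third column used as id). Sequences are normalized (T to U,
#' upper case) and validated against the window contract: odd length
#' `2*xi + 1` with U at the central position.
#'
#' @param path file to read.
#' @param format `"fasta"` or `"two_column"`.
#' @return A validated tibble of windows (see [psi_windows()]).
#' @examples
#' f <- tempfile(fileext = ".fasta")
#' writeLines(c(">w1|label=1", "ACGUACGUACUACGUACGUAC"), f)
#' read_dataset(f)
#' @export
read_dataset <- function(path, format = c("fasta", "two_column")) {
  format <- match.arg(format)
  if (!file.exists(path)) {
    abort(paste0("no such file: ", path))
  }
  if (format == "fasta") {
    recs <- Biostrings::readBStringSet(path)
    headers <- names(recs)
    if (length(headers) > 0 && any(!nzchar(headers))) {
      abort(paste0("empty FASTA header in ", path))
    }
    lab <- parse_label_token(headers)
    id <- sub("[| ].*$", "", headers)
    ds <- psi_windows(id, as.character(recs), lab,
                      species = parse_species_token(headers))
  } else {
    lines <- readLines(path)
    lines <- lines[nzchar(trimws(lines))]
    fields <- strsplit(trimws(lines), "[ \t]+")
    nf <- lengths(fields)
    bad <- which(nf < 2L)
    if (length(bad) > 0) {
      abort(paste0("line ", bad[1], " of ", path,
                   ": expected 'sequence label [id]', got '", lines[bad[1]], "'"))
    }
    seqs <- vapply(fields, `[[`, "", 1L)
    lab <- suppressWarnings(as.integer(vapply(fields, `[[`, "", 2L)))
    bad <- which(is.na(lab))
    if (length(bad) > 0) {
      abort(paste0("line ", bad[1], " of ", path, ": label is not 0/1"))
    }
    id <- ifelse(nf >= 3L, vapply(fields, function(f) f[3L], ""),
                 paste0("w", seq_along(seqs)))
    ds <- psi_windows(id, seqs, lab)
  }
  ds
}

parse_label_token <- function(headers) {
  m <- regmatches(headers, regexpr("label=[01]", headers))
  found <- grepl("label=[01]", headers)
  if (any(!found)) {
    abort(paste0("header '", headers[which(!found)[1]],
                 "' carries no label=0|1 token"))
  }
  as.integer(sub("label=", "", m))
}

parse_species_token <- function(headers) {
  out <- rep(NA_character_, length(headers))
  hit <- regexpr("species=[^| ]+", headers)
  has <- hit > 0
  out[has] <- sub("species=", "", regmatches(headers, hit))
  out
}

#' Write a labeled window set
#'
#' Writes windows in the format [read_dataset()] reads, so that a write
#' followed by a read reproduces the same windows, labels and order.
#'
#' @param ds validated tibble of windows.
#' @param path output file.
#' @param format `"fasta"` or `"two_column"`.
#' @return `path`, invisibly.
#' @export
write_dataset <- function(ds, path, format = c("fasta", "two_column")) {
  format <- match.arg(format)
  validate_windows(ds)
  if (nrow(ds) == 0L) {
    writeLines(character(0), path)
    return(invisible(path))
  }
  if (format == "fasta") {
    hdr <- paste0(ds$id, "|label=", ds$label)
    sp <- !is.na(ds[["species"]]) & nzchar(ds[["species"]])
    if (!is.null(ds[["species"]]) && any(sp)) {
      hdr[sp] <- paste0(hdr[sp], "|species=", ds$species[sp])
    }
    x <- Biostrings::BStringSet(setNames(ds$residues, hdr))
    Biostrings::writeXStringSet(x, path)
  } else {
    writeLines(paste(ds$residues, ds$label, ds$id), path)
  }
  invisible(path)
}

#' Read per-record secondary structures
#'
#' Parses an RNAfold-style structure file: for each record a header line
#' (`>id`), a sequence line, and a dot-bracket line with an optional
#' trailing free energy in parentheses (the energy is ignored). A bare
#' two-line dialect without headers is also accepted, in which case
#' records are numbered. Each structure is checked for equal length with
#' its sequence and balanced brackets.
#'
#' @param path structure file.
#' @return A tibble with columns `id`, `residues`, `structure`.
#' @export
read_structures <- function(path) {
  if (!file.exists(path)) {
    abort(paste0("no such file: ", path))
  }
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  ids <- character()
  seqs <- character()
  structs <- character()
  i <- 1L
  k <- 0L
  while (i <= length(lines)) {
    if (startsWith(lines[i], ">")) {
      id <- sub("^>", "", sub("[| ].*$", "", lines[i]))
      i <- i + 1L
    } else {
      k <- k + 1L
      id <- paste0("s", k)
    }
    if (i + 1L > length(lines)) {
      abort(paste0("record '", id, "' in ", path,
                   ": truncated (need sequence and structure lines)"))
    }
    seq <- normalize_residues(trimws(lines[i]))
    struct <- strip_energy(trimws(lines[i + 1L]))
    if (nchar(struct) != nchar(seq)) {
      abort(paste0("record '", id, "': structure length ", nchar(struct),
                   " does not match sequence length ", nchar(seq)))
    }
    parse_dot_bracket(struct)  # balanced / alphabet check
    ids <- c(ids, id)
    seqs <- c(seqs, seq)
    structs <- c(structs, struct)
    i <- i + 2L
  }
  tibble::tibble(id = ids, residues = seqs, structure = structs)
}

# "((((....)))) (-3.20)" -> "((((....))))"
strip_energy <- function(line) {
  sub("[ \t]+\\([-+0-9. ]*\\)[ \t]*$", "", line)
}

#' Write a structure file
#'
#' Inverse of [read_structures()]: writes `>id` / sequence / dot-bracket
#' triples.
#'
#' @param structures tibble with columns `id`, `residues`, `structure`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_structures <- function(structures, path) {
  stopifnot(all(c("id", "residues", "structure") %in% names(structures)))
  out <- rbind(paste0(">", structures$id), structures$residues,
               structures$structure)
  writeLines(as.character(out), path)
  invisible(path)
}
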