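#' Position frequency matrix
#'
#' A `psi_pfm` holds per-position base probabilities (rows A, U, C, G;
#' columns are motif positions; every column sums to 1) plus the number of
#' subsequences that contributed (`support`).
#'
#' @param counts 4 x width non-negative count (or probability) matrix with
#'   rows in the order A, U, C, G.
#' @param support number of contributing subsequences.
#' @return A `psi_pfm`.
#' @export
psi_pfm <- function(counts, support) {
  if (nrow(counts) != 4L) {
    abort("a PFM has exactly 4 rows (A, U, C, G)")
  }
  if (support < 1L) {
    abort("PFM support must be at least 1")
  }
  cs <- colSums(counts)
  if (any(cs <= 0)) {
    abort("every PFM column needs positive mass")
  }
  probs <- sweep(counts, 2, cs, `/`)
  rownames(probs) <- c("A", "U", "C", "G")
  structure(list(probs = probs, support = as.integer(support)),
            class = "psi_pfm")
}

#' @export
print.psi_pfm <- function(x, ...) {
  cat("<psi_pfm> width ", ncol(x$probs), ", support ", x$support,
      ", consensus ", consensus(x), "\n", sep = "")
  print(round(x$probs, 3))
  invisible(x)
}

#' Consensus sequence of a PFM
#'
#' The most probable base per column; ties resolve to the first base in
#' A, U, C, G order.
#'
#' @param pfm a `psi_pfm`.
#' @return Consensus string.
#' @export
consensus <- function(pfm) {
  paste(rownames(pfm$probs)[apply(pfm$probs, 2, which.max)], collapse = "")
}

#' Per-column information content of a PFM
#'
#' `IC_j = 2 + sum_b p_bj * log2(p_bj)` bits (0 log 0 = 0), i.e. 2 bits
#' minus the column entropy against a uniform background — 0 for a uniform
#' column, 2 for a deterministic one.
#'
#' @param pfm a `psi_pfm`.
#' @return Numeric vector of bits per column, each in `[0, 2]`.
#' @export
information_content <- function(pfm) {
  p <- pfm$probs
  plogp <- ifelse(p > 0, p * log2(p), 0)
  2 + colSums(plogp)
}

#' Convert trained convolution kernels into motifs
#'
#' For every first-layer filter, scans its activation over all windows of
#' the dataset and collects, at every position where the activation
#' reaches at least `activation_frac` of that filter's maximum over the
#' whole set, the filter-height subsequence at that position. The
#' collected subsequences are stacked into a position frequency matrix.
#' Filters whose maximum activation is not positive (e.g. dead kernels)
#' yield no hits and are omitted. For merged-seq inputs each (base,
#' structure-symbol) pair is projected to its base, so the motifs are
#' 4-letter nucleotide motifs for both encodings.
#'
#' @param model a trained `psi_cnn`.
#' @param data list with `x` (encoded array, same shape the model was
#'   trained on); typically only the positive class is passed.
#' @param activation_frac hit threshold as a fraction of the per-filter
#'   maximum activation, in (0, 1]; default 0.5 (half-max rule).
#' @return Named list of `psi_pfm` (names `ch<channel>_f<filter>`),
#'   possibly empty.
#' @export
extract_motifs <- function(model, data, activation_frac = 0.5) {
  if (!inherits(model, "psi_cnn") || !model$trained) {
    abort("extract_motifs() needs a trained psi_cnn")
  }
  if (activation_frac <= 0 || activation_frac > 1) {
    abort("activation_frac must lie in (0, 1]")
  }
  x <- if (is.list(data) && !is.null(data$x)) data$x else data
  n <- dim(x)[1]
  if (is.null(n) || n == 0L) {
    abort("empty dataset")
  }
  cfg <- model$config
  check_shapes(x, cfg)
  base_of_col <- if (cfg$input_cols == 4L) {
    1:4
  } else {
    rep(1:4, each = 3)                       # merged pairs project to base
  }
  base_idx <- apply(x, c(1, 2), function(r) base_of_col[which.max(r)])
  heights <- unique(cfg$filter_heights)
  cols <- lapply(heights, function(h) im2col(x, h))
  hmap <- match(cfg$filter_heights, heights)
  pfms <- list()
  for (ch in seq_len(cfg$n_channels)) {
    M <- cols[[hmap[ch]]]
    P <- attr(M, "P")
    h <- cfg$filter_heights[ch]
    A <- relu(sweep(M %*% model$params[[paste0("convW", ch)]], 2,
                    model$params[[paste0("convb", ch)]], `+`))
    for (f in seq_len(cfg$filters_per_channel)) {
      a <- A[, f]
      amax <- max(a)
      if (amax <= 0) next
      hits <- which(a >= activation_frac * amax)
      counts <- matrix(0, 4, h)
      for (lin in hits) {
        i <- (lin - 1L) %/% P + 1L
        p <- (lin - 1L) %% P + 1L
        seg <- base_idx[i, p:(p + h - 1L)]
        counts[cbind(seg, seq_len(h))] <- counts[cbind(seg, seq_len(h))] + 1
      }
      pfms[[paste0("ch", ch, "_f", f)]] <- psi_pfm(counts, length(hits))
    }
  }
  pfms
}

#' Dataset-level (ground truth) PFM
#'
#' Per-position base frequencies of a window set — the logo one would draw
#' directly from the data.
#'
#' @param ds validated window tibble; filter to one class first if a
#'   class-specific logo is wanted.
#' @return A `psi_pfm` of width `2 * xi + 1`.
#' @export
pfm_from_windows <- function(ds) {
  validate_windows(ds)
  if (nrow(ds) == 0L) {
    abort("empty dataset")
  }
  chars <- do.call(rbind, strsplit(ds$residues, ""))
  counts <- apply(chars, 2, function(col) {
    table(factor(col, levels = c("A", "U", "C", "G")))
  })
  psi_pfm(counts, nrow(ds))
}

#' Did any extracted motif recover the planted consensus?
#'
#' A PFM counts as a recovery when its consensus equals the planted
#' consensus or is a contiguous substring of it (filters are often
#' shorter than the planted motif), or contains it.
#'
#' @param pfms list of `psi_pfm` from [extract_motifs()].
#' @param planted_consensus the planted consensus string.
#' @param min_width minimum PFM width considered (default 4).
#' @return Logical.
#' @export
motif_recovered <- function(pfms, planted_consensus, min_width = 4L) {
  any(vapply(pfms, function(p) {
    if (ncol(p$probs) < min_width) return(FALSE)
    cons <- consensus(p)
    grepl(cons, planted_consensus, fixed = TRUE) ||
      grepl(planted_consensus, cons, fixed = TRUE)
  }, TRUE))
}

pfm_tidy <- function(pfm, mode) {
  ic <- information_content(pfm)
  df <- tidyr::pivot_longer(
    dplyr::mutate(tibble::as_tibble(t(pfm$probs)),
                  position = seq_len(ncol(pfm$probs))),
    cols = c("A", "U", "C", "G"), names_to = "base", values_to = "prob"
  )
  df$height <- if (mode == "information_content") {
    df$prob * ic[df$position]
  } else {
    df$prob
  }
  # stack order: smallest at the bottom, tallest letter on top
  df <- dplyr::arrange(df, .data$position, .data$height)
  df <- dplyr::group_by(df, .data$position)
  df <- dplyr::mutate(df, ymax = cumsum(.data$height),
                      ymin = .data$ymax - .data$height)
  dplyr::ungroup(df)
}

#' Sequence-logo plot of a PFM
#'
#' Stacked-letter logo: per position, each base occupies a stack segment
#' whose height equals its probability (probability mode) or its share of
#' the column information content in bits (information-content mode, column
#' total in `[0, 2]`).
#'
#' @param object a `psi_pfm`.
#' @param mode `"probability"` or `"information_content"`.
#' @param ... unused.
#' @return A ggplot object.
#' @method autoplot psi_pfm
#' @export
autoplot.psi_pfm <- function(object, mode = c("probability", "information_content"),
                             ...) {
  mode <- match.arg(mode)
  df <- pfm_tidy(object, mode)
  base_cols <- c(A = "#109648", U = "#D62839", C = "#255C99", G = "#F7B32B")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$position)) +
    ggplot2::geom_rect(
      ggplot2::aes(xmin = .data$position - 0.45, xmax = .data$position + 0.45,
                   ymin = .data$ymin, ymax = .data$ymax, fill = .data$base),
      alpha = 0.25
    ) +
    ggplot2::geom_text(
      ggplot2::aes(y = (.data$ymin + .data$ymax) / 2, label = .data$base,
                   colour = .data$base, size = .data$height),
      fontface = "bold", show.legend = FALSE
    ) +
    ggplot2::scale_size_continuous(range = c(0, 8), limits = c(0, NA)) +
    ggplot2::scale_fill_manual(values = base_cols) +
    ggplot2::scale_colour_manual(values = base_cols) +
    ggplot2::labs(
      x = "Position",
      y = if (mode == "probability") "Probability" else "Bits"
    ) +
    ggplot2::theme_minimal()
}

#' Render sequence logos to an image file
#'
#' Writes one stacked-letter logo (or a column of logos for a PFM list) in
#' probability or information-content mode. Layout is deterministic for a
#' fixed input.
#'
#' @param pfms a `psi_pfm` or list of them.
#' @param path output image (extension decides the device, e.g. `.png`,
#'   `.svg` via [ggplot2::ggsave()]).
#' @param mode `"probability"` or `"information_content"`.
#' @param width,height device size in inches per logo.
#' @return `path`, invisibly.
#' @export
render_logo <- function(pfms, path, mode = c("probability", "information_content"),
                        width = 6, height = 2.2) {
  mode <- match.arg(mode)
  if (inherits(pfms, "psi_pfm")) {
    pfms <- list(pfms)
  }
  plots <- lapply(seq_along(pfms), function(i) {
    p <- autoplot(pfms[[i]], mode = mode)
    if (!is.null(names(pfms)) && nzchar(names(pfms)[i])) {
      p <- p + ggplot2::ggtitle(names(pfms)[i])
    }
    p
  })
  # open the target device before building grobs, so no stray default
  # device (Rplots.pdf) is created in non-interactive sessions
  grDevices_open(path, width, height * length(plots))
  on.exit(grDevices::dev.off(), add = TRUE)
  # stack panels vertically without extra dependencies
  g <- do.call(rbind, lapply(plots, ggplot2::ggplotGrob))
  grid::grid.newpage()
  grid::grid.draw(g)
  invisible(path)
}

grDevices_open <- function(path, width, height) {
  ext <- tolower(tools::file_ext(path))
  switch(ext,
    png = grDevices::png(path, width = width, height = height, units = "in",
                         res = 150),
    svg = grDevices::svg(path, width = width, height = height),
    pdf = grDevices::pdf(path, width = width, height = height),
    abort(paste0("unsupported image extension: .", ext))
  )
}

#' Export PFMs in MEME minimal motif format
#'
#' @param pfms named list of `psi_pfm`.
#' @param path output text file.
#' @param background background base frequencies (A, C, G, U order in the
#'   output, per MEME convention).
#' @return `path`, invisibly.
#' @export
write_meme <- function(pfms, path, background = rep(0.25, 4)) {
  if (inherits(pfms, "psi_pfm")) {
    pfms <- list(motif1 = pfms)
  }
  lines <- c(
    "MEME version 4", "",
    "ALPHABET= ACGU", "",
    "strands: +", "",
    "Background letter frequencies",
    sprintf("A %.5f C %.5f G %.5f U %.5f",
            background[1], background[2], background[3], background[4]),
    ""
  )
  nms <- names(pfms)
  if (is.null(nms)) nms <- paste0("motif", seq_along(pfms))
  for (i in seq_along(pfms)) {
    p <- pfms[[i]]$probs[c("A", "C", "G", "U"), , drop = FALSE]
    lines <- c(
      lines,
      paste0("MOTIF ", nms[i]),
      sprintf("letter-probability matrix: alength= 4 w= %d nsites= %d E= 0",
              ncol(p), pfms[[i]]$support),
      apply(t(p), 1, function(r) paste(sprintf("%.6f", r), collapse = " ")),
      ""
    )
  }
  writeLines(lines, path)
  invisible(path)
}
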