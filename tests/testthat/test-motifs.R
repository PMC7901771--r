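test_that("information content has the closed-form values", {
  pfm <- psi_pfm(matrix(c(
    0.25, 1, 0.5,
    0.25, 0, 0.5,
    0.25, 0, 0,
    0.25, 0, 0
  ), nrow = 4, byrow = TRUE), support = 10)
  expect_equal(information_content(pfm), c(0, 2, 1))
  expect_true(all(information_content(pfm) >= 0 &
                    information_content(pfm) <= 2))
})

test_that("PFM construction normalizes columns and keeps support", {
  counts <- matrix(c(3, 1, 0, 0,
                     0, 2, 2, 0,
                     1, 1, 1, 1), nrow = 4)
  pfm <- psi_pfm(counts, support = 4)
  expect_equal(colSums(pfm$probs), rep(1, 3), ignore_attr = TRUE)
  expect_equal(pfm$support, 4L)
  expect_error(psi_pfm(counts, support = 0), "support")
  expect_error(psi_pfm(matrix(0, 4, 2), support = 1), "positive mass")
})

test_that("dataset-level PFM equals direct per-position base frequencies", {
  ds <- psi_windows(
    c("a", "b", "c"),
    c("AAUUA", "GAUUC", "AGUUG"),
    label = c(1, 1, 1)
  )
  pfm <- pfm_from_windows(ds)
  expect_equal(ncol(pfm$probs), 5L)
  expect_equal(pfm$probs[, 1], c(A = 2 / 3, U = 0, C = 0, G = 1 / 3))
  expect_equal(pfm$probs[, 4], c(A = 0, U = 1, C = 0, G = 0))
  expect_equal(pfm$support, 3L)
  expect_error(pfm_from_windows(ds[0, ]), "empty")
})

test_that("trained kernels recover the planted motif", {
  fit <- shared_tiny_fit()
  pos <- list(x = fit$train$x[fit$train$y == 1, , , drop = FALSE])
  pfms <- extract_motifs(fit$model, pos)
  expect_gt(length(pfms), 0L)
  for (p in pfms) {
    expect_equal(colSums(p$probs), rep(1, ncol(p$probs)), ignore_attr = TRUE)
    expect_gte(p$support, 1L)
  }
  planted <- attr(fit$ds, "planted")
  expect_true(motif_recovered(pfms, planted$motif))

  # recovery property: among the most informative kernels, at least one
  # consensus is a contiguous piece of the planted consensus
  ics <- vapply(pfms, function(p) max(information_content(p)), 0)
  top <- pfms[order(ics, decreasing = TRUE)[1:min(5, length(pfms))]]
  expect_true(any(vapply(top, function(p) {
    grepl(consensus(p), planted$motif, fixed = TRUE)
  }, TRUE)))
})

test_that("threshold boundary and degenerate kernels behave", {
  fit <- shared_tiny_fit()
  pos <- list(x = fit$train$x[fit$train$y == 1, , , drop = FALSE])
  pfms1 <- extract_motifs(fit$model, pos, activation_frac = 1)
  expect_true(all(vapply(pfms1, function(p) p$support >= 1L, TRUE)))

  # zeroed kernels produce no hits and are omitted
  dead <- fit$model
  for (ch in 1:dead$config$n_channels) {
    dead$params[[paste0("convW", ch)]][] <- 0
    dead$params[[paste0("convb", ch)]][] <- 0
  }
  expect_length(extract_motifs(dead, pos), 0L)

  expect_error(extract_motifs(fit$model, pos, activation_frac = 0), "frac")
  expect_error(
    extract_motifs(fit$model, list(x = pos$x[0, , , drop = FALSE])),
    "empty"
  )
  expect_error(extract_motifs(build_model(fit$model$config), pos), "trained")
})

test_that("merged-seq motifs project pairs down to nucleotides", {
  ds <- generate_windows(generator_spec(30L, xi = 7L, motif = "GACUC",
                                        strength = 1, motif_offset = -3L,
                                        seed = 19L))
  st <- fold_windows(ds)
  enc <- encode_dataset(ds, "merged", structures = st)
  cfg <- tiny_config(rows = 15L, cols = 12L)
  cfg$max_epochs <- 10L
  fit <- train_cnn(build_model(cfg), enc)
  pfms <- extract_motifs(fit, list(x = enc$x[enc$y == 1, , , drop = FALSE]))
  expect_gt(length(pfms), 0L)
  expect_true(all(vapply(pfms, function(p) nrow(p$probs) == 4L, TRUE)))
  expect_true(all(rownames(pfms[[1]]$probs) == c("A", "U", "C", "G")))
})

test_that("logo layers encode probabilities as stack heights", {
  pfm <- psi_pfm(matrix(c(0.7, 0.1, 0.1, 0.1,
                          0.25, 0.25, 0.25, 0.25), nrow = 4), support = 20)
  p <- autoplot(pfm, mode = "probability")
  df <- p$data
  h1 <- df[df$position == 1, ]
  expect_equal(sort(h1$ymax - h1$ymin), sort(pfm$probs[, 1]),
               ignore_attr = TRUE)
  expect_equal(max(h1$ymax), 1)

  # IC mode: a uniform column collapses to zero height
  p2 <- autoplot(pfm, mode = "information_content")
  h2 <- p2$data[p2$data$position == 2, ]
  expect_equal(max(h2$ymax), 0)
})

test_that("logos render to image files deterministically", {
  pfm <- psi_pfm(matrix(c(8, 1, 1, 0,
                          1, 8, 0, 1,
                          2, 2, 2, 2), nrow = 4), support = 10)
  f <- withr::local_tempfile(fileext = ".png")
  render_logo(pfm, f)
  expect_true(file.exists(f) && file.size(f) > 0)
  f2 <- withr::local_tempfile(fileext = ".pdf")
  render_logo(list(a = pfm, b = pfm), f2, mode = "information_content")
  expect_true(file.size(f2) > 0)
  expect_error(render_logo(pfm, withr::local_tempfile(fileext = ".bmp")),
               "extension")
})

test_that("MEME export round-trips probabilities", {
  pfm <- psi_pfm(matrix(c(8, 1, 1, 0,
                          1, 8, 0, 1), nrow = 4), support = 10)
  f <- withr::local_tempfile(fileext = ".meme")
  write_meme(list(kern1 = pfm), f)
  lines <- readLines(f)
  expect_true(any(grepl("^MOTIF kern1$", lines)))
  expect_true(any(grepl("alength= 4 w= 2 nsites= 10", lines)))
  hdr <- grep("letter-probability matrix", lines)
  vals <- do.call(rbind, lapply(lines[(hdr + 1):(hdr + 2)], function(l) {
    as.numeric(strsplit(l, " ")[[1]])
  }))
  expect_equal(rowSums(vals), c(1, 1))
  # MEME rows are A C G U; ours are A U C G
  expect_equal(vals[1, ], unname(pfm$probs[c("A", "C", "G", "U"), 1]))
})
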