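# Shared fixtures and independent oracles used across the suite.

# Random valid uridine-centered windows.
random_windows <- function(n, xi, seed) {
  withr::with_seed(seed, {
    len <- 2L * xi + 1L
    seqs <- vapply(seq_len(n), function(i) {
      s <- sample(c("A", "C", "G", "U"), len, replace = TRUE)
      s[xi + 1L] <- "U"
      paste(s, collapse = "")
    }, "")
    psi_windows(paste0("r", seq_len(n)), seqs,
                label = rep_len(c(1L, 0L), n))
  })
}

random_rna <- function(len, seed = NULL) {
  draw <- function() paste(sample(c("A", "C", "G", "U"), len, replace = TRUE),
                           collapse = "")
  if (is.null(seed)) draw() else withr::with_seed(seed, draw())
}

# Exhaustive-enumeration oracle for the maximum number of canonical nested
# base pairs: recursively enumerates every nested structure (position i left
# unpaired, or paired with every admissible k) without memoization.
brute_max_pairs <- function(seq, min_loop = 3L) {
  b <- strsplit(seq, "")[[1]]
  pairable <- function(a, c) paste0(a, c) %in% c("AU", "UA", "GC", "CG", "GU", "UG")
  rec <- function(i, j) {
    if (i >= j) return(0L)
    best <- rec(i + 1L, j)
    ks <- seq_len(j)
    for (k in ks[ks > i + min_loop]) {
      if (pairable(b[i], b[k])) {
        best <- max(best, 1L + rec(i + 1L, k - 1L) + rec(k + 1L, j))
      }
    }
    best
  }
  rec(1L, length(b))
}

count_pairs <- function(db) nrow(parse_dot_bracket(db)$pairs)

# Naive recount oracle: metrics recomputed from raw (label, prediction)
# pairs with explicit loops and textbook formulas.
naive_metrics_from_pairs <- function(truth, predicted) {
  tp <- 0; tn <- 0; fp <- 0; fn <- 0
  for (i in seq_along(truth)) {
    if (truth[i] == 1 && predicted[i] == 1) tp <- tp + 1
    if (truth[i] == 0 && predicted[i] == 0) tn <- tn + 1
    if (truth[i] == 0 && predicted[i] == 1) fp <- fp + 1
    if (truth[i] == 1 && predicted[i] == 0) fn <- fn + 1
  }
  sn <- if (tp + fn == 0) NA_real_ else tp / (tp + fn)
  sp <- if (tn + fp == 0) NA_real_ else tn / (tn + fp)
  ac <- (tp + tn) / length(truth)
  den <- (tp + fp) * (tp + fn) * (tn + fp) * (tn + fn)
  mcc <- if (den == 0) NA_real_ else (tp * tn - fp * fn) / sqrt(den)
  list(tp = tp, tn = tn, fp = fp, fn = fn,
       sensitivity = sn, specificity = sp, accuracy = ac, mcc = mcc)
}

# A small configuration that trains in seconds; used wherever a real fit is
# needed but the full-size network is not the point of the test.
tiny_config <- function(rows, cols, seed = 7L, ...) {
  model_config(
    input_rows = rows, input_cols = cols, n_channels = 3L,
    filter_heights = c(3L, 5L, 5L), filters_per_channel = 8L,
    dense_units = 32L, dropout_p = 0.3, learning_rate = 2e-3,
    batch_size = 16L, max_epochs = 15L, early_stop_patience = 5L,
    seed = seed, ...
  )
}

# One small trained model on strongly separable synthetic data, shared by
# the network / motif tests (built lazily, cached for the session).
shared_tiny_fit <- local({
  cache <- NULL
  function() {
    if (!is.null(cache)) return(cache)
    spec <- generator_spec(n_per_class = 60L, xi = 8L, motif = "GACUCG",
                           strength = 1, motif_offset = -3L, seed = 11L)
    ds <- generate_windows(spec)
    enc <- encode_dataset(ds, "general")
    hold <- withr::with_seed(3L, sort(sample(nrow(ds), 30)))
    train <- list(x = enc$x[-hold, , , drop = FALSE], y = enc$y[-hold])
    eval <- list(x = enc$x[hold, , , drop = FALSE], y = enc$y[hold])
    cfg <- tiny_config(rows = 17L, cols = 4L)
    fit <- train_cnn(build_model(cfg), train)
    cache <<- list(spec = spec, ds = ds, enc = enc, train = train,
                   eval = eval, model = fit)
    cache
  }
})
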