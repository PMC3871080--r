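# fixtures built once per test run and shared across files

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (is.null(.fixture_cache[[key]])) .fixture_cache[[key]] <- force(expr)
  .fixture_cache[[key]]
}

# full default paired-wear study (8 subjects, 2 devices) and its windows
default_study <- function() cached("study", build_study(master_seed = 1))

default_windows <- function() cached("windows", study_windows(default_study()))

# small study for cheap structural checks
small_study <- function() {
  cached("small_study",
         build_study(subjects = sprintf("P%d", 1:4), master_seed = 11))
}

small_windows <- function() cached("small_windows", study_windows(small_study()))

# a synthetic, trivially separable feature table: each class sits on its own
# mean with noise far smaller than the class gaps
separable_table <- function(subjects = sprintf("S%d", 1:4), n_win = 3,
                            noise = 0.01, shift = 0, seed = 99) {
  lev <- activity_labels("coarse")
  centers <- seq_along(lev)
  rows <- list()
  withr::with_seed(seed, {
    for (s in subjects) for (ci in seq_along(lev)) for (w in seq_len(n_win)) {
      rows[[length(rows) + 1]] <- data.frame(
        subject_id = s, device_id = "dev", activity = lev[ci],
        fine_label = lev[ci], window_index = w,
        f1 = centers[ci] + shift + rnorm(1, 0, noise),
        f2 = 2 * centers[ci] + shift + rnorm(1, 0, noise),
        stringsAsFactors = FALSE)
    }
  })
  out <- do.call(rbind, rows)
  attr(out, "feature_set") <- "TD"
  out
}

# the published worked confusion-matrix example: TD model trained and tested
# on the same monitor (row = truth, column = prediction)
worked_confusion_counts <- function() {
  lev <- activity_labels("coarse")
  m <- matrix(c(19, 0, 0, 5, 0, 0,
                0, 23, 1, 0, 0, 0,
                0, 2, 18, 2, 0, 0,
                1, 0, 0, 47, 0, 0,
                0, 0, 0, 0, 48, 0,
                0, 0, 0, 0, 0, 24),
              nrow = 6, byrow = TRUE,
              dimnames = list(c("clean", "computer", "throw",
                                "walk", "run", "vacuum"), lev))
  m
}

# expand a counts matrix back into (truth, predicted) label vectors
labels_from_counts <- function(m) {
  truth <- character(0); pred <- character(0)
  for (i in rownames(m)) for (j in colnames(m)) {
    k <- m[i, j]
    if (k > 0) {
      truth <- c(truth, rep(i, k))
      pred <- c(pred, rep(j, k))
    }
  }
  list(truth = truth, predicted = pred)
}
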