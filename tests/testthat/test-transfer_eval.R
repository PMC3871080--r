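test_that("confusion summary identities hold and labels are validated", {
  withr::with_seed(13, {
    lev <- activity_labels("coarse")
    truth <- sample(lev, 300, replace = TRUE)
    pred <- sample(lev, 300, replace = TRUE)
  })
  cm <- confusion_summary(truth, pred)
  expect_equal(sum(cm$counts), 300)
  expect_equal(cm$n_correct, sum(diag(cm$counts)))
  expect_equal(cm$overall_accuracy,
               round(100 * sum(diag(cm$counts)) / 300, 1))
  expect_equal(unname(rowSums(cm$counts)),
               as.vector(table(factor(truth, levels = lev))[lev]))

  perfect <- confusion_summary(truth, truth)
  expect_equal(perfect$overall_accuracy, 100)
  expect_equal(unname(perfect$per_class_recall),
               rep(100, 6))

  expect_error(confusion_summary(c("walk", "jump"), c("walk", "walk")),
               "vocabulary")
  expect_error(confusion_summary(character(0), character(0)), "length")
})

test_that("worked confusion example reproduces published per-class recalls", {
  m <- worked_confusion_counts()
  lab <- labels_from_counts(m)
  cm <- confusion_summary(lab$truth, lab$predicted)
  expect_equal(cm$per_class_recall[["clean"]], 79.2)   # 19/24
  expect_equal(cm$per_class_recall[["walk"]], 97.9)    # 47/48
  expect_equal(cm$per_class_recall[["run"]], 100.0)
  expect_equal(cm$per_class_recall[["vacuum"]], 100.0)
})

test_that("pooled two-proportion z matches hand values and the chi-square identity", {
  z0 <- two_proportion_z(50, 100, 50, 100)
  expect_equal(z0$z, 0)
  expect_equal(z0$p, 1)

  z1 <- two_proportion_z(90, 100, 80, 100)
  expect_equal(round(z1$z, 3), 1.980)

  # antisymmetry
  z2 <- two_proportion_z(80, 100, 90, 100)
  expect_equal(z2$z, -z1$z)
  expect_equal(z2$p, z1$p)

  # degenerate pooled proportion
  expect_equal(two_proportion_z(10, 10, 12, 12), list(z = 0, p = 1))
  expect_error(two_proportion_z(5, 4, 1, 2), "counts")

  # z^2 equals the uncorrected chi-square statistic (independent route)
  for (cs in list(c(90, 100, 80, 100), c(7, 12, 11, 12), c(40, 60, 33, 55))) {
    zz <- two_proportion_z(cs[1], cs[2], cs[3], cs[4])
    pt <- suppressWarnings(
      stats::prop.test(c(cs[1], cs[3]), c(cs[2], cs[4]), correct = FALSE))
    expect_equal(zz$z^2, unname(pt$statistic), tolerance = 1e-9)
    expect_equal(zz$p, pt$p.value, tolerance = 1e-9)
  }
})

test_that("z approximation tracks an exact binomial comparison at small n", {
  # oracle: exact two-sided randomization p over the pooled null, enumerated
  exact_p <- function(k1, n1, k2, n2) {
    K <- k1 + k2
    obs <- abs(k1 / n1 - k2 / n2)
    num <- 0; den <- 0
    for (a in max(0, K - n2):min(n1, K)) {
      w <- choose(n1, a) * choose(n2, K - a)
      den <- den + w
      if (abs(a / n1 - (K - a) / n2) >= obs - 1e-12) num <- num + w
    }
    num / den
  }
  for (cs in list(c(10, 12, 6, 12), c(8, 10, 9, 12), c(11, 12, 7, 10))) {
    zp <- two_proportion_z(cs[1], cs[2], cs[3], cs[4])$p
    ep <- exact_p(cs[1], cs[2], cs[3], cs[4])
    # at n <= 12 the exact permutation p is coarsely discrete, so the
    # continuous normal approximation can sit up to ~a quarter away from it
    expect_lt(abs(zp - ep), 0.25)
  }
})

test_that("LOSO is perfect on separable classes and near chance on shuffled labels", {
  tab <- separable_table()
  spec <- model_spec("TD", n_trees = 100, seed = 3)
  res <- loso_transfer(tab, tab, spec)
  expect_equal(res$accuracy, 100)
  expect_equal(res$n_total, nrow(tab))

  # permuted training labels: accuracy concentrates at the chance level
  # implied by class frequencies (uniform here: 1/6)
  shuf <- tab
  withr::with_seed(41, shuf$activity <- sample(shuf$activity))
  attr(shuf, "feature_set") <- "TD"
  res0 <- loso_transfer(shuf, shuf, spec)
  expect_lt(res0$accuracy, 45)

  # contract errors
  fdtab <- tab; attr(fdtab, "feature_set") <- "FD"
  expect_error(loso_transfer(tab, fdtab, spec), "mismatch")
  one <- tab[tab$subject_id == "S1", ]
  attr(one, "feature_set") <- "TD"
  expect_error(loso_transfer(one, one, spec), "2 subjects")
})

test_that("a small feature shift degrades magnitude-based classification", {
  spec <- model_spec("TD", n_trees = 100, seed = 7)
  train <- separable_table(noise = 0.25, seed = 50)
  same <- loso_transfer(train, separable_table(noise = 0.25, seed = 51),
                        spec)
  shifted <- loso_transfer(train,
                           separable_table(noise = 0.25, shift = 0.6,
                                           seed = 51), spec)
  expect_gt(same$accuracy, shifted$accuracy)
})

test_that("transfer grid is complete, reproducible, and symmetric for identical devices", {
  twins <- list(A = device_model("devA", noise_sd = 0.01),
                B = device_model("devB", noise_sd = 0.01))
  study <- build_study(subjects = sprintf("Q%d", 1:4), devices = twins,
                       master_seed = 9)
  wins <- study_windows(study)
  tables <- lapply(wins, function(w)
    list(TD = extract_table(w, "TD"), FD = extract_table(w, "FD")))
  spec <- model_spec(n_trees = 100, seed = 5)

  g1 <- transfer_grid(tables, spec)
  expect_equal(nrow(g1$table), 8)
  expect_setequal(unique(g1$table$feature_set), c("TD", "FD"))
  expect_equal(g1$table$n_total, rep(96, 8))

  # determinism: identical inputs give identical accuracies
  g2 <- transfer_grid(tables, spec)
  expect_identical(g1$table, g2$table)

  # near-identical devices: all four cells of a feature set agree closely
  for (fset in c("TD", "FD")) {
    accs <- g1$table$accuracy[g1$table$feature_set == fset]
    expect_lt(diff(range(accs)), 8)
  }

  zt <- transfer_ztests(g1)
  expect_equal(nrow(zt), 4)
  expect_true(all(zt$p >= 0 & zt$p <= 1))
})
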