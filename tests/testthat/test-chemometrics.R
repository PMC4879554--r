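test_that("PCA conserves variance, reconstructs data and orders factors", {
  set.seed(11)
  x <- matrix(rnorm(15 * 30), 15, 30)
  colnames(x) <- 700:729
  pca <- fit_pca(x, n_factors = 14)
  expect_equal(sum(pca$explained_variance), pca$total_variance,
               tolerance = 1e-8)
  expect_true(all(diff(pca$explained_variance) <= 1e-12))
  # loadings orthonormal
  g <- crossprod(pca$loadings)
  expect_equal(g, diag(14), tolerance = 1e-8, ignore_attr = TRUE)
  # full-rank reconstruction of the centred data
  centred <- sweep(x, 2, pca$mean_vector)
  sc <- sweep(x, 2, pca$mean_vector) %*% pca$loadings
  expect_lt(max(abs(sc %*% t(pca$loadings) - centred)), 1e-8)
})

test_that("PCA degenerate structure is reported faithfully", {
  x <- matrix(rep(c(1, 2, 3), each = 3), 3, 3) * 0 + 5
  colnames(x) <- 700:702
  pca <- fit_pca(x, n_factors = 2)
  expect_lt(max(pca$explained_variance), 1e-20)
  # rank-2 data: variance beyond factor 2 is numerically zero
  set.seed(12)
  b1 <- rnorm(40); b2 <- rnorm(40)
  coef <- matrix(rnorm(20), 10, 2)
  x2 <- coef %*% rbind(b1, b2)
  colnames(x2) <- 700:739
  pca2 <- fit_pca(x2, n_factors = 9)
  expect_lt(sum(pca2$explained_variance[3:9]), 1e-10 * pca2$total_variance)
  expect_error(fit_pca(x2, n_factors = 10), "n_factors")
})

test_that("factor cap is strictly below half the smallest group", {
  expect_identical(group_size_factor_cap(c(17, 16, 16, 16, 20, 19, 18, 22)), 7L)
  expect_identical(group_size_factor_cap(c(45, 45)), 22L)
  expect_identical(group_size_factor_cap(4), 1L)
  expect_error(group_size_factor_cap(integer(0)), "empty")
  expect_error(group_size_factor_cap(c(5, 1)), ">= 2")
})

test_that("factor selection matches the exact F distribution and cap rule", {
  set.seed(21)
  labels <- rep(c("a", "b"), each = 20)
  flat <- rnorm(40)                      # no group structure
  strong <- rnorm(40) + ifelse(labels == "b", 10, 0)  # 10-SD separation
  scores <- cbind(flat, strong)
  # independent oracle: F statistic and p computed from first principles
  f_oracle <- function(v) {
    mns <- tapply(v, labels, mean)
    ssb <- sum(tapply(v, labels, length) * (mns - mean(v))^2)
    ssw <- sum((v - ave(v, labels))^2)
    f <- (ssb / 1) / (ssw / 38)
    stats::pf(f, 1, 38, lower.tail = FALSE)
  }
  sel <- select_significant_pcs(scores, labels, alpha = 0.05, cap = 2)
  expect_equal(sel$p_values, c(f_oracle(flat), f_oracle(strong)),
               tolerance = 1e-10)
  expect_identical(sel$selected_indices, 2L)
  expect_lt(sel$p_values[2], 1e-6)
  expect_gt(sel$p_values[1], 0.05)
})

test_that("factor selection keeps the cap smallest p-values, ties by index", {
  set.seed(22)
  labels <- rep(c("a", "b"), each = 30)
  shift <- c(9, 8, 7, 6, 5, 4, 3.5, 3, 2.5)
  scores <- sapply(shift, function(d) rnorm(60) + ifelse(labels == "b", d, 0))
  sel <- select_significant_pcs(scores, labels, alpha = 0.05, cap = 5)
  expect_length(sel$selected_indices, 5)
  expect_identical(sel$selected_indices,
                   sort(order(sel$p_values, seq_along(shift))[1:5]))
})

test_that("selection falls back to the best factor when none is significant", {
  set.seed(23)
  scores <- matrix(rnorm(40), 20, 2)
  expect_warning(
    sel <- select_significant_pcs(scores, rep(c("a", "b"), 10), 0.05, 3),
    "no component significant")
  expect_length(sel$selected_indices, 1)
})

test_that("PC-LDA separates a 5-sigma class band shift in training", {
  cfg <- sim_config(n_per_group = 20, seed = 31)
  delta <- 5 * cfg$noise_sd * 1.0
  prof <- list(P = profile_preset("parent", delta),
               R = profile_preset("recurrent", delta))
  proc <- classification_pipeline(simulate_set(prof, cfg))
  model <- fit_pclda(proc)
  cm <- predict(model, proc)$confusion
  expect_identical(unname(diag(unclass(cm))), c(20L, 20L))
})

test_that("duplicated groups under two labels classify near chance", {
  set.seed(32)
  x <- matrix(rnorm(30 * 40), 30, 40)
  colnames(x) <- 700:739
  labels <- rep(c("dup1", "dup2"), 15)  # same distribution, two labels
  proc <- set_from_matrix(x, labels)
  cm <- suppressWarnings(loocv(proc, n_factors = 6))
  eff <- classification_efficiency(cm)$overall
  se <- 100 * sqrt(0.25 / 30)
  expect_lt(abs(eff - 50), 3 * se)
})

test_that("an 8-group model has 8 class means and at most 7 axes", {
  cfg <- sim_config(n_per_group = 5, seed = 33)
  set <- simulate_cell_study(cfg)
  proc <- classification_pipeline(set)
  model <- suppressWarnings(fit_pclda(proc, n_factors = 10))
  expect_length(model$class_labels, 8)
  expect_lte(ncol(model$discriminant_axes), 7)
  expect_lte(ncol(model$discriminant_axes),
             length(model$selection$selected_indices))
})

test_that("loocv equals a naive refit-per-fold loop on toy sets", {
  for (seed in c(42, 43)) {
    proc <- separated_toy_set(n_per_group = 6, seed = seed, shift = 2.5)
    cm <- suppressWarnings(loocv(proc, n_factors = 4))
    truth <- set_labels(proc)
    pred <- character(length(proc))
    for (i in seq_along(proc$spectra)) {  # independent naive loop
      m <- suppressWarnings(
        fit_pclda(set_subset(proc, -i), n_factors = 4))
      pred[i] <- predict(m, set_subset(proc, i))$labels
    }
    naive <- confusion_matrix(truth, pred, labels = sort(unique(truth)),
                              kind = "loocv")
    expect_identical(unclass(cm), unclass(naive))
    expect_equal(unname(rowSums(cm)), as.integer(table(truth)))
  }
})

test_that("frozen-model prediction is consistent and recognises class means", {
  proc <- separated_toy_set(n_per_group = 8, seed = 44)
  model <- fit_pclda(proc, n_factors = 3)
  train_pred <- predict(model, proc)$labels
  expect_identical(predict(model, proc)$labels, train_pred)
  # per-class mean spectra are assigned to their own class
  m <- set_matrix(proc)
  lab <- set_labels(proc)
  means <- rbind(colMeans(m[lab == "A", ]), colMeans(m[lab == "B", ]))
  colnames(means) <- colnames(m)
  mean_set <- set_from_matrix(means, c("A", "B"))
  expect_identical(predict(model, mean_set)$labels, c("A", "B"))
})

test_that("in-package LDA agrees with MASS::lda on the selected scores", {
  skip_if_not_installed("MASS")
  proc <- separated_toy_set(n_per_group = 10, seed = 45, shift = 1.5)
  model <- fit_pclda(proc, n_factors = 5)
  sc <- pca_scores(model$pca, proc)[, model$selection$selected_indices,
                                    drop = FALSE]
  lab <- set_labels(proc)
  ref <- MASS::lda(sc, grouping = lab, prior = c(0.5, 0.5))
  ref_pred <- as.character(predict(ref, sc)$class)
  expect_identical(predict(model, proc)$labels, ref_pred)
})

test_that("classification efficiency reproduces published-table arithmetic", {
  cm1 <- reference_confusion("cell_standard")
  eff1 <- classification_efficiency(cm1)
  expect_equal(eff1$overall, 100 * 135 / 144)
  expect_equal(sum(cm1), 144)
  cm2 <- reference_confusion("tissue_standard")
  eff2 <- classification_efficiency(cm2)
  expect_equal(eff2$overall, 100 * 76 / 90)
  expect_equal(unname(eff2$per_group),
               c(100 * 34 / 45, 100 * 42 / 45))
  ident <- confusion_matrix(rep(c("a", "b"), 5), rep(c("a", "b"), 5))
  expect_equal(classification_efficiency(ident)$overall, 100)
})

test_that("model JSON serialization round-trips predictions", {
  proc <- separated_toy_set(n_per_group = 6, seed = 46)
  model <- fit_pclda(proc, n_factors = 3)
  f <- withr::local_tempfile(fileext = ".json")
  write_model(model, f)
  back <- read_model(f)
  expect_identical(predict(back, proc)$labels, predict(model, proc)$labels)
  expect_equal(back$pca$mean_vector, model$pca$mean_vector)
  expect_equal(back$class_means, model$class_means, ignore_attr = TRUE)
})

test_that("confusion matrices survive the CSV layout round-trip", {
  cm <- confusion_matrix(rep(c("P", "R"), c(4, 5)),
                         c("P", "P", "R", "P", "R", "R", "R", "P", "R"),
                         kind = "test")
  f <- withr::local_tempfile(fileext = ".csv")
  write_confusion(cm, f)
  back <- read_confusion(f, kind = "test")
  expect_equal(unclass(back), unclass(cm), ignore_attr = TRUE)
})
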