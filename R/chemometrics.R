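# PC-LDA classification engine: PCA on preprocessed spectra, significance
# screening of component scores, linear discriminant analysis in the selected
# score space, LOOCV and frozen-model test prediction.

#' Principal component analysis of a preprocessed spectrum set
#'
#' Mean-centred PCA (no scaling) of the intensity matrix; the first
#' `n_factors` components are retained as the candidate feature space.
#'
#' @param set a [raman_set] with a common axis, or a numeric matrix
#'   (spectra in rows).
#' @param n_factors number of components to keep, at most
#'   `min(n_spectra - 1, n_points)`; default 10.
#' @return list of class `pca_model` with `mean_vector`, `loadings`
#'   (points x factors, orthonormal columns), `explained_variance`
#'   (per-factor variances, non-increasing), `n_factors`, `axis`.
#' @export
fit_pca <- function(set, n_factors = 10L) {
  x <- if (is.matrix(set)) set else set_matrix(set)
  axis <- if (is.matrix(set)) as.numeric(colnames(set)) else set$common_axis
  n_max <- min(nrow(x) - 1L, ncol(x))
  if (nrow(x) < 2) stop("PCA needs at least 2 spectra")
  if (n_factors > n_max)
    stop("n_factors must be <= min(n_spectra - 1, n_points) = ", n_max)
  pc <- stats::prcomp(x, center = TRUE, scale. = FALSE, rank. = n_factors)
  structure(list(
    mean_vector = as.numeric(pc$center),
    loadings = unname(pc$rotation[, seq_len(n_factors), drop = FALSE]),
    explained_variance = unname(pc$sdev[seq_len(n_factors)]^2),
    total_variance = sum(pc$sdev^2),
    n_factors = as.integer(n_factors),
    axis = axis
  ), class = "pca_model")
}

#' Project spectra onto a fitted PCA basis
#'
#' @param pca a `pca_model` from [fit_pca()].
#' @param set a [raman_set] on the model's axis, or a matrix with matching
#'   columns.
#' @return score matrix, spectra in rows, factors in columns.
#' @export
pca_scores <- function(pca, set) {
  x <- if (is.matrix(set)) set else set_matrix(set)
  if (ncol(x) != length(pca$mean_vector))
    stop("axis mismatch: model expects ", length(pca$mean_vector),
         " points, got ", ncol(x))
  sweep(x, 2, pca$mean_vector) %*% pca$loadings
}

#' Factor cap from the smallest group size
#'
#' Over-fitting guard: the number of factors entering LDA is kept strictly
#' below half the size of the smallest group.
#'
#' @param group_sizes integer vector of per-group spectrum counts, all >= 2.
#' @return the largest integer strictly less than `min(group_sizes) / 2`.
#' @export
group_size_factor_cap <- function(group_sizes) {
  if (!length(group_sizes)) stop("group_sizes is empty")
  if (any(group_sizes < 2)) stop("all group sizes must be >= 2")
  m <- min(group_sizes)
  as.integer(ceiling(m / 2) - 1)
}

#' Select significant principal components
#'
#' Screens each factor's scores with a one-way ANOVA F test across groups;
#' factors with p below `alpha` are retained, capped at `cap` (smallest p
#' first, ties broken by lower factor index). If no factor reaches `alpha`
#' the single smallest-p factor is kept, with a warning, so downstream
#' modelling is always defined.
#'
#' @param scores score matrix from [pca_scores()].
#' @param labels group label per row; every group needs >= 2 spectra.
#' @param alpha significance level, default 0.05.
#' @param cap maximum number of factors, from [group_size_factor_cap()].
#' @return list of class `factor_selection` with `selected_indices` (sorted
#'   ascending), `p_values` (per factor), `alpha`, `max_factors`.
#' @export
select_significant_pcs <- function(scores, labels, alpha = 0.05, cap) {
  labels <- factor(labels)
  if (nlevels(labels) < 2) stop("need at least 2 groups")
  if (any(table(labels) < 2))
    stop("every group needs >= 2 spectra for the F test")
  p_values <- apply(scores, 2, function(sc) {
    stats::anova(stats::lm(sc ~ labels))[["Pr(>F)"]][1]
  })
  sig <- which(p_values < alpha)
  if (!length(sig)) {
    warning("no component significant at alpha = ", alpha,
            "; keeping the smallest-p factor")
    sig <- which.min(p_values)
  }
  if (length(sig) > cap)
    sig <- sig[order(p_values[sig], sig)][seq_len(cap)]
  structure(list(
    selected_indices = sort(as.integer(sig)),
    p_values = as.numeric(p_values),
    alpha = alpha, max_factors = as.integer(cap)
  ), class = "factor_selection")
}

# LDA in the selected-score space: pooled within-class covariance Sw,
# between-class scatter Sb; discriminant axes are eigenvectors of
# Sw^{-1/2} Sb Sw^{-1/2} mapped back by Sw^{-1/2}, so Euclidean distance in
# discriminant space equals Mahalanobis distance under the pooled covariance.
.fit_lda <- function(scores, labels) {
  labels <- factor(labels)
  g <- nlevels(labels)
  d <- ncol(scores)
  n <- nrow(scores)
  grand <- colMeans(scores)
  class_means <- do.call(rbind, lapply(levels(labels), function(l)
    colMeans(scores[labels == l, , drop = FALSE])))
  rownames(class_means) <- levels(labels)
  sw <- matrix(0, d, d)
  for (l in levels(labels)) {
    xi <- scores[labels == l, , drop = FALSE]
    xi <- sweep(xi, 2, class_means[l, ])
    sw <- sw + crossprod(xi)
  }
  sw <- sw / (n - g)
  sb <- matrix(0, d, d)
  for (l in levels(labels)) {
    dm <- class_means[l, ] - grand
    sb <- sb + sum(labels == l) * tcrossprod(dm)
  }
  esw <- eigen(sw, symmetric = TRUE)
  if (min(esw$values) < 1e-10 * max(esw$values))
    stop("within-class scatter is numerically singular; use fewer factors")
  w_half_inv <- esw$vectors %*% diag(1 / sqrt(esw$values), d) %*% t(esw$vectors)
  m <- w_half_inv %*% sb %*% w_half_inv
  em <- eigen((m + t(m)) / 2, symmetric = TRUE)
  n_axes <- min(d, g - 1L)
  axes <- w_half_inv %*% em$vectors[, seq_len(n_axes), drop = FALSE]
  list(labels = levels(labels),
       discriminant_axes = axes,
       class_means_ld = class_means %*% axes,
       eigenvalues = em$values[seq_len(n_axes)])
}

#' Fit a PC-LDA model
#'
#' The full training chain: PCA ([fit_pca()]), score projection, factor cap
#' from the smallest group ([group_size_factor_cap()]), significance
#' screening ([select_significant_pcs()]), then multi-class LDA on the
#' selected scores. Prediction assigns the nearest class mean in discriminant
#' space (equal class priors).
#'
#' @param set a preprocessed [raman_set] with >= 2 groups of >= 3 spectra.
#' @param n_factors candidate PCA factors, default 10.
#' @param alpha significance level for factor selection, default 0.05.
#' @return list of class `pclda_model` with components `pca`, `selection`,
#'   `class_labels`, `discriminant_axes`, `class_means`, `training_meta`.
#' @export
fit_pclda <- function(set, n_factors = 10L, alpha = 0.05) {
  labels <- set_labels(set)
  sizes <- table(labels)
  if (length(sizes) < 2) stop("need at least 2 groups")
  if (any(sizes < 3)) stop("every group needs >= 3 spectra")
  n_factors <- min(n_factors, length(set) - 1L, length(set$common_axis))
  pca <- fit_pca(set, n_factors)
  scores <- pca_scores(pca, set)
  cap <- group_size_factor_cap(as.integer(sizes))
  sel <- select_significant_pcs(scores, labels, alpha, cap)
  lda <- .fit_lda(scores[, sel$selected_indices, drop = FALSE], labels)
  structure(list(
    pca = pca, selection = sel,
    class_labels = lda$labels,
    discriminant_axes = lda$discriminant_axes,
    class_means = lda$class_means_ld,
    lda_eigenvalues = lda$eigenvalues,
    training_meta = list(group_sizes = as.list(sizes),
                         n_factors = pca$n_factors, alpha = alpha)
  ), class = "pclda_model")
}

#' @export
print.pclda_model <- function(x, ...) {
  cat(sprintf(
    "<pclda_model> %d classes, %d candidate factors, %d selected (%s)\n",
    length(x$class_labels), x$pca$n_factors,
    length(x$selection$selected_indices),
    paste(x$selection$selected_indices, collapse = ",")))
  invisible(x)
}

# Discriminant-space coordinates for preprocessed spectra.
.discriminant_coords <- function(model, set) {
  scores <- pca_scores(model$pca, set)
  scores[, model$selection$selected_indices, drop = FALSE] %*%
    model$discriminant_axes
}

#' Predict class labels with a frozen PC-LDA model
#'
#' Spectra are centred with the model's training mean, projected onto the
#' selected loadings and assigned to the nearest class mean in discriminant
#' space; ties go to the lowest class index in model label order.
#'
#' @param object a `pclda_model`.
#' @param set a preprocessed [raman_set] on the model's axis.
#' @param ... unused.
#' @return list with `labels` (predicted, one per spectrum) and, when the
#'   set carries true group labels, `confusion` (a test-kind
#'   [confusion_matrix()]).
#' @export
predict.pclda_model <- function(object, set, ...) {
  ld <- .discriminant_coords(object, set)
  d2 <- outer(rowSums(ld^2), rep(1, nrow(object$class_means))) -
    2 * ld %*% t(object$class_means) +
    outer(rep(1, nrow(ld)), rowSums(object$class_means^2))
  pred <- object$class_labels[apply(d2, 1, which.min)]
  truth <- tryCatch(set_labels(set), error = function(e) NULL)
  out <- list(labels = pred)
  if (!is.null(truth))
    out$confusion <- confusion_matrix(truth, pred,
                                      labels = union(object$class_labels,
                                                     unique(truth)),
                                      kind = "test")
  out
}

#' Leave-one-out cross-validation of the PC-LDA pipeline
#'
#' For every spectrum the entire chain — PCA, factor selection, LDA — is
#' refitted on the remaining spectra and the held-out spectrum predicted, so
#' no information leaks from the held-out observation into the model.
#'
#' @inheritParams fit_pclda
#' @return a [confusion_matrix()] of kind `"loocv"`; row sums equal the
#'   group sizes.
#' @export
loocv <- function(set, n_factors = 10L, alpha = 0.05) {
  truth <- set_labels(set)
  n <- length(set)
  pred <- character(n)
  for (i in seq_len(n)) {
    fold <- tryCatch(
      fit_pclda(set_subset(set, -i), n_factors = n_factors, alpha = alpha),
      error = function(e)
        stop("LOOCV fold ", i, ": ", conditionMessage(e), call. = FALSE))
    pred[i] <- predict(fold, set_subset(set, i))$labels
  }
  confusion_matrix(truth, pred, labels = sort(unique(truth)), kind = "loocv")
}

#' Build a confusion matrix
#'
#' @param truth,predicted character vectors of true and predicted labels.
#' @param labels ordered label set for rows and columns; defaults to the
#'   sorted union.
#' @param kind `"training"`, `"loocv"` or `"test"`.
#' @return integer matrix of class `confusion_matrix`, true groups in rows,
#'   predicted in columns, with a `kind` attribute.
#' @export
confusion_matrix <- function(truth, predicted, labels = NULL,
                             kind = c("training", "loocv", "test")) {
  kind <- match.arg(kind)
  if (is.null(labels)) labels <- sort(unique(c(truth, predicted)))
  m <- table(factor(truth, levels = labels),
             factor(predicted, levels = labels))
  m <- matrix(as.integer(m), nrow = length(labels),
              dimnames = list(true = labels, predicted = labels))
  structure(m, class = c("confusion_matrix", class(m)), kind = kind)
}

#' @export
print.confusion_matrix <- function(x, ...) {
  cat(sprintf("Confusion matrix (%s), true rows x predicted columns:\n",
              attr(x, "kind")))
  y <- unclass(x)
  attr(y, "kind") <- NULL
  print(y)
  eff <- classification_efficiency(x)
  cat(sprintf("Overall efficiency: %.2f%%\n", eff$overall))
  invisible(x)
}

#' Classification efficiencies of a confusion matrix
#'
#' @param cm a [confusion_matrix()] (or plain square count matrix) with
#'   positive row sums.
#' @return list with `overall` (100 x trace / total) and `per_group`
#'   (100 x diagonal / row sum, named by group).
#' @export
classification_efficiency <- function(cm) {
  cm <- unclass(cm)
  rs <- rowSums(cm)
  if (any(rs <= 0)) stop("every true group must have at least one spectrum")
  list(overall = 100 * sum(diag(cm)) / sum(cm),
       per_group = 100 * diag(cm) / rs)
}

#' Serialize a PC-LDA model to JSON
#'
#' Versioned plain-text snapshot (axis, mean, loadings, selection,
#' discriminants) so a frozen standard model can be reused for later test
#' prediction.
#'
#' @param model a `pclda_model`.
#' @param path output JSON path.
#' @return `path`, invisibly.
#' @export
write_model <- function(model, path) {
  doc <- list(
    format = "ramanclass/pclda", version = 1L,
    axis = model$pca$axis,
    mean_vector = model$pca$mean_vector,
    loadings = model$pca$loadings,
    explained_variance = model$pca$explained_variance,
    total_variance = model$pca$total_variance,
    n_factors = model$pca$n_factors,
    selection = model$selection[c("selected_indices", "p_values", "alpha",
                                  "max_factors")],
    class_labels = model$class_labels,
    discriminant_axes = model$discriminant_axes,
    class_means = model$class_means,
    lda_eigenvalues = model$lda_eigenvalues,
    training_meta = model$training_meta
  )
  jsonlite::write_json(doc, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' Read a PC-LDA model written by [write_model()]
#' @param path JSON path.
#' @return a `pclda_model`.
#' @export
read_model <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(doc$format, "ramanclass/pclda"))
    stop(path, " is not a serialized PC-LDA model")
  structure(list(
    pca = structure(list(
      mean_vector = doc$mean_vector,
      loadings = matrix(unlist(doc$loadings), ncol = doc$n_factors),
      explained_variance = doc$explained_variance,
      total_variance = doc$total_variance,
      n_factors = as.integer(doc$n_factors),
      axis = doc$axis), class = "pca_model"),
    selection = structure(list(
      selected_indices = as.integer(doc$selection$selected_indices),
      p_values = doc$selection$p_values,
      alpha = doc$selection$alpha,
      max_factors = as.integer(doc$selection$max_factors)),
      class = "factor_selection"),
    class_labels = doc$class_labels,
    discriminant_axes = matrix(unlist(doc$discriminant_axes),
                               nrow = length(doc$selection$selected_indices)),
    class_means = matrix(unlist(doc$class_means),
                         nrow = length(doc$class_labels)),
    lda_eigenvalues = doc$lda_eigenvalues,
    training_meta = doc$training_meta
  ), class = "pclda_model")
}

#' Write a confusion matrix as CSV (true rows x predicted columns)
#' @param cm a [confusion_matrix()].
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_confusion <- function(cm, path) {
  df <- as.data.frame.matrix(unclass(cm))
  df <- cbind(true = rownames(cm), df)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a confusion matrix CSV written by [write_confusion()]
#' @param path CSV path with a `true` label column.
#' @param kind stored in the `kind` attribute.
#' @return a [confusion_matrix()].
#' @export
read_confusion <- function(path, kind = "training") {
  df <- utils::read.csv(path, check.names = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  storage.mode(m) <- "integer"
  names(dimnames(m)) <- c("true", "predicted")
  structure(m, class = c("confusion_matrix", class(m)), kind = kind)
}

#' Published reference confusion matrices
#'
#' Confusion matrices as printed in the recurrent-glioblastoma Raman study
#' the package's workflow follows: the 8-group cell standard model and its
#' LOOCV, and the 2-group responder/non-responder tissue model and its LOOCV.
#' Shipped as plain-text CSVs; useful as arithmetic fixtures for
#' [classification_efficiency()].
#'
#' @param which one of `"cell_standard"`, `"cell_loocv"`, `"tissue_standard"`,
#'   `"tissue_loocv"`.
#' @return a [confusion_matrix()].
#' @export
reference_confusion <- function(which = c("cell_standard", "cell_loocv",
                                          "tissue_standard", "tissue_loocv")) {
  which <- match.arg(which)
  path <- system.file("extdata", paste0(which, "_confusion.csv"),
                      package = "ramanclass", mustWork = TRUE)
  kind <- if (grepl("loocv", which)) "loocv" else "training"
  read_confusion(path, kind = kind)
}
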