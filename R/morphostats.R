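# Downstream statistics: ROC/AUC discrimination screening per feature,
# best-percentile-variant selection, feature correlation matrix, PCA compound
# score (PC1), group tests, and manual-vs-automated agreement.

#' ROC AUC of one feature between two groups
#'
#' The area under the ROC curve computed by the rank-sum (Mann-Whitney)
#' construction, which equals the pairwise-comparison probability with ties
#' counting 0.5. Raw AUC is the probability that a random case (`labels ==
#' positive`) scores higher than a random control. The folded AUC
#' `max(A, 1 - A)` is reported with the direction of the effect, because the
#' discrimination screen does not care which group scores higher.
#'
#' @param values numeric feature values.
#' @param labels two-level vector, same length; `positive` defines the case
#'   group.
#' @param positive the label treated as the case group; default the first
#'   level encountered.
#' @return A list: `auc_raw`, `auc` (folded, in `[0.5, 1]`), `direction`
#'   (which group scores higher), `n_positive`, `n_negative`.
#' @export
roc_auc <- function(values, labels, positive = NULL) {
  labels <- as.character(labels)
  lv <- unique(labels)
  if (length(lv) != 2L) stop("labels must have exactly two levels",
                             call. = FALSE)
  if (is.null(positive)) positive <- lv[1]
  pos <- values[labels == positive]
  neg <- values[labels != positive]
  if (length(pos) == 0L || length(neg) == 0L) {
    stop("both groups must be non-empty", call. = FALSE)
  }
  r <- rank(c(pos, neg))  # mid-ranks: ties count 0.5 in the pair sum
  auc_raw <- (sum(r[seq_along(pos)]) - length(pos) * (length(pos) + 1) / 2) /
    (length(pos) * length(neg))
  auc <- max(auc_raw, 1 - auc_raw)
  list(auc_raw = auc_raw,
       auc = auc,
       direction = if (auc_raw >= 0.5) positive else setdiff(lv, positive),
       n_positive = length(pos),
       n_negative = length(neg))
}

#' ROC screen of every feature in a feature table
#'
#' @param table a `feature_table` with a `group` column (or supply `labels`).
#' @param labels optional explicit group labels.
#' @param positive case-group label passed to [roc_auc()].
#' @return A tibble of class `mglia_roc`: feature, family, percentile tag,
#'   raw and folded AUC, direction, group sizes.
#' @export
roc_screen <- function(table, labels = NULL, positive = NULL) {
  if (is.null(labels)) {
    stopifnot("group" %in% names(table))
    labels <- table$group
  }
  roster <- attr(table, "roster") %||% feature_roster()
  rows <- lapply(seq_len(nrow(roster)), function(i) {
    f <- roster$feature[i]
    r <- roc_auc(table[[f]], labels, positive)
    tibble::tibble(feature = f, family = roster$family[i],
                   percentile_tag = roster$percentile_tag[i],
                   auc_raw = r$auc_raw, auc = r$auc,
                   direction = r$direction,
                   n_positive = r$n_positive, n_negative = r$n_negative)
  })
  out <- dplyr::bind_rows(rows)
  class(out) <- c("mglia_roc", class(out))
  out
}

#' Select features for the compound score
#'
#' Keeps features whose folded AUC exceeds `auc_cutoff` (default 0.85), then
#' collapses each percentile-variant family (same base name, different
#' percentile tag) to its single highest-AUC variant; AUC ties break toward
#' the lower percentile tag. Returns features ordered as in the roster.
#'
#' @param roc an `mglia_roc` tibble from [roc_screen()].
#' @param auc_cutoff folded-AUC threshold, default 0.85 (strict `>`).
#' @return Character vector of selected feature names (possibly empty, with a
#'   warning).
#' @export
select_features <- function(roc, auc_cutoff = 0.85) {
  keep <- roc[roc$auc > auc_cutoff, , drop = FALSE]
  if (nrow(keep) == 0L) {
    warning("no feature exceeds the AUC cutoff")
    return(character(0))
  }
  base_name <- ifelse(
    keep$percentile_tag == "none", keep$feature,
    sub(paste0(" (", paste(PCT_TAGS, collapse = "|"), ")$"), "",
        keep$feature))
  tag_rank <- match(keep$percentile_tag, PCT_TAGS)  # NA for "none"
  tag_rank[is.na(tag_rank)] <- 0L
  ord <- order(base_name, -keep$auc, tag_rank)
  keep <- keep[ord, ]
  bn <- base_name[ord]
  best <- keep$feature[!duplicated(bn)]
  roster_order <- feature_roster()$feature
  best[order(match(best, roster_order))]
}

#' Pearson correlation matrix of selected features
#'
#' @param table a `feature_table`.
#' @param features character vector of feature columns (>= 2).
#' @return Symmetric correlation matrix with unit diagonal. Zero-variance
#'   features get 0 rows/columns (diagonal kept at 1) with a warning.
#' @export
correlation_matrix <- function(table, features) {
  stopifnot(length(features) >= 2L, nrow(table) >= 3L)
  x <- as.matrix(table[, features])
  sds <- apply(x, 2, sd)
  m <- suppressWarnings(cor(x))
  if (any(sds == 0)) {
    warning("zero-variance feature(s): ",
            paste(features[sds == 0], collapse = ", "))
    m[sds == 0, ] <- 0
    m[, sds == 0] <- 0
  }
  diag(m) <- 1
  m
}

#' PCA compound score over the selected features
#'
#' Principal component analysis with centering and scaling of the selected
#' features (i.e. the eigendecomposition of their correlation matrix). The
#' first component serves as a single compound morphology score per cell. Its
#' sign is oriented so that PC1 correlates positively with "Segments per
#' branch": higher PC1 means a more ramified cell.
#'
#' @param table a `feature_table`.
#' @param features selected feature names (>= 2); e.g. from
#'   [select_features()].
#' @return An object of class `mglia_pca`: `selected_features`, `loadings`,
#'   `explained_variance_fraction`, `scores` (tibble with `cell_id`, `group`
#'   if present, and `PC1..PCk`), `orientation_sign`.
#' @export
pca_compound_score <- function(table, features) {
  stopifnot(length(features) >= 2L)
  if (nrow(table) < 3L) stop("need at least 3 cells", call. = FALSE)
  x <- as.matrix(table[, features])
  fit <- stats::prcomp(x, center = TRUE, scale. = TRUE)
  evf <- fit$sdev^2 / sum(fit$sdev^2)
  sgn <- rep(1, ncol(fit$rotation))
  ref <- table[["Segments per branch"]]
  if (!is.null(ref) && sd(ref) > 0 && sd(fit$x[, 1]) > 0) {
    r1 <- suppressWarnings(cor(fit$x[, 1], ref))
    if (is.finite(r1) && r1 < 0) sgn[1] <- -1
  }
  scores <- sweep(fit$x, 2, sgn, `*`)
  loadings <- sweep(fit$rotation, 2, sgn, `*`)
  sc <- tibble::as_tibble(scores)
  if ("cell_id" %in% names(table)) sc <- dplyr::bind_cols(
    table[, intersect(c("stack_id", "cell_id", "group"), names(table))], sc)
  structure(
    list(selected_features = features,
         loadings = loadings,
         explained_variance_fraction = evf,
         scores = sc,
         orientation_sign = sgn,
         center = fit$center,
         scale = fit$scale),
    class = "mglia_pca")
}

#' @export
print.mglia_pca <- function(x, ...) {
  cat(sprintf("<mglia_pca> %d features, PC1 explains %.1f%% of variance\n",
              length(x$selected_features),
              100 * x$explained_variance_fraction[1]))
  invisible(x)
}

#' Wilcoxon rank-sum group comparison
#'
#' Two-sided Wilcoxon rank sum test with continuity correction.
#'
#' @param values numeric vector.
#' @param labels two-level group vector.
#' @return A tibble: statistic, p_value, n per group.
#' @export
group_test <- function(values, labels) {
  labels <- as.character(labels)
  lv <- unique(labels)
  stopifnot(length(lv) == 2L)
  a <- values[labels == lv[1]]
  b <- values[labels == lv[2]]
  if (length(a) < 2L || length(b) < 2L) {
    stop("both groups need at least 2 observations", call. = FALSE)
  }
  ht <- suppressWarnings(stats::wilcox.test(a, b, correct = TRUE))
  tibble::tibble(statistic = unname(ht$statistic), p_value = ht$p.value,
                 n_1 = length(a), n_2 = length(b))
}

#' Manual-vs-automated agreement
#'
#' Pearson and Spearman correlations (with p-values) between paired manual
#' and automated scores of the same cells, e.g. manual circularity vs the
#' automated "Circularity" feature, or the Shoenen ramification index (end
#' branches / primary branches) vs "End-nodes per branch".
#'
#' @param manual,automated paired numeric vectors (n >= 3).
#' @return A tibble with one row per correlation type.
#' @export
compare_manual <- function(manual, automated) {
  stopifnot(length(manual) == length(automated))
  if (length(manual) < 3L) stop("need at least 3 pairs", call. = FALSE)
  pe <- stats::cor.test(manual, automated, method = "pearson")
  sp <- suppressWarnings(
    stats::cor.test(manual, automated, method = "spearman"))
  tibble::tibble(method = c("pearson", "spearman"),
                 estimate = c(unname(pe$estimate), unname(sp$estimate)),
                 p_value = c(pe$p.value, sp$p.value),
                 n = length(manual))
}

# ---------------------------------------------------------------------------
# broom-style accessors

#' Tidy an mglia_pca: loadings in long form
#' @param x an `mglia_pca`.
#' @param ... unused.
#' @return Tibble: feature, component, loading.
#' @export
tidy.mglia_pca <- function(x, ...) {
  l <- x$loadings
  tibble::tibble(
    feature = rep(rownames(l), ncol(l)),
    component = rep(colnames(l), each = nrow(l)),
    loading = as.numeric(l))
}

#' One-row summary of an mglia_pca
#' @param x an `mglia_pca`.
#' @param ... unused.
#' @return Tibble: n_features, n_cells, pc1/pc2 explained variance fractions.
#' @export
glance.mglia_pca <- function(x, ...) {
  tibble::tibble(
    n_features = length(x$selected_features),
    n_cells = nrow(x$scores),
    pc1_variance_fraction = x$explained_variance_fraction[1],
    pc2_variance_fraction = if (length(x$explained_variance_fraction) > 1) {
      x$explained_variance_fraction[2]
    } else {
      NA_real_
    })
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

# ---------------------------------------------------------------------------
# plots

#' Plot method for ROC screens: folded AUC per feature by family
#' @param object an `mglia_roc`.
#' @param auc_cutoff reference line, default 0.85.
#' @param ... unused.
#' @return A ggplot.
#' @export
autoplot.mglia_roc <- function(object, auc_cutoff = 0.85, ...) {
  df <- dplyr::arrange(object, .data$family, .data$auc)
  df$feature <- factor(df$feature, levels = df$feature)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$auc, y = .data$feature,
                                   colour = .data$family)) +
    ggplot2::geom_point() +
    ggplot2::geom_vline(xintercept = auc_cutoff, linetype = 2) +
    ggplot2::labs(x = "folded AUC", y = NULL, colour = "family") +
    ggplot2::theme_minimal()
}

#' Plot method for PCA compound scores: PC1/PC2 scatter
#' @param object an `mglia_pca`.
#' @param ... unused.
#' @return A ggplot.
#' @export
autoplot.mglia_pca <- function(object, ...) {
  sc <- object$scores
  has_pc2 <- "PC2" %in% names(sc)
  p <- ggplot2::ggplot(
    sc, ggplot2::aes(x = .data$PC1,
                     y = if (has_pc2) .data$PC2 else 0)) +
    ggplot2::labs(
      x = sprintf("PC1 (%.0f%%)",
                  100 * object$explained_variance_fraction[1]),
      y = if (has_pc2) {
        sprintf("PC2 (%.0f%%)", 100 * object$explained_variance_fraction[2])
      } else {
        NULL
      }) +
    ggplot2::theme_minimal()
  if ("group" %in% names(sc)) {
    p + ggplot2::geom_point(ggplot2::aes(colour = .data$group))
  } else {
    p + ggplot2::geom_point()
  }
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
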