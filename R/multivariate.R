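# Z-score normalization and PCA of the combined phenotype + expression
# feature matrix (observations = treatment-group replicates; variables =
# G, MGT, shoot/root length, strand-break a.u., per-gene expression).

#' Column-wise Z-scores
#'
#' Autoscaling: each column is mean-centered and divided by its sample SD.
#' Zero-variance columns are dropped with a warning (they carry no
#' correlation information); columns with fewer than 2 non-missing values
#' are an error.
#'
#' @param m Numeric matrix or data frame (rows = observations).
#' @return Matrix with every retained column of mean 0 and sample SD 1.
#' @export
zscore_columns <- function(m) {
  m <- as.matrix(m)
  n_ok <- colSums(!is.na(m))
  if (any(n_ok < 2)) {
    stop(sprintf("column(s) with < 2 values: %s",
                 paste(colnames(m)[n_ok < 2], collapse = ", ")), call. = FALSE)
  }
  sds <- apply(m, 2, sd, na.rm = TRUE)
  if (any(sds == 0)) {
    warning(sprintf("dropping zero-variance column(s): %s",
                    paste(colnames(m)[sds == 0], collapse = ", ")),
            call. = FALSE)
    m <- m[, sds > 0, drop = FALSE]
  }
  scale(m)[, , drop = FALSE]
}

#' Principal component analysis of a Z-scored matrix
#'
#' Singular-value decomposition of the (already column-standardized)
#' matrix, equivalent to correlation-matrix PCA of the raw variables.
#' The sign of each component is fixed so that its largest-magnitude
#' loading is positive; scores are the data projected on the loadings. No
#' rotation is applied.
#'
#' @param m Z-scored matrix from [zscore_columns()] (rows >= 2,
#'   columns >= 2).
#' @param n_components Components to retain (default all,
#'   `min(nrow - 1, ncol)`).
#' @return A `pca_result` list: `scores` (observations x components),
#'   `loadings` (variables x components, orthonormal columns),
#'   `explained_variance` (percent per retained component) and
#'   `explained_variance_all` (over all components, summing to 100).
#' @export
pca <- function(m, n_components = NULL) {
  m <- as.matrix(m)
  if (nrow(m) < 2 || ncol(m) < 2) {
    stop("need at least 2 rows and 2 columns", call. = FALSE)
  }
  max_comp <- min(nrow(m) - 1, ncol(m))
  if (is.null(n_components)) n_components <- max_comp
  if (n_components < 1 || n_components > max_comp) {
    stop(sprintf("n_components must be in 1..%d", max_comp), call. = FALSE)
  }
  fit <- prcomp(m, center = FALSE, scale. = FALSE)
  load_all <- fit$rotation
  # deterministic sign: largest |loading| positive in every component
  for (j in seq_len(ncol(load_all))) {
    peak <- which.max(abs(load_all[, j]))
    if (load_all[peak, j] < 0) load_all[, j] <- -load_all[, j]
  }
  scores_all <- m %*% load_all
  var_all <- fit$sdev^2
  expl_all <- 100 * var_all / sum(var_all)
  keep <- seq_len(n_components)
  structure(list(
    scores = scores_all[, keep, drop = FALSE],
    loadings = load_all[, keep, drop = FALSE],
    explained_variance = expl_all[keep],
    explained_variance_all = expl_all
  ), class = "pca_result")
}

#' @export
print.pca_result <- function(x, ...) {
  cat(sprintf("PCA: %d observations x %d variables, %d component(s) retained\n",
              nrow(x$scores), nrow(x$loadings), ncol(x$scores)))
  cat("explained variance (%):",
      paste(sprintf("%.1f", x$explained_variance), collapse = ", "), "\n")
  invisible(x)
}

#' Combined scores + loadings table for a biplot
#'
#' One long table holding the observation scores and the variable loadings
#' scaled to the score range (directions preserved exactly; the scale
#' factor is recorded so the raw loadings can be recovered).
#'
#' @param p A [pca()] result with >= 2 retained components.
#' @param components Which two components to tabulate (default `c(1, 2)`).
#' @return Data frame with columns `label`, `kind` ("score" or "loading"),
#'   `x`, `y`; attributes `scale_factor` and `axis_labels` (axis titles with
#'   explained-variance percentages).
#' @export
biplot_table <- function(p, components = c(1, 2)) {
  stopifnot(inherits(p, "pca_result"))
  if (ncol(p$scores) < max(components)) {
    stop("requested components not retained", call. = FALSE)
  }
  sc <- p$scores[, components, drop = FALSE]
  ld <- p$loadings[, components, drop = FALSE]
  scale_factor <- max(abs(sc)) / max(abs(ld))
  out <- rbind(
    data.frame(label = rownames(sc) %||% paste0("obs", seq_len(nrow(sc))),
               kind = "score", x = sc[, 1], y = sc[, 2],
               stringsAsFactors = FALSE),
    data.frame(label = rownames(ld) %||% paste0("var", seq_len(nrow(ld))),
               kind = "loading",
               x = ld[, 1] * scale_factor, y = ld[, 2] * scale_factor,
               stringsAsFactors = FALSE))
  rownames(out) <- NULL
  attr(out, "scale_factor") <- scale_factor
  attr(out, "axis_labels") <- sprintf(
    "PC%d (%.1f%%)", components, p$explained_variance[components])
  out
}

#' Assemble the PCA feature matrix
#'
#' Joins the replicate-level phenotype variables (G, MGT, shoot length SL,
#' root length RL, strand-break score SB) with the per-group relative
#' expression values for one accession. Expression is measured once per
#' group (reaction triplicates, no biological replicates), so each gene's
#' value is broadcast to the group's replicate rows; rows are labelled
#' `group.replicate`.
#'
#' @param germination Output of [germination_indices()] for one accession.
#' @param biometry Output of [biometry_replicates()] for one accession.
#' @param comet Output of [comet_scores()] for one accession.
#' @param expression Optional gene x group matrix (e.g. `n_rel` from
#'   [expression_analysis()]); only the columns matching the phenotype
#'   groups are used.
#' @return Numeric matrix, rows = replicates, columns = variables.
#' @export
build_feature_matrix <- function(germination, biometry, comet,
                                 expression = NULL) {
  key <- function(df) {
    data.frame(group = group_label(df$priming, df$stress),
               replicate = df$replicate)
  }
  base <- cbind(key(germination),
                G = germination$G, MGT = germination$MGT)
  bio <- cbind(key(biometry),
               SL = biometry$shoot_len_cm, RL = biometry$root_len_cm)
  com <- cbind(key(comet), SB = comet$au)
  merged <- merge(merge(base, bio, by = c("group", "replicate")),
                  com, by = c("group", "replicate"))
  merged <- merged[order(merged$group, merged$replicate), ]
  m <- as.matrix(merged[c("G", "MGT", "SL", "RL", "SB")])
  rownames(m) <- paste(merged$group, merged$replicate, sep = ".")
  if (!is.null(expression)) {
    missing_groups <- setdiff(unique(merged$group), colnames(expression))
    if (length(missing_groups)) {
      stop(sprintf("expression matrix lacks group(s): %s",
                   paste(missing_groups, collapse = ", ")), call. = FALSE)
    }
    expr <- t(expression[, merged$group, drop = FALSE])
    rownames(expr) <- rownames(m)
    m <- cbind(m, expr)
  }
  m
}
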