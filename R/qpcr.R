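# Efficiency-standardized qPCR relative quantification and geNorm
# reference-gene stability. Quantities are calibrator-relative:
# Q = E^(Ct_calibrator - Ct_sample), with a standardized amplification
# efficiency E (default 1.8, i.e. 1.8-fold per cycle).

#' Collapse technical replicates to mean Ct
#'
#' Arithmetic mean of the technical-replicate Ct values per accession x
#' gene x group, with missing reactions excluded and their count recorded.
#'
#' @param table A ct `study_table` (see [load_table()]); `ct` may be `NA`
#'   for flagged-missing reactions.
#' @return Data frame with columns `accession`, `gene`, `group`, `mean_ct`,
#'   `sd_ct`, `n`, `n_missing`. `mean_ct` is `NA` when every replicate is
#'   missing.
#' @export
collapse_technical <- function(table) {
  df <- as.data.frame(table)
  out <- summarize_groups(df, "ct", c("accession", "gene", "group"))
  names(out)[names(out) == "mean"] <- "mean_ct"
  names(out)[names(out) == "sd"] <- "sd_ct"
  out
}

#' Mean-Ct matrix for one accession
#'
#' Pivot of [collapse_technical()] output to a gene x group matrix.
#'
#' @param mean_ct Output of [collapse_technical()].
#' @param accession Accession to extract (default: the only one present).
#' @return Numeric matrix, rows = genes, columns = groups (input order
#'   preserved).
#' @export
ct_matrix <- function(mean_ct, accession = NULL) {
  if (!is.null(accession)) {
    mean_ct <- mean_ct[mean_ct$accession == accession, , drop = FALSE]
  } else if (length(unique(mean_ct$accession)) > 1) {
    stop("several accessions present; supply `accession`", call. = FALSE)
  }
  genes <- unique(mean_ct$gene)
  groups <- unique(mean_ct$group)
  m <- matrix(NA_real_, length(genes), length(groups),
              dimnames = list(genes, groups))
  m[cbind(match(mean_ct$gene, genes), match(mean_ct$group, groups))] <-
    mean_ct$mean_ct
  m
}

#' Calibrator-relative quantities Q
#'
#' Q = E^(Ct_calibrator - Ct_sample) per gene x group, so Q = 1 in the
#' calibrator group and a sample one cycle below the calibrator has Q = E.
#' The calibrator is chosen per gene: either a named group or, by default,
#' the group with the minimum mean Ct (the most-expressed group, giving
#' Q <= 1 everywhere else).
#'
#' @param ct_mat Gene x group matrix of mean Ct (see [ct_matrix()]).
#' @param efficiency Amplification efficiency E, one shared value in
#'   (1, 2\] (default 1.8) or a named per-gene vector.
#' @param calibrator `NULL` (per-gene minimum-Ct group) or the name of a
#'   group, e.g. `"DS"`.
#' @return Gene x group matrix of quantities Q (> 0).
#' @export
relative_quantity <- function(ct_mat, efficiency = 1.8, calibrator = NULL) {
  stopifnot(is.matrix(ct_mat))
  E <- if (length(efficiency) == 1 && is.null(names(efficiency))) {
    setNames(rep(efficiency, nrow(ct_mat)), rownames(ct_mat))
  } else {
    if (!all(rownames(ct_mat) %in% names(efficiency))) {
      stop("per-gene efficiency must name every gene", call. = FALSE)
    }
    efficiency[rownames(ct_mat)]
  }
  if (any(E <= 1 | E > 2)) {
    stop("efficiency must satisfy 1 < E <= 2", call. = FALSE)
  }
  if (!is.null(calibrator) && !calibrator %in% colnames(ct_mat)) {
    stop(sprintf("calibrator group '%s' not in table", calibrator), call. = FALSE)
  }
  q <- ct_mat
  for (g in rownames(ct_mat)) {
    row <- ct_mat[g, ]
    cal_ct <- if (is.null(calibrator)) {
      if (all(is.na(row))) NA_real_ else min(row, na.rm = TRUE)
    } else {
      row[[calibrator]]
    }
    if (is.na(cal_ct)) {
      stop(sprintf("missing calibrator Ct for gene '%s'", g), call. = FALSE)
    }
    q[g, ] <- E[[g]]^(cal_ct - row)
  }
  q
}

#' geNorm expression-stability measure M
#'
#' For each candidate reference gene j, the pairwise variation with every
#' other candidate k is V_jk = SD over samples of log2(Q_j / Q_k); the
#' stability measure is M_j = mean of V_jk over all k != j. Lower M means
#' more stable expression; the selected reference set is the `k_select`
#' genes with the lowest M.
#'
#' @param q Gene x sample matrix of positive quantities (>= 3 genes,
#'   >= 2 samples).
#' @param k_select Size of the selected reference set (default 2).
#' @return A data frame (class `stability_ranking`) with columns `gene`,
#'   `M`, `rank` (1 = most stable, ties broken by gene order), `selected`.
#' @export
genorm_m <- function(q, k_select = 2) {
  stopifnot(is.matrix(q))
  if (nrow(q) < 3) stop("geNorm M needs at least 3 candidate genes", call. = FALSE)
  if (ncol(q) < 2) stop("geNorm M needs at least 2 samples", call. = FALSE)
  if (any(is.na(q)) || any(q <= 0)) {
    stop("quantities must be positive and non-missing", call. = FALSE)
  }
  lg <- log2(q)
  n <- nrow(q)
  M <- vapply(seq_len(n), function(j) {
    v <- vapply(setdiff(seq_len(n), j), function(k) sd(lg[j, ] - lg[k, ]), 0)
    mean(v)
  }, 0)
  rank_ <- order(order(M, seq_len(n)))
  out <- data.frame(gene = rownames(q), M = M, rank = rank_,
                    selected = rank_ <= k_select,
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  structure(out, class = c("stability_ranking", "data.frame"))
}

#' geNorm ranking by stepwise exclusion
#'
#' The full geNorm procedure: repeatedly recompute M on the remaining
#' candidates and exclude the least stable (highest M) gene until two
#' remain. The default reference selection used elsewhere in the package is
#' the simpler single-pass "two lowest M" rule of [genorm_m()]; the
#' stepwise ranking is provided for inspection of the candidate panel.
#'
#' @param q Gene x sample matrix of positive quantities.
#' @return Data frame with columns `gene` and `exclusion_order` (1 = first
#'   excluded, i.e. least stable; the final pair shares the highest order).
#' @export
genorm_rank <- function(q) {
  remaining <- rownames(q)
  order_out <- setNames(rep(NA_integer_, nrow(q)), remaining)
  step <- 1L
  while (length(remaining) > 2) {
    m <- genorm_m(q[remaining, , drop = FALSE], k_select = 2)
    worst <- m$gene[which.max(m$M)]
    order_out[worst] <- step
    remaining <- setdiff(remaining, worst)
    step <- step + 1L
  }
  order_out[remaining] <- step
  data.frame(gene = names(order_out),
             exclusion_order = unname(order_out),
             stringsAsFactors = FALSE)
}

#' Select reference genes
#'
#' The `k` candidates with the lowest geNorm M-values.
#'
#' @param q Gene x sample matrix of positive quantities.
#' @param k Number of references (default 2).
#' @return Character vector of selected gene names.
#' @export
select_references <- function(q, k = 2) {
  m <- genorm_m(q, k_select = k)
  m$gene[m$selected]
}

#' Reference-normalized relative expression
#'
#' N_rel = Q_target / geometric mean of the reference genes' Q, per sample
#' (column). Rescaling any single reference by a constant across all
#' samples leaves N_rel unchanged up to a global factor shared by every
#' target, and doubling all references in one sample halves every target's
#' N_rel in that sample.
#'
#' @param q Gene x sample matrix of quantities (targets and references).
#' @param refs Character vector of reference gene names (rows of `q`).
#' @return Gene x sample matrix of normalized expression for all non-reference
#'   rows of `q`.
#' @export
normalize_expression <- function(q, refs) {
  stopifnot(is.matrix(q))
  if (!all(refs %in% rownames(q))) {
    stop("reference genes not found in quantity matrix", call. = FALSE)
  }
  ref_q <- q[refs, , drop = FALSE]
  if (any(is.na(ref_q))) {
    bad <- colnames(q)[colSums(is.na(ref_q)) > 0]
    warning(sprintf("missing reference quantity in group(s): %s; flagged missing",
                    paste(bad, collapse = ", ")), call. = FALSE)
  }
  geo <- exp(colMeans(log(ref_q)))
  targets <- setdiff(rownames(q), refs)
  sweep(q[targets, , drop = FALSE], 2, geo, "/")
}

#' Row-wise Z-scores of an expression matrix
#'
#' Per gene (row): subtract the mean over groups and divide by the sample
#' SD, giving the matrix displayed as an expression heat map. Rows with
#' zero SD are set to all-zero and flagged.
#'
#' @param m Gene x group numeric matrix.
#' @return Matrix of the same shape with rows standardized; attribute
#'   `constant_rows` names any zero-variance rows.
#' @export
zscore_by_gene <- function(m) {
  stopifnot(is.matrix(m))
  if (ncol(m) < 2) stop("need at least 2 groups per gene", call. = FALSE)
  out <- m
  constant <- character()
  for (i in seq_len(nrow(m))) {
    v <- m[i, ]
    s <- sd(v)
    if (is.na(s) || s == 0) {
      out[i, ] <- 0
      constant <- c(constant, rownames(m)[i] %||% as.character(i))
    } else {
      out[i, ] <- (v - mean(v)) / s
    }
  }
  attr(out, "constant_rows") <- constant
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Full expression analysis for one accession
#'
#' Chains the qPCR stages: collapse technical replicates, compute
#' calibrator-relative quantities, rank candidate references by geNorm M,
#' normalize the targets by the geometric mean of the selected references,
#' and Z-score by gene.
#'
#' @param table A ct `study_table`.
#' @param accession Accession to analyse (default: the only one present).
#' @param efficiency Amplification efficiency E (default 1.8).
#' @param calibrator Calibrator group passed to [relative_quantity()].
#' @param candidates Candidate reference panel (gene names) that geNorm
#'   ranks; `NULL` ranks every gene in the table. Target genes under strong
#'   regulation should not be in the panel.
#' @param refs Reference gene names; `NULL` selects the two lowest-M
#'   candidates.
#' @return List with `mean_ct`, `q` (quantities), `stability`
#'   ([genorm_m()] table over the candidates), `refs`, `n_rel` (normalized
#'   targets) and `zscores` (per-gene Z-scored `n_rel`).
#' @export
expression_analysis <- function(table, accession = NULL, efficiency = 1.8,
                                calibrator = NULL, candidates = NULL,
                                refs = NULL) {
  mean_ct <- collapse_technical(table)
  cmat <- ct_matrix(mean_ct, accession)
  q <- relative_quantity(cmat, efficiency, calibrator)
  if (is.null(candidates)) candidates <- rownames(q)
  if (!all(candidates %in% rownames(q))) {
    stop("candidate genes not found in table", call. = FALSE)
  }
  stability <- genorm_m(q[candidates, , drop = FALSE])
  if (is.null(refs)) refs <- stability$gene[stability$selected]
  n_rel <- normalize_expression(q, refs)
  list(mean_ct = mean_ct, q = q, stability = stability, refs = refs,
       n_rel = n_rel, zscores = zscore_by_gene(n_rel))
}
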