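# Inference layer: heteroscedastic t-test with star annotation, one-way
# ANOVA, Duncan's multiple range test and compact letter displays.

#' Star annotation for a p-value
#'
#' `***` for p < 0.001, `**` for p < 0.01, `*` for p < 0.05, `""` otherwise.
#'
#' @param p A p-value (vectorised).
#' @return Character vector of star strings.
#' @export
p_stars <- function(p) {
  vapply(p, function(pi) {
    if (is.na(pi)) return(NA_character_)
    if (pi < 0.001) "***" else if (pi < 0.01) "**" else if (pi < 0.05) "*" else ""
  }, "")
}

#' Welch's heteroscedastic two-tailed t-test
#'
#' Two-sample t-test without the equal-variance assumption:
#' t = (mean(a) - mean(b)) / sqrt(s_a^2/n_a + s_b^2/n_b) with
#' Welch-Satterthwaite degrees of freedom, two-tailed p, and star
#' annotation at the 0.05 / 0.01 / 0.001 thresholds.
#'
#' @param a,b Numeric vectors of replicate values, each of length >= 2.
#' @return A `welch_result` list: `statistic`, `df`, `p_value`, `stars`,
#'   `mean_a`, `mean_b`.
#' @export
welch_t <- function(a, b) {
  if (length(a) < 2 || length(b) < 2) {
    stop("each group needs at least 2 values", call. = FALSE)
  }
  if (any(!is.finite(a)) || any(!is.finite(b))) {
    stop("values must be finite", call. = FALSE)
  }
  ht <- t.test(a, b, var.equal = FALSE, alternative = "two.sided")
  structure(list(
    statistic = unname(ht$statistic),
    df = unname(ht$parameter),
    p_value = ht$p.value,
    stars = p_stars(ht$p.value),
    mean_a = mean(a), mean_b = mean(b)
  ), class = "welch_result")
}

#' @export
print.welch_result <- function(x, ...) {
  cat(sprintf("Welch t = %.4f, df = %.2f, p = %.4g %s\n",
              x$statistic, x$df, x$p_value, x$stars))
  invisible(x)
}

as_group_samples <- function(groups) {
  if (is.data.frame(groups)) {
    stopifnot(all(c("group", "value") %in% names(groups)))
    groups <- split(groups$value, groups$group)
  }
  if (is.null(names(groups)) || anyDuplicated(names(groups))) {
    stop("groups must be a named list with unique labels", call. = FALSE)
  }
  lapply(groups, function(v) {
    if (any(!is.finite(v))) stop("values must be finite", call. = FALSE)
    as.numeric(v)
  })
}

#' One-way analysis of variance
#'
#' Standard between/within decomposition over k groups (fitted through
#' `stats::lm`/`anova`), returning the pieces Duncan's test needs: F and its
#' p-value, the within-group mean square MSW, group means and sizes, and the
#' harmonic mean group size n_h. With zero within-group variance and unequal
#' means, F is reported as `Inf` with p = 0 and a degeneracy flag.
#'
#' @param groups Named list of numeric vectors (one per group), or a data
#'   frame with columns `group` and `value`.
#' @return An `anova_result` list: `F`, `df_between`, `df_within`,
#'   `p_value`, `msw`, `means`, `ns`, `n_h`, `degenerate`.
#' @export
oneway_anova <- function(groups) {
  samples <- as_group_samples(groups)
  k <- length(samples)
  if (k < 2) stop("need at least 2 groups", call. = FALSE)
  ns <- vapply(samples, length, 0L)
  N <- sum(ns)
  if (N <= k) stop("need total N > number of groups", call. = FALSE)
  df <- data.frame(
    group = factor(rep(names(samples), ns), levels = names(samples)),
    value = unlist(samples, use.names = FALSE))
  # perfect fits warn in anova.lm; degeneracy is detected and handled below
  tab <- suppressWarnings(anova(lm(value ~ group, data = df)))
  msw <- tab$`Mean Sq`[2]
  means <- vapply(samples, mean, 0)
  # guard against ~1e-30 round-off in the sums of squares
  degenerate <- msw <= 100 * .Machine$double.eps * max(1, var(df$value))
  means_differ <- diff(range(means)) >
    sqrt(.Machine$double.eps) * max(1, max(abs(means)))
  if (degenerate && means_differ) {
    Fv <- Inf; pv <- 0
  } else if (degenerate) {
    Fv <- 0; pv <- 1
  } else {
    Fv <- tab$`F value`[1]; pv <- tab$`Pr(>F)`[1]
  }
  structure(list(
    F = Fv, df_between = tab$Df[1], df_within = tab$Df[2],
    p_value = pv, msw = msw, means = means, ns = ns,
    n_h = k / sum(1 / ns), degenerate = degenerate
  ), class = "anova_result")
}

#' @export
print.anova_result <- function(x, ...) {
  cat(sprintf("One-way ANOVA: F(%d, %d) = %.4f, p = %.4g\n",
              x$df_between, x$df_within, x$F, x$p_value))
  invisible(x)
}

#' Duncan critical range quantile
#'
#' The "significant studentized range" entering Duncan's least significant
#' range for a span of p ordered means: the studentized-range quantile at
#' Duncan's protection level alpha_p = 1 - (1-alpha)^(p-1), i.e.
#' `qtukey((1-alpha)^(p-1), p, df)`. For p = 2 this reduces to
#' sqrt(2) * t(alpha/2, df), so Duncan's two-mean decision coincides with
#' Fisher's LSD.
#'
#' @param p Span (number of ordered means covered), >= 2.
#' @param df Within-group (error) degrees of freedom.
#' @param alpha Base significance level.
#' @return The critical range quantile (vectorised over `p`).
#' @export
duncan_q <- function(p, df, alpha = 0.05) {
  qtukey((1 - alpha)^(p - 1), nmeans = p, df = df)
}

#' Duncan's multiple range test with compact letters
#'
#' Sorts group means in decreasing order and compares each pair (i, j)
#' spanning p ordered means against the least significant range
#' LSR_p = q_p * sqrt(MSW / n_h), with q_p from [duncan_q()] and n_h the
#' harmonic mean group size (Kramer-style adjustment for unbalance; equal to
#' the common n for balanced designs). A pair differs when its mean
#' difference exceeds LSR_p and no wider non-significant span contains it
#' (the containment rule of range tests). Letters are assigned by
#' insert-and-absorb so that two groups share a letter iff they are not
#' declared different.
#'
#' Letters are reported regardless of the omnibus F outcome; the result
#' records whether F was significant at `alpha`.
#'
#' @param groups Named list of numeric vectors, or data frame with `group`
#'   and `value` columns.
#' @param alpha Significance level (default 0.05).
#' @param anova Optional precomputed [oneway_anova()] result on the same
#'   groups.
#' @return A `letter_display` list: `display` (data frame `group`, `mean`,
#'   `sd`, `n`, `letters`, in decreasing mean order), `different` (logical
#'   group x group matrix), `lsr` (least significant ranges by span),
#'   `anova`, `alpha`, `omnibus_significant`.
#' @export
duncan_mrt <- function(groups, alpha = 0.05, anova = NULL) {
  samples <- as_group_samples(groups)
  if (is.null(anova)) anova <- oneway_anova(samples)
  stopifnot(inherits(anova, "anova_result"))
  if (anova$df_within < 1) stop("within-group df must be >= 1", call. = FALSE)
  k <- length(samples)
  means <- vapply(samples, mean, 0)
  # decreasing means; ties broken by label order for determinism
  ord <- order(-means, names(samples))
  m <- means[ord]
  lsr <- c(NA_real_,
           duncan_q(2:k, anova$df_within, alpha) * sqrt(anova$msw / anova$n_h))
  if (anova$degenerate && anova$msw == 0) lsr[-1] <- 0
  # raw span decisions, then containment: a pair is non-significant if any
  # window enclosing it has range <= its LSR
  nonsig_raw <- matrix(FALSE, k, k)
  for (i in seq_len(k - 1)) {
    for (j in (i + 1):k) {
      span <- j - i + 1
      nonsig_raw[i, j] <- (m[i] - m[j]) <= lsr[span]
    }
  }
  different <- matrix(FALSE, k, k, dimnames = list(names(m), names(m)))
  for (i in seq_len(k - 1)) {
    for (j in (i + 1):k) {
      covered <- FALSE
      for (a in seq_len(i)) {
        for (b in j:k) {
          if (nonsig_raw[a, b]) { covered <- TRUE; break }
        }
        if (covered) break
      }
      different[i, j] <- different[j, i] <- !covered
    }
  }
  letters <- letters_from_pairs(different, m)
  sds <- vapply(samples, function(v) if (length(v) >= 2) sd(v) else NA_real_, 0)
  display <- data.frame(
    group = names(m), mean = unname(m),
    sd = unname(sds[ord]), n = unname(anova$ns[ord]),
    letters = letters$display$letters,
    stringsAsFactors = FALSE)
  structure(list(
    display = display, different = different,
    lsr = data.frame(span = 2:k, lsr = lsr[-1]),
    anova = anova, alpha = alpha,
    omnibus_significant = is.finite(anova$p_value) && anova$p_value < alpha
  ), class = "letter_display")
}

#' @export
print.letter_display <- function(x, ...) {
  print.data.frame(x$display, ...)
  cat(sprintf("alpha = %g; omnibus F p = %.4g (%ssignificant)\n",
              x$alpha, x$anova$p_value,
              if (x$omnibus_significant) "" else "not "))
  invisible(x)
}

#' Compact letter display from a pairwise significance matrix
#'
#' Builds a minimal letter annotation by the insert-and-absorb algorithm:
#' starting from a single letter covering all groups, each significantly
#' different pair splits every letter column containing both members, and
#' columns that become subsets of another are absorbed. The resulting
#' display satisfies: two groups share at least one letter iff their pair is
#' NOT significantly different. Groups are lettered in the order given
#' (conventionally decreasing mean), making the output deterministic.
#'
#' @param different Symmetric logical matrix; `TRUE` marks a significantly
#'   different pair. Row/column names label the groups.
#' @param means Optional numeric vector (same order) recorded in the output.
#' @return A list with `display` (data frame `group`, `letters`) and
#'   `columns` (the logical membership matrix behind the letters).
#' @export
letters_from_pairs <- function(different, means = NULL) {
  different <- as.matrix(different)
  k <- nrow(different)
  if (k != ncol(different) || !isTRUE(all(different == t(different)))) {
    stop("significance matrix must be square and symmetric", call. = FALSE)
  }
  diag(different) <- FALSE
  labels <- rownames(different)
  if (is.null(labels)) labels <- paste0("g", seq_len(k))
  cols <- list(rep(TRUE, k))
  # drop any column that is a subset of another (keeping the earlier of equals)
  absorb <- function(cols) {
    keep <- rep(TRUE, length(cols))
    for (j in seq_along(cols)) {
      for (i in seq_along(cols)) {
        if (i == j || !keep[i]) next
        j_subset_i <- all(!cols[[j]] | cols[[i]])
        if (j_subset_i && (!identical(cols[[i]], cols[[j]]) || i < j)) {
          keep[j] <- FALSE
          break
        }
      }
    }
    cols[keep]
  }
  for (i in seq_len(k - 1)) {
    for (j in (i + 1):k) {
      if (!different[i, j]) next
      new_cols <- list()
      for (col in cols) {
        if (col[i] && col[j]) {
          c1 <- col; c1[j] <- FALSE
          c2 <- col; c2[i] <- FALSE
          new_cols <- c(new_cols, list(c1, c2))
        } else {
          new_cols <- c(new_cols, list(col))
        }
      }
      cols <- absorb(new_cols)
    }
  }
  # order columns by their first member for stable lettering
  first <- vapply(cols, function(c) which(c)[1], 0L)
  cols <- cols[order(first)]
  mat <- do.call(cbind, cols)
  letter_strings <- apply(mat, 1, function(row) {
    paste(letters[which(row)], collapse = "")
  })
  display <- data.frame(group = labels, letters = letter_strings,
                        stringsAsFactors = FALSE)
  if (!is.null(means)) display$mean <- unname(means)
  rownames(mat) <- labels
  colnames(mat) <- letters[seq_len(ncol(mat))]
  list(display = display, columns = mat)
}
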