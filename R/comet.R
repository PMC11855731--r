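# Alkaline comet assay: arbitrary-units scoring of visually classified
# nucleoids. Each scored nucleoid falls in a damage class c = 0 (intact) to
# 4 (maximal tail); a slide is a 5-vector of class counts.

#' Arbitrary-units DNA-damage score of one slide
#'
#' a.u. = \[sum(N_c * c) * 100\] / N_tot for class counts N_c, c = 0..4.
#' The score ranges from 0 (all nucleoids intact, class 0) to 400 (all in
#' class 4).
#'
#' @param counts Non-negative integer vector of length 5: nucleoid counts in
#'   classes 0, 1, 2, 3, 4.
#' @param n_tot Total nucleoids scored on the slide (nominally 100). Defaults
#'   to `sum(counts)`; if supplied it must equal that sum.
#' @return The a.u. score, a number in \[0, 400\].
#' @export
slide_au <- function(counts, n_tot = sum(counts)) {
  if (length(counts) != 5 || any(is.na(counts)) || any(counts < 0)) {
    stop("counts must be 5 non-negative class counts (classes 0..4)",
         call. = FALSE)
  }
  if (sum(counts) != n_tot) {
    stop(sprintf("class counts sum to %d but n_tot = %d",
                 sum(counts), n_tot), call. = FALSE)
  }
  if (n_tot < 1) stop("at least one nucleoid must be scored", call. = FALSE)
  sum(counts * 0:4) * 100 / n_tot
}

#' Aggregate a.u. over slides
#'
#' Two aggregation modes: `per_slide_mean` scores each slide separately and
#' returns the arithmetic mean +/- sample SD of the slide scores; `pooled`
#' sums the class counts over slides and scores the pooled counts once. For
#' equal numbers of nucleoids per slide the two means coincide.
#'
#' @param slides Matrix (slides x 5 classes) or list of 5-vectors of class
#'   counts.
#' @param mode `"per_slide_mean"` (default) or `"pooled"`.
#' @return List with `au` (the aggregate score), `sd` (per-slide SD, `NA`
#'   under `pooled` or with a single slide) and `n` (number of slides).
#' @export
aggregate_au <- function(slides, mode = c("per_slide_mean", "pooled")) {
  mode <- match.arg(mode)
  if (is.list(slides)) slides <- do.call(rbind, slides)
  slides <- as.matrix(slides)
  if (!nrow(slides)) stop("no slides supplied", call. = FALSE)
  if (ncol(slides) != 5) stop("slides must have 5 class-count columns", call. = FALSE)
  if (mode == "pooled") {
    list(au = slide_au(colSums(slides)), sd = NA_real_, n = nrow(slides))
  } else {
    per <- apply(slides, 1, slide_au)
    list(au = mean(per),
         sd = if (length(per) >= 2) sd(per) else NA_real_,
         n = length(per))
  }
}

#' Replicate-level comet scores from a comet table
#'
#' Scores every slide of a comet `study_table` and aggregates to one a.u.
#' value per replicate (the unit entering ANOVA), by default the mean over
#' that replicate's slides.
#'
#' @param table A comet `study_table` (see [load_table()]).
#' @param mode Aggregation over slides within a replicate, as in
#'   [aggregate_au()].
#' @return Data frame with columns `accession`, `priming`, `stress`,
#'   `replicate`, `au`, `n_slides`.
#' @export
comet_scores <- function(table, mode = c("per_slide_mean", "pooled")) {
  mode <- match.arg(mode)
  df <- as.data.frame(table)
  class_cols <- paste0("class_", 0:4)
  key <- interaction(df$accession, df$priming, df$stress, df$replicate,
                     drop = TRUE, lex.order = TRUE)
  pieces <- lapply(split(df, key), function(sub) {
    agg <- aggregate_au(as.matrix(sub[class_cols]), mode)
    data.frame(
      accession = sub$accession[1], priming = sub$priming[1],
      stress = sub$stress[1], replicate = sub$replicate[1],
      au = agg$au, n_slides = agg$n, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, pieces)
  rownames(out) <- NULL
  out
}

#' Group contrast of DNA-damage scores
#'
#' Per accession, compares the replicate-level a.u. scores of the treatment
#' groups by one-way ANOVA followed by Duncan's multiple range test, and
#' annotates group means with compact letters (groups sharing no letter
#' differ at the given alpha).
#'
#' @param scores Replicate-level scores from [comet_scores()].
#' @param alpha Significance level for Duncan's test (default 0.05).
#' @return Data frame with columns `accession`, `group`, `mean_au`, `sd_au`,
#'   `n`, `letters`, `p_omnibus`.
#' @export
damage_contrast <- function(scores, alpha = 0.05) {
  pieces <- lapply(split(scores, scores$accession), function(sub) {
    grp <- group_label(sub$priming, sub$stress)
    samples <- split(sub$au, grp)
    disp <- duncan_mrt(samples, alpha = alpha)
    data.frame(accession = sub$accession[1],
               disp$display,
               p_omnibus = disp$anova$p_value,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, pieces)
  rownames(out) <- NULL
  names(out)[names(out) == "mean"] <- "mean_au"
  names(out)[names(out) == "sd"] <- "sd_au"
  out
}
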