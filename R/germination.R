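# Germination kinetics indices and seedling phenotyping.
#
# A seed is scored germinated at the first inspection where its radicle
# protrudes > 1 mm; the schedule records, per replicate tray, the number of
# seeds NEWLY germinated at each inspection time.

#' Germinability (G)
#'
#' Percentage of seeds germinated by the end of the test:
#' G = 100 * sum(n_i) / total_seeds, where n_i is the count of seeds newly
#' germinated at inspection time t_i.
#'
#' @param counts Integer vector of newly-germinated counts per inspection.
#' @param total_seeds Number of seeds sown in the replicate (> 0).
#' @return G in percent, in \[0, 100\].
#' @export
germinability <- function(counts, total_seeds) {
  if (length(total_seeds) != 1 || is.na(total_seeds) || total_seeds <= 0) {
    stop("total_seeds must be a single positive number", call. = FALSE)
  }
  if (any(is.na(counts)) || any(counts < 0)) {
    stop("counts must be non-negative", call. = FALSE)
  }
  tot <- sum(counts)
  if (tot > total_seeds) {
    stop("germinated count exceeds total_seeds", call. = FALSE)
  }
  100 * tot / total_seeds
}

#' Mean germination time (MGT)
#'
#' Germination-count-weighted mean of inspection times,
#' MGT = sum(n_i * t_i) / sum(n_i), in the units of `times` (hours
#' throughout this package). Undefined when no seed germinated, in which
#' case `NA` is returned with a warning; such replicates are excluded from
#' group summaries rather than imputed.
#'
#' @param counts Integer vector of newly-germinated counts per inspection.
#' @param times Inspection times (hours since sowing), strictly increasing,
#'   same length as `counts`.
#' @return MGT in hours, or `NA` if no seed germinated.
#' @export
mean_germination_time <- function(counts, times) {
  if (length(counts) != length(times)) {
    stop("counts and times must have equal length", call. = FALSE)
  }
  if (any(is.na(counts)) || any(counts < 0)) {
    stop("counts must be non-negative", call. = FALSE)
  }
  if (is.unsorted(times, strictly = FALSE)) {
    stop("times must be non-decreasing", call. = FALSE)
  }
  tot <- sum(counts)
  if (tot == 0) {
    warning("no germinated seeds: MGT undefined", call. = FALSE)
    return(NA_real_)
  }
  sum(counts * times) / tot
}

#' Per-replicate germination indices from a schedule table
#'
#' Computes G and MGT for every accession x priming x stress x replicate
#' combination of a germination `study_table`.
#'
#' @param table A germination `study_table` (see [load_table()]).
#' @return Data frame with columns `accession`, `priming`, `stress`,
#'   `replicate`, `total_seeds`, `G`, `MGT`. `MGT` is `NA` for replicates
#'   with zero germination.
#' @export
germination_indices <- function(table) {
  df <- as.data.frame(table)
  key <- interaction(df$accession, df$priming, df$stress, df$replicate,
                     drop = TRUE, lex.order = TRUE)
  pieces <- lapply(split(df, key), function(sub) {
    tot <- unique(sub$total_seeds)
    if (length(tot) != 1) {
      stop("total_seeds must be constant within a replicate", call. = FALSE)
    }
    sub <- sub[order(sub$time_h), ]
    data.frame(
      accession = sub$accession[1], priming = sub$priming[1],
      stress = sub$stress[1], replicate = sub$replicate[1],
      total_seeds = tot,
      G = germinability(sub$n_new_germinated, tot),
      MGT = suppressWarnings(
        mean_germination_time(sub$n_new_germinated, sub$time_h)),
      stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, pieces)
  rownames(out) <- NULL
  if (any(is.na(out$MGT))) {
    warning(sprintf("%d replicate(s) with zero germination: MGT undefined, excluded from summaries",
                    sum(is.na(out$MGT))), call. = FALSE)
  }
  out
}

#' Group summaries of germination indices
#'
#' Mean +/- sample SD of G and MGT over replicate trays, per accession x
#' priming x stress group. Replicates with undefined MGT are excluded from
#' the MGT summary (their count appears in `n_missing`).
#'
#' @param indices Output of [germination_indices()].
#' @return Long data frame with columns `accession`, `priming`, `stress`,
#'   `metric` (G or MGT), `mean`, `sd`, `n`, `n_missing`.
#' @export
summarize_germination <- function(indices) {
  by <- c("accession", "priming", "stress")
  g <- summarize_groups(indices, "G", by)
  g$metric <- "G"
  m <- summarize_groups(indices, "MGT", by)
  m$metric <- "MGT"
  out <- rbind(g, m)
  out[c(by, "metric", "mean", "sd", "n", "n_missing")]
}

#' Seedling phenotype frequencies
#'
#' Per-replicate percentage of seedlings classified normal, aberrant or
#' non-germinating; the three percentages sum to 100 within each replicate.
#'
#' @param table A biometry `study_table` with one row per seed.
#' @return Data frame with columns `accession`, `priming`, `stress`,
#'   `replicate`, `category`, `percent`.
#' @export
phenotype_frequencies <- function(table) {
  df <- as.data.frame(table)
  cats <- c("normal", "aberrant", "non_germinating")
  key <- interaction(df$accession, df$priming, df$stress, df$replicate,
                     drop = TRUE, lex.order = TRUE)
  pieces <- lapply(split(df, key), function(sub) {
    counts <- table(factor(sub$category, levels = cats))
    data.frame(
      accession = sub$accession[1], priming = sub$priming[1],
      stress = sub$stress[1], replicate = sub$replicate[1],
      category = cats,
      percent = 100 * as.numeric(counts) / nrow(sub),
      stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, pieces)
  rownames(out) <- NULL
  out
}

#' Group summaries of phenotype frequencies
#'
#' @param freqs Output of [phenotype_frequencies()].
#' @return Mean +/- SD percent per accession x priming x stress x category.
#' @export
summarize_phenotypes <- function(freqs) {
  summarize_groups(freqs, "percent",
                   c("accession", "priming", "stress", "category"))
}

#' Shoot and root length summaries
#'
#' Mean +/- sample SD of shoot and root length per accession x priming x
#' stress group, over seedlings with measurable growth (categories normal
#' and aberrant; non-germinating seeds carry no lengths and are excluded).
#'
#' @param table A biometry `study_table`.
#' @param unit_of_analysis `"seedling"` pools all measured seedlings in a
#'   group; `"replicate"` first averages within each replicate tray and
#'   summarises the replicate means (the tray being the statistical unit
#'   used for inference).
#' @return Long data frame with columns `accession`, `priming`, `stress`,
#'   `organ` (shoot/root), `mean`, `sd`, `n`, `n_missing`. `sd` is `NA`
#'   (flagged undefined) when a single measurement remains.
#' @export
biometry_summary <- function(table,
                             unit_of_analysis = c("seedling", "replicate")) {
  unit_of_analysis <- match.arg(unit_of_analysis)
  df <- as.data.frame(table)
  if (any(df$shoot_len_cm < 0 | df$root_len_cm < 0, na.rm = TRUE)) {
    stop("negative length", call. = FALSE)
  }
  df <- df[df$category %in% c("normal", "aberrant"), , drop = FALSE]
  long <- rbind(
    data.frame(df[c("accession", "priming", "stress", "replicate")],
               organ = "shoot", length = df$shoot_len_cm),
    data.frame(df[c("accession", "priming", "stress", "replicate")],
               organ = "root", length = df$root_len_cm))
  if (unit_of_analysis == "replicate") {
    long <- summarize_groups(
      long, "length",
      c("accession", "priming", "stress", "organ", "replicate"))
    names(long)[names(long) == "mean"] <- "length"
  }
  summarize_groups(long, "length",
                   c("accession", "priming", "stress", "organ"))
}

#' Per-replicate mean shoot and root lengths
#'
#' Replicate-tray means of shoot and root length (normal and aberrant
#' seedlings), the unit entering ANOVA/Duncan and the PCA feature matrix.
#'
#' @param table A biometry `study_table`.
#' @return Data frame with columns `accession`, `priming`, `stress`,
#'   `replicate`, `shoot_len_cm`, `root_len_cm`.
#' @export
biometry_replicates <- function(table) {
  df <- as.data.frame(table)
  df <- df[df$category %in% c("normal", "aberrant"), , drop = FALSE]
  by <- c("accession", "priming", "stress", "replicate")
  sh <- summarize_groups(df, "shoot_len_cm", by)
  rt <- summarize_groups(df, "root_len_cm", by)
  out <- sh[by]
  out$shoot_len_cm <- sh$mean
  out$root_len_cm <- rt$mean
  out
}
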