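# Pipeline driver: chains simulation / loading of the four input tables
# through the analysis stages and writes per-stage CSV outputs plus a run
# log. Outputs are deterministic: identical config + seed give
# byte-identical numeric CSVs.

pipeline_stages <- function() {
  c("simulate", "germination", "comet", "qpcr", "stats", "pca")
}

read_config <- function(config) {
  if (is.character(config)) {
    if (!file.exists(config)) {
      stop(sprintf("config file not found: %s", config), call. = FALSE)
    }
    config <- yaml::read_yaml(config)
  }
  stopifnot(is.list(config))
  config
}

need_table <- function(tables, name, stage) {
  if (is.null(tables[[name]])) {
    stop(sprintf("dependency error: stage '%s' needs the %s table; add 'simulate' to the stages or an inputs$%s path",
                 stage, name, name), call. = FALSE)
  }
  tables[[name]]
}

write_out <- function(df, out_dir, name) {
  write.csv(df, file.path(out_dir, name), row.names = FALSE, quote = FALSE)
}

#' Run the analysis pipeline
#'
#' Executes the requested stages in order. `simulate` generates the four
#' input tables from `config$simulation` (a [default_config()]-shaped
#' list); without it, tables are read from the CSV paths in
#' `config$inputs`. Analysis stages: `germination` (G/MGT indices,
#' phenotype frequencies, biometry), `comet` (replicate a.u. scores),
#' `qpcr` (geNorm stability, relative expression, per-gene Z-scores),
#' `stats` (Duncan letter displays of G, MGT, shoot/root length and a.u.
#' per accession), `pca` (Z-score PCA of the combined feature matrix per
#' accession). Each stage writes CSV files to `out_dir`; a
#' `run_log.yaml` records the seed, derived stage seeds, stages and
#' package version. A stage whose required tables are neither simulated
#' nor supplied raises a dependency error.
#'
#' @param config Path to a YAML config file, or an equivalent list. Keys:
#'   `seed`, `stages`, `simulation`, `inputs` (paths keyed by schema name).
#' @param out_dir Output directory (created if absent).
#' @param seed Master seed; overrides `config$seed`. All stage randomness
#'   derives from it.
#' @param stages Character vector of stages (subset of
#'   `c("simulate", "germination", "comet", "qpcr", "stats", "pca")`), or
#'   `"all"`/`"run"`; overrides `config$stages`.
#' @return Invisibly, a list with the input `tables` and per-stage results.
#' @export
run_pipeline <- function(config, out_dir, seed = NULL, stages = NULL) {
  cfg <- read_config(config)
  if (is.null(seed)) seed <- cfg$seed %||% 1L
  seed <- as.integer(seed)
  stages <- stages %||% cfg$stages %||% "all"
  if (any(stages %in% c("all", "run"))) stages <- pipeline_stages()
  bad <- setdiff(stages, pipeline_stages())
  if (length(bad)) {
    stop(sprintf("unknown stage(s): %s", paste(bad, collapse = ", ")),
         call. = FALSE)
  }
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

  tables <- list()
  if ("simulate" %in% stages) {
    sim_cfg <- cfg$simulation %||% default_config()
    tables <- simulate_study(sim_cfg, seed)
    for (name in names(tables)) {
      write_table(tables[[name]], file.path(out_dir, paste0(name, ".csv")))
    }
  } else if (!is.null(cfg$inputs)) {
    for (name in intersect(names(cfg$inputs), schema_names())) {
      tables[[name]] <- load_table(cfg$inputs[[name]], name)
    }
  }

  results <- list(tables = tables)

  if ("germination" %in% stages) {
    germ <- need_table(tables, "germination", "germination")
    idx <- suppressWarnings(germination_indices(germ))
    results$germination <- idx
    write_out(idx, out_dir, "germination_indices.csv")
    write_out(summarize_germination(idx), out_dir, "germination_summary.csv")
    if (!is.null(tables$biometry)) {
      freqs <- phenotype_frequencies(tables$biometry)
      results$phenotypes <- freqs
      write_out(summarize_phenotypes(freqs), out_dir, "phenotype_summary.csv")
      bio <- biometry_replicates(tables$biometry)
      results$biometry <- bio
      write_out(bio, out_dir, "biometry_replicates.csv")
      write_out(biometry_summary(tables$biometry), out_dir,
                "biometry_summary.csv")
    }
  }

  if ("comet" %in% stages) {
    com <- need_table(tables, "comet", "comet")
    sc <- comet_scores(com)
    results$comet <- sc
    write_out(sc, out_dir, "comet_replicate_au.csv")
    write_out(summarize_groups(sc, "au", c("accession", "priming", "stress")),
              out_dir, "comet_summary.csv")
  }

  if ("qpcr" %in% stages) {
    ct <- need_table(tables, "ct", "qpcr")
    E <- cfg$simulation$qpcr$efficiency %||% 1.8
    cand <- cfg$simulation$qpcr$candidate_genes
    per_acc <- lapply(unique(ct$accession), function(acc) {
      res <- expression_analysis(ct, accession = acc, efficiency = E,
                                 candidates = cand)
      list(accession = acc, res = res)
    })
    results$qpcr <- per_acc
    long <- function(m, value) {
      data.frame(gene = rep(rownames(m), ncol(m)),
                 group = rep(colnames(m), each = nrow(m)),
                 value = as.vector(m), stringsAsFactors = FALSE,
                 check.names = FALSE) |> setNames(c("gene", "group", value))
    }
    stab <- do.call(rbind, lapply(per_acc, function(p) {
      cbind(accession = p$accession, as.data.frame(p$res$stability))
    }))
    write_out(stab, out_dir, "expression_stability.csv")
    expr <- do.call(rbind, lapply(per_acc, function(p) {
      q <- long(p$res$q, "q")
      nr <- long(p$res$n_rel, "n_rel")
      cbind(accession = p$accession,
            merge(q, nr, by = c("gene", "group"), all.x = TRUE))
    }))
    write_out(expr, out_dir, "expression.csv")
    heat <- do.call(rbind, lapply(per_acc, function(p) {
      cbind(accession = p$accession, long(p$res$zscores, "zscore"))
    }))
    write_out(heat, out_dir, "expression_heatmap.csv")
  }

  if ("stats" %in% stages) {
    germ_idx <- results$germination %||%
      suppressWarnings(germination_indices(
        need_table(tables, "germination", "stats")))
    bio <- results$biometry %||%
      biometry_replicates(need_table(tables, "biometry", "stats"))
    com <- results$comet %||% comet_scores(need_table(tables, "comet", "stats"))
    metrics <- list(
      G = germ_idx[c("accession", "priming", "stress", "replicate")] |>
        cbind(value = germ_idx$G),
      MGT = germ_idx[c("accession", "priming", "stress", "replicate")] |>
        cbind(value = germ_idx$MGT),
      shoot_len = bio[c("accession", "priming", "stress", "replicate")] |>
        cbind(value = bio$shoot_len_cm),
      root_len = bio[c("accession", "priming", "stress", "replicate")] |>
        cbind(value = bio$root_len_cm),
      au = com[c("accession", "priming", "stress", "replicate")] |>
        cbind(value = com$au))
    letter_rows <- list()
    for (metric in names(metrics)) {
      df <- metrics[[metric]]
      df <- df[!is.na(df$value), , drop = FALSE]
      for (acc in unique(df$accession)) {
        sub <- df[df$accession == acc, , drop = FALSE]
        samples <- split(sub$value, group_label(sub$priming, sub$stress))
        if (length(samples) < 2 || any(lengths(samples) < 2)) next
        disp <- duncan_mrt(samples)
        letter_rows[[length(letter_rows) + 1L]] <- cbind(
          accession = acc, metric = metric, disp$display,
          p_omnibus = disp$anova$p_value)
      }
    }
    stats_out <- do.call(rbind, letter_rows)
    results$stats <- stats_out
    write_out(stats_out, out_dir, "stats_letters.csv")
  }

  if ("pca" %in% stages) {
    germ_idx <- results$germination %||%
      suppressWarnings(germination_indices(
        need_table(tables, "germination", "pca")))
    bio <- results$biometry %||%
      biometry_replicates(need_table(tables, "biometry", "pca"))
    com <- results$comet %||% comet_scores(need_table(tables, "comet", "pca"))
    ct <- need_table(tables, "ct", "pca")
    E <- cfg$simulation$qpcr$efficiency %||% 1.8
    pca_rows <- function(m, kind) {
      data.frame(label = rownames(m), kind = kind,
                 PC1 = m[, 1], PC2 = m[, 2], stringsAsFactors = FALSE)
    }
    pieces <- lapply(unique(germ_idx$accession), function(acc) {
      pick <- function(df) df[df$accession == acc, , drop = FALSE]
      expr <- expression_analysis(
        ct, accession = acc, efficiency = E,
        candidates = cfg$simulation$qpcr$candidate_genes)$n_rel
      fm <- build_feature_matrix(pick(germ_idx), pick(bio), pick(com), expr)
      fit <- pca(zscore_columns(fm))
      list(accession = acc, fit = fit,
           scores = cbind(accession = acc, pca_rows(fit$scores, "score")),
           loadings = cbind(accession = acc, pca_rows(fit$loadings, "loading")),
           variance = data.frame(
             accession = acc,
             component = seq_along(fit$explained_variance_all),
             explained_pct = fit$explained_variance_all))
    })
    results$pca <- pieces
    write_out(do.call(rbind, lapply(pieces, `[[`, "scores")),
              out_dir, "pca_scores.csv")
    write_out(do.call(rbind, lapply(pieces, `[[`, "loadings")),
              out_dir, "pca_loadings.csv")
    write_out(do.call(rbind, lapply(pieces, `[[`, "variance")),
              out_dir, "pca_variance.csv")
  }

  log <- list(
    seed = seed,
    stage_seeds = as.list(setNames(seed + 1:4,
                                   c("germination", "biometry", "comet", "ct"))),
    stages = stages,
    package = "seedstress",
    version = as.character(packageVersion("seedstress"))
  )
  yaml::write_yaml(log, file.path(out_dir, "run_log.yaml"))
  invisible(results)
}
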