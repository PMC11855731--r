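# Synthetic-data generator emulating the factorial priming x heat-wave
# design: per-seed Bernoulli germination with log-normal timing discretized
# to an inspection schedule, multinomial comet class counts with a single
# damage parameter theta (E[a.u.] = 400 * theta), Gaussian technical noise
# on Ct with planted log2 fold-changes, and truncated-normal biometry.

group_param <- function(block, group, what) {
  if (is.list(block)) {
    if (!group %in% names(block)) {
      stop(sprintf("%s: no value for group '%s'", what, group), call. = FALSE)
    }
    as.numeric(block[[group]])
  } else {
    as.numeric(block)
  }
}

#' Packaged default simulation configuration
#'
#' The default study conditions of the generator: two accessions, four
#' treatment groups (UP/HP x NT/HW), 3 replicate trays of 20 seeds,
#' inspections every 12 h over a 7-day (168 h) test, 3 comet slides of 100
#' nucleoids per replicate, and triplicate qPCR reactions over the six
#' expression groups (DS, DB plus the factorial four) with E = 1.8.
#'
#' Effect sizes are set to echo the magnitudes the analysis is designed
#' around: the heat wave lowers germination probability and delays
#' germination times, raises the comet damage parameter theta (expected
#' a.u. 400*theta, in the 115-155 range), and up-regulates DNA-repair
#' targets in unprimed seeds; hydropriming lowers theta and down-regulates
#' the antioxidant/repair panel. The candidate reference panel holds the
#' two true references (exactly zero planted effect) plus one mildly
#' regulated decoy, so geNorm selection has a recoverable ground truth.
#'
#' @return A nested list (YAML-serializable) understood by the
#'   `simulate_*` functions and [run_pipeline()].
#' @export
default_config <- function() {
  zero6 <- as.list(setNames(rep(0, 6), expression_groups()))
  eff <- function(DS, DB, upnt, uphw, hpnt, hphw) {
    as.list(setNames(c(DS, DB, upnt, uphw, hpnt, hphw), expression_groups()))
  }
  list(
    design = list(
      species = "Lathyrus sativus",
      accessions = c("Maleme-107", "Sofades"),
      groups = as.list(treatment_groups()),
      replicates = 3L,
      seeds_per_replicate = 20L,
      schedule_h = as.list(seq(12, 168, by = 12)),
      slides_per_replicate = 3L,
      nucleoids_per_slide = 100L,
      tech_reps = 3L
    ),
    germination = list(
      pi = list(`UP-NT` = 0.92, `UP-HW` = 0.30, `HP-NT` = 0.95, `HP-HW` = 0.38),
      meanlog = list(`UP-NT` = log(44), `UP-HW` = log(64),
                     `HP-NT` = log(36), `HP-HW` = log(56)),
      sdlog = 0.25
    ),
    comet = list(
      theta = list(`UP-NT` = 0.3295, `UP-HW` = 0.3825,
                   `HP-NT` = 0.2860, `HP-HW` = 0.2975)
    ),
    biometry = list(
      shoot_mean = list(`UP-NT` = 5.5, `UP-HW` = 1.8,
                        `HP-NT` = 5.8, `HP-HW` = 2.0),
      root_mean = list(`UP-NT` = 7.0, `UP-HW` = 2.2,
                       `HP-NT` = 8.2, `HP-HW` = 2.5),
      shoot_sd = 0.8,
      root_sd = 1.0,
      aberrant_length_factor = 0.3,
      aberrant_given_germinated = list(`UP-NT` = 0.12, `UP-HW` = 0.45,
                                       `HP-NT` = 0.10, `HP-HW` = 0.40)
    ),
    qpcr = list(
      efficiency = 1.8,
      sd_tech = 0.15,
      reference_genes = c("LsEF2", "LsGAPDH"),
      candidate_genes = c("LsEF2", "LsGAPDH", "LsTUB"),
      baseline = list(LsEF2 = 21, LsGAPDH = 19, LsTUB = 23, LsSODa = 25,
                      LsAPXb = 26, LsMT1 = 24, LsTOP1 = 27, LsPCNA = 26),
      effects = list(
        LsEF2  = zero6,
        LsGAPDH = zero6,
        LsTUB  = eff(0.5, 0.0, 0.9, 1.3, 0.2, 0.4),
        LsSODa = eff(2.0, 0.3, 2.0, 2.1, 0.4, 0.4),
        LsAPXb = eff(0.2, 2.2, 0.8, 1.8, 0.3, 0.3),
        LsMT1  = eff(2.2, 2.0, 0.5, 0.5, 0.3, 0.3),
        LsTOP1 = eff(0.5, 0.4, 1.5, 2.3, 0.6, 0.8),
        LsPCNA = eff(0.4, 0.5, 1.4, 2.0, 0.6, 0.8)
      )
    )
  )
}

#' Validate a simulation configuration
#'
#' Checks the structural invariants: probabilities in \[0, 1\], SDs >= 0,
#' strictly increasing inspection schedule, 1 < E <= 2, and exactly zero
#' planted effects on the declared reference genes.
#'
#' @param cfg A configuration list shaped like [default_config()].
#' @return `cfg`, invisibly; errors on violation.
#' @export
check_config <- function(cfg) {
  sched <- unlist(cfg$design$schedule_h)
  if (any(diff(sched) <= 0)) stop("schedule must be strictly increasing", call. = FALSE)
  probs <- c(unlist(cfg$germination$pi), unlist(cfg$comet$theta),
             unlist(cfg$biometry$aberrant_given_germinated))
  if (any(probs < 0 | probs > 1)) stop("probabilities must be in [0, 1]", call. = FALSE)
  sds <- c(cfg$germination$sdlog, cfg$biometry$shoot_sd,
           cfg$biometry$root_sd, cfg$qpcr$sd_tech)
  if (any(sds < 0)) stop("SDs must be >= 0", call. = FALSE)
  E <- cfg$qpcr$efficiency
  if (E <= 1 || E > 2) stop("efficiency must satisfy 1 < E <= 2", call. = FALSE)
  for (ref in cfg$qpcr$reference_genes) {
    if (any(unlist(cfg$qpcr$effects[[ref]]) != 0)) {
      stop(sprintf("reference gene '%s' must have zero planted effect", ref),
           call. = FALSE)
    }
  }
  cand <- cfg$qpcr$candidate_genes
  if (!is.null(cand)) {
    if (!all(cfg$qpcr$reference_genes %in% cand) ||
        !all(cand %in% names(cfg$qpcr$baseline))) {
      stop("candidate panel must contain the references and only known genes",
           call. = FALSE)
    }
  }
  invisible(cfg)
}

each_cell <- function(cfg) {
  expand.grid(accession = cfg$design$accessions,
              group = unlist(cfg$design$groups),
              replicate = seq_len(cfg$design$replicates),
              stringsAsFactors = FALSE)
}

#' Simulate a germination schedule table
#'
#' Per seed: Bernoulli(pi) germination; germinating seeds draw a log-normal
#' germination time (hours), right-censored at the end of the inspection
#' schedule, and are scored at the first inspection time at or after their
#' true time (as a human scorer would record them).
#'
#' @param cfg Configuration list (see [default_config()]).
#' @param seed Integer random seed.
#' @return A germination `study_table` with one row per replicate x
#'   inspection time.
#' @export
simulate_germination <- function(cfg, seed) {
  check_config(cfg)
  set.seed(seed)
  sched <- unlist(cfg$design$schedule_h)
  n_seeds <- cfg$design$seeds_per_replicate
  cells <- each_cell(cfg)
  rows <- lapply(seq_len(nrow(cells)), function(i) {
    grp <- cells$group[i]
    pi_g <- group_param(cfg$germination$pi, grp, "pi")
    mu <- group_param(cfg$germination$meanlog, grp, "meanlog")
    sdl <- group_param(cfg$germination$sdlog, grp, "sdlog")
    n_germ <- rbinom(1, n_seeds, pi_g)
    times <- rlnorm(n_germ, mu, sdl)
    times <- times[times <= max(sched)]  # censored: never scored germinated
    idx <- vapply(times, function(t) which(sched >= t)[1], 0L)
    counts <- tabulate(idx, nbins = length(sched))
    pr <- split_group(grp)
    data.frame(accession = cells$accession[i],
               priming = pr$priming, stress = pr$stress,
               replicate = cells$replicate[i],
               total_seeds = n_seeds, time_h = sched,
               n_new_germinated = counts, stringsAsFactors = FALSE)
  })
  as_study_table(do.call(rbind, rows), "germination")
}

rnorm_trunc0 <- function(n, mean, sd) {
  if (n == 0) return(numeric())
  x <- rnorm(n, mean, sd)
  while (any(x < 0)) x[x < 0] <- rnorm(sum(x < 0), mean, sd)
  x
}

#' Simulate a seedling biometry table
#'
#' Per seed: category drawn consistently with the germination probability
#' (non-germinating with probability 1 - pi; germinated seeds aberrant with
#' a per-group conditional probability, otherwise normal). Normal seedlings
#' draw truncated-at-0 normal shoot and root lengths; aberrant seedlings
#' draw stunted lengths (configured fraction of the normal means);
#' non-germinating seeds carry no lengths.
#'
#' @inheritParams simulate_germination
#' @return A biometry `study_table` with one row per seed.
#' @export
simulate_biometry <- function(cfg, seed) {
  check_config(cfg)
  set.seed(seed)
  n_seeds <- cfg$design$seeds_per_replicate
  cells <- each_cell(cfg)
  rows <- lapply(seq_len(nrow(cells)), function(i) {
    grp <- cells$group[i]
    pi_g <- group_param(cfg$germination$pi, grp, "pi")
    p_ab <- group_param(cfg$biometry$aberrant_given_germinated, grp,
                        "aberrant_given_germinated")
    germ <- rbinom(n_seeds, 1, pi_g) == 1
    ab <- germ & rbinom(n_seeds, 1, p_ab) == 1
    category <- ifelse(!germ, "non_germinating",
                       ifelse(ab, "aberrant", "normal"))
    sm <- group_param(cfg$biometry$shoot_mean, grp, "shoot_mean")
    rm_ <- group_param(cfg$biometry$root_mean, grp, "root_mean")
    fac <- cfg$biometry$aberrant_length_factor %||% 0.3
    shoot <- root <- rep(NA_real_, n_seeds)
    shoot[category == "normal"] <-
      rnorm_trunc0(sum(category == "normal"), sm, cfg$biometry$shoot_sd)
    root[category == "normal"] <-
      rnorm_trunc0(sum(category == "normal"), rm_, cfg$biometry$root_sd)
    shoot[category == "aberrant"] <-
      rnorm_trunc0(sum(category == "aberrant"), sm * fac, cfg$biometry$shoot_sd)
    root[category == "aberrant"] <-
      rnorm_trunc0(sum(category == "aberrant"), rm_ * fac, cfg$biometry$root_sd)
    pr <- split_group(grp)
    data.frame(accession = cells$accession[i],
               priming = pr$priming, stress = pr$stress,
               replicate = cells$replicate[i],
               seedling_id = seq_len(n_seeds), category = category,
               shoot_len_cm = shoot, root_len_cm = root,
               stringsAsFactors = FALSE)
  })
  as_study_table(do.call(rbind, rows), "biometry")
}

#' Comet damage-class probabilities for a damage parameter
#'
#' Binomial-over-classes model: class probabilities Binomial(4, theta), so
#' the expected a.u. score is exactly 400 * theta.
#'
#' @param theta Damage parameter in \[0, 1\].
#' @return Length-5 probability vector over classes 0..4.
#' @export
comet_class_probs <- function(theta) {
  stats::dbinom(0:4, size = 4, prob = theta)
}

#' Simulate a comet slide table
#'
#' Per slide: class counts ~ Multinomial(nucleoids_per_slide,
#' [comet_class_probs()]) with the per-group damage parameter theta.
#'
#' @inheritParams simulate_germination
#' @return A comet `study_table` with one row per slide.
#' @export
simulate_comet <- function(cfg, seed) {
  check_config(cfg)
  set.seed(seed)
  n_tot <- cfg$design$nucleoids_per_slide
  n_slides <- cfg$design$slides_per_replicate
  cells <- each_cell(cfg)
  rows <- lapply(seq_len(nrow(cells)), function(i) {
    grp <- cells$group[i]
    theta <- group_param(cfg$comet$theta, grp, "theta")
    counts <- t(rmultinom(n_slides, n_tot, comet_class_probs(theta)))
    colnames(counts) <- paste0("class_", 0:4)
    pr <- split_group(grp)
    data.frame(accession = cells$accession[i],
               priming = pr$priming, stress = pr$stress,
               replicate = cells$replicate[i], slide = seq_len(n_slides),
               counts, stringsAsFactors = FALSE)
  })
  as_study_table(do.call(rbind, rows), "comet")
}

#' Simulate a qPCR Ct table
#'
#' Ct = baseline - effect * log(2) / log(E) + Normal(0, sd_tech) per
#' technical replicate, where `effect` is the planted log2 fold-change of
#' the gene in the group relative to its baseline; a 1-unit effect thus
#' yields a downstream quantity ratio of exactly 2 (and a planted effect of
#' log2(E-fold) one cycle). Reference genes carry zero effect everywhere.
#'
#' @inheritParams simulate_germination
#' @return A ct `study_table` with one row per accession x gene x group x
#'   technical replicate.
#' @export
simulate_ct <- function(cfg, seed) {
  check_config(cfg)
  set.seed(seed)
  E <- cfg$qpcr$efficiency
  genes <- names(cfg$qpcr$baseline)
  groups <- expression_groups()
  tech <- seq_len(cfg$design$tech_reps)
  grid <- expand.grid(accession = cfg$design$accessions, gene = genes,
                      group = groups, tech_rep = tech,
                      stringsAsFactors = FALSE)
  effect <- mapply(function(g, grp) {
    as.numeric(cfg$qpcr$effects[[g]][[grp]])
  }, grid$gene, grid$group)
  baseline <- unlist(cfg$qpcr$baseline)[grid$gene]
  grid$ct <- baseline - effect * log(2) / log(E) +
    rnorm(nrow(grid), 0, cfg$qpcr$sd_tech)
  as_study_table(grid, "ct")
}

#' Simulate every input table of a study
#'
#' Runs the four generators with seeds derived deterministically from one
#' master seed (offsets 1..4), so identical configuration + master seed
#' reproduce identical tables.
#'
#' @inheritParams simulate_germination
#' @param seed Master seed.
#' @return Named list of `study_table`s: `germination`, `biometry`,
#'   `comet`, `ct`.
#' @export
simulate_study <- function(cfg, seed) {
  list(
    germination = simulate_germination(cfg, seed + 1L),
    biometry = simulate_biometry(cfg, seed + 2L),
    comet = simulate_comet(cfg, seed + 3L),
    ct = simulate_ct(cfg, seed + 4L)
  )
}
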