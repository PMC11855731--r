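# Fixture builders: all test data is constructed in code.

# Germination table for one accession/group: `counts` is a list with one
# numeric vector per replicate, scored at `times`.
make_germination <- function(counts, times, total_seeds = 20,
                             accession = "Maleme-107",
                             priming = "UP", stress = "HW") {
  rows <- lapply(seq_along(counts), function(r) {
    data.frame(accession = accession, priming = priming, stress = stress,
               replicate = r, total_seeds = total_seeds,
               time_h = times, n_new_germinated = counts[[r]])
  })
  as_study_table(do.call(rbind, rows), "germination")
}

# Comet table: `slides` is a list of 5-vectors per replicate (list of lists).
make_comet <- function(slides_by_rep, accession = "Maleme-107",
                       priming = "UP", stress = "NT") {
  rows <- lapply(seq_along(slides_by_rep), function(r) {
    m <- do.call(rbind, slides_by_rep[[r]])
    colnames(m) <- paste0("class_", 0:4)
    data.frame(accession = accession, priming = priming, stress = stress,
               replicate = r, slide = seq_len(nrow(m)), m)
  })
  as_study_table(do.call(rbind, rows), "comet")
}

# Biometry table from per-seed category/length vectors.
make_biometry <- function(category, shoot = NA_real_, root = NA_real_,
                          accession = "Maleme-107", priming = "UP",
                          stress = "NT", replicate = 1) {
  as_study_table(data.frame(
    accession = accession, priming = priming, stress = stress,
    replicate = replicate, seedling_id = seq_along(category),
    category = category, shoot_len_cm = shoot, root_len_cm = root),
    "biometry")
}

# Random symmetric significance matrix for k groups.
random_sig_matrix <- function(k) {
  m <- matrix(FALSE, k, k, dimnames = list(paste0("g", 1:k), paste0("g", 1:k)))
  for (i in seq_len(k - 1)) {
    for (j in (i + 1):k) m[i, j] <- m[j, i] <- runif(1) < 0.5
  }
  m
}

# Scaled-down simulation config: one accession, fewer genes.
small_config <- function() {
  cfg <- default_config()
  cfg$design$accessions <- "Maleme-107"
  keep <- c("LsEF2", "LsGAPDH", "LsTUB", "LsSODa", "LsTOP1")
  cfg$qpcr$baseline <- cfg$qpcr$baseline[keep]
  cfg$qpcr$effects <- cfg$qpcr$effects[keep]
  cfg
}

expect_tables_equal <- function(a, b) {
  expect_equal(as.data.frame(a), as.data.frame(b), ignore_attr = TRUE)
}
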