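test_that("simulation is deterministic given config and seed", {
  cfg <- small_config()
  t1 <- simulate_study(cfg, 9)
  t2 <- simulate_study(cfg, 9)
  for (name in names(t1)) expect_identical(t1[[name]], t2[[name]])
  t3 <- simulate_study(cfg, 10)
  expect_false(identical(t1$germination, t3$germination))
})

test_that("generated tables pass validation against their own design", {
  cfg <- small_config()
  tabs <- simulate_study(cfg, 21)
  design <- study_design(cfg$design$accessions,
                         replicates = cfg$design$replicates,
                         seeds_per_replicate = cfg$design$seeds_per_replicate)
  for (name in c("germination", "biometry", "comet")) {
    expect_identical(nrow(validate_design(tabs[[name]], design)), 0L)
  }
  ct_design <- study_design(cfg$design$accessions, groups = expression_groups())
  expect_identical(nrow(validate_design(tabs$ct, ct_design)), 0L)
})

test_that("degenerate germination settings behave as configured", {
  cfg <- small_config()
  cfg$germination$pi <- 1
  cfg$germination$sdlog <- 0
  cfg$germination$meanlog <- log(47)
  tab <- simulate_germination(cfg, 4)
  idx <- germination_indices(tab)
  expect_true(all(idx$G == 100))
  # every seed germinates at 47 h, scored at the first inspection after it
  expect_true(all(idx$MGT == 48))

  cfg$germination$pi <- 0
  tab0 <- simulate_germination(cfg, 4)
  expect_true(all(tab0$n_new_germinated == 0))
  expect_warning(idx0 <- germination_indices(tab0), "zero germination")
  expect_true(all(is.na(idx0$MGT)))
})

test_that("large-sample germination matches the closed-form discretized law", {
  cfg <- small_config()
  cfg$design$accessions <- "A"
  cfg$design$replicates <- 1L
  cfg$design$seeds_per_replicate <- 1000L
  pi_g <- 0.7; mu <- log(50); sdl <- 0.3
  cfg$germination$pi <- pi_g
  cfg$germination$meanlog <- mu
  cfg$germination$sdlog <- sdl
  tab <- simulate_germination(cfg, 31)
  idx <- germination_indices(tab)
  sched <- unlist(cfg$design$schedule_h)
  # censoring at the last inspection slightly lowers realised G
  p_obs <- pi_g * plnorm(max(sched), mu, sdl)
  se_g <- 100 * sqrt(p_obs * (1 - p_obs) / 1000)
  expect_true(all(abs(idx$G - 100 * p_obs) < 3 * se_g))
  # discretized log-normal mean as the MGT oracle
  cell_p <- diff(plnorm(c(0, sched), mu, sdl))
  mgt_expected <- sum(sched * cell_p) / sum(cell_p)
  cell_m <- sum(sched^2 * cell_p) / sum(cell_p)
  se_mgt <- sqrt((cell_m - mgt_expected^2) / (1000 * p_obs))
  expect_true(all(abs(idx$MGT - mgt_expected) < 3 * se_mgt))
})

test_that("comet simulation hits the 400*theta expectation", {
  cfg <- small_config()
  cfg$comet$theta <- 0
  t0 <- simulate_comet(cfg, 7)
  expect_true(all(comet_scores(t0)$au == 0))
  cfg$comet$theta <- 1
  t4 <- simulate_comet(cfg, 7)
  expect_true(all(comet_scores(t4)$au == 400))

  cfg$design$accessions <- "A"
  cfg$design$replicates <- 1L
  cfg$design$slides_per_replicate <- 1L
  cfg$design$nucleoids_per_slide <- 10000L
  cfg$comet$theta <- 0.3825
  tab <- simulate_comet(cfg, 8)
  sc <- comet_scores(tab)
  se <- 100 * sqrt(4 * 0.3825 * (1 - 0.3825) / 10000)
  expect_true(all(abs(sc$au - 153.0) < 3 * se))

  expect_equal(sum(comet_class_probs(0.3)), 1)
  expect_equal(sum(comet_class_probs(0.3) * 0:4 * 100), 400 * 0.3)
})

test_that("Ct simulation inverts through relative quantification", {
  cfg <- small_config()
  cfg$qpcr$sd_tech <- 0
  for (g in names(cfg$qpcr$effects)) {
    cfg$qpcr$effects[[g]] <- as.list(setNames(rep(0, 6), expression_groups()))
  }
  ct <- simulate_ct(cfg, 5)
  q <- relative_quantity(ct_matrix(collapse_technical(ct)),
                         efficiency = cfg$qpcr$efficiency)
  expect_true(all(abs(q - 1) < 1e-12))

  # a planted one-cycle decrease yields Q = E in that group
  cfg$qpcr$effects$LsSODa$`UP-HW` <- log2(1.8)
  ct2 <- simulate_ct(cfg, 5)
  q2 <- relative_quantity(ct_matrix(collapse_technical(ct2)),
                          efficiency = 1.8, calibrator = "DS")
  expect_equal(unname(q2["LsSODa", "UP-HW"]), 1.8)
})

test_that("biometry simulation matches its configured moments at large n", {
  cfg <- small_config()
  cfg$design$accessions <- "A"
  cfg$design$replicates <- 1L
  cfg$design$seeds_per_replicate <- 2000L
  cfg$germination$pi <- 1
  cfg$biometry$aberrant_given_germinated <- 0
  cfg$biometry$shoot_mean <- 6; cfg$biometry$shoot_sd <- 0.5
  cfg$biometry$root_mean <- 8; cfg$biometry$root_sd <- 0.5
  tab <- simulate_biometry(cfg, 19)
  df <- as.data.frame(tab)
  sub <- df[df$priming == "UP" & df$stress == "NT", ]
  expect_true(abs(mean(sub$shoot_len_cm) - 6) < 3 * 0.5 / sqrt(2000))
  expect_true(abs(sd(sub$root_len_cm) - 0.5) < 0.05)

  cfg$biometry$shoot_sd <- 0; cfg$biometry$root_sd <- 0
  tab0 <- simulate_biometry(cfg, 19)
  expect_true(all(tab0$shoot_len_cm == 6))

  cfg$germination$pi <- 0
  tabng <- simulate_biometry(cfg, 19)
  expect_true(all(tabng$category == "non_germinating"))
  expect_true(all(is.na(tabng$shoot_len_cm)))
})

test_that("config invariants are enforced", {
  cfg <- small_config()
  cfg$comet$theta <- 1.2
  expect_error(check_config(cfg), "probabilities")
  cfg <- small_config()
  cfg$qpcr$effects$LsEF2$DS <- 1
  expect_error(check_config(cfg), "reference")
  cfg <- small_config()
  cfg$design$schedule_h <- list(12, 12, 24)
  expect_error(check_config(cfg), "increasing")
})
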