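test_that("germinability reproduces the printed group mean and SD", {
  # replicates with 9, 10, 12 of 20 seeds germinated
  tab <- make_germination(list(c(4, 5), c(4, 6), c(5, 7)), times = c(48, 72),
                          total_seeds = 20)
  idx <- germination_indices(tab)
  expect_equal(sort(idx$G), c(45, 50, 60))
  sm <- summarize_germination(idx)
  g <- sm[sm$metric == "G", ]
  expect_equal(round(g$mean, 2), 51.67)
  expect_equal(round(g$sd, 2), 7.64)
})

test_that("germinability handles the boundary cases", {
  expect_equal(germinability(c(10, 10), 20), 100)
  expect_equal(germinability(c(0, 0), 20), 0)
  expect_error(germinability(c(1, 1), 0), "positive")
  expect_error(germinability(c(15, 10), 20), "exceeds")
})

test_that("MGT reproduces the printed value and flags zero germination", {
  expect_equal(mean_germination_time(c(10, 10), c(60, 76.4)), 68.2)
  expect_equal(mean_germination_time(c(0, 7, 0), c(24, 48, 72)), 48)
  expect_warning(m <- mean_germination_time(c(0, 0), c(24, 48)), "undefined")
  expect_true(is.na(m))
})

test_that("MGT equals the plain average over a per-seed expansion", {
  set.seed(101)
  for (rep in 1:25) {
    times <- sort(runif(8, 12, 168))
    counts <- rpois(8, 2)
    if (sum(counts) == 0) counts[1] <- 1
    per_seed <- rep(times, counts)
    expect_equal(mean_germination_time(counts, times), mean(per_seed))
  }
})

test_that("G and MGT invariants hold", {
  set.seed(202)
  for (rep in 1:25) {
    times <- sort(runif(6, 12, 168))
    counts <- rpois(6, 3); counts[1] <- counts[1] + 1
    g <- germinability(counts, 100)
    expect_gte(g, 0); expect_lte(g, 100)
    # G invariant under permutation of inspection entries
    p <- sample(6)
    expect_equal(germinability(counts[p], 100), g)
    # MGT bounded by the inspection window
    m <- mean_germination_time(counts, times)
    expect_gte(m, min(times)); expect_lte(m, max(times))
    # splitting one count across two entries at the same time changes nothing
    split_counts <- c(counts[1] - 1, 1, counts[-1])
    split_times <- c(times[1], times[1], times[-1])
    expect_equal(mean_germination_time(split_counts, split_times), m)
    # delaying one germination event never decreases MGT
    pos <- which(counts > 0)
    i <- pos[sample.int(length(pos), 1)]
    delayed <- times; delayed[i] <- delayed[i] + 10
    delayed_counts <- counts
    ord <- order(delayed)
    expect_gte(mean_germination_time(delayed_counts[ord], delayed[ord]), m)
  }
})

test_that("phenotype frequencies reproduce the worked percentages and sum to 100", {
  tab <- make_biometry(rep(c("normal", "aberrant", "non_germinating"),
                           c(2, 8, 10)),
                       shoot = c(rep(2, 10), rep(NA, 10)),
                       root = c(rep(3, 10), rep(NA, 10)))
  fr <- phenotype_frequencies(tab)
  expect_equal(fr$percent[match(c("normal", "aberrant", "non_germinating"),
                                fr$category)], c(10, 40, 50))
  expect_equal(sum(fr$percent), 100)

  all_normal <- make_biometry(rep("normal", 12), shoot = 2, root = 3)
  fr2 <- phenotype_frequencies(all_normal)
  expect_equal(fr2$percent[fr2$category == "normal"], 100)

  # per-replicate percentages always sum to 100 on random tables
  set.seed(303)
  for (rep in 1:10) {
    cats <- sample(c("normal", "aberrant", "non_germinating"), 20, replace = TRUE)
    fr3 <- phenotype_frequencies(make_biometry(cats, shoot = 1, root = 1))
    expect_equal(sum(fr3$percent), 100)
  }
})

test_that("pooled frequencies equal the mean of per-replicate frequencies for equal sizes", {
  cats1 <- rep(c("normal", "aberrant", "non_germinating"), c(10, 5, 5))
  cats2 <- rep(c("normal", "aberrant", "non_germinating"), c(4, 6, 10))
  tab <- rbind(data.frame(as.data.frame(make_biometry(cats1, 1, 1, replicate = 1))),
               as.data.frame(make_biometry(cats2, 1, 1, replicate = 2)))
  fr <- phenotype_frequencies(as_study_table(tab, "biometry"))
  sm <- summarize_phenotypes(fr)
  pooled_normal <- 100 * (10 + 4) / 40
  expect_equal(sm$mean[sm$category == "normal"], pooled_normal)
})

test_that("biometry summaries match a direct two-pass oracle", {
  tab <- make_biometry(rep("normal", 3), shoot = c(2, 4, 6), root = c(1, 2, 3))
  sm <- biometry_summary(tab)
  expect_equal(sm$mean[sm$organ == "shoot"], 4)
  expect_equal(sm$sd[sm$organ == "shoot"], 2)

  single <- biometry_summary(make_biometry("normal", shoot = 5, root = 4))
  expect_true(all(is.na(single$sd)))
  expect_true(all(single$n == 1))

  expect_error(biometry_summary(make_biometry("normal", shoot = -1, root = 2)),
               "negative")

  set.seed(404)
  shoot <- round(runif(30, 1, 9), 2); root <- round(runif(30, 1, 9), 2)
  tab2 <- make_biometry(rep(c("normal", "aberrant"), 15), shoot, root)
  sm2 <- biometry_summary(tab2)
  oracle_mean <- sum(shoot) / 30
  oracle_sd <- sqrt(sum((shoot - oracle_mean)^2) / 29)
  expect_equal(sm2$mean[sm2$organ == "shoot"], oracle_mean)
  expect_equal(sm2$sd[sm2$organ == "shoot"], oracle_sd)
})
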