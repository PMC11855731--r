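test_that("Welch t matches the textbook formula and star thresholds", {
  a <- c(45, 50, 60); b <- c(20, 25, 30)
  w <- welch_t(a, b)
  se2 <- var(a) / 3 + var(b) / 3
  t_hand <- (mean(a) - mean(b)) / sqrt(se2)
  df_hand <- se2^2 / ((var(a) / 3)^2 / 2 + (var(b) / 3)^2 / 2)
  p_hand <- 2 * pt(-abs(t_hand), df_hand)
  expect_equal(w$statistic, t_hand, tolerance = 1e-12)
  expect_equal(w$df, df_hand, tolerance = 1e-12)
  expect_equal(w$p_value, p_hand, tolerance = 1e-12)

  same <- welch_t(c(1, 2, 3), c(1, 2, 3))
  expect_equal(same$statistic, 0)
  expect_equal(same$p_value, 1)
  expect_identical(same$stars, "")

  expect_identical(p_stars(c(0.0005, 0.005, 0.04, 0.2)),
                   c("***", "**", "*", ""))
  expect_error(welch_t(1, c(1, 2)), "at least 2")
})

test_that("Welch t is antisymmetric in its arguments", {
  set.seed(71)
  for (rep in 1:20) {
    a <- rnorm(sample(3:6, 1)); b <- rnorm(sample(3:6, 1), 1)
    w1 <- welch_t(a, b); w2 <- welch_t(b, a)
    expect_equal(w1$statistic, -w2$statistic)
    expect_equal(w1$p_value, w2$p_value)
  }
})

test_that("one-way ANOVA matches the explicit sums-of-squares oracle", {
  set.seed(72)
  for (rep in 1:20) {
    groups <- lapply(setNames(1:4, paste0("g", 1:4)),
                     function(i) rnorm(3, i / 2))
    res <- oneway_anova(groups)
    all_v <- unlist(groups); N <- length(all_v); k <- 4
    grand <- mean(all_v)
    ssb <- sum(vapply(groups, function(v) length(v) * (mean(v) - grand)^2, 0))
    ssw <- sum(vapply(groups, function(v) sum((v - mean(v))^2), 0))
    expect_equal(res$F, (ssb / (k - 1)) / (ssw / (N - k)), tolerance = 1e-10)
    expect_equal(res$msw, ssw / (N - k), tolerance = 1e-10)
    expect_equal(res$df_between, k - 1)
    expect_equal(res$df_within, N - k)
    expect_equal(res$n_h, 3)
  }
})

test_that("two-group ANOVA F equals the squared pooled t statistic", {
  set.seed(73)
  a <- rnorm(5); b <- rnorm(4, 1)
  res <- oneway_anova(list(a = a, b = b))
  t_pooled <- t.test(a, b, var.equal = TRUE)$statistic
  expect_equal(res$F, unname(t_pooled)^2, tolerance = 1e-10)
})

test_that("degenerate ANOVA inputs are flagged", {
  same <- oneway_anova(list(a = c(2, 2, 2), b = c(2, 2, 2)))
  expect_equal(same$F, 0)
  expect_equal(same$p_value, 1)
  sep <- oneway_anova(list(a = c(1, 1, 1), b = c(2, 2, 2)))
  expect_true(is.infinite(sep$F))
  expect_equal(sep$p_value, 0)
})

test_that("Duncan critical ranges match published table values", {
  # Harter's corrected 5% tables for Duncan's multiple range test
  expect_equal(duncan_q(2:4, df = 8), c(3.261, 3.399, 3.475), tolerance = 0.005)
  expect_equal(duncan_q(2:4, df = 20), c(2.950, 3.097, 3.190), tolerance = 0.005)
  # p = 2 coincides with Fisher's LSD quantile
  expect_equal(duncan_q(2, df = 12), sqrt(2) * qt(0.975, 12), tolerance = 1e-6)
})

test_that("Duncan's test reproduces a hand-worked four-group example", {
  # k = 4, n = 3, every within-group variance 1 => MSW = 1, df = 8;
  # LSR(2..4) = (3.2612, 3.3985, 3.4752) * sqrt(1/3) = (1.883, 1.962, 2.006).
  # Means 25, 20, 18.5, 10: only |20 - 18.5| = 1.5 < LSR(2) is non-significant.
  g <- list(A = c(24, 25, 26), B = c(19, 20, 21),
            C = c(17.5, 18.5, 19.5), D = c(9, 10, 11))
  disp <- duncan_mrt(g)
  expect_equal(disp$display$letters, c("a", "b", "b", "c"))
  expect_equal(disp$display$group, c("A", "B", "C", "D"))
  expect_equal(disp$lsr$lsr, duncan_q(2:4, 8) * sqrt(1 / 3), tolerance = 1e-10)
})

test_that("Duncan separates extreme means and merges near ones", {
  set.seed(74)
  g <- list(a = rnorm(3, 0), b = rnorm(3, 0.1), c = rnorm(3, 50))
  disp <- duncan_mrt(g)
  lt <- setNames(disp$display$letters, disp$display$group)
  expect_identical(unname(lt["c"]), "a")  # highest mean lettered first
  expect_identical(unname(lt["a"]), unname(lt["b"]))
  expect_false(lt["c"] == lt["a"])
})

test_that("Duncan decisions are shift-invariant, scale-equivariant and monotone in alpha", {
  set.seed(75)
  for (rep in 1:15) {
    g <- lapply(setNames(rnorm(4, sd = 2), paste0("g", 1:4)),
                function(mu) rnorm(3, mu))
    d1 <- duncan_mrt(g)
    d_shift <- duncan_mrt(lapply(g, `+`, 100))
    d_scale <- duncan_mrt(lapply(g, `*`, 3.7))
    expect_identical(d1$different, d_shift$different)
    expect_identical(d1$different, d_scale$different)
    # lowering alpha never creates a new significant pair
    d_strict <- duncan_mrt(g, alpha = 0.01)
    expect_true(all(d1$different[d_strict$different]))
  }
})

test_that("letter displays satisfy the share-letter iff not-different contract", {
  trivial_none <- letters_from_pairs(matrix(FALSE, 3, 3))
  expect_true(all(trivial_none$display$letters == "a"))
  all_sig <- matrix(TRUE, 4, 4); diag(all_sig) <- FALSE
  expect_identical(letters_from_pairs(all_sig)$display$letters,
                   c("a", "b", "c", "d"))
  expect_error(letters_from_pairs(matrix(c(FALSE, TRUE, FALSE, FALSE), 2, 2)),
               "symmetric")

  set.seed(76)
  for (rep in 1:200) {
    k <- sample(2:6, 1)
    sig <- random_sig_matrix(k)
    res <- letters_from_pairs(sig)
    cols <- res$columns
    for (i in seq_len(k - 1)) {
      for (j in (i + 1):k) {
        share <- any(cols[i, ] & cols[j, ])
        expect_identical(share, !sig[i, j])
      }
    }
  }
})
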