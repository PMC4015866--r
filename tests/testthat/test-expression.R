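test_that("TPM normalization is count/total x 1e6 and sums to 1e6", {
  expect_equal(compute_tpm(100, 1e6), 100)
  expect_equal(compute_tpm(0, 123456), 0)
  expect_error(compute_tpm(5, 0), "total")
  expect_error(compute_tpm(-1, 10), ">= 0")
  counts <- c(5, 0, 995, 4000)
  expect_equal(sum(compute_tpm(counts, sum(counts))), 1e6)
})

test_that("count-test tails match the arbitrary-precision rational oracle", {
  # values frozen from an exact rational summation of the formula
  # (17 significant digits)
  frozen <- list(
    list(x = 5, y = 50, n1 = 1e6, n2 = 1e6,
         p = 4.8277506992100427e-11, C = 0.99999999994148538,
         D = 1.0679213069408888e-10),
    list(x = 10, y = 10, n1 = 1e6, n2 = 1e6,
         p = 0.088098526000976562, C = 0.50000000000000000,
         D = 0.58809852600097656),
    list(x = 0, y = 100, n1 = 1e6, n2 = 1e6,
         p = 3.9443045261050590e-31, C = 1.0, D = 7.8886090522101181e-31),
    list(x = 3, y = 7, n1 = 1e4, n2 = 1e6,
         p = 1.0755884610213663e-06, C = 2.9996954978225787e-06,
         D = 0.99999807589296320),
    list(x = 120, y = 80, n1 = 13282907, n2 = 13525513,
         p = 0.00035076862449489308, C = 0.0015497480827118665,
         D = 0.99880102054178303)
  )
  for (f in frozen) {
    got <- ac_tail_prob(f$x, f$y, f$n1, f$n2)
    expect_equal(got$p_point, f$p, tolerance = 1e-12)
    expect_equal(got$C, f$C, tolerance = 1e-12)
    expect_equal(got$D, f$D, tolerance = 1e-12)
    # the recurrence-route oracle agrees too
    orc <- ac_oracle(f$x, f$y, f$n1, f$n2)
    expect_equal(got$p_point, orc$p_point, tolerance = 1e-11)
    expect_equal(got$C, orc$C, tolerance = 1e-11)
    expect_equal(got$D, orc$D, tolerance = 1e-11)
  }
  # closed form at the origin: p(0|0) = 1/2^(x+y+1) = 0.5 with equal totals
  z <- ac_tail_prob(0, 0, 54321, 54321)
  expect_identical(z$p_point, 0.5)
  expect_identical(z$C, 0.5)
  expect_identical(z$D, 1)
})

test_that("count-test identities: symmetry, normalization, C + D = 1 + p", {
  grid <- expand.grid(x = c(0, 1, 7, 40, 100), y = c(0, 3, 25, 100))
  r <- ac_tail_prob(grid$x, grid$y, 1e6, 1e6)
  expect_equal(r$C + r$D, 1 + r$p_point, tolerance = 1e-12)
  # point-probability symmetry at N1 = N2 is exact; tail symmetry is only
  # asymptotic (tails condition on different margins), so the two-sided p
  # is compared at moderate counts with a loose band
  expect_equal(ac_tail_prob(grid$x, grid$y, 1e6, 1e6)$p_point,
               ac_tail_prob(grid$y, grid$x, 1e6, 1e6)$p_point,
               tolerance = 1e-12)
  big <- grid[grid$x >= 25 & grid$y >= 25, ]
  expect_equal(ac_pvalue(big$x, big$y, 1e6, 1e6),
               ac_pvalue(big$y, big$x, 1e6, 1e6), tolerance = 0.25)
  # sum over y of p(y|x) = 1
  for (x in c(0, 5, 100)) {
    row <- ac_tail_prob(x, 0, 1e6, 1e6)
    expect_equal(row$C + row$D - row$p_point, 1, tolerance = 1e-10)
  }
  # a 100-vs-0 split must be significant
  expect_lt(ac_pvalue(0, 100, 1e6, 1e6), 0.05)
  # p decreases as |y - x| grows at fixed x (monotone evidence)
  ps <- ac_pvalue(10, c(10, 20, 40, 80), 1e6, 1e6)
  expect_true(all(diff(ps) < 0))
  expect_gte(ac_pvalue(10, 10, 1e6, 1e6), ac_tail_prob(10, 10, 1e6, 1e6)$p_point)
})

test_that("log2 fold-change handles the zero-TPM pseudo rule", {
  expect_equal(log2_fold_change(40, 20), 1)
  expect_equal(log2_fold_change(20, 20), 0)
  # undetectable at a late stage: large negative but finite
  v <- log2_fold_change(0, 150.97, pseudo = 0.01)
  expect_true(is.finite(v))
  expect_lt(v, -13)
  # pseudo not applied when both operands are positive
  expect_equal(log2_fold_change(3, 6, pseudo = 0.01), -1)
})

test_that("de_scan flags induced features and partitions up/down", {
  counts <- tibble::tibble(
    mirna_id = c("m1", "m2", "m3"),
    `5DAP` = c(100L, 500L, 40L),
    `15DAP` = c(800L, 500L, 40L),   # m1 induced 8-fold
    `25DAP` = c(100L, 60L, 40L))    # m2 repressed
  totals <- c(`5DAP` = 1e6, `15DAP` = 1e6, `25DAP` = 1e6)
  de <- de_scan(counts, totals = totals, baseline = "5DAP")
  td <- tidy(de)
  m1 <- td[td$mirna_id == "m1" & td$stage == "15DAP", ]
  expect_true(m1$significant)
  expect_gt(m1$log2fc, 2.5)
  m2 <- td[td$mirna_id == "m2" & td$stage == "25DAP", ]
  expect_true(m2$significant)
  expect_lt(m2$log2fc, 0)
  g <- glance(de)
  expect_equal(g$up + g$down, g$significant)

  # all-equal counts with equal totals: nothing significant
  flat <- tibble::tibble(mirna_id = c("a", "b"),
                         `5DAP` = c(50L, 9L), `15DAP` = c(50L, 9L))
  de0 <- de_scan(flat, totals = c(`5DAP` = 1e6, `15DAP` = 1e6),
                 baseline = "5DAP")
  expect_equal(sum(tidy(de0)$significant), 0L)
  expect_error(de_scan(flat, baseline = "99DAP"), "baseline")
})

test_that("high-expression filter keeps max-stage TPM >= threshold inclusively", {
  counts <- tibble::tibble(
    mirna_id = c("kept", "boundary", "dropped"),
    `5DAP` = c(0L, 0L, 0L),
    `15DAP` = c(250L, 200L, 199L),  # at 1e7 totals: TPM 25, 20, 19.9
    `25DAP` = c(50L, 50L, 30L))
  totals <- c(`5DAP` = 1e7, `15DAP` = 1e7, `25DAP` = 1e7)
  de <- de_scan(counts, totals = totals, baseline = "5DAP")
  kept <- filter_high_expression(de, tpm_min = 20)
  expect_setequal(kept$counts$mirna_id, c("kept", "boundary"))
  # the same rule at TPM >= 10 is the novel-candidate inclusion filter
  kept10 <- filter_high_expression(de, tpm_min = 10)
  expect_equal(nrow(kept10$counts), 3)
})

test_that("type-I error is controlled and power rises with fold-change", {
  set.seed(42)
  n_rep <- 2000
  rate <- 5e-5
  x <- rbinom(n_rep, 1e6, rate)
  y <- rbinom(n_rep, 1e6, rate)
  rej <- mean(ac_pvalue(x, y, 1e6, 1e6) < 0.05)
  se <- sqrt(0.05 * 0.95 / n_rep)
  expect_lte(rej, 0.05 + 3 * se)
  # power monotone in the true fold-change
  power <- vapply(c(1.5, 2.5, 6), function(fc) {
    y2 <- rbinom(400, 1e6, rate * fc)
    mean(ac_pvalue(x[1:400], y2, 1e6, 1e6) < 0.05)
  }, numeric(1))
  expect_true(all(diff(power) >= 0))
  expect_gt(power[3], 0.95)
})
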