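test_that("window tiling enumerates overlapping windows and truncates at ends", {
  tw <- tile_windows(c(chr1 = 2000))
  expect_equal(tw$start, c(1, 501, 1001, 1501))
  expect_equal(tw$end, c(1000, 1500, 2000, 2000))

  tw2 <- tile_windows(c(chr1 = 1000))
  expect_equal(tw2$start, c(1, 501))
  expect_equal(tw2$end, c(1000, 1000))

  # every base covered by >= 1 window, interior bases by exactly 2
  tw3 <- tile_windows(c(c1 = 5000))
  cover <- integer(5000)
  for (i in seq_len(nrow(tw3)))
    cover[tw3$start[i]:tw3$end[i]] <- cover[tw3$start[i]:tw3$end[i]] + 1L
  expect_true(all(cover >= 1))
  expect_true(all(cover[501:4500] == 2))

  # consecutive windows differ by the step
  expect_equal(diff(tw3$start), rep(500L, nrow(tw3) - 1))
  expect_error(tile_windows(c(chr1 = 1000), window = 0), "positive")
})

test_that("depth filter keeps a CpG only when every sample passes", {
  depth <- rbind(c(25, 22, 30, 21, 20, 20),   # all >= 20 -> kept
                 c(25, 22, 30, 21, 19, 20),   # one sample at 19 -> dropped
                 c(1, 1, 1, 1, 1, 1))         # kept at min_depth 1
  meth <- depth * 0L
  sheet <- two_group_sheet()
  cs <- build_cpg_set(cpg_samples_from_counts(meth, depth, sheet = sheet))
  f20 <- filter_cpgs(cs, min_depth = 20)
  expect_equal(nrow(f20$sites), 1)
  expect_equal(f20$sites$pos, 150L)
  f1 <- filter_cpgs(cs, min_depth = 1)
  expect_equal(nrow(f1$sites), 3)   # identity filter
})

test_that("window test matches the logistic-regression oracle and handles edge cases", {
  # identical pooled proportions -> delta 0, p exactly 1
  m <- matrix(50, 2, 6); d <- matrix(100, 2, 6)
  r <- test_window(m[, 1:3], d[, 1:3], m[, 4:6], d[, 4:6])
  expect_equal(r$delta_beta, 0)
  expect_equal(r$p, 1)

  # complete separation: all-unmethylated vs all-methylated
  r2 <- test_window(matrix(0, 2, 3), matrix(15, 2, 3),
                    matrix(15, 2, 3), matrix(15, 2, 3))
  expect_equal(r2$delta_beta, 100)
  expect_lt(r2$p, 1e-6)
  fp <- fisher.test(matrix(c(0, 90, 90, 0), 2))$p.value
  expect_lt(fp, 1e-6)   # agrees with the exact-test oracle in magnitude

  # label swap negates delta and leaves p unchanged
  set.seed(3)
  ma <- matrix(rbinom(6, 30, 0.3), 2); da <- matrix(30, 2, 3)
  mb <- matrix(rbinom(6, 30, 0.7), 2); db <- matrix(30, 2, 3)
  f <- test_window(ma, da, mb, db)
  b <- test_window(mb, db, ma, da)
  expect_equal(b$delta_beta, -f$delta_beta)
  expect_equal(b$p, f$p)

  # closed-form LRT equals glm(cbind(meth, unmeth) ~ group) deviance drop
  for (i in 1:5) {
    mm <- matrix(rbinom(12, 40, runif(1, 0.2, 0.8)), 2)
    dd <- matrix(40, 2, 6)
    wm <- colSums(mm); wd <- colSums(dd)
    grp <- rep(c("a", "b"), each = 3)
    fit <- glm(cbind(wm, wd - wm) ~ grp, family = binomial)
    lrt_glm <- fit$null.deviance - fit$deviance
    p_mine <- test_window(mm[, 1:3], dd[, 1:3], mm[, 4:6], dd[, 4:6],
                          method = "lrt")$p
    expect_equal(p_mine, pchisq(lrt_glm, 1, lower.tail = FALSE),
                 tolerance = 1e-8)
  }

  # fewer than two CpGs -> not testable
  expect_null(test_window(matrix(5, 1, 3), matrix(10, 1, 3),
                          matrix(5, 1, 3), matrix(10, 1, 3)))
})

test_that("count scaling preserves delta beta and cannot weaken the plain LRT", {
  set.seed(4)
  for (i in 1:10) {
    ma <- matrix(rbinom(9, 25, 0.35), 3); da <- matrix(25, 3, 3)
    mb <- matrix(rbinom(9, 25, 0.55), 3); db <- matrix(25, 3, 3)
    r1 <- test_window(ma, da, mb, db, method = "lrt")
    r3 <- test_window(3 * ma, 3 * da, 3 * mb, 3 * db, method = "lrt")
    expect_equal(r3$delta_beta, r1$delta_beta)
    expect_lte(r3$p, r1$p)
  }
})

test_that("single-replicate test ranks significance like Fisher's exact test", {
  set.seed(6)
  n <- 150
  p_lrt <- p_fish <- numeric(n)
  for (i in seq_len(n)) {
    d1 <- rpois(1, 60) + 20; d2 <- rpois(1, 60) + 20
    m1 <- rbinom(1, d1, runif(1, 0.05, 0.95))
    m2 <- rbinom(1, d2, runif(1, 0.05, 0.95))
    r <- test_window(matrix(c(m1, m1), 2, 1), matrix(c(d1, d1), 2, 1),
                     matrix(c(m2, m2), 2, 1), matrix(c(d2, d2), 2, 1),
                     method = "lrt")
    p_lrt[i] <- r$p
    p_fish[i] <- fisher.test(matrix(c(2 * m1, 2 * (d1 - m1),
                                      2 * m2, 2 * (d2 - m2)), 2))$p.value
  }
  expect_gt(cor(-log(p_lrt), -log(p_fish), method = "spearman"), 0.99)
})

test_that("DMR calling recovers planted windows and respects its thresholds", {
  cfg <- small_config(seed = 9)
  d <- quiet(simulate_methylome(cfg))
  res <- quiet(call_dmrs(d$samples, d$sample_sheet, c("control", "disease")))

  # every planted window is recovered
  expect_true(all(d$truth$dmr_id %in% res$id[res$dmr]))
  # windows not touching planted signal are essentially never called
  # (overlapping neighbours of planted windows share their shifted CpGs
  # and legitimately fire, so exclude anything within a window width)
  pw <- parse_region_id(d$truth$dmr_id)
  near <- rep(FALSE, nrow(res))
  for (i in seq_len(nrow(pw)))
    near <- near | (res$chrom == pw$chrom[i] &
                    res$start >= pw$start[i] - 1000 &
                    res$start <= pw$end[i])
  expect_lt(mean(res$dmr[!near]), 0.01)
  # every DMR satisfies the calling rule
  expect_true(all(abs(res$delta_beta[res$dmr]) >= 10))
  expect_true(all(res$q[res$dmr] < 0.01))
  expect_true(all(res$n_cpgs >= 2))
  # direction matches the delta sign
  expect_true(all((res$direction == "hyper") == (res$delta_beta > 0),
                  na.rm = TRUE))
  # impossible difference threshold -> zero DMRs
  res2 <- quiet(call_dmrs(d$samples, d$sample_sheet,
                          c("control", "disease"), min_diff = 101))
  expect_equal(sum(res2$dmr), 0)
})

test_that("contrast order only flips the sign of delta beta", {
  cfg <- small_config(seed = 10)
  d <- quiet(simulate_methylome(cfg))
  ab <- quiet(call_dmrs(d$samples, d$sample_sheet, c("control", "disease")))
  ba <- quiet(call_dmrs(d$samples, d$sample_sheet, c("disease", "control")))
  expect_equal(ab$id, ba$id)
  expect_equal(ab$delta_beta, -ba$delta_beta)
  expect_equal(ab$q, ba$q, tolerance = 1e-12)
})

test_that("DMR percentages of tested bins reproduce printed precision", {
  expect_equal(dmr_summary(23154, 12247, 445288),
               c(hyper = 5.2, hypo = 2.75))
  expect_equal(dmr_summary(4818, 4379, 449539),
               c(hyper = 1.07, hypo = 0.97))
  expect_equal(dmr_summary(0, 0, 100), c(hyper = 0, hypo = 0))
  expect_error(dmr_summary(1, 1, 0), "positive")
})
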