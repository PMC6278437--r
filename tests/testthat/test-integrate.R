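test_that("methylation restoration patterns classify published-scale values", {
  # a receptor-kinase DMR restored by treatment: hyper then hypo
  expect_equal(classify_meth_pattern(11.51523, 7.89e-5, -10.3308, 3.31e-5),
               "hyper_hypo")
  # a growth-factor DMR moving the other way
  expect_equal(classify_meth_pattern(-13.0325, 0.004499, 18.71345, 3.94e-6),
               "hypo_hyper")
  # below the 10-pp threshold, however significant
  expect_equal(classify_meth_pattern(5, 1e-9, -5, 1e-9), "none")
  # non-significant q blocks the call
  expect_equal(classify_meth_pattern(15, 0.02, -15, 1e-9), "none")
  # same-direction changes are not a restoration
  expect_equal(classify_meth_pattern(15, 1e-9, 15, 1e-9), "none")
  expect_error(classify_meth_pattern(150, 0.1, 0, 0.1), "100")
})

test_that("expression restoration patterns classify published-scale values", {
  expect_equal(classify_expr_pattern(-7.78059, 0.000103, 6.402056, 0.00061),
               "down_up")
  expect_equal(classify_expr_pattern(2.522877, 0.014275, -2.46869, 0.007728),
               "up_down")
  # optional magnitude screen: |fc| < 2 fails when min_fc = 2
  expect_equal(classify_expr_pattern(-1.5, 0.01, 1.5, 0.01, min_fc = 2),
               "none")
  expect_equal(classify_expr_pattern(-1.5, 0.01, 1.5, 0.01), "down_up")
  expect_equal(classify_expr_pattern(-3, 0.2, 3, 0.01), "none")
  expect_error(classify_expr_pattern(0.5, 0.01, 2, 0.01), "magnitude")
})

test_that("unit-interval scaling is affine-invariant with the degenerate rule", {
  expect_equal(scale_unit_interval(c(1, 2, 3)), c(0, 0.5, 1))
  expect_equal(scale_unit_interval(c(7, 7, 7)), c(0.5, 0.5, 0.5))
  set.seed(30)
  x <- rnorm(20)
  expect_equal(scale_unit_interval(3.7 * x + 11), scale_unit_interval(x))
})

test_that("Spearman correlation matches a brute-force rank oracle", {
  expect_equal(spearman_rho(1:4, c(8, 6, 4, 2)), -1)
  expect_equal(spearman_rho(1:4, c(2, 4, 6, 8)), 1)
  # ties handled by average ranks
  expect_equal(spearman_rho(c(1, 2, 2, 3), c(3, 2, 2, 1)), -1)
  set.seed(31)
  for (i in 1:20) {
    x <- sample(1:5, 8, replace = TRUE)
    y <- rnorm(8)
    expect_equal(spearman_rho(x, y), brute_spearman(x, y), tolerance = 1e-12)
  }
  # zero rank variance -> undefined
  expect_true(is.na(spearman_rho(c(1, 1, 1), c(1, 2, 3))))
})

# in-memory stage tables for integrator tests
fake_meth <- function(ids, delta, q) {
  data.frame(id = ids, delta_beta = delta, q = q, stringsAsFactors = FALSE)
}
fake_expr <- function(tx, fc, p) {
  data.frame(transcript_id = tx, fc_signed = fc, p = p,
             stringsAsFactors = FALSE)
}
fake_links <- function(ids, tx, gene) {
  data.frame(region_id = ids, transcript_id = tx, gene = gene,
             stringsAsFactors = FALSE)
}

test_that("integration joins layers, applies patterns, and deduplicates", {
  ids <- c("chr1$1001$2000", "chr1$5001$6000", "chr1$9001$10000")
  m1 <- fake_meth(ids, c(20, -15, 30), c(1e-4, 1e-4, 1e-4))
  m2 <- fake_meth(ids, c(-18, 14, -25), c(1e-4, 1e-4, 1e-4))
  e1 <- fake_expr(c("t1", "t2", "t3"), c(-4, 3, 2), c(0.001, 0.01, 0.2))
  e2 <- fake_expr(c("t1", "t2", "t3"), c(3, -2.5, -2), c(0.001, 0.01, 0.2))
  links <- fake_links(ids, c("t1", "t2", "t3"), c("g1", "g2", "g3"))
  ig <- integrate_patterns(m1, m2, e1, e2, links)
  # g1: hyper/hypo + down/up -> A; g2: hypo/hyper + up/down -> B;
  # g3: expression not significant -> excluded
  expect_equal(ig$pattern[ig$gene == "g1"], "A")
  expect_equal(ig$pattern[ig$gene == "g2"], "B")
  expect_false("g3" %in% ig$gene)
  s <- integration_summary(ig)
  expect_equal(s$n_pattern_a, 1)
  expect_equal(s$n_pattern_b, 1)
  # duplicate links collapse to one record per (dmr, transcript)
  ig2 <- integrate_patterns(m1, m2, e1, e2, rbind(links, links))
  expect_equal(nrow(ig2), nrow(ig))
  # empty DMR set -> empty output
  ig0 <- integrate_patterns(m1[0, ], m2[0, ], e1, e2, links)
  expect_equal(nrow(ig0), 0)
  # a link to a transcript missing from expression warns and is skipped
  links_bad <- fake_links(ids[1], "unknown_tx", "gX")
  expect_warning(integrate_patterns(m1, m2, e1, e2, links_bad), "absent")
})

test_that("no record can be both Pattern A and Pattern B", {
  # the defining sign conditions are mutually exclusive by construction;
  # verify over random tables
  set.seed(32)
  ids <- region_id("chr1", 1000 * (1:50) + 1, 1000 * (1:50) + 1000)
  m1 <- fake_meth(ids, runif(50, -30, 30), runif(50, 0, 0.02))
  m2 <- fake_meth(ids, runif(50, -30, 30), runif(50, 0, 0.02))
  tx <- paste0("t", 1:50)
  e1 <- fake_expr(tx, signed_fold_change(runif(50, 1, 10), runif(50, 1, 10)),
                  runif(50, 0, 0.1))
  e2 <- fake_expr(tx, signed_fold_change(runif(50, 1, 10), runif(50, 1, 10)),
                  runif(50, 0, 0.1))
  links <- fake_links(ids, tx, paste0("g", 1:50))
  ig <- integrate_patterns(m1, m2, e1, e2, links)
  expect_equal(anyDuplicated(ig[, c("dmr_id", "transcript_id")]), 0)
  mp <- classify_meth_pattern(ig$delta1, ig$q1, ig$delta2, ig$q2)
  ep <- classify_expr_pattern(ig$fc1, ig$p1, ig$fc2, ig$p2)
  expect_true(all((ig$pattern == "A") ==
                  (mp == "hyper_hypo" & ep == "down_up")))
})

test_that("tightening any threshold never adds integrated records", {
  set.seed(33)
  ids <- region_id("chr1", 1000 * (1:80) + 1, 1000 * (1:80) + 1000)
  m1 <- fake_meth(ids, runif(80, -40, 40), runif(80, 0, 0.03))
  m2 <- fake_meth(ids, runif(80, -40, 40), runif(80, 0, 0.03))
  tx <- paste0("t", 1:80)
  e1 <- fake_expr(tx, signed_fold_change(runif(80, 1, 8), runif(80, 1, 8)),
                  runif(80, 0, 0.1))
  e2 <- fake_expr(tx, signed_fold_change(runif(80, 1, 8), runif(80, 1, 8)),
                  runif(80, 0, 0.1))
  links <- fake_links(ids, tx, paste0("g", 1:80))
  base <- nrow(integrate_patterns(m1, m2, e1, e2, links))
  for (args in list(list(min_diff = 20), list(max_q = 0.005),
                    list(min_fc = 2), list(alpha = 0.01))) {
    n <- nrow(do.call(integrate_patterns,
                      c(list(m1, m2, e1, e2, links), args)))
    expect_lte(n, base)
  }
})

test_that("the inverse-correlation filter drops positively correlated pairs", {
  ids <- c("w1", "w2")
  m1 <- fake_meth(ids, c(20, 20), c(1e-4, 1e-4))
  m2 <- fake_meth(ids, c(-20, -20), c(1e-4, 1e-4))
  e1 <- fake_expr(c("t1", "t2"), c(-4, -4), c(0.001, 0.001))
  e2 <- fake_expr(c("t1", "t2"), c(4, 4), c(0.001, 0.001))
  links <- fake_links(ids, c("t1", "t2"), c("g1", "g2"))
  samp <- paste0("s", 1:6)
  betas <- rbind(w1 = seq(0.1, 0.6, 0.1), w2 = seq(0.1, 0.6, 0.1))
  colnames(betas) <- samp
  expr <- rbind(t1 = seq(600, 100, -100),  # inverse to w1
                t2 = seq(100, 600, 100))   # parallel to w2
  colnames(expr) <- samp
  ig <- integrate_patterns(m1, m2, e1, e2, links,
                           sample_betas = betas, sample_expr = expr)
  expect_equal(ig$gene, "g1")
  expect_lt(ig$rho, 0)
})

test_that("window beta matrices pool counts per sample", {
  sheet <- two_group_sheet(2, 2)
  meth <- rbind(c(2, 4, 6, 8), c(8, 6, 4, 2))
  depth <- matrix(10, 2, 4)
  cs <- build_cpg_set(cpg_samples_from_counts(meth, depth, sheet = sheet,
                                              pos = c(120L, 480L)))
  b <- window_betas(cs, "chr1$1$1000")
  expect_equal(as.vector(b), c(1.0, 1.0, 1.0, 1.0) * 0.5)
  # a window with no CpGs is all NA
  b2 <- window_betas(cs, "chr9$1$1000")
  expect_true(all(is.na(b2)))
})
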