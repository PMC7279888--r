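# Fold changes, pooled t-test, s0 statistic and permutation FDR.

test_that("log2 fold change is the group-mean difference and shift-equivariant", {
  expect_equal(log2_fold_change(c(5, 5, 5), c(5, 5, 5)), 0)
  expect_equal(log2_fold_change(c(6, 7, 8), c(5, 6, 7)), 1.0)
  set.seed(1)
  tg <- rnorm(3); wt <- rnorm(3)
  expect_equal(log2_fold_change(tg + 1, wt), log2_fold_change(tg, wt) + 1)
  expect_error(log2_fold_change(1, c(1, 2)), ">= 2 observed")
})

test_that("pooled t-test matches the closed form and t.test(var.equal)", {
  # hand oracle: pooled variance formula with df = 4
  tg <- c(6, 7, 8); wt <- c(1, 2, 3)
  sp2 <- (2 * var(tg) + 2 * var(wt)) / 4
  t_hand <- (mean(tg) - mean(wt)) / sqrt(sp2 * (2 / 3))
  p_hand <- 2 * pt(-abs(t_hand), df = 4)
  expect_equal(student_t_test(tg, wt), p_hand, tolerance = 1e-12)
  # independent reference implementation on random draws
  set.seed(42)
  for (i in 1:25) {
    a <- rnorm(3 + i %% 3); b <- rnorm(3)
    expect_equal(student_t_test(a, b),
                 t.test(a, b, var.equal = TRUE)$p.value, tolerance = 1e-10)
    expect_equal(student_t_test(a, b, welch = TRUE),
                 t.test(a, b)$p.value, tolerance = 1e-10)
  }
  # conventions and within-group permutation invariance
  expect_equal(student_t_test(c(1, 2, 3), c(1, 2, 3)),
               student_t_test(c(3, 1, 2), c(2, 3, 1)))
  expect_equal(student_t_test(c(2, 2, 2), c(2, 2, 2)), 1)
  expect_equal(student_t_test(c(2, 2, 2), c(3, 3, 3)), 0)
})

test_that("s0 statistic reduces to Student t at s0 = 0 and matches hand arithmetic", {
  set.seed(7)
  for (i in 1:1000) {
    a <- rnorm(3); b <- rnorm(3)
    se <- sqrt(((2 * var(a) + 2 * var(b)) / 4) * (2 / 3))
    expect_equal(s0_statistic(a, b, s0 = 0), (mean(a) - mean(b)) / se,
                 tolerance = 1e-12)
  }
  tg <- c(6, 7, 8); wt <- c(1, 2, 3)
  se <- sqrt(1 * (2 / 3))      # both group variances are 1
  expect_equal(s0_statistic(tg, wt, s0 = 0.1), 5 / (se + 0.1), tolerance = 1e-12)
  expect_equal(s0_statistic(c(4, 5, 6), c(4, 5, 6), s0 = 0.3), 0)
})

test_that("permutation FDR flags equal exhaustive enumeration on a 3v3 toy slice", {
  tc <- toy_contrast(n_proteins = 12, seed = 9,
                     effect = c(3, -3, 2.5, -2.5))   # 4 strong planted effects
  cfg <- fdr_config(target_fdr = 0.05, s0 = 0.1)
  res <- permutation_fdr(tc$pm, tg = sprintf("TG_r%d", 1:3),
                         wt = sprintf("WT_r%d", 1:3), config = cfg)
  orc <- oracle_permutation_fdr(tc$e, 1:3, 4:6, s0 = 0.1, target = 0.05)
  expect_true(res$exact)
  expect_equal(res$n_null_sets, 18)
  expect_equal(unname(res$d_stat), orc$d, tolerance = 1e-12)
  expect_equal(res$cutoff, orc$cutoff, tolerance = 1e-12)
  expect_identical(unname(res$significant), orc$flags)
  expect_true(any(res$significant))
})

test_that("estimated FDR is non-increasing and flags are monotone in the target", {
  tc <- toy_contrast(n_proteins = 100, seed = 13,
                     effect = rep(c(2, -2), 10))
  flags <- lapply(c(0.01, 0.05, 0.2), function(q) {
    r <- permutation_fdr(tc$pm, 1:3, 4:6, fdr_config(target_fdr = q))
    expect_true(all(diff(r$table$fdr) <= 1e-12))
    which(r$significant)
  })
  expect_true(all(flags[[1]] %in% flags[[2]]))
  expect_true(all(flags[[2]] %in% flags[[3]]))
})

test_that("swapping group labels negates effect statistics and keeps p-values", {
  tc <- toy_contrast(n_proteins = 30, seed = 21, effect = c(2, -1.5))
  cfg <- fdr_config()
  a <- permutation_fdr(tc$pm, 1:3, 4:6, cfg)
  b <- permutation_fdr(tc$pm, 4:6, 1:3, cfg)
  expect_equal(a$d_stat, -b$d_stat, tolerance = 1e-12)
  expect_equal(a$cutoff, b$cutoff, tolerance = 1e-12)
  set.seed(3)
  x <- rnorm(3); y <- rnorm(3)
  expect_equal(student_t_test(x, y), student_t_test(y, x))
  expect_equal(log2_fold_change(x, y), -log2_fold_change(y, x))
})

test_that("p-values are approximately uniform under a pure null", {
  set.seed(99)
  e <- matrix(rnorm(5000 * 6, 25, 0.3), 5000)
  p <- apply(e, 1, function(v) student_t_test(v[1:3], v[4:6]))
  ks <- ks.test(p, "punif")
  expect_gt(ks$p.value, 0.01)
})

test_that("planted strong effects are recovered with controlled FDP", {
  # 10% of proteins at |log2FC| = 2, noise 0.2
  set.seed(31)
  n <- 800; n_reg <- 80
  e <- matrix(rnorm(n * 6, 25, 0.2), n,
              dimnames = list(sprintf("P%04d", 1:n),
                              c(paste0("TG", 1:3), paste0("WT", 1:3))))
  sgn <- sample(c(2, -2), n_reg, replace = TRUE)
  e[1:n_reg, 1:3] <- e[1:n_reg, 1:3] + sgn
  res <- permutation_fdr(protein_matrix(e), 1:3, 4:6, fdr_config(seed = 1))
  flagged <- which(res$significant)
  expect_gte(mean(seq_len(n_reg) %in% flagged), 0.90)
  fdp <- sum(flagged > n_reg) / max(1, length(flagged))
  expect_lte(fdp, 0.05)
})

test_that("regulation calls require all three conditions", {
  expect_equal(call_regulation(0.4, 0.001, TRUE), "none")   # |FC| too small
  expect_equal(call_regulation(0.8, 0.2, FALSE), "none")
  expect_equal(call_regulation(-0.8, 0.01, TRUE), "down")
  expect_equal(call_regulation(0.8, 0.01, TRUE), "up")
  expect_equal(call_regulation(0.8, 0.01, FALSE), "none")   # FDR flag missing
})

test_that("volcano table mirrors the contrast and round-trips through CSV", {
  tc <- toy_contrast(n_proteins = 40, seed = 17, effect = c(2, -2, 2))
  cc <- run_contrast(tc$pm, tc$sheet, "M1", 3, fdr_config())
  v <- volcano_table(cc)
  expect_equal(v$minus_log10_p, -log10(cc$p_value))
  expect_equal(sum(v$regulated), sum(cc$direction != "none"))
  path <- withr::local_tempfile(fileext = ".csv")
  write_contrast_csv(cc, path)
  back <- read_contrast_csv(path)
  expect_equal(back$log2_fc, cc$log2_fc)
  expect_equal(back$p_value, cc$p_value)
  expect_equal(back$direction, cc$direction)
})

test_that("zero-variance proteins are excluded with a warning when s0 = 0", {
  e <- matrix(c(rep(1, 6), rnorm(6)), 2, byrow = TRUE,
              dimnames = list(c("flat", "ok"), paste0("s", 1:6)))
  expect_warning(
    res <- permutation_fdr(protein_matrix(e), 1:3, 4:6,
                           fdr_config(s0 = 0)),
    "zero-variance"
  )
  expect_true(is.na(res$d_stat["flat"]))
  expect_false(res$significant["flat"])
})
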