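# The study generator: determinism, planted effects, onset lag, MNAR
# missingness, transcript tables and recovery scoring.

test_that("invalid configurations name the offending field", {
  expect_error(simulation_config(frac_regulated = 1.2), "frac_regulated")
  expect_error(simulation_config(ages = c(3, 3, 6, 12)), "ages")
  expect_error(simulation_config(stage_mix = c(0.5, 0.4, 0.2)), "stage_mix")
  expect_error(simulation_config(effect_size_range = c(-1, 2)), "effect_size_range")
  expect_error(simulation_config(missing_rate_at_floor = 2), "missing_rate_at_floor")
})

test_that("equal seeds give bit-identical studies; RNG state is restored", {
  cfg <- simulation_config(n_proteins = 120, seed = 7)
  set.seed(999); before <- rnorm(1)
  set.seed(999)
  a <- generate_study(cfg)
  after <- rnorm(1)
  b <- generate_study(cfg)
  expect_identical(a$matrices$APPPS1$exprs, b$matrices$APPPS1$exprs)
  expect_identical(a$matrices$APPKI$exprs, b$matrices$APPKI$exprs)
  expect_identical(as.data.frame(a$truth), as.data.frame(b$truth))
  expect_identical(before, after)   # generator does not consume caller RNG
})

test_that("null configuration has no planted group differences", {
  cfg <- simulation_config(n_proteins = 400, frac_regulated = 0,
                           missing_rate_at_floor = 0, batch_offset_sd = 0,
                           sample_offset_sd = 0, seed = 3)
  st <- generate_study(cfg)
  expect_true(all(st$truth$direction == "null"))
  e <- st$matrices$APPPS1$exprs
  sh <- st$sheet[st$sheet$model == "APPPS1", ]
  for (a in cfg$ages) {
    tg <- sh$sample_id[sh$age_months == a & sh$genotype == "TG"]
    wt <- sh$sample_id[sh$age_months == a & sh$genotype == "WT"]
    diff <- mean(rowMeans(e[, tg]) - rowMeans(e[, wt]))
    # group means differ only by noise: 3 SE bound on the grand mean diff
    se <- cfg$noise_sd * sqrt(2 / 3) / sqrt(nrow(e))
    expect_lt(abs(diff), 3 * se)
  }
})

test_that("noise-free limit realizes planted effects exactly with zero pre-onset", {
  cfg <- simulation_config(n_proteins = 150, frac_regulated = 0.3,
                           noise_sd = 0, missing_rate_at_floor = 0,
                           batch_offset_sd = 0, sample_offset_sd = 0, seed = 5)
  st <- generate_study(cfg)
  for (m in cfg$models) {
    e <- st$matrices[[m]]$exprs
    sh <- st$sheet[st$sheet$model == m, ]
    onset <- st$truth[[paste0("onset_", m)]]
    sgn <- ifelse(st$truth$direction == "up", 1,
                  ifelse(st$truth$direction == "down", -1, 0))
    for (a in cfg$ages) {
      tg <- sh$sample_id[sh$age_months == a & sh$genotype == "TG"]
      wt <- sh$sample_id[sh$age_months == a & sh$genotype == "WT"]
      diff <- rowMeans(e[, tg]) - rowMeans(e[, wt])
      planted <- ifelse(!is.na(onset) & a >= onset, sgn * st$truth$effect_size, 0)
      expect_equal(unname(diff), unname(planted), tolerance = 1e-12)
    }
  }
  # baseline age never carries an effect
  expect_true(all(is.na(st$truth$onset_APPPS1) |
                    st$truth$onset_APPPS1 >= cfg$ages[2]))
})

test_that("sample mean of planted fold changes is within 3 SE of the target", {
  # 2000 proteins, 10% regulated at |log2FC| = 1, noise 0.3
  cfg <- simulation_config(n_proteins = 2000, frac_regulated = 0.1,
                           effect_size_range = c(1, 1), noise_sd = 0.3,
                           missing_rate_at_floor = 0, batch_offset_sd = 0,
                           sample_offset_sd = 0, seed = 21)
  st <- generate_study(cfg)
  e <- st$matrices$APPPS1$exprs
  sh <- st$sheet[st$sheet$model == "APPPS1", ]
  tg <- sh$sample_id[sh$age_months == 12 & sh$genotype == "TG"]
  wt <- sh$sample_id[sh$age_months == 12 & sh$genotype == "WT"]
  reg <- st$truth$direction != "null"        # all onsets <= 12 months
  sgn <- ifelse(st$truth$direction[reg] == "up", 1, -1)
  fc <- (rowMeans(e[reg, tg]) - rowMeans(e[reg, wt])) * sgn
  se <- cfg$noise_sd * sqrt(2 / 3) / sqrt(sum(reg))
  expect_lt(abs(mean(fc) - 1.0), 3 * se)
})

test_that("lagged model onset never precedes the reference model onset", {
  st <- generate_study(simulation_config(n_proteins = 600, seed = 13))
  reg <- st$truth$direction != "null"
  expect_true(all(st$truth$onset_APPKI[reg] >= st$truth$onset_APPPS1[reg]))
  # lag is one age position, capped at the final age
  ages <- c(1, 3, 6, 12)
  expected <- ages[pmin(match(st$truth$onset_APPPS1[reg], ages) + 1, 4)]
  expect_equal(st$truth$onset_APPKI[reg], expected)
})

test_that("missingness is left-censored: rate non-increasing in intensity decile", {
  cfg <- simulation_config(n_proteins = 3000, frac_regulated = 0, seed = 17)
  st <- generate_study(cfg)
  e <- st$matrices$APPPS1$exprs
  dec <- cut(st$truth$baseline_log2,
             quantile(st$truth$baseline_log2, 0:10 / 10),
             include.lowest = TRUE, labels = FALSE)
  rate <- tapply(rowMeans(is.na(e)), dec, mean)
  expect_gt(rate[[1]], rate[[10]])
  expect_gt(rate[[1]], 0.05)          # floor proteins are censored noticeably
  expect_true(all(diff(rate) <= 0.01))  # monotone up to sampling jitter
})

test_that("transcript table respects planted concordance classes", {
  st <- generate_study(simulation_config(n_proteins = 500, frac_regulated = 0.3,
                                         seed = 19))
  tt <- generate_transcript_table(st$truth, seed = 2)
  truth <- st$truth
  expect_equal(unname(table(tt$transcript_class)[names(table(truth$transcript_class))]),
               unname(table(truth$transcript_class)))
  sgn <- ifelse(truth$direction == "up", 1, ifelse(truth$direction == "down", -1, 0))
  conc <- truth$transcript_class == "concordant"
  expect_true(all(sign(tt$log2_fc[conc]) == sgn[conc]))
  expect_true(all(tt$regulated[conc]))
  inv <- truth$transcript_class == "inverse"
  expect_true(all(sign(tt$log2_fc[inv]) == -sgn[inv]))
  expect_true(all(tt$regulated[inv]))
  t_only <- truth$transcript_class == "transcript_only"
  expect_true(all(tt$regulated[t_only]))
  expect_true(all(abs(tt$log2_fc[t_only]) > 0.5))
  rest <- truth$transcript_class %in% c("protein_only", "null")
  expect_false(any(tt$regulated[rest]))
  # determinism
  expect_identical(tt, generate_transcript_table(st$truth, seed = 2))
})

test_that("ground truth JSON round trip", {
  st <- generate_study(simulation_config(n_proteins = 50, seed = 23))
  path <- withr::local_tempfile(fileext = ".json")
  write_ground_truth(st$truth, path)
  back <- read_ground_truth(path)
  expect_equal(as.data.frame(back), as.data.frame(st$truth), tolerance = 1e-12)
  expect_equal(attr(back, "models"), attr(st$truth, "models"))
})

test_that("recovery scoring handles perfect, empty and random call sets", {
  st <- generate_study(simulation_config(n_proteins = 300, frac_regulated = 0.2,
                                         seed = 29))
  truth <- st$truth
  planted <- truth[truth$stage != "none", ]
  perfect <- data.frame(accession = planted$accession, stage = planted$stage,
                        direction = planted$direction)
  r1 <- evaluate_recovery(perfect, truth)
  expect_equal(unname(r1$sensitivity), c(1, 1, 1))
  expect_equal(r1$fdp, 0)
  expect_equal(r1$direction_accuracy, 1)

  none <- perfect[0, ]
  r2 <- evaluate_recovery(none, truth)
  expect_equal(unname(r2$sensitivity), c(0, 0, 0))
  expect_equal(r2$fdp, 0)      # empty call set convention

  # random calls on nulls: FDP equals the brute-force count ratio
  set.seed(1)
  nulls <- truth$accession[truth$direction == "null"][1:100]
  called <- sample(nulls, 30)
  rand <- data.frame(accession = c(called, planted$accession[1:10]),
                     stage = sample(c("early", "middle", "advanced"), 40, TRUE),
                     direction = "up")
  r3 <- evaluate_recovery(rand, truth)
  expect_equal(r3$fdp, 30 / 40)
  expect_equal(r3$n_called, 40)

  expect_error(evaluate_recovery(data.frame(accession = "NOPE", stage = "early",
                                            direction = "up"), truth),
               "absent from truth")
})
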