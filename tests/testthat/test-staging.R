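# Temporal staging, cross-model intersection and heatmap export.

# build a profiles table from per-model direction patterns at ages 3/6/12
make_profiles <- function(patterns, model = "M1", fc = NULL) {
  rows <- do.call(rbind, lapply(names(patterns), function(acc) {
    dirs <- patterns[[acc]]
    data.frame(accession = acc, gene = toupper(acc), model = model,
               age_months = c(3, 6, 12), direction = dirs,
               log2_fc = if (is.null(fc)) ifelse(dirs == "up", 1,
                                          ifelse(dirs == "down", -1, 0))
                         else fc[[acc]],
               stringsAsFactors = FALSE)
  }))
  class(rows) <- c("temporal_profiles", class(rows))
  rows
}

test_that("stage assignment matches a hand-written truth table over all patterns", {
  dirs <- c("up", "down", "none")
  grid <- expand.grid(d3 = dirs, d6 = dirs, d12 = dirs,
                      stringsAsFactors = FALSE)
  # independent rule written out longhand
  expected <- apply(grid, 1, function(g) {
    reg <- g != "none"
    if (all(reg)) {
      if (length(unique(g)) == 1) paste("early", g[1]) else "none"
    } else if (!reg[1] && reg[2] && reg[3]) {
      if (g[2] == g[3]) paste("middle", g[2]) else "none"
    } else if (!reg[1] && !reg[2] && reg[3]) {
      paste("advanced", g[3])
    } else {
      "none"
    }
  })
  patterns <- setNames(lapply(seq_len(nrow(grid)), function(i) unlist(grid[i, ])),
                       sprintf("p%02d", seq_len(nrow(grid))))
  st <- assign_stage(make_profiles(patterns), "M1")
  got <- ifelse(st$stage == "none", "none", paste(st$stage, st$direction))
  expect_equal(got, unname(expected))
  expect_true(all(st$stageable))
  # stages partition the staged set
  expect_true(all(table(st$accession[st$stage != "none"]) == 1))
})

test_that("untested staging ages block staging; direction flips are annotated", {
  st <- assign_stage(make_profiles(list(
    a = c("up", "untested", "up"),
    b = c("up", "down", "down"),
    c = c("none", "up", "down")
  )), "M1")
  expect_equal(st$stage, rep("none", 3))
  expect_false(st$stageable[st$accession == "a"])
  expect_true(st$direction_flip[st$accession == "b"])
  expect_true(st$direction_flip[st$accession == "c"])
})

test_that("cross-model rule keeps same-direction support and allows later onset", {
  ref <- make_profiles(list(
    early_up   = c("up", "up", "up"),
    mid_down   = c("none", "down", "down"),
    adv_up     = c("none", "none", "up"),
    unsupported = c("up", "up", "up"),
    inverse    = c("up", "up", "up")
  ), model = "REF")
  sec <- make_profiles(list(
    early_up   = c("none", "none", "up"),    # late support allowed
    mid_down   = c("none", "down", "down"),
    adv_up     = c("none", "none", "up"),
    unsupported = c("none", "none", "none"),
    inverse    = c("down", "down", "down")   # wrong direction
  ), model = "SEC")
  profiles <- rbind(ref, sec)
  class(profiles) <- class(ref)
  st <- assign_stage(profiles, "REF")
  marps <- cross_model_filter(st, profiles, "SEC")
  expect_setequal(marps$accession, c("early_up", "mid_down", "adv_up"))
  expect_equal(marps$supporting_ages[marps$accession == "early_up"], "12")
  expect_equal(marps$supporting_ages[marps$accession == "mid_down"], "6,12")
  expect_equal(marp_counts(marps),
               c(early = 1L, middle = 1L, advanced = 1L))
  # relaxing the direction requirement never shrinks the MARP set
  relaxed <- cross_model_filter(st, profiles, "SEC", require_same_direction = FALSE)
  expect_true(all(marps$accession %in% relaxed$accession))
  expect_true("inverse" %in% relaxed$accession)
  # fold-change columns present for both models
  expect_true(all(c("log2_fc_REF_3m", "log2_fc_SEC_12m") %in% names(marps)))
})

test_that("temporal profiles mark untested contrasts distinctly from tested none", {
  tc <- toy_contrast(n_proteins = 30, seed = 5, effect = c(2, -2))
  pm <- tc$pm
  pm$exprs[3, 1] <- NA        # P003 fails the consistency filter
  cc <- run_contrast(pm, tc$sheet, "M1", 3, fdr_config())
  prof <- temporal_profiles(list(cc), universe = rownames(pm$exprs))
  expect_equal(prof$direction[prof$accession == "P003"], "untested")
  expect_true(is.na(prof$log2_fc[prof$accession == "P003"]))
  tested <- prof[prof$accession != "P003", ]
  expect_false(any(tested$direction == "untested"))
})

test_that("top-regulated selection matches an independent sort", {
  pats <- list(a = c("up", "up", "up"), b = c("up", "up", "up"),
               c = c("up", "up", "up"), d = c("down", "down", "down"))
  fcs <- list(a = c(0.8, 1, 1), b = c(2.5, 2, 2), c = c(1.4, 1, 1),
              d = c(-3, -3, -3))
  profiles <- rbind(make_profiles(pats, "REF", fc = fcs),
                    make_profiles(pats, "SEC", fc = fcs))
  class(profiles) <- c("temporal_profiles", "data.frame")
  st <- assign_stage(profiles, "REF")
  marps <- cross_model_filter(st, profiles, "SEC")
  top1 <- top_regulated_heatmap_table(marps, "REF", k = 1)
  expect_equal(top1$accession[top1$direction == "up"], "b")   # max |FC| at onset
  expect_equal(top1$accession[top1$direction == "down"], "d")
  top2 <- top_regulated_heatmap_table(marps, "REF", k = 2)
  up2 <- top2[top2$direction == "up", ]
  expect_equal(up2$accession, c("b", "c"))                    # brute-force order
  expect_equal(up2$rank, 1:2)
  topk <- top_regulated_heatmap_table(marps, "REF", k = 74)
  expect_match(attr(topk, "note")[1], "only")
})
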