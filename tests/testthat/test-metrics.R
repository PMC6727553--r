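test_that("consensus masks mark pointwise agreement", {
  a <- hypnogram(c("W", "N1", "R"))
  expect_equal(consensus_epochs(a, a), rep(TRUE, 3))
  b <- hypnogram(c("N1", "W", "N2"))
  expect_equal(consensus_epochs(a, b), rep(FALSE, 3))
  c3 <- hypnogram(c("W", "N2", "R"))
  expect_equal(consensus_epochs(a, c3), c(TRUE, FALSE, TRUE))
  expect_error(consensus_epochs(a, hypnogram(c("W", "R"))), "length")
})

test_that("confusion matrices count reference x test pairs", {
  a <- hypnogram(c("W", "W", "R"))
  b <- hypnogram(c("W", "R", "R"))
  cm <- confusion(a, b)
  expect_equal(cm["W", "W"], 1L)
  expect_equal(cm["W", "R"], 1L)
  expect_equal(cm["R", "R"], 1L)
  expect_equal(sum(cm), 3L)
  ident <- confusion(a, a)
  expect_equal(sum(ident) - sum(diag(ident)), 0L)
  # masked counting
  cm2 <- confusion(a, b, mask = c(TRUE, FALSE, TRUE))
  expect_equal(sum(cm2), 2L)
})

test_that("published 5-stage validation table reproduces its statistics", {
  cm <- validation_confusion(5)
  expect_equal(sum(cm), 168656L)
  expect_equal(unname(rowSums(cm)),
               c(80440L, 48144L, 21434L, 5329L, 13309L))
  expect_equal(unname(colSums(cm)),
               c(82436L, 45488L, 21545L, 5081L, 14106L))
  expect_equal(overall_agreement(cm), 92.32, tolerance = 1e-4)
  expect_equal(round(cohens_kappa(cm), 2), 0.88)
  expect_equal(kappa_band(cohens_kappa(cm)), "excellent")
  sm <- stage_metrics(cm, reference_axis = "columns")
  expect_equal(sm$se[sm$stage == "W"], 94.4, tolerance = 1e-3)
  expect_equal(sm$se[sm$stage == "N1"], 91.13, tolerance = 1e-4)
  expect_equal(sm$ppv[sm$stage == "W"], 96.75, tolerance = 1e-4)
  expect_equal(sm$sp[sm$stage == "W"], 96.96, tolerance = 1e-4)
  expect_equal(sm$npv[sm$stage == "W"], 94.77, tolerance = 1e-4)
})

test_that("published 3-stage validation table reproduces its statistics", {
  cm <- validation_confusion(3)
  expect_equal(sum(cm), 168656L)
  expect_equal(overall_agreement(cm), 94.97, tolerance = 1e-4)
  expect_equal(round(cohens_kappa(cm), 2), 0.91)
  sm <- stage_metrics(cm, reference_axis = "columns")
  expect_equal(sm$se[sm$stage == "N"], 96.5, tolerance = 1e-3)
  expect_equal(sm$se[sm$stage == "R"], 90.48, tolerance = 1e-4)
  expect_equal(sm$sp[sm$stage == "N"], 94.49, tolerance = 1e-4)
  # collapsing the 5-stage table yields the 3-stage table
  cm5 <- validation_confusion(5)
  grp <- c(W = "W", N1 = "N", N2 = "N", TS = "N", R = "R")
  coll <- rowsum(t(rowsum(cm5, grp[rownames(cm5)])), grp[colnames(cm5)])
  coll <- t(coll)[c("W", "N", "R"), c("W", "N", "R")]
  expect_equal(unname(coll), unname(cm), ignore_attr = TRUE)
  expect_gte(overall_agreement(coll), overall_agreement(cm5))
})

test_that("kappa has its characteristic fixed points and invariances", {
  expect_equal(cohens_kappa(matrix(c(40, 10, 10, 40), 2)), 0.6,
               tolerance = 1e-12)
  # diagonal matrix: kappa 1
  expect_equal(cohens_kappa(diag(c(5, 9, 2))), 1)
  # outer product of margins: chance agreement, kappa 0
  p <- c(0.5, 0.3, 0.2)
  m <- 1000 * (p %o% p)
  expect_equal(cohens_kappa(m), 0, tolerance = 1e-12)
  # invariance under simultaneous permutation
  set.seed(21)
  cm <- matrix(rpois(25, 40), 5)
  perm <- sample(5)
  expect_equal(cohens_kappa(cm[perm, perm]), cohens_kappa(cm),
               tolerance = 1e-12)
  # degenerate single-category table
  one <- matrix(0, 2, 2); one[1, 1] <- 10
  expect_true(is.na(cohens_kappa(one)))
})

test_that("stage metrics respect the reference axis and recover the trace", {
  cm <- validation_confusion(5)
  sm_rows <- stage_metrics(cm, "rows")
  # sum of per-stage TPs equals the trace irrespective of axis
  tp <- vapply(seq_len(5), function(i) cm[i, i], 0)
  expect_equal(sum(tp), sum(diag(cm)))
  # rows-reference SE of wake equals its columns-reference PPV
  sm_cols <- stage_metrics(cm, "columns")
  expect_equal(sm_rows$se[1], sm_cols$ppv[1], tolerance = 1e-9)
  # perfect diagonal: everything 100
  d <- stage_metrics(diag(c(4, 4, 4)) * 10L)
  expect_true(all(unlist(d[c("se", "sp", "ppv", "npv")]) == 100))
  # zero-denominator statistics are NA, not 0 or 100
  z <- matrix(c(10, 0, 5, 0), 2, dimnames = list(c("a", "b"), c("a", "b")))
  expect_true(is.na(stage_metrics(z, "rows")$se[2]))
})

test_that("kappa interpretation bands follow the published scale", {
  expect_equal(kappa_band(0.88), "excellent")
  expect_equal(kappa_band(0.78), "substantial")
  expect_equal(kappa_band(-0.1), "poor")
  expect_equal(kappa_band(0.0), "slight")
  expect_equal(kappa_band(0.205), "slight")   # gap value by 2-dp rounding
  expect_equal(kappa_band(0.41), "moderate")
  expect_equal(kappa_band(0.601), "moderate")
})

test_that("per-subject summary reproduces the published mean and spread", {
  subj <- validation_subjects()
  s <- subject_summary(subj$agr_5stage)
  expect_equal(round(s$mean, 2), 91.94)
  expect_equal(round(s$sd, 2), 2.93)
  s3 <- subject_summary(subj$agr_3stage)
  expect_equal(round(s3$mean, 2), 94.39)
  expect_equal(round(subject_summary(subj$kappa_5stage)$mean, 2), 0.87)
  expect_equal(subject_summary(rep(5, 4))$sd, 0)
  expect_true(is.na(subject_summary(3.2)$sd))
})

test_that("hypnogram duration summaries tally stages per light period", {
  all_n1 <- hypnogram(rep("N1", 12 * 360))  # 12 h of 10-s epochs
  s <- summarize_hypnogram(all_n1)
  expect_equal(s$light_h[s$stage == "N1"], 12)
  expect_equal(s$dark_h[s$stage == "N1"], 0)
  alt <- hypnogram(rep(c("W", "R"), 180))   # 1 h alternating
  s2 <- summarize_hypnogram(alt)
  expect_equal(s2$light_h[s2$stage == "W"], 0.5)
  expect_equal(s2$light_h[s2$stage == "R"], 0.5)
  # randomized hypnogram against a direct tally
  set.seed(30)
  lab <- sample(stage_levels(5), 5000, replace = TRUE)
  hyp <- hypnogram(lab)
  s3 <- summarize_hypnogram(hyp, light_onset_s = 3600,
                            start_time_s = 7200)
  mid <- 7200 + (seq_along(lab) - 0.5) * 10
  lightmask <- ((mid - 3600) %% 86400) < 12 * 3600
  for (st in stage_levels(5)) {
    expect_equal(s3$light_h[s3$stage == st],
                 sum(lab == st & lightmask) * 10 / 3600)
  }
})
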