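ep_row <- function(w = 0, n = 0, r = 0, a = 0) {
  data.frame(index_w = w, index_n = n, index_r = r, index_a = a,
             snra = n + r + a)
}

seg_rows <- function(pr_lo = 0, pr_delta = 0, pr_alpha = 0,
                     i1 = 1, i2 = 0, i3 = 0, i4 = 1) {
  rep5 <- function(x) if (length(x) == 1) rep(x, 5) else x
  data.frame(pr_lo = rep5(pr_lo), pr_delta = rep5(pr_delta),
             pr_alpha = rep5(pr_alpha), index_1 = rep5(i1),
             index_2 = rep5(i2), index_3 = rep5(i3), index_4 = rep5(i4))
}

test_that("artifact detection fires strictly above the 0.9 ratio", {
  expect_true(detect_artifact(ep_row(n = 0.02, r = 0.02, a = 0.95)))
  expect_false(detect_artifact(ep_row(n = 0.5, r = 0.5, a = 0)))
  expect_false(detect_artifact(ep_row(n = 0.05, r = 0.05, a = 0.9)))  # = 0.9
  d <- classify_epoch(ep_row(n = 0.02, r = 0.02, a = 0.95), seg_rows())
  expect_equal(d$stage, "W")
  expect_true(d$artifact)
  expect_equal(d$testing_point, 1)
})

test_that("condition assignment is the arg-max with wake-first ties", {
  expect_equal(classify_condition(ep_row(0.771, 0.194, 0.036)), "W")
  expect_equal(classify_condition(ep_row(0.122, 0.744, 0.134)), "N")
  expect_equal(classify_condition(ep_row(0.134, 0.178, 0.689)), "R")
  expect_equal(classify_condition(ep_row(0.5, 0.5, 0.2)), "W")
  expect_equal(classify_condition(ep_row(0.1, 0.4, 0.4)), "N")
  cfg <- tree_config(tie_priority = c("R", "N", "W"))
  expect_equal(classify_condition(ep_row(0.5, 0.5, 0.5), cfg), "R")
})

test_that("W-branch refinement follows testing points 2 and 3", {
  s <- seg_rows(i1 = 0.1, i2 = 0.5)
  s$pr_lo[3] <- 0.6
  expect_equal(refine_stage_W(s), "W")                    # tp2 overrides
  expect_equal(refine_stage_W(seg_rows(i1 = 0.496, i2 = 0.194)), "W")  # tp3
  s2 <- seg_rows(i1 = 0.496, i2 = 0.194)
  s2$index_2[4] <- 0.6                                    # one segment fails
  expect_equal(refine_stage_W(s2), "N1")
  # boundary: pr_lo exactly 0.5 does not count
  expect_equal(refine_stage_W(seg_rows(pr_lo = 0.5, i1 = 0, i4 = 1)), "N1")
})

test_that("N-branch refinement follows testing points 4, 5, 6 in order", {
  s <- seg_rows()
  s$pr_lo[c(2, 5)] <- 0.7
  expect_equal(refine_stage_N(s), "W")                    # tp4
  expect_equal(refine_stage_N(seg_rows(i3 = 0.615, i4 = 0.145)), "TS")  # tp5
  expect_equal(refine_stage_N(seg_rows(pr_delta = c(0.6, 0.6, 0.6, 0.3, 0.3))),
               "N2")
  expect_equal(refine_stage_N(seg_rows(pr_delta = c(0.6, 0.6, 0.3, 0.3, 0.3))),
               "N1")
  # tp4 pre-empts tp5; tp5 pre-empts tp6
  s2 <- seg_rows(i3 = 1, i4 = 0, pr_delta = 0.9)
  expect_equal(refine_stage_N(s2), "TS")
  s2$pr_lo[1:2] <- 0.8
  expect_equal(refine_stage_N(s2), "W")
})

test_that("R-branch refinement follows testing point 7 with a strict boundary", {
  s <- seg_rows()
  s$pr_alpha[1] <- 0.35
  expect_equal(refine_stage_R(s), "TS")
  expect_equal(refine_stage_R(seg_rows(pr_alpha = 0.3)), "R")  # exactly 0.3
  expect_equal(refine_stage_R(seg_rows(pr_alpha = 0.29)), "R")
})

test_that("tree implementation agrees with the independent rule transcription", {
  set.seed(2024)
  cfg <- tree_config()
  for (i in seq_len(2000)) {
    inp <- random_epoch_inputs()
    got <- classify_epoch(inp$ep, inp$segs, cfg)$stage
    expect_identical(got, oracle_classify(inp$ep, inp$segs, cfg))
  }
})

test_that("scoring a recording is total and deterministic", {
  hyp <- generate_hypnogram(60, seed = 3)
  rec <- generate_recording(hyp, seed = 4)
  fit1 <- score_recording(rec)
  expect_length(fit1$hypnogram, 60)
  expect_false(anyNA(fit1$hypnogram))
  fit2 <- score_recording(rec)
  expect_identical(as.character(fit1$hypnogram), as.character(fit2$hypnogram))
  # every decision carries a condition and a testing point
  expect_true(all(fit1$decisions$condition %in% c("W", "N", "R", "A")))
  expect_true(all(fit1$decisions$testing_point %in% 1:7))
})

test_that("stage collapse merges the NREM family and is length-preserving", {
  h5 <- hypnogram(c("W", "N1", "N2", "TS", "R"))
  h3 <- collapse_to_3stage(h5)
  expect_equal(as.character(h3), c("W", "N", "N", "N", "R"))
  allr <- collapse_to_3stage(hypnogram(rep("R", 7)))
  expect_equal(as.character(allr), rep("R", 7))
  expect_error(collapse_to_3stage(allr), "5-stage")
})

test_that("collapsed agreement never falls below 5-stage agreement", {
  set.seed(15)
  lev <- stage_levels(5)
  for (i in 1:10) {
    a <- hypnogram(sample(lev, 100, replace = TRUE))
    b <- hypnogram(sample(lev, 100, replace = TRUE))
    agr5 <- mean(as.character(a) == as.character(b))
    agr3 <- mean(as.character(collapse_to_3stage(a)) ==
                 as.character(collapse_to_3stage(b)))
    expect_gte(agr3, agr5)
  }
})
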