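test_that("mid-plane split follows the floor rule and conserves indices", {
  s240 <- split_indices(240)
  expect_equal(range(s240$lower), c(1, 120))
  expect_equal(range(s240$upper), c(121, 240))
  s155 <- split_indices(155)
  expect_equal(range(s155$lower), c(1, 77))
  expect_equal(range(s155$upper), c(78, 155))
  for (n in c(2, 3, 7, 40, 155)) {
    s <- split_indices(n)
    expect_length(intersect(s$lower, s$upper), 0)
    expect_setequal(c(s$lower, s$upper), seq_len(n))
  }
  expect_error(split_indices(1), "ostvol_split_error")
})

test_that("subregion volumes count each label and the mask directly", {
  labels <- array(0L, c(3, 3, 3))
  labels[1, 1, 1] <- 1L
  labels[c(2, 6, 10)] <- 2L
  labels[c(15, 20)] <- 4L
  vol <- labeled_volume(labels, array(1:27 * 1.0, c(3, 3, 3)))
  full <- structure(list(mask = array(TRUE, c(3, 3, 3)), voxel_count = 27L,
                         threshold = 0), class = "brain_mask")
  v <- subregion_volumes(vol, full)
  expect_equal(v, c(Vb = 27, Vwt = 6, Vet = 2, Vncr = 1, Ved = 3))

  empty <- labeled_volume(array(0L, c(3, 3, 3)))
  v0 <- subregion_volumes(empty, full)
  expect_equal(unname(v0[c("Vwt", "Vet", "Vncr", "Ved")]), rep(0, 4))
})

test_that("half counts match brute-force voxel iteration and sum to whole counts", {
  for (seed in c(1, 2, 3)) {
    vol <- random_tiny_volume(seed)
    mask <- brain_mask(vol)
    for (ap in c("mid_sagittal", "mid_coronal", "mid_horizontal")) {
      ax <- split_axis(vol, ap)
      halves <- split_indices(vol$shape[ax])
      lower <- subregion_volumes(vol, mask, ax, halves$lower)
      upper <- subregion_volumes(vol, mask, ax, halves$upper)
      whole <- subregion_volumes(vol, mask)
      expect_equal(lower + upper, whole)
      expect_equal(lower, brute_counts(vol$labels, mask$mask, ax, halves$lower))
      expect_equal(upper, brute_counts(vol$labels, mask$mask, ax, halves$upper))
    }
  }
})

test_that("approach feature vectors have 12 entries in the documented order", {
  vol <- random_tiny_volume(4)
  mask <- brain_mask(vol)
  fv <- extract_approach_features(vol, mask, "mid_coronal")
  expect_length(fv, 12L)
  expect_equal(names(fv),
               c("lower_Vb", "lower_Vwt", "lower_Vet", "lower_Vncr", "lower_Ved",
                 "upper_Vb", "upper_Vwt", "upper_Vet", "upper_Vncr", "upper_Ved",
                 "whole_Vb", "whole_Vwt"))
  expect_true(all(fv >= 0) && all(fv == floor(fv)))
  # the whole-brain block is plane-independent
  fvs <- sapply(c("mid_sagittal", "mid_coronal", "mid_horizontal"),
                function(ap) extract_approach_features(vol, mask, ap))
  expect_equal(unique(fvs["whole_Vb", ]), fv[["whole_Vb"]])
  expect_equal(unique(fvs["whole_Vwt", ]), fv[["whole_Vwt"]])
})

test_that("a tumor confined to one sagittal half leaves the other half empty", {
  labels <- array(0L, c(8, 6, 6))
  labels[2:3, 3:4, 3:4] <- 2L
  labels[2, 3, 3] <- 4L
  intensity <- array(0, c(8, 6, 6))
  intensity[2:7, 2:5, 2:5] <- 100
  vol <- labeled_volume(labels, intensity)
  fv <- extract_approach_features(vol, brain_mask(vol), "mid_sagittal")
  expect_true(all(fv[c("upper_Vwt", "upper_Vet", "upper_Vncr", "upper_Ved")] == 0))
  expect_gt(fv[["lower_Vwt"]], 0)
})

test_that("mirror reflection swaps the sagittal half blocks", {
  vol <- random_tiny_volume(6, shape = c(8L, 6L, 5L))  # even sagittal size
  mask <- brain_mask(vol)
  fv <- extract_approach_features(vol, mask, "mid_sagittal")
  refl <- labeled_volume(vol$labels[8:1, , ], vol$intensity[8:1, , ])
  mr <- brain_mask(refl)
  fr <- extract_approach_features(refl, mr, "mid_sagittal")
  expect_equal(unname(fr[1:5]), unname(fv[6:10]))
  expect_equal(unname(fr[6:10]), unname(fv[1:5]))
  expect_equal(fr[11:12], fv[11:12])
})

test_that("clinical fusion appends age then resection with the published encoding", {
  vol <- random_tiny_volume(8)
  fv <- extract_approach_features(vol, brain_mask(vol), "mid_horizontal")
  f13 <- fuse_clinical(fv, age = 62.1)
  expect_length(f13, 13L)
  expect_equal(f13[["age"]], 62.1)
  f14 <- fuse_clinical(fv, age = 62.1, resection = "GTR",
                       include_resection = TRUE)
  expect_length(f14, 14L)
  expect_equal(f14[["resection"]], 1)
  expect_equal(encode_resection(c("GTR", "STR", NA)), c(1L, 0L, 0L))
  expect_error(encode_resection("partial"), "ostvol_parse_error")
  expect_error(fuse_clinical(f13, age = 50), "ostvol_length_error")
  expect_error(fuse_clinical(fv, age = -1), "ostvol_parse_error")
})

test_that("features recover the generator's ground-truth counts", {
  cfg <- cohort_config(preset = "tiny", seed = 31)
  s <- generate_subject("mid", cfg, subject_seed = 77)
  mask <- brain_mask(s$volume)
  for (ax in 1:3) {
    ap <- c("mid_sagittal", "mid_coronal", "mid_horizontal")[ax]
    fv <- extract_approach_features(s$volume, mask, ap)
    for (side in c("lower", "upper")) {
      truth <- s$truth$counts[[paste0("axis", ax, "_", side)]]
      for (q in c("Vwt", "Vet", "Vncr", "Ved")) {
        expect_equal(fv[[paste0(side, "_", q)]], truth[[q]])
      }
      expect_equal(fv[[paste0(side, "_Vb")]], truth[["Vb"]], tolerance = 0.01)
    }
  }
})
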