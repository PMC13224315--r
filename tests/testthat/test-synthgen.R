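# Synthetic cohort tables and imaging phantoms.

test_that("cohort spec validation lists offending fields", {
  expect_error(cohort_spec(n_subjects = 1), "n_subjects")
  expect_error(cohort_spec(glx_sd = c(rest = -1, movie = 0.5)), "glx_sd")
  expect_error(cohort_spec(subject_metab_frac = 2), "subject_metab_frac")
  err <- tryCatch(cohort_spec(n_subjects = 0, residual_sd = -1),
                  error = conditionMessage)
  expect_match(err, "n_subjects")
  expect_match(err, "residual_sd")
})

test_that("noiseless generative model shifts H by exactly the rest effect", {
  spec <- cohort_spec(n_subjects = 6, glx_sd = c(rest = 0, movie = 0),
                      gaba_sd = c(rest = 0, movie = 0),
                      subject_intercept_sd = 0, residual_sd = 0,
                      beta_ei = 0, seed = 2)
  tab <- generate_cohort_table(spec)
  wide <- merge(tab[tab$condition == "rest", c("subject_id", "hurst")],
                tab[tab$condition == "movie", c("subject_id", "hurst")],
                by = "subject_id")
  expect_equal(wide$hurst.x - wide$hurst.y, rep(spec$beta_rest, 6),
               tolerance = 1e-12)
  # metabolites collapse to the condition means
  expect_equal(unique(tab$glx_mM[tab$condition == "rest"]), 9.84)
  expect_equal(unique(tab$gaba_mM[tab$condition == "movie"]), 5.23)
})

test_that("cohort tables are deterministic given the seed", {
  spec <- cohort_spec(n_subjects = 10, seed = 33)
  expect_identical(generate_cohort_table(spec), generate_cohort_table(spec))
  spec2 <- spec
  spec2$seed <- 34L
  expect_false(identical(generate_cohort_table(spec),
                         generate_cohort_table(spec2)))
})

test_that("large cohorts reproduce the target metabolite distribution", {
  tab <- generate_cohort_table(cohort_spec(n_subjects = 2000, seed = 8))
  rest <- tab[tab$condition == "rest", ]
  movie <- tab[tab$condition == "movie", ]
  expect_equal(mean(rest$glx_mM), 9.84, tolerance = 0.1 / 9.84)
  expect_equal(sd(rest$glx_mM), 1.06, tolerance = 0.08)
  expect_equal(mean(movie$glx_mM), 10.04, tolerance = 0.015)
  expect_equal(mean(rest$gaba_mM), 5.48, tolerance = 0.015)
  expect_equal(mean(movie$gaba_mM), 5.23, tolerance = 0.015)
  expect_equal(tab$ei, tab$glx_mM / tab$gaba_mM, tolerance = 1e-9)
  # within-subject metabolite correlation induced by the shared offset
  wide <- merge(rest[, c("subject_id", "glx_mM")],
                movie[, c("subject_id", "glx_mM")], by = "subject_id")
  expect_gt(cor(wide$glx_mM.x, wide$glx_mM.y), 0.1)
})

test_that("phantom echoes scale as the tissue decay of the first echo", {
  spec <- phantom_spec(dim = c(8, 8, 8), n_frames = 64, noise_sd = 0,
                       seed = 4)
  ph <- generate_phantom_subject(spec)
  e1 <- ph$series$echo_volumes[[1]]
  e3 <- ph$series$echo_volumes[[3]]
  for (tis in c("gm", "wm", "csf")) {
    vox <- which(ph$masks[[tis]])[1]
    idx <- arrayInd(vox, spec$dim)
    s1 <- mean(e1[idx[1], idx[2], idx[3], ])
    s3 <- mean(e3[idx[1], idx[2], idx[3], ])
    ratio_expected <- exp(-(spec$te_ms[3] - spec$te_ms[1]) /
                            spec$tissue_t2star_ms[[tis]])
    expect_equal(s3 / s1, ratio_expected, tolerance = 1e-10)
  }
})

test_that("tissue labels partition the grid and the MRS voxel stays inside", {
  spec <- phantom_spec(dim = c(10, 10, 10), n_frames = 64, seed = 1)
  ph <- generate_phantom_subject(spec)
  counts <- table(ph$tissue_labels)
  expect_equal(sum(counts), 1000)
  expect_true(all(c("gm", "wm", "csf") %in% names(counts)))
  expect_equal(sum(ph$mrs_mask), spec$mrs_size^3)
  # jitter that pushes the voxel off the grid is a placement error
  bad <- phantom_spec(dim = c(10, 10, 10), n_frames = 64,
                      mrs_center = c(5, 1, 5), mrs_jitter = 0)
  expect_error(generate_phantom_subject(bad), "outside the grid")
})

test_that("single-tissue phantoms recover their target H through the estimator", {
  ests <- vapply(1:20, function(i) {
    paths <- fractalEI:::with_seed(100 + i,
      fractalEI:::fgn_sample_matrix(0.7, 1, 480, 27))
    vol <- array(t(paths), c(3, 3, 3, 480))
    mean(hurst_map(vol, 1.5)$hurst)
  }, numeric(1))
  expect_equal(mean(ests), 0.7, tolerance = 0.05)
})

test_that("zero jitter across subjects gives a consensus Dice of 1", {
  spec <- phantom_spec(dim = c(10, 10, 10), n_frames = 64, mrs_jitter = 0)
  masks <- lapply(1:3, function(i) {
    s <- spec
    s$seed <- i
    generate_phantom_subject(s)$mrs_mask
  })
  out <- consensus_mask(masks)
  expect_equal(out$mean_dice, 1)
  expect_equal(out$consensus, masks[[1]])
})

test_that("phantom generation is deterministic given the seed", {
  spec <- phantom_spec(dim = c(6, 6, 6), n_frames = 64, noise_sd = 1,
                       mrs_size = 2L, mrs_jitter = 0L, seed = 12)
  a <- generate_phantom_subject(spec)
  b <- generate_phantom_subject(spec)
  expect_identical(a$series$echo_volumes, b$series$echo_volumes)
  expect_identical(a$motion, b$motion)
  expect_identical(a$mrs_mask, b$mrs_mask)
})
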