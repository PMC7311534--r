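noiseless_phantom <- function() {
  fx_memo("phantom_noiseless", function() {
    generate_phantom(phantom_spec(shape = c(10, 10, 3), inputs = fx_inputs()))
  })
}

test_that("noiseless dictionary mapping recovers on-grid ground truth exactly", {
  ph <- noiseless_phantom()
  tissue <- mask_in(ph$mask, 1:3)
  maps <- map_volume(ph$volume, tissue, fx_inputs(), acquisition_params(),
                     method = "dictionary", dictionary = fx_dict())
  sel <- tissue & maps$valid
  expect_true(all(maps$valid[tissue]))
  expect_equal(maps$af[sel], ph$truth$af[sel])
  expect_equal(maps$mtt[sel], ph$truth$mtt[sel])
  expect_equal(maps$dv[sel], ph$truth$dv[sel], tolerance = 1e-6)
  expect_true(all(maps$inner_product[sel] > 1 - 1e-9))
  # unmasked voxels carry no estimates
  expect_true(all(is.na(maps$af[!tissue])))
})

test_that("dictionary and fitting maps agree on a noiseless phantom", {
  ph <- noiseless_phantom()
  # one voxel per tissue class is enough to compare the estimators
  tissue <- array(FALSE, dim(ph$mask))
  for (lab in 1:3) tissue[which(ph$mask == lab)[1]] <- TRUE
  mdict <- map_volume(ph$volume, tissue, fx_inputs(), acquisition_params(),
                      method = "dictionary", dictionary = fx_dict())
  mfit <- map_volume(ph$volume, tissue, fx_inputs(), acquisition_params(),
                     method = "fit")
  for (p in c("af", "dv", "mtt")) {
    rel <- abs(mdict[[p]][tissue] - mfit[[p]][tissue]) / ph$truth[[p]][tissue]
    expect_lt(mean(rel), 0.02)
  }
})

test_that("flat-signal voxels are flagged invalid and bad geometry errors", {
  ph <- noiseless_phantom()
  vol <- ph$volume
  flat_vox <- which(ph$mask == 1L)[1]
  nxyz <- prod(dim(ph$mask))
  vol[flat_vox + (seq_len(dim(vol)[4]) - 1) * nxyz] <- 500  # constant signal
  tissue <- ph$mask == 1L
  maps <- map_volume(vol, tissue, fx_inputs(), acquisition_params(),
                     method = "dictionary", dictionary = fx_dict())
  expect_false(maps$valid[flat_vox])
  expect_true(is.na(maps$af[flat_vox]))

  expect_error(map_volume(ph$volume, ph$mask[1:5, , ], fx_inputs()),
               class = "dcedict_geometry_error")
  expect_error(map_volume(ph$volume, array(FALSE, dim(ph$mask)), fx_inputs()),
               class = "dcedict_invalid_inputs")
})

test_that("difference maps are antisymmetric and NA-propagating", {
  ph <- noiseless_phantom()
  tissue <- mask_in(ph$mask, 1:2)
  m1 <- map_volume(ph$volume, tissue, fx_inputs(), acquisition_params(),
                   method = "dictionary", dictionary = fx_dict())
  d0 <- difference_map(m1, m1)
  expect_true(all(d0$af[tissue] == 0))
  m2 <- m1
  m2$af <- m1$af + 0.05
  m2$valid[which(tissue)[1]] <- FALSE
  d12 <- difference_map(m1, m2)
  d21 <- difference_map(m2, m1)
  expect_equal(d12$af, -d21$af)
  expect_true(is.na(d12$af[which(tissue)[1]]))  # invalid in one input
  m3 <- m1
  m3$af <- m3$af[1:5, , , drop = FALSE]
  expect_error(difference_map(m1, m3), class = "dcedict_geometry_error")
})

test_that("ROI summaries match direct arithmetic and identical maps give p = 1", {
  ph <- noiseless_phantom()
  tissue <- mask_in(ph$mask, 1:3)
  maps <- map_volume(ph$volume, tissue, fx_inputs(), acquisition_params(),
                     method = "dictionary", dictionary = fx_dict())
  labels <- array(0L, dim(ph$mask))
  labels[mask_in(ph$mask, 1:2)] <- ph$mask[mask_in(ph$mask, 1:2)]
  res <- roi_compare(maps, maps, labels)
  expect_true(all(res$p_value == 1))
  expect_true(all(res$t_statistic == 0))
  row <- dplyr::filter(res, roi == 1, property == "af")
  vox <- maps$af[labels == 1L & maps$valid]
  expect_equal(row$mean_a, mean(vox))
  expect_equal(row$sd_a, sd(vox))
  expect_equal(row$n_a, length(vox))
})

test_that("roi_compare separates genuinely different parameter populations", {
  dims <- c(10, 10, 2)
  labels <- array(0L, dims); labels[1:100] <- 1L
  set.seed(77)
  mk <- function(mu) {
    m <- list(af = array(NA_real_, dims), dv = array(NA_real_, dims),
              mtt = array(NA_real_, dims), valid = array(FALSE, dims))
    m$af[1:100] <- rnorm(100, mu, 0.05)
    m$dv[1:100] <- rnorm(100, 0.4, 0.05)
    m$mtt[1:100] <- rnorm(100, 20, 2)
    m$valid[1:100] <- TRUE
    structure(m, class = "dce_maps")
  }
  res <- roi_compare(mk(0.3), mk(0.6), labels)
  expect_lt(res$p_value[res$property == "af"], 0.05)
  # too-small ROIs are excluded with a warning
  labels2 <- labels; labels2[2:100] <- 0L
  expect_warning(res2 <- roi_compare(mk(0.3), mk(0.6), labels2))
  expect_equal(nrow(res2), 0)
})

test_that("maps survive a NIfTI write/read round trip", {
  ph <- noiseless_phantom()
  tissue <- ph$mask == 1L
  maps <- map_volume(ph$volume, tissue, fx_inputs(), acquisition_params(),
                     method = "dictionary", dictionary = fx_dict())
  dir <- withr::local_tempdir()
  paths <- write_maps(maps, file.path(dir, "test"))
  expect_true(all(file.exists(file.path(dir, c("test_af.nii.gz",
                                               "test_mtt.nii.gz")))))
  back <- read_volume(file.path(dir, "test_af.nii.gz"))
  expect_equal(array(as.numeric(back), dim(back)), maps$af, tolerance = 1e-6)
})
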