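test_that("accuracy is 100 for identical masks and 0 for disjoint ones", {
  v <- array(0, dim = c(10, 10, 4)); v[3:6, 3:6, 2:3] <- 1
  m <- toy_mask(v)
  expect_equal(accuracy(m, m, 0.65), 100)
  w <- array(0, dim = c(10, 10, 4)); w[8:9, 8:9, 2:3] <- 1
  expect_equal(accuracy(toy_mask(w), m, 0.65), 0)
  empty <- toy_mask(array(0, dim = c(10, 10, 4)))
  expect_error(accuracy(m, empty, 0.65), "threshold")
  # grids must match
  other <- toy_mask(v, spacing = 1)
  expect_error(accuracy(other, m, 0.65), "grid")
})

test_that("the worked 2D figure arithmetic is reproduced", {
  # template: rotated square thresholded at 0.65 covers 34 mm^2 (136 px);
  # subject overlaps it on 31 mm^2 (124 px) -> 91.2% (the printed figure
  # truncates 31/34 to 91.1%)
  tv <- array(0, dim = c(20, 20, 1)); tv[3:18, 3:10, 1] <- 1  # 128 px
  tv[3:10, 11, 1] <- 1                                        # 136 px
  sv <- array(0, dim = c(20, 20, 1))
  idx <- which(tv == 1)[1:124]; sv[idx] <- 1
  tm <- toy_mask(tv); sm <- toy_mask(sv)
  expect_equal(sum(tv > 0.65), 136)
  acc <- accuracy(sm, tm, 0.65)
  expect_equal(acc, 100 * 31 / 34)
  expect_equal(round(acc, 1), 91.2)
})

test_that("between-subject overlap averages subject voxels only", {
  v <- array(0, dim = c(12, 12, 1)); v[3:8, 3:8, 1] <- 1
  m <- toy_mask(v)
  expect_equal(between_subject_overlap(list(m, m, m), m, 0.65), 100)
  # one mask: its own superlevel count over the template count (the
  # template voxel never enters the between-subject average)
  w <- array(0, dim = c(12, 12, 1)); w[4:9, 3:8, 1] <- 1
  wm <- toy_mask(w)
  expect_equal(between_subject_overlap(list(wm), m, 0.65),
               100 * sum(w > 0.65) / sum(v > 0.65))
  expect_error(between_subject_overlap(list(), m, 0.65), "at least one")
})

test_that("overlap metrics match the brute-force pixel counter", {
  # three shifted copies on a toy grid
  base <- array(0, dim = c(16, 16, 1))
  mk <- function(dx) {
    v <- base; v[(4 + dx):(11 + dx), 4:11, 1] <- 1; toy_mask(v)
  }
  tm <- mk(0); subs <- list(mk(0), mk(1), mk(2))
  t <- 0.65
  got <- between_subject_overlap(subs, tm, t)
  want <- brute_force_overlap(lapply(subs, `[[`, "values"), tm$values, t)
  expect_equal(got, want)
  # permutation invariance
  expect_equal(between_subject_overlap(rev(subs), tm, t), got)
  # within-subject with two timepoints, against both denominators
  w_got <- within_subject_overlap(subs[1:2], tm, t)
  w_want <- brute_force_overlap(lapply(subs[1:2], `[[`, "values"),
                                tm$values, t)
  expect_equal(w_got, w_want)
  # accuracy via the same counter (average of subject + template)
  a_got <- accuracy(subs[[2]], tm, t)
  a_want <- brute_force_overlap(list(subs[[2]]$values, tm$values),
                                tm$values, t)
  expect_equal(a_got, a_want)
})

test_that("between-subject overlap is independent of mask multiplicity", {
  v <- array(0, dim = c(14, 14, 2))
  v[3:10, 4:11, ] <- 1
  w <- array(0, dim = c(14, 14, 2)); w[4:11, 4:11, ] <- 1
  tm <- toy_mask(v); sm <- toy_mask(w)
  one <- between_subject_overlap(list(sm), tm, 0.65)
  for (n in c(2, 5))
    expect_equal(between_subject_overlap(rep(list(sm), n), tm, 0.65), one)
})

test_that("within-subject overlap validates and hits its limit cases", {
  v <- array(0, dim = c(10, 10, 1)); v[3:8, 3:8, 1] <- 1
  m <- toy_mask(v)
  expect_equal(within_subject_overlap(list(m, m), m, 0.65), 100)
  w <- array(0, dim = c(10, 10, 1)); w[1:2, 1:2, 1] <- 1
  expect_equal(within_subject_overlap(list(m, toy_mask(w)), m, 0.6), 0)
  expect_error(within_subject_overlap(list(m), m, 0.65), "2 timepoints")
})

test_that("metric bounds hold for equal-sized voxels above t = 0.5", {
  set.seed(51)
  for (i in 1:10) {
    v <- array(runif(500), dim = c(10, 10, 5))
    w <- array(runif(500), dim = c(10, 10, 5))
    tm <- toy_mask((v > 0.4) * 1); sm <- toy_mask((w > 0.4) * 1)
    a <- accuracy(sm, tm, 0.65)
    expect_gte(a, 0); expect_lte(a, 100)
  }
})

test_that("cv_percent matches its closed forms", {
  expect_equal(cv_percent(c(5, 5, 5)), 0)
  expect_equal(cv_percent(c(1, 2, 3)), 50)   # sd 1, mean 2
  expect_error(cv_percent(10), "two values")
  expect_error(cv_percent(c(-1, 1)), "mean")
})

test_that("tissue fractions recover constructed compositions", {
  v <- array(0, dim = c(10, 10, 4)); v[3:8, 3:8, 2:3] <- 1
  mask <- toy_mask(v)
  aff <- grid_affine(mask$grid)
  ones <- array(1, dim = dim(v)); zeros <- array(0, dim = dim(v))
  pure_gm <- list(gm = image_volume(ones, aff),
                  wm = image_volume(zeros, aff),
                  csf = image_volume(zeros, aff))
  expect_equal(tissue_fractions(pure_gm, mask, 0.65),
               c(gm = 100, wm = 0, csf = 0))
  half <- list(gm = image_volume(ones * 0.5, aff),
               wm = image_volume(ones * 0.5, aff),
               csf = image_volume(zeros, aff))
  fr <- tissue_fractions(half, mask, 0.65)
  expect_equal(fr, c(gm = 50, wm = 50, csf = 0))
  expect_equal(sum(fr), 100, tolerance = 0.5)
  expect_error(tissue_fractions(pure_gm, toy_mask(zeros), 0.65), "empty")
})

test_that("phantom tissue composition is recovered within 2%", {
  ph <- quick_phantom(seed = 52, noise_sigma = 0)
  # an unrotated voxel deep in WM, away from boundaries
  spec <- voxel_spec("s", "wmbox", c(20, 20, 20), c(0, -20, 0), c(0, 0, 0))
  mask <- rasterize_voxel(spec, grid_for_spec(spec, spacing = 1))
  fr <- tissue_fractions(ph$pve, mask, 0.65)
  # analytic construction: that region is pure white matter
  expect_gt(fr[["wm"]], 98)
  expect_equal(sum(fr), 100, tolerance = 0.5)
  # a voxel centred on the ventricle blob picks up its CSF
  spec2 <- voxel_spec("s", "ventbox", c(24, 30, 24),
                      c(0.18 * 59, 0.22 * 71.7, 0.05 * 65.3), c(0, 0, 0))
  fr2 <- tissue_fractions(ph$pve,
                          rasterize_voxel(spec2,
                                          grid_for_spec(spec2, spacing = 1)),
                          0.65)
  expect_gt(fr2[["csf"]], 20)
  expect_equal(sum(fr2), 100, tolerance = 0.5)
})

test_that("reconstruction through the identity image matches direct rasterization", {
  ph <- quick_phantom(seed = 53)
  spec <- voxel_spec("s", "d", c(15, 20, 15), c(20, 30, 8), c(7, 20, 15))
  av <- acquired_voxel("sub01", "baseline", spec, subject_image = ph$image)
  grid <- grid_for_spec(spec, margin = 6)
  rec <- reconstruct_in_template(av, ph$image, grid = grid)
  direct <- rasterize_voxel(spec, grid)
  # agreement within one boundary-pixel layer
  expect_gte(accuracy(rec, direct, 0.65), 99)
  expect_equal(mask_volume(rec), 4500, tolerance = 0.02)
})

test_that("reconstruction preserves dims under subject scaling", {
  ph <- quick_phantom(seed = 54, shape = 64, spacing = 3, head_scale = 0.85)
  ctr <- image_center(ph$image)
  gt <- affine9_about(c(0, 0, 0), rep(1.1, 3), c(0, 0, 0), ctr)
  sub <- perturb_subject(ph$image, gt, seed = 55)
  # the acquired voxel sits at 1.1x the template offset in subject space
  tmpl_spec <- voxel_spec("s", "d", c(15, 20, 15), c(18, 30, 9), c(7, 20, 15))
  acq_spec <- voxel_spec("s", "d", c(15, 20, 15),
                         ctr + 1.1 * (tmpl_spec$center - ctr),
                         c(7, 20, 15))
  av <- acquired_voxel("sub01", "baseline", acq_spec, subject_image = sub$image)
  rec <- reconstruct_in_template(av, ph$image)
  # dimension preservation: mask volume stays nominal despite the scaling
  expect_equal(mask_volume(rec), 4500, tolerance = 0.01)
  # and the reconstructed centre compensates the scale back to the template
  expect_lt(max(abs(rec$spec$center - tmpl_spec$center)), 2)
})

test_that("metrics from reread sidecars are bit-identical to in-memory specs", {
  ph <- quick_phantom(seed = 56)
  spec <- voxel_spec("s", "d", c(15, 20, 15), c(20, 30, 8), c(5, -10, 12))
  f <- withr::local_tempfile(fileext = ".json")
  write_voxel_sidecar(acquired_voxel("sub01", "baseline", spec), f)
  reread <- read_acquired_voxel(f)
  expect_identical(reread$spec$center, spec$center)
  expect_identical(as.numeric(reread$spec$angulation),
                   as.numeric(spec$angulation))
  grid <- grid_for_spec(spec)
  m1 <- rasterize_voxel(spec, grid)
  m2 <- rasterize_voxel(reread$spec, grid)
  tm <- rasterize_voxel(voxel_spec("s", "t", c(15, 20, 15), c(21, 30, 8),
                                   c(5, -10, 12)), grid)
  expect_identical(accuracy(m1, tm, 0.65), accuracy(m2, tm, 0.65))
})

test_that("the full overlap pipeline produces a coherent report", {
  ph <- quick_phantom(seed = 57)
  ctr <- image_center(ph$image)
  tmpl_spec <- voxel_spec("s", "d", c(15, 20, 15), c(20, 30, 8), c(7, 20, 15))
  acqs <- list()
  set.seed(57)
  for (i in 1:2) {
    gt <- rigid_about(runif(3, -8, 8), runif(3, -8, 8), ctr)
    sub <- perturb_subject(ph$image, gt, seed = 570 + i)
    acq_spec <- voxel_spec("s", "d", tmpl_spec$dims,
                           tf_apply(gt, tmpl_spec$center),
                           angulation_from_rotation(
                             gt$matrix[1:3, 1:3] %*%
                               rotation_from_angulation(tmpl_spec$angulation)))
    acqs[[i]] <- acquired_voxel(sprintf("sub%02d", i), "baseline", acq_spec,
                                subject_image = sub$image)
  }
  rep <- avp_overlap(ph$image, tmpl_spec, acqs, pve = ph$pve)
  expect_s3_class(rep, "overlap_report")
  expect_true(all(rep$accuracy$accuracy >= 90))
  expect_true(all(rep$between_subject >= 0 & rep$between_subject <= 110))
  expect_equal(nrow(rep$tissue_fractions), 2)
  expect_equal(rowSums(rep$tissue_fractions[, c("gm", "wm", "csf")]),
               c(100, 100), tolerance = 0.5, ignore_attr = TRUE)
  f <- withr::local_tempfile(fileext = ".txt")
  write_overlap_summary(rep, f)
  lines <- readLines(f)
  expect_true(any(grepl("Percent Total Voxel", lines)))
  expect_true(any(grepl("^sub01\tbaseline", lines)))
})
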