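# 4x4x4 cube and the same cube shifted 2 voxels along axis 1: the standard
# worked pair (tp = fp = fn = 32)
shifted_cubes <- function(spacing = c(1, 1, 1)) {
  list(
    pred = cuboid_mask(c(8, 8, 8), c(1, 1, 1), c(4, 4, 4), spacing),
    ref = cuboid_mask(c(8, 8, 8), c(3, 1, 1), c(6, 4, 4), spacing)
  )
}

test_that("confusion counts match hand-enumerated pairs", {
  m <- random_mask(c(6, 6, 6), p_fg = 0.5)
  cc <- confusion_counts(m, m)
  expect_equal(cc$tp, sum(m$voxels))
  expect_equal(cc$fp + cc$fn, 0)
  expect_equal(cc$tp + cc$fp + cc$fn + cc$tn, prod(m$shape))

  a <- cuboid_mask(c(10, 10, 10), c(1, 1, 1), c(1, 2, 5))   # 10 voxels
  b <- cuboid_mask(c(10, 10, 10), c(5, 1, 1), c(6, 2, 5))   # 20, disjoint
  cc <- confusion_counts(a, b)
  expect_equal(c(cc$tp, cc$fp, cc$fn), c(0, 10, 20))

  sc <- shifted_cubes()
  cc <- confusion_counts(sc$pred, sc$ref)
  expect_equal(c(cc$tp, cc$fp, cc$fn), c(32, 32, 32))
})

test_that("overlap and volume metrics match closed forms", {
  sc <- shifted_cubes()
  expect_equal(dice_coef(sc$pred, sc$ref)$value, 0.5)
  expect_equal(precision_coef(sc$pred, sc$ref)$value, 0.5)
  expect_equal(recall_coef(sc$pred, sc$ref)$value, 0.5)

  # pred strictly inside ref at half its volume
  inner <- cuboid_mask(c(8, 8, 8), c(3, 3, 3), c(4, 4, 6))  # 2x2x4 = 16
  outerm <- cuboid_mask(c(8, 8, 8), c(3, 3, 3), c(4, 6, 6)) # 2x4x4 = 32
  expect_equal(precision_coef(inner, outerm)$value, 1.0)
  expect_equal(recall_coef(inner, outerm)$value, 0.5)

  # VS with volumes 10 and 30 ml
  v10 <- cuboid_mask(c(40, 40, 40), c(1, 1, 1), c(10, 25, 40))
  v30 <- cuboid_mask(c(40, 40, 40), c(1, 1, 1), c(30, 25, 40))
  expect_equal(volume_ml(v10), 10)
  expect_equal(volumetric_similarity(v10, v30)$value, 0.5)
  expect_equal(absolute_volume_difference(v10, v30)$value, 20)

  a <- array(0, c(10, 10, 10)); a[1:4, 1:5, 1:5] <- 1
  m100 <- seg_mask(a, c(3.0, 0.45, 0.45))
  empty <- seg_mask(array(0, c(10, 10, 10)), c(3.0, 0.45, 0.45))
  expect_equal(absolute_volume_difference(m100, empty)$value, 0.06075)
})

test_that("surface voxels follow 6-connectivity with the grid edge as background", {
  one <- seg_mask(array(c(rep(0, 13), 1, rep(0, 13)), c(3, 3, 3)))
  expect_equal(nrow(surface_voxels(one)), 1)

  solid3 <- cuboid_mask(c(5, 5, 5), c(2, 2, 2), c(4, 4, 4))
  s <- surface_voxels(solid3)
  expect_equal(nrow(s), 26)  # all but the centre
  expect_false(any(s[, 1] == 3 & s[, 2] == 3 & s[, 3] == 3))

  solid2 <- cuboid_mask(c(4, 4, 4), c(2, 2, 2), c(3, 3, 3))
  expect_equal(nrow(surface_voxels(solid2)), 8)

  # touching the image edge counts as surface (only the centre is interior)
  full <- seg_mask(array(1, c(3, 3, 3)))
  expect_equal(nrow(surface_voxels(full)), 26)
  expect_equal(nrow(surface_voxels(seg_mask(array(0, c(3, 3, 3))))), 0)
})

test_that("directed surface distances match hand computations", {
  a <- matrix(c(1, 1, 1), 1, dimnames = list(NULL, c("i", "j", "k")))
  b <- matrix(c(1, 1, 11), 1, dimnames = list(NULL, c("i", "j", "k")))
  expect_equal(directed_surface_distances(a, b, c(1, 1, 1), c(2, 2, 12)), 10)

  a2 <- matrix(c(2, 1, 1), 1)
  b2 <- matrix(c(1, 1, 1), 1)
  expect_equal(directed_surface_distances(a2, b2, c(3, 1, 1), c(3, 2, 2)), 3)

  m <- random_mask(c(6, 6, 6), p_fg = 0.5)
  s <- surface_voxels(m)
  expect_equal(directed_surface_distances(s, s, m$spacing_mm, m$shape),
               rep(0, nrow(s)))
  expect_error(directed_surface_distances(s, s[0, , drop = FALSE], c(1, 1, 1)),
               "empty")
})

test_that("hd95 matches examples", {
  m <- random_mask(c(7, 7, 7), p_fg = 0.4)
  expect_equal(hd95(m, m)$value, 0)

  a1 <- array(0, c(3, 3, 12)); a1[2, 2, 1] <- 1
  a2 <- array(0, c(3, 3, 12)); a2[2, 2, 11] <- 1
  expect_equal(hd95(seg_mask(a1), seg_mask(a2))$value, 10)
})

test_that("hd95 agrees with brute force on a constructed near-match pair", {
  # pred = ref plus one extra voxel well away from ref's surface
  ref <- cuboid_mask(c(20, 10, 10), c(1, 2, 2), c(6, 8, 8))
  a <- ref$voxels
  a[14, 5, 5] <- 1  # 8 voxels beyond the cuboid face along axis 1
  pred <- seg_mask(a, ref$spacing_mm)
  expect_gte(nrow(surface_voxels(ref)), 40)
  expect_equal(hd95(pred, ref)$value, brute_hd95(pred, ref), tolerance = 1e-12)
  # pooled variant never exceeds the max-directed variant here
  expect_lte(hd95(pred, ref, method = "pooled")$value, hd95(pred, ref)$value)
})

test_that("surface dice matches examples and saturates at large tolerance", {
  m <- random_mask(c(6, 6, 6), p_fg = 0.5)
  expect_equal(surface_dice_at_tolerance(m, m, 0.5)$value, 1)

  sc <- shifted_cubes()
  diag_mm <- sqrt(sum((sc$pred$shape * sc$pred$spacing_mm)^2))
  expect_equal(surface_dice_at_tolerance(sc$pred, sc$ref, diag_mm)$value, 1)
  expect_equal(surface_dice_at_tolerance(sc$pred, sc$ref, 2.0)$value,
               brute_sdt(sc$pred, sc$ref, 2.0), tolerance = 1e-12)
  expect_error(surface_dice_at_tolerance(sc$pred, sc$ref, -1), "positive")
})

test_that("evaluate_pair applies the empty-mask conventions", {
  m <- random_mask(c(6, 6, 6), p_fg = 0.5)
  full <- evaluate_pair(m, m)
  expect_equal(full$value[full$metric %in%
                            c("VS", "Dice", "Precision", "Recall", "SDT")],
               rep(1, 5))
  expect_equal(full$value[full$metric %in% c("AVD", "HD95")], c(0, 0))

  e <- seg_mask(array(0, c(6, 6, 6)))
  both <- evaluate_pair(e, e)
  expect_equal(both$value, c(1, 0, 1, 1, 1, 0, 1))
  expect_true(all(both$defined))

  one <- evaluate_pair(e, m)
  expect_equal(one$value[one$metric == "VS"], 0)
  expect_equal(one$value[one$metric == "Dice"], 0)
  expect_equal(one$value[one$metric == "SDT"], 0)
  expect_equal(one$value[one$metric == "AVD"], volume_ml(m))
  expect_false(one$defined[one$metric == "HD95"])
  expect_false(one$defined[one$metric == "Precision"])  # empty prediction
  expect_equal(one$value[one$metric == "Recall"], 0)
})

test_that("metric symmetries and dual relations hold on random pairs", {
  set.seed(21)
  for (i in 1:20) {
    dm <- sample(4:9, 3, TRUE)
    sp <- if (i %% 2) c(1, 1, 1) else runif(3, 0.4, 3)
    a <- random_mask(dm, sp, p_fg = runif(1, 0.2, 0.7))
    b <- random_mask(dm, sp, p_fg = runif(1, 0.2, 0.7))
    if (sum(a$voxels) == 0 || sum(b$voxels) == 0) next
    expect_equal(dice_coef(a, b)$value, dice_coef(b, a)$value)
    expect_equal(volumetric_similarity(a, b)$value,
                 volumetric_similarity(b, a)$value)
    expect_equal(absolute_volume_difference(a, b)$value,
                 absolute_volume_difference(b, a)$value)
    expect_equal(hd95(a, b)$value, hd95(b, a)$value)
    expect_equal(surface_dice_at_tolerance(a, b, 2)$value,
                 surface_dice_at_tolerance(b, a, 2)$value)
    expect_equal(precision_coef(a, b)$value, recall_coef(b, a)$value)
  }
})

test_that("translation of both masks leaves every metric unchanged", {
  set.seed(31)
  base <- array(0, c(10, 10, 10))
  base[2:4, 2:5, 2:4] <- 1
  other <- array(0, c(10, 10, 10))
  other[3:6, 3:5, 2:5] <- runif(48) < 0.8
  sp <- c(1.5, 0.7, 2.1)
  shift <- c(3, 2, 4)
  tr <- function(a) {
    out <- array(0, dim(a))
    out[(1 + shift[1]):10, (1 + shift[2]):10, (1 + shift[3]):10] <-
      a[1:(10 - shift[1]), 1:(10 - shift[2]), 1:(10 - shift[3])]
    out
  }
  m1 <- seg_mask(base, sp); m2 <- seg_mask(other, sp)
  t1 <- seg_mask(tr(base), sp); t2 <- seg_mask(tr(other), sp)
  expect_equal(evaluate_pair(m1, m2)$value, evaluate_pair(t1, t2)$value)
})
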