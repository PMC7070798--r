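# scene generator: frustum arithmetic, layout counts, analytic truth

test_that("frustum_volume matches the closed form and rejects degenerate input", {
  seg <- function(r0, r1, h)
    data.frame(x0 = 0, y0 = 0, z0 = 0, x1 = 0, y1 = 0, z1 = h,
               r0 = r0, r1 = r1)
  expect_equal(frustum_volume(seg(0.005, 0.005, 1)), 7.853982e-5,
               tolerance = 1e-6)
  expect_equal(frustum_volume(seg(0.005, 0.003, 1)), 5.131268e-5,
               tolerance = 1e-6)
  # vectorized and orientation-independent
  s2 <- data.frame(x0 = c(0, 1), y0 = c(0, 2), z0 = c(0, 3),
                   x1 = c(0, 1), y1 = c(0, 2), z1 = c(2, 4),
                   r0 = c(0.01, 0.02), r1 = c(0.01, 0.01))
  expect_equal(frustum_volume(s2),
               c(pi * 2 * 0.01^2,
                 pi / 3 * (0.02^2 + 0.02 * 0.01 + 0.01^2)))
  expect_error(frustum_volume(seg(0.005, 0.005, 0)), "zero-length")
})

test_that("default field layout yields 150 vines in 15 disjoint batches", {
  scene <- build_scene(scene_spec(), seed = 3)
  expect_equal(sum(scene$segments$tag == "trunk"), 150)
  b <- scene$batches
  expect_equal(nrow(b), 15)
  expect_equal(length(unique(b$treatment)), 5)
  o <- order(b$xmin)
  expect_true(all(b$xmax[o][-15] <= b$xmin[o][-1] + 1e-12))  # disjoint
  # every shoot lies inside its own batch interval
  sh <- scene$segments[scene$segments$tag == "shoot", ]
  expect_true(all(sh$x0 >= b$xmin[sh$batch] & sh$x0 < b$xmax[sh$batch]))
  expect_true(all(sh$x1 >= b$xmin[sh$batch] & sh$x1 < b$xmax[sh$batch]))
  # shoots are thin: diameters below 1 cm
  expect_true(all(pmax(sh$r0, sh$r1) <= 0.005 + 1e-12))
})

test_that("scene generation is deterministic per seed", {
  s1 <- build_scene(scene_spec(treatments = 2, plots_per_treatment = 1,
                               vines_per_plot = 2), seed = 42)
  s2 <- build_scene(scene_spec(treatments = 2, plots_per_treatment = 1,
                               vines_per_plot = 2), seed = 42)
  s3 <- build_scene(scene_spec(treatments = 2, plots_per_treatment = 1,
                               vines_per_plot = 2), seed = 43)
  expect_identical(s1$segments, s2$segments)
  expect_false(identical(s1$segments, s3$segments))
})

test_that("degenerate layouts are rejected; zero shoots give zero truth", {
  expect_error(scene_spec(treatments = 0), "positive")
  spec0 <- scene_spec(treatments = 1, plots_per_treatment = 1,
                      vines_per_plot = 1, shoots_per_vine = 0)
  tr <- batch_truth(build_scene(spec0, seed = 1))
  expect_equal(tr$true_shoot_volume, 0)
  expect_equal(tr$true_biomass, 0)
})

test_that("batch truth: single known shoot, additivity, density link", {
  # hand-made scene: one batch, one cylindrical shoot r = 5 mm, h = 1 m
  scene <- cylinder_scene()
  scene$segments$tag <- "shoot"
  scene$segments$r0 <- 0.005
  scene$segments$r1 <- 0.005
  scene$segments$z1 <- 1
  tr <- batch_truth(scene)
  expect_equal(tr$true_shoot_volume, 7.853982e-5, tolerance = 1e-6)
  expect_equal(tr$true_biomass, 450 * 7.853982e-5, tolerance = 1e-6)

  full <- build_scene(scene_spec(treatments = 2, plots_per_treatment = 2,
                                 vines_per_plot = 2), seed = 9)
  tr <- batch_truth(full)
  # brute-force sum over all shoot segments equals the batch total
  sh <- full$segments[full$segments$tag == "shoot", ]
  expect_equal(sum(tr$true_shoot_volume), sum(frustum_volume(sh)),
               tolerance = 1e-12)
  # order invariance of the segment table
  perm <- full
  perm$segments <- perm$segments[rev(seq_len(nrow(perm$segments))), ]
  expect_equal(batch_truth(perm)$true_shoot_volume, tr$true_shoot_volume)
  # biomass / volume ratio is exactly the wood density
  nz <- tr$true_shoot_volume > 0
  expect_equal(tr$true_biomass[nz] / tr$true_shoot_volume[nz],
               rep(450, sum(nz)))
})

test_that("structure masks cover posts and markers with margin", {
  scene <- build_scene(scene_spec(treatments = 1, plots_per_treatment = 1,
                                  vines_per_plot = 2), seed = 5)
  # wires are deliberately not masked (negligible volume; a wire capsule
  # would cut through every cane crossing it)
  m <- structure_masks(scene, margin = 0.05)
  st <- scene$segments[scene$segments$tag %in% c("post", "marker"), ]
  expect_equal(nrow(m), nrow(st))
  expect_true(all(m$radius >= pmax(st$r0, st$r1) + 0.05 - 1e-12))
  expect_setequal(unique(m$type), c("capsule", "sphere"))
  # wires opt-in
  mw <- structure_masks(scene, tags = c("post", "wire", "marker"))
  expect_equal(nrow(mw), sum(scene$segments$tag %in%
                             c("post", "wire", "marker")))
})
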