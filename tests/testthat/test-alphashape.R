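# alpha shapes: circumspheres, Delaunay correctness, volumes, selection

test_that("circumsphere closed forms: regular tetra, cube corner, degenerate", {
  # regular tetrahedron with edge 1: R = sqrt(3/8)
  reg <- rbind(c(0, 0, 0), c(1, 0, 0), c(0.5, sqrt(3) / 2, 0),
               c(0.5, sqrt(3) / 6, sqrt(6) / 3))
  expect_equal(circumradius(reg), sqrt(3 / 8), tolerance = 1e-9)
  expect_equal(circumradius(reg), 0.612372, tolerance = 1e-6)

  corner <- rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0), c(0, 0, 1))
  cs <- circumsphere(corner)
  expect_equal(cs$center, c(0.5, 0.5, 0.5))
  expect_equal(cs$radius, 0.866025, tolerance = 1e-6)

  flat <- rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0), c(1, 1, 0))
  cf <- circumsphere(flat)
  expect_true(cf$degenerate)
  expect_equal(circumradius(flat), Inf)
})

test_that("Delaunay property holds: circumspheres are empty (brute force)", {
  for (seed in 1:3) {
    set.seed(seed)
    n <- 30
    pts <- matrix(runif(3 * n), ncol = 3)
    d <- delaunay3d(pts, seed = seed)
    for (t in seq_len(nrow(d$tetra))) {
      cs <- circumsphere(pts[d$tetra[t, ], ])
      d2 <- rowSums((pts - matrix(cs$center, n, 3, byrow = TRUE))^2)
      inside <- which(d2 < cs$radius^2 - 1e-9)
      expect_length(setdiff(inside, d$tetra[t, ]), 0)
      # stored circumradius matches the direct computation; the 1e-9 jitter
      # is amplified on slivers, so the comparison is loose and skips the
      # worst-conditioned tetrahedra
      if (cs$radius < 5)
        expect_equal(d$circumradius[t], cs$radius, tolerance = 1e-4)
    }
  }
})

test_that("hull limit: full complex volume equals the convex hull volume", {
  # cube corners: alpha above the circumradius gives the full cube
  cube <- as.matrix(expand.grid(0:1, 0:1, 0:1))
  a <- alpha_complex(cube, alpha = 10)
  expect_equal(a$volume, 1.0, tolerance = 1e-6)
  expect_equal(a$n_components, 1L)
  expect_equal(a$n_points_covered, 8L)
  # no tetrahedron from cube corners has circumradius below sqrt(3)/2
  expect_equal(alpha_complex(cube, alpha = 0.1)$volume, 0)

  # independent oracle: Qhull (scipy) convex hull volume on random clouds
  skip_if(Sys.which("python") == "", "python not available")
  set.seed(42)
  pts <- matrix(runif(3 * 120), ncol = 3)
  f <- tempfile(fileext = ".txt")
  write.table(pts, f, row.names = FALSE, col.names = FALSE)
  hull <- as.numeric(system2("python", c("-c", shQuote(paste0(
    "import numpy,sys; from scipy.spatial import ConvexHull; ",
    "print(ConvexHull(numpy.loadtxt('", f, "')).volume)"))),
    stdout = TRUE))
  d <- delaunay3d(pts)
  expect_equal(sum(d$volume), hull, tolerance = 1e-9)
  amax <- max(d$circumradius[is.finite(d$circumradius)])
  expect_equal(alpha_complex(d, amax * 1.001)$volume, hull,
               tolerance = 1e-9)
})

test_that("volume is monotone in alpha and bounded by the hull", {
  for (seed in 1:4) {
    set.seed(seed)
    pts <- matrix(runif(3 * 100), ncol = 3)
    d <- delaunay3d(pts, seed = seed)
    alphas <- seq(0.05, 1, length.out = 25)
    vols <- vapply(alphas, function(a) alpha_complex(d, a)$volume,
                   numeric(1))
    expect_true(all(diff(vols) >= 0))
    expect_true(all(vols <= sum(d$volume) + 1e-12))
  }
})

test_that("enclosed volume agrees with a Monte-Carlo point-in-complex oracle", {
  set.seed(31)
  for (seed in c(31, 32)) {
    set.seed(seed)
    pts <- matrix(runif(3 * 200), ncol = 3)
    a <- alpha_complex(pts, alpha = 0.35, seed = seed)
    M <- 60000
    q <- cbind(runif(M), runif(M), runif(M))
    inside <- vinescan:::.points_in_tets_cpp(a$delaunay$points, a$tetra, q)
    phat <- mean(inside)
    vmc <- phat            # bounding box volume is 1
    se <- sqrt(phat * (1 - phat) / M)
    expect_lt(abs(a$volume - vmc), 3 * se)
  }
})

test_that("surface-sampled thin cylinder recovers the analytic volume", {
  # full-circumference sampling at <= 5 mm spacing, r = 5 mm, L = 1 m
  th <- rep(seq(0, 2 * pi, length.out = 13)[-13], 250)
  z <- rep(seq(0, 1, length.out = 250), each = 12)
  pts <- cbind(0.005 * cos(th), 0.005 * sin(th), z)
  a <- alpha_complex(pts, alpha = 0.1)
  truth <- pi * 0.005^2
  expect_lt(abs(a$volume - truth) / truth, 0.25)
  expect_equal(a$n_components, 1L)
})

test_that("alpha selection follows the smallest-void-free-volume rule", {
  # dense single blob: the smallest candidate qualifies
  set.seed(21)
  blob <- matrix(rnorm(3 * 400, sd = 0.05), ncol = 3)
  sel <- select_alpha(blob, c(0.1, 0.3, 0.5))
  expect_equal(sel$alpha, 0.1)
  expect_true(all(diff(sel$sweep$volume) >= 0))

  # two blobs 1 m apart: 0.1 leaves two components, 0.9 joins them
  two <- rbind(blob, sweep(blob, 2, c(1, 0, 0), "+"))
  sel2 <- select_alpha(two, c(0.1, 0.9))
  expect_equal(sel2$alpha, 0.9)
  expect_gt(sel2$sweep$n_components[1], 1)
  expect_equal(sel2$sweep$n_components[2], 1)

  # a single tetrahedron: any candidate at/above its circumradius works
  tet <- rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0), c(0, 0, 1))
  sel3 <- select_alpha(tet, c(0.9, 1.5, 2))
  expect_equal(sel3$alpha, 0.9)

  # nothing qualifies: largest candidate with a warning
  expect_warning(sel4 <- select_alpha(two, c(0.05, 0.1)), "no candidate")
  expect_equal(sel4$alpha, 0.1)
})

test_that("degenerate inputs give empty complexes, not crashes", {
  expect_warning(a <- alpha_complex(matrix(runif(9), 3, 3), 0.5),
                 "fewer than 4")
  expect_equal(a$volume, 0)
  expect_equal(a$n_components, 0L)
  flat <- cbind(runif(30), runif(30), 0.5)
  expect_warning(af <- alpha_complex(flat, 0.5, jitter = 0), "coplanar")
  expect_equal(af$volume, 0)
})

test_that("volume subtraction clamps at zero and passes through", {
  expect_equal(volume_without_structures(5e-4, 1e-4), 4e-4)
  expect_equal(volume_without_structures(5e-4, 0), 5e-4)
  expect_warning(v <- volume_without_structures(1e-4, 5e-4), "clamp")
  expect_equal(v, 0)
})

test_that("boundary triangles are faces of exactly one retained tetrahedron", {
  set.seed(8)
  pts <- matrix(runif(3 * 80), ncol = 3)
  a <- alpha_complex(pts, 0.3)
  fk <- vinescan:::.face_keys(a$tetra)
  cnt <- table(fk$key)
  expect_true(all(cnt %in% c(1, 2)))
  expect_equal(nrow(a$boundary), sum(cnt == 1))
})
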