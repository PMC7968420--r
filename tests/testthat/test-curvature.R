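# Discrete curvature, RPC, folding classification, ICP and label transfer.

test_that("total angle deficit of closed genus-0 meshes is exactly 4*pi", {
  fixtures <- list(
    cubeMesh(),
    icosphereMesh(10, 3),
    marchingCubes(labelGrid(rasterizeShape("sphere", radius = 6)), 1),
    marchingCubes(labelGrid(
      rasterizeShape("two_lobe", radius = 4, separation = 5)), 1))
  for (mesh in fixtures)
    expect_lt(abs(sum(gaussianCurvature(mesh)) - 4 * pi), 1e-9)
  # torus: total deficit 0 (genus 1)
  tor <- marchingCubes(labelGrid(
    rasterizeShape("torus", majorRadius = 6, minorRadius = 2)), 1)
  expect_lt(abs(sum(gaussianCurvature(tor))), 1e-9)
})

test_that("flat regions have zero Gaussian and mean curvature", {
  # a box has large planar faces; its face-interior vertices are flat
  m <- array(0L, c(12, 12, 6)); m[2:11, 2:11, 2:5] <- 1L
  mesh <- marchingCubes(m, 1)
  K <- gaussianCurvature(mesh)
  H <- meanCurvature(mesh)
  expect_gt(sum(abs(K) < 1e-12 & abs(H) < 1e-12), 100)
})

test_that("icosphere curvature matches the analytic sphere", {
  ico <- icosphereMesh(10, 4)
  K <- gaussianCurvature(ico, "area_normalized")
  H <- meanCurvature(ico, "area_normalized")
  expect_lt(abs(median(K) / 0.01 - 1), 0.10)
  expect_lt(abs(median(H) / 0.1 - 1), 0.10)
  cf <- curvatureField(ico, "area_normalized")
  expect_lte(median(cf@rpc), 1.2)
})

test_that("orientation reversal flips the sign of H everywhere", {
  ico <- icosphereMesh(5, 2)
  H <- meanCurvature(ico)
  flipped <- SurfaceMesh(vertices(ico), faces(ico)[, c(1, 3, 2)])
  expect_equal(meanCurvature(flipped), -H, tolerance = 1e-12)
  expect_gt(median(H), 0)  # convex w.r.t. outward normal is positive
})

test_that("area-normalized curvatures scale as 1/mm and 1/mm^2", {
  ico <- icosphereMesh(7, 3)
  big <- SurfaceMesh(vertices(ico) * 2, faces(ico))
  expect_equal(median(meanCurvature(big, "area_normalized")),
               median(meanCurvature(ico, "area_normalized")) / 2,
               tolerance = 1e-9)
  expect_equal(median(gaussianCurvature(big, "area_normalized")),
               median(gaussianCurvature(ico, "area_normalized")) / 4,
               tolerance = 1e-9)
  # RPC is exactly scale-invariant in the dimensionally consistent mode
  # (in as_written mode K carries radians and H mm-radians, so H^2 - K and
  # hence RPC change under rescaling; see the methods vignette)
  expect_equal(median(curvatureField(big, "area_normalized")@rpc),
               median(curvatureField(ico, "area_normalized")@rpc),
               tolerance = 1e-9)
})

test_that("mean curvature requires a closed mesh", {
  open <- SurfaceMesh(vertices(cubeMesh()), faces(cubeMesh())[-1, ])
  expect_error(meanCurvature(open), "closed")
})

test_that("principal curvatures follow the closed form with clamping", {
  pc <- principalCurvatures(K = 0.75, H = 1)
  expect_equal(pc$cmax, 1.5); expect_equal(pc$cmin, 0.5)
  expect_identical(pc$clampCount, 0L)
  umb <- principalCurvatures(K = 4, H = 2)
  expect_equal(umb$cmax, 2); expect_equal(umb$cmin, 2)
  cl <- principalCurvatures(K = 1, H = 0.5)  # disc = -0.75 -> clamp
  expect_equal(cl$cmax, 0.5); expect_equal(cl$cmin, 0.5)
  expect_identical(cl$clampCount, 1L)
  expect_error(principalCurvatures(1:3, 1:2), "length")
})

test_that("RPC follows its definition, floor and symmetry", {
  expect_equal(rpcIndex(2, 1), 2)
  expect_equal(rpcIndex(0.3, 0.3), 1)
  expect_equal(rpcIndex(-3, 1.5), 2)            # uses absolute values
  expect_equal(rpcIndex(1, 0), 1e8)             # default eps floor
  expect_equal(rpcIndex(1, 2), rpcIndex(2, 1))  # symmetric
  expect_equal(rpcIndex(0, 0), 1)               # degenerate umbilic
  expect_error(rpcIndex(1, 1, eps = 0), "eps")
  set.seed(1)
  a <- rnorm(100); b <- rnorm(100)
  expect_true(all(rpcIndex(a, b) >= 1))
})

test_that("clamped vertices stay rare on smoothed reconstructions", {
  vol <- sphereVolumeFixture()
  mesh <- laplacianSmooth(marchingCubes(extractMask(vol, "CA1"), 1), 50)
  cf <- curvatureField(mesh, "area_normalized")
  expect_lt(clampCount(cf) / length(cf@K), 0.20)
})

test_that("folding classification follows the decision table", {
  res <- classifyFolding(cmax = c(0.5, 0.5, 0.05, 0.5, -0.5, 0.05),
                         cmin = c(0.4, 0.0, 0.0, -0.5, -0.6, -0.5),
                         tau = 0.1)
  expect_identical(as.character(res$class),
                   c("cap", "ridge", "flat", "saddle", "cup", "valley"))
  h <- res$histogram
  expect_equal(sum(h@fractions), 1)
  expect_identical(sum(h@counts), 6L)
  expect_equal(h@tau, 0.1)
  # adaptive threshold is recorded and positive
  ico <- curvatureField(icosphereMesh(4, 2), "area_normalized")
  auto <- classifyFolding(ico@cmax, ico@cmin)
  expect_gt(auto$histogram@tau, 0)
  expect_error(classifyFolding(1, 0, tau = -1), "tau")
})

test_that("ICP recovers identity and known rigid transforms", {
  set.seed(10)
  cloud <- vertices(icosphereMesh(8, 2))
  cloud <- cloud + matrix(rnorm(length(cloud), 0, 0.2), ncol = 3)
  idt <- icpRegister(cloud, cloud)
  expect_equal(idt@rotation, diag(3), tolerance = 1e-9)
  expect_equal(idt@translation, c(0, 0, 0), tolerance = 1e-9)
  expect_lt(idt@rms, 1e-12)
  R <- rotZ(10)
  tgt <- sweep(cloud %*% t(R), 2, c(1, 2, 3), "+")
  tf <- icpRegister(cloud, tgt)
  expect_lt(tf@rms, 1e-3)
  expect_equal(tf@rotation, R, tolerance = 1e-6)
  expect_equal(tf@translation, c(1, 2, 3), tolerance = 1e-6)
  moved <- applyTransform(tf, cloud)
  expect_lt(sqrt(mean(rowSums((moved - tgt)^2))), 1e-3)
  expect_rms_nonincreasing(tf@rmsHistory)
})

test_that("ICP rejects degenerate inputs", {
  line <- cbind(1:10, 2 * (1:10), 3 * (1:10))
  expect_error(icpRegister(line, line), "collinear")
  expect_error(icpRegister(matrix(rnorm(6), 2, 3),
                           matrix(rnorm(30), 10, 3)), "at least 3")
})

test_that("label transfer reproduces an exact vertex partition", {
  lobes <- rasterizeShape("two_lobe", radius = 4, separation = 5)
  mesh <- marchingCubes(labelGrid(lobes), 1)
  V <- vertices(mesh)
  truth <- ifelse(V[, 1] < mean(range(V[, 1])), "CA1", "subiculum")
  parts <- list(CA1 = V[truth == "CA1", ], subiculum = V[truth == "subiculum", ])
  expect_identical(transferLabels(mesh, parts), truth)
})

test_that("label transfer survives 0.1 mm jitter with >= 95% agreement", {
  lobes <- rasterizeShape("two_lobe", radius = 4, separation = 5)
  mesh <- marchingCubes(labelGrid(lobes), 1)
  V <- vertices(mesh)
  truth <- ifelse(V[, 1] < mean(range(V[, 1])), "CA1", "subiculum")
  parts <- list(CA1 = V[truth == "CA1", ], subiculum = V[truth == "subiculum", ])
  set.seed(77)
  jparts <- lapply(parts, function(p) p + matrix(rnorm(length(p), 0, 0.1),
                                                 ncol = 3))
  agree <- mean(transferLabels(mesh, jparts) == truth)
  expect_gte(agree, 0.95)
})

test_that("label transfer ties break deterministically by region name", {
  whole <- rbind(c(0, 0, 0))
  subs <- list(zeta = rbind(c(1, 0, 0)), alpha = rbind(c(-1, 0, 0)))
  expect_identical(transferLabels(whole, subs), "alpha")
  expect_error(transferLabels(whole, list()), "empty")
})
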