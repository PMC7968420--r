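# Shared fixtures, built in code at test time.

# unit cube [0,1]^3 as 12 outward-oriented triangles
cubeMesh <- function() {
  V <- rbind(c(0, 0, 0), c(1, 0, 0), c(1, 1, 0), c(0, 1, 0),
             c(0, 0, 1), c(1, 0, 1), c(1, 1, 1), c(0, 1, 1))
  f <- rbind(
    c(1, 3, 2), c(1, 4, 3),   # z = 0 (normal -z)
    c(5, 6, 7), c(5, 7, 8),   # z = 1 (+z)
    c(1, 2, 6), c(1, 6, 5),   # y = 0 (-y)
    c(4, 8, 7), c(4, 7, 3),   # y = 1 (+y)
    c(1, 5, 8), c(1, 8, 4),   # x = 0 (-x)
    c(2, 3, 7), c(2, 7, 6))   # x = 1 (+x)
  SurfaceMesh(V, f)
}

sphereVolumeFixture <- function(radius = 10, spacing = 1) {
  rasterizeShape("sphere", radius = radius, spacing = spacing,
                 labelId = 4L, labelMap = c(CA1 = 4L))
}

# rotation by `deg` degrees about z
rotZ <- function(deg) {
  th <- deg * pi / 180
  rbind(c(cos(th), -sin(th), 0), c(sin(th), cos(th), 0), c(0, 0, 1))
}

# RMS history tolerance: non-increasing up to floating jitter near convergence
expect_rms_nonincreasing <- function(h) {
  expect_true(all(diff(h) <= pmax(1e-9, 1e-6 * h[-length(h)])))
}
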