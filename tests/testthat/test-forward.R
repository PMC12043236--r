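unit_triangle_mesh <- function() {
  structure(list(
    vertices = rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0), c(5, 5, 5)),
    triangles = matrix(1:3, 1),
    region_of_vertex = c(1, 1, 1, 2)), class = "vep_mesh")
}

test_that("vertex areas follow the one-third rule", {
  mesh <- unit_triangle_mesh()
  a <- vertex_areas(mesh)
  expect_equal(a[1:3], rep(1 / 6, 3))   # triangle area 0.5, split 3 ways
  expect_equal(a[4], 0)                 # isolated vertex
  expect_equal(sum(a), 0.5)             # conservation
})

test_that("gain matches hand-computed values", {
  # one-vertex region at distance 1, area 1
  mesh <- structure(list(
    vertices = rbind(c(0, 0, 0)), triangles = matrix(integer(), 0, 3),
    region_of_vertex = 1, vertex_area = 1), class = "vep_mesh")
  sensors <- rbind(s1 = c(1, 0, 0))
  expect_equal(unname(compute_gain(mesh, sensors)[1, 1]), 1)
  # inverse-square: doubling distance quarters the gain
  expect_equal(unname(compute_gain(mesh, rbind(s1 = c(2, 0, 0)))[1, 1]),
               0.25)
  # two vertices (a = 1, d = 1) and (a = 2, d = 2): g = 1 + 2/4 = 1.5
  mesh2 <- structure(list(
    vertices = rbind(c(1, 0, 0), c(2, 0, 0)),
    triangles = matrix(integer(), 0, 3),
    region_of_vertex = c(1, 1), vertex_area = c(1, 2)), class = "vep_mesh")
  expect_equal(unname(compute_gain(mesh2, rbind(s = c(0, 0, 0)))[1, 1]), 1.5)
  # sensor on a vertex is rejected
  expect_error(compute_gain(mesh2, rbind(s = c(1, 0, 0))), "zero distance")
})

test_that("gain equals an independently written naive double loop", {
  set.seed(31)
  R <- 5; V <- 40; N <- 4
  mesh <- structure(list(
    vertices = matrix(rnorm(V * 3, sd = 20), V, 3),
    triangles = matrix(integer(), 0, 3),
    region_of_vertex = sample(seq_len(R), V, replace = TRUE),
    vertex_area = runif(V, 0.5, 3)), class = "vep_mesh")
  sensors <- matrix(rnorm(N * 3, sd = 40), N, 3)
  rownames(sensors) <- paste0("s", 1:N)
  G <- compute_gain(mesh, sensors)
  oracle <- matrix(0, R, N)
  for (j in seq_len(R)) for (k in seq_len(N)) {
    for (i in which(mesh$region_of_vertex == j)) {
      d2 <- sum((mesh$vertices[i, ] - sensors[k, ])^2)
      oracle[j, k] <- oracle[j, k] + mesh$vertex_area[i] / d2
    }
  }
  expect_equal(unname(G), oracle, tolerance = 1e-12)
})

test_that("splitting a vertex's area over colocated vertices leaves gain unchanged", {
  mesh1 <- structure(list(
    vertices = rbind(c(3, 1, 2)), triangles = matrix(integer(), 0, 3),
    region_of_vertex = 1, vertex_area = 2), class = "vep_mesh")
  mesh2 <- structure(list(
    vertices = rbind(c(3, 1, 2), c(3, 1, 2)),
    triangles = matrix(integer(), 0, 3),
    region_of_vertex = c(1, 1), vertex_area = c(1.2, 0.8)),
    class = "vep_mesh")
  s <- rbind(s = c(0, 0, 0))
  expect_equal(compute_gain(mesh1, s), compute_gain(mesh2, s))
})

test_that("sensor projection is the gain-transposed product and linear", {
  gain <- matrix(c(1, 2), 2, 1)           # 2 regions, 1 sensor
  src <- rbind(c(1, 0, 2), c(3, 1, 0))    # s1, s2 over 3 time points
  expect_equal(as.vector(project_to_sensors(gain, src)),
               src[1, ] + 2 * src[2, ])
  expect_equal(project_to_sensors(gain, src * 0), 0 * project_to_sensors(gain, src))
  a <- matrix(rnorm(6), 2); b <- matrix(rnorm(6), 2)
  expect_equal(project_to_sensors(gain, a + b),
               project_to_sensors(gain, a) + project_to_sensors(gain, b))
  expect_error(project_to_sensors(gain, matrix(0, 3, 4)))
})

test_that("bipolar montage forms adjacent same-shaft differences", {
  geo <- generate_parcellation_geometry(R = 4, vertices_per_region = 12,
                                        seed = 6)
  # force a 15-contact shaft by searching seeds
  elec <- NULL
  for (s in 1:50) {
    e <- generate_electrode_implantation(geo$parcellation, 1, seed = s)
    if (nrow(e$contacts) == 15) { elec <- e; break }
  }
  expect_false(is.null(elec))
  mon <- bipolar_montage(elec)
  expect_equal(nrow(mon), 14)

  ts <- matrix(0, 15, 10)
  rownames(ts) <- elec$contacts$label
  ts[mon$positive[1], ] <- 3
  ts[mon$negative[1], ] <- 1
  bip <- apply_montage(ts, mon)
  expect_equal(unname(bip[1, ]), rep(2, 10))
  expect_true(all(bip[-1, ] %in% c(-3, -1, 0, 1, 3)))
  # identical signals cancel
  ts2 <- matrix(rep(rnorm(10), each = 15), 15)
  rownames(ts2) <- elec$contacts$label
  expect_equal(max(abs(apply_montage(ts2, mon))), 0)
  # unknown label errors
  bad <- mon; bad$positive[1] <- "ZZ9"
  expect_error(apply_montage(ts, bad), "ZZ9")
})
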