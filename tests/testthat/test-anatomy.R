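test_that("parcellation geometry has the forced counts and is seeded", {
  geo <- generate_parcellation_geometry(R = 2, vertices_per_region = 12,
                                        seed = 1)
  expect_equal(nrow(geo$mesh$vertices), 24)
  expect_equal(as.vector(table(geo$mesh$region_of_vertex)), c(12, 12))
  expect_equal(length(geo$parcellation$region_labels), 2)
  expect_false(any(duplicated(geo$parcellation$region_labels)))

  geo2 <- generate_parcellation_geometry(R = 2, vertices_per_region = 12,
                                         seed = 1)
  expect_identical(geo$mesh$vertices, geo2$mesh$vertices)
  expect_identical(geo$parcellation$centers, geo2$parcellation$centers)

  expect_error(generate_parcellation_geometry(R = 1, 12))
  expect_error(generate_parcellation_geometry(R = 3, 2))
})

test_that("every region of a large parcellation has positive surface area", {
  geo <- generate_parcellation_geometry(R = 162, vertices_per_region = 30,
                                        seed = 7)
  a <- geo$mesh$vertex_area
  per_region <- tapply(a, geo$mesh$region_of_vertex, sum)
  expect_length(per_region, 162)
  expect_true(all(per_region > 0))
  # independent recomputation of total area from the triangles
  v <- geo$mesh$vertices
  tr <- geo$mesh$triangles
  tot <- 0
  for (k in seq_len(nrow(tr))) {
    u <- v[tr[k, 2], ] - v[tr[k, 1], ]
    w <- v[tr[k, 3], ] - v[tr[k, 1], ]
    cr <- c(u[2] * w[3] - u[3] * w[2], u[3] * w[1] - u[1] * w[3],
            u[1] * w[2] - u[2] * w[1])
    tot <- tot + 0.5 * sqrt(sum(cr^2))
  }
  expect_equal(sum(a), tot, tolerance = 1e-10)
})

test_that("connectome invariants hold and density is honoured", {
  con <- generate_connectome(3, density = 1, seed = 0)
  expect_equal(diag(con$weights), c(0, 0, 0))
  expect_equal(max(con$weights), 1)
  expect_equal(con$weights, t(con$weights))
  expect_silent(validate_connectome(con))

  con2 <- generate_connectome(162, density = 0.3, seed = 5)
  offdiag <- con2$weights[upper.tri(con2$weights)]
  expect_equal(mean(offdiag > 0), 0.3, tolerance = 0.05 / 0.3)
  expect_silent(validate_connectome(con2))

  expect_error(generate_connectome(1, 0.5))
  expect_error(generate_connectome(5, 0))
})

test_that("electrode implantations respect the clinical geometry", {
  geo <- generate_parcellation_geometry(R = 8, vertices_per_region = 12,
                                        seed = 2)
  e1 <- generate_electrode_implantation(geo$parcellation, 1, seed = 3)
  n <- nrow(e1$contacts)
  expect_true(n >= 10 && n <= 18)

  pos <- contact_positions(e1)
  gaps <- sqrt(rowSums(diff(pos)^2))
  expect_true(all(abs(gaps - gaps[1]) < 1e-9))
  expect_true(min(abs(gaps[1] - c(1.5, 5))) < 1e-9)

  e8 <- generate_electrode_implantation(geo$parcellation, 8, seed = 9)
  expect_false(any(duplicated(e8$contacts$label)))
  for (sh in unique(e8$contacts$shaft)) {
    ns <- sum(e8$contacts$shaft == sh)
    expect_true(ns >= 10 && ns <= 18)
  }

  e5 <- generate_electrode_implantation(geo$parcellation, 2, seed = 4,
                                        spacing = 5)
  expect_true(all(e5$spacing == 5))
  expect_error(generate_electrode_implantation(geo$parcellation, 0))
})

test_that("connectome bundle round-trips through the ZIP archive", {
  geo <- generate_parcellation_geometry(R = 3, vertices_per_region = 12,
                                        seed = 1)
  con <- generate_connectome(3, density = 1, seed = 2)
  path <- tempfile(fileext = ".zip")
  write_connectome_bundle(con, geo$parcellation, path)
  back <- read_connectome_bundle(path)
  expect_equal(back$connectome$weights, con$weights, tolerance = 1e-8)
  expect_equal(back$connectome$tract_lengths, con$tract_lengths,
               tolerance = 1e-8)
  expect_equal(back$parcellation$region_labels,
               geo$parcellation$region_labels)
  expect_equal(back$parcellation$centers, geo$parcellation$centers,
               tolerance = 1e-8)
})

test_that("a bundle missing its weights table is rejected by name", {
  # build a zip that lacks weights.txt
  tmp <- tempfile(fileext = ".zip")
  files <- list("centres.txt" = "r1 0 0 0\n")
  vepsim:::write_zip_store(files, tmp)
  expect_error(read_connectome_bundle(tmp), "weights.txt")
})

test_that("gain and electrode TSVs round-trip", {
  g <- matrix(runif(12), 3, 4)
  p <- tempfile(fileext = ".tsv")
  write_gain_tsv(g, p)
  g2 <- read_gain_tsv(p)
  expect_equal(dim(g2), c(3, 4))
  expect_equal(g2, g, tolerance = 1e-10)

  b <- tiny_patient()
  pe <- tempfile(fileext = ".tsv")
  write_electrodes_tsv(b$electrodes, pe)
  df <- read_electrodes_tsv(pe)
  expect_equal(df$name, b$electrodes$contacts$label)
  expect_equal(df$x, b$electrodes$contacts$x, tolerance = 1e-6)
})
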