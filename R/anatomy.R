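#' Synthetic brain parcellation and surface geometry
#'
#' Generates the structural scaffold of a virtual patient: a parcellation
#' of `R` regions with distinct centers and, per region, a small closed
#' triangulated sphere section standing in for the region's pial (or
#' volume-bounding) surface. Only vertex positions, region assignment and
#' vertex areas feed the sensor gain computation, so spheres are a
#' sufficient stand-in for folded cortical sheets.
#'
#' Region centers are drawn uniformly inside a brain-sized box
#' (roughly 140 x 180 x 120 mm) with a minimum separation, and each
#' region's mesh is an icosphere-like triangulation of radius `region_radius`.
#'
#' @param R Number of regions (>= 2; the atlas used clinically has 162).
#' @param vertices_per_region Vertices per region sphere (>= 3).
#' @param seed Integer seed; the output is a pure function of the
#'   arguments and the seed.
#' @param region_radius Sphere radius in mm (default 8).
#' @return A list with `parcellation` (class `vep_parcellation`: fields
#'   `region_labels`, `centers`, `cortical`, `R`) and `mesh` (class
#'   `vep_mesh`: fields `vertices`, `triangles`, `region_of_vertex`,
#'   `vertex_area`).
#' @export
generate_parcellation_geometry <- function(R = 162, vertices_per_region = 30,
                                           seed = 1, region_radius = 8) {
  if (R < 2) stop("R must be >= 2")
  if (vertices_per_region < 3) stop("vertices_per_region must be >= 3")
  set.seed(seed)
  box <- c(140, 180, 120)
  centers <- matrix(NA_real_, R, 3)
  n_placed <- 0
  sep <- 2.2 * region_radius
  tries <- 0
  while (n_placed < R) {
    cand <- (runif(3) - 0.5) * box
    if (n_placed == 0 ||
        min(sqrt(colSums((t(centers[seq_len(n_placed), , drop = FALSE]) -
                          cand)^2))) > sep) {
      n_placed <- n_placed + 1
      centers[n_placed, ] <- cand
      tries <- 0
    } else {
      tries <- tries + 1
      if (tries > 5000) { sep <- sep * 0.9; tries <- 0 }  # avoid jamming
    }
  }
  labels <- sprintf("Region-%03d", seq_len(R))
  cortical <- rep(TRUE, R)
  if (R > 4) cortical[sample.int(R, max(1, round(0.15 * R)))] <- FALSE

  verts <- vector("list", R)
  tris <- vector("list", R)
  offset <- 0L
  for (j in seq_len(R)) {
    sp <- fibonacci_sphere(vertices_per_region)
    # a closed surface needs >= 4 vertices; with 3 the region degenerates
    # to a single triangle patch
    hull <- if (vertices_per_region == 3) matrix(1:3, 1) else convhull_tris(sp)
    verts[[j]] <- sweep(sp * region_radius, 2, centers[j, ], "+")
    tris[[j]] <- hull + offset
    offset <- offset + vertices_per_region
  }
  vertices <- do.call(rbind, verts)
  triangles <- do.call(rbind, tris)
  region_of_vertex <- rep(seq_len(R), each = vertices_per_region)
  mesh <- structure(list(vertices = vertices, triangles = triangles,
                         region_of_vertex = region_of_vertex),
                    class = "vep_mesh")
  mesh$vertex_area <- vertex_areas(mesh)
  parc <- structure(list(region_labels = labels, centers = centers,
                         cortical = cortical, R = R),
                    class = "vep_parcellation")
  list(parcellation = parc, mesh = mesh)
}

# Near-uniform points on the unit sphere (golden-angle spiral).
fibonacci_sphere <- function(n) {
  i <- seq_len(n) - 0.5
  phi <- acos(1 - 2 * i / n)
  theta <- pi * (1 + sqrt(5)) * i
  cbind(sin(phi) * cos(theta), sin(phi) * sin(theta), cos(phi))
}

# Convex-hull triangulation of points on a sphere, oriented outward.
convhull_tris <- function(pts) {
  hull <- geometry_convhulln(pts)
  # orient each triangle so its normal points away from the origin
  for (k in seq_len(nrow(hull))) {
    v <- pts[hull[k, ], ]
    nrm <- crossprod3(v[2, ] - v[1, ], v[3, ] - v[1, ])
    if (sum(nrm * colMeans(v)) < 0) hull[k, ] <- hull[k, c(1, 3, 2)]
  }
  hull
}

# Minimal incremental convex hull for small point sets on a sphere.
# Gift-wrapping would be quadratic per face; for the few dozen vertices a
# region uses, a simple incremental hull is plenty.
geometry_convhulln <- function(pts) {
  n <- nrow(pts)
  stopifnot(n >= 4)
  # start from a non-degenerate tetrahedron
  i1 <- 1
  i2 <- which.max(rowSums((pts - matrix(pts[i1, ], n, 3, byrow = TRUE))^2))
  d12 <- pts[i2, ] - pts[i1, ]
  cr <- t(apply(pts, 1, function(p) crossprod3(d12, p - pts[i1, ])))
  i3 <- which.max(rowSums(cr^2))
  nrm <- crossprod3(d12, pts[i3, ] - pts[i1, ])
  dst <- abs(as.vector((pts - matrix(pts[i1, ], n, 3, byrow = TRUE)) %*% nrm))
  i4 <- which.max(dst)
  faces <- rbind(c(i1, i2, i3), c(i1, i2, i4), c(i1, i3, i4), c(i2, i3, i4))
  centroid <- colMeans(pts[c(i1, i2, i3, i4), ])
  orient <- function(f) {
    v <- pts[f, ]
    nn <- crossprod3(v[2, ] - v[1, ], v[3, ] - v[1, ])
    if (sum(nn * (colMeans(v) - centroid)) < 0) f[c(1, 3, 2)] else f
  }
  faces <- t(apply(faces, 1, orient))
  for (p in setdiff(seq_len(n), c(i1, i2, i3, i4))) {
    vis <- logical(nrow(faces))
    for (k in seq_len(nrow(faces))) {
      v <- pts[faces[k, ], ]
      nn <- crossprod3(v[2, ] - v[1, ], v[3, ] - v[1, ])
      vis[k] <- sum(nn * (pts[p, ] - v[1, ])) > 1e-12
    }
    if (!any(vis)) next
    # horizon edges: edges of visible faces not shared by two visible faces
    edges <- NULL
    for (k in which(vis)) {
      f <- faces[k, ]
      edges <- rbind(edges, f[c(1, 2)], f[c(2, 3)], f[c(3, 1)])
    }
    key <- apply(edges, 1, function(e) paste(sort(e), collapse = "-"))
    horizon <- edges[key %in% names(which(table(key) == 1)), , drop = FALSE]
    faces <- faces[!vis, , drop = FALSE]
    for (k in seq_len(nrow(horizon)))
      faces <- rbind(faces, orient(c(horizon[k, ], p)))
  }
  unname(faces)
}

crossprod3 <- function(u, v) {
  c(u[2] * v[3] - u[3] * v[2],
    u[3] * v[1] - u[1] * v[3],
    u[1] * v[2] - u[2] * v[1])
}

#' Synthetic structural connectome
#'
#' Emulates a streamline-count connectome statistically: symmetric,
#' non-negative, zero diagonal, with log-normal weight magnitudes (heavy
#' tailed, as streamline counts are) on a random subset of edges. The
#' diagonal is zeroed first and the matrix then max-normalized, so the
#' largest entry is exactly 1.
#'
#' @param R Number of regions (>= 2).
#' @param density Expected fraction of nonzero off-diagonal entries
#'   (0 < density <= 1; default 0.3).
#' @param seed Integer seed.
#' @return A `vep_connectome` object: fields `weights` (R x R) and
#'   `tract_lengths` (R x R, mm).
#' @export
generate_connectome <- function(R, density = 0.3, seed = 1) {
  if (R < 2) stop("R must be >= 2")
  if (density <= 0 || density > 1) stop("density must be in (0, 1]")
  set.seed(seed)
  W <- matrix(0, R, R)
  up <- upper.tri(W)
  n_up <- sum(up)
  present <- runif(n_up) < density
  w <- ifelse(present, stats::rlnorm(n_up, meanlog = 0, sdlog = 1), 0)
  W[up] <- w
  W <- W + t(W)
  diag(W) <- 0
  if (max(W) > 0) W <- W / max(W)
  L <- matrix(0, R, R)
  L[up] <- ifelse(present, runif(n_up, 10, 150), 0)
  L <- L + t(L)
  structure(list(weights = W, tract_lengths = L), class = "vep_connectome")
}

#' Validate connectome invariants
#'
#' Checks symmetry, non-negativity, zero diagonal and max-normalization.
#'
#' @param con A `vep_connectome` or weight matrix.
#' @return Invisibly `TRUE`; errors otherwise.
#' @export
validate_connectome <- function(con) {
  W <- if (inherits(con, "vep_connectome")) con$weights else con
  if (!isTRUE(all.equal(W, t(W)))) stop("connectome is not symmetric")
  if (any(W < 0)) stop("connectome has negative weights")
  if (any(diag(W) != 0)) stop("connectome diagonal is not zero")
  if (max(W) > 0 && abs(max(W) - 1) > 1e-12)
    stop("connectome is not max-normalized")
  invisible(TRUE)
}

#' Synthetic SEEG implantation
#'
#' Generates `n_shafts` straight depth-electrode shafts aimed at randomly
#' chosen region centers. Each shaft carries 10-18 contacts at a constant
#' spacing of 1.5 or 5 mm, entering from outside the implanted volume so
#' that contact depth spans the target. Labels follow the clinical
#' shaft-letter + index convention (A1, A2, ..., B1, ...).
#'
#' @param parcellation A `vep_parcellation`.
#' @param n_shafts Number of shafts (>= 1).
#' @param seed Integer seed.
#' @param target_regions Optional region indices to aim the shafts at
#'   (recycled); default random.
#' @param spacing Optional fixed contact spacing in mm (1.5 or 5) applied
#'   to every shaft; default random per shaft (1.5 with probability 0.8).
#' @return A `vep_electrodes` object: data frame `contacts` with columns
#'   `label`, `shaft`, `x`, `y`, `z`, plus `spacing` (mm per shaft).
#' @export
generate_electrode_implantation <- function(parcellation, n_shafts, seed = 1,
                                            target_regions = NULL,
                                            spacing = NULL) {
  if (!is.null(spacing) && !spacing %in% c(1.5, 5))
    stop("spacing must be 1.5 or 5 mm")
  if (n_shafts < 1) stop("n_shafts must be >= 1")
  set.seed(seed)
  shaft_letters <- c(LETTERS, paste0(LETTERS, "'"))
  if (n_shafts > length(shaft_letters)) stop("too many shafts to label")
  centers <- parcellation$centers
  if (is.null(target_regions))
    target_regions <- sample.int(parcellation$R, n_shafts, replace = TRUE)
  target_regions <- rep_len(target_regions, n_shafts)
  out <- vector("list", n_shafts)
  spacing_all <- numeric(n_shafts)
  for (s in seq_len(n_shafts)) {
    n_contacts <- sample(10:18, 1)
    sp_s <- if (is.null(spacing)) sample(c(1.5, 5), 1, prob = c(0.8, 0.2))
            else spacing
    spacing_all[s] <- sp_s
    # aim near, not exactly at, the region center: clinical trajectories
    # pass by their target, and an exactly central pass would give adjacent
    # contacts nearly equal gain (bipolar channels would cancel)
    target <- centers[target_regions[s], ] + rnorm(3, sd = 4)
    dir <- rnorm(3)
    dir <- dir / sqrt(sum(dir^2))
    # entry point outside the head volume, shaft passes through the target;
    # the deepest contact sits just past the target center
    depth <- (seq_len(n_contacts) - 1) * sp_s
    deepest <- max(depth)
    pos <- t(vapply(depth, function(d) target + dir * (deepest / 2 - d),
                    numeric(3)))
    out[[s]] <- data.frame(
      label = paste0(shaft_letters[s], seq_len(n_contacts)),
      shaft = shaft_letters[s],
      x = pos[, 1], y = pos[, 2], z = pos[, 3],
      stringsAsFactors = FALSE)
  }
  contacts <- do.call(rbind, out)
  rownames(contacts) <- NULL
  structure(list(contacts = contacts,
                 spacing = stats::setNames(spacing_all,
                                           shaft_letters[seq_len(n_shafts)]),
                 contact_length_mm = 2),
            class = "vep_electrodes")
}

#' Contact coordinates as a matrix
#'
#' @param electrodes A `vep_electrodes` object.
#' @return N x 3 matrix with contact labels as row names.
#' @export
contact_positions <- function(electrodes) {
  m <- as.matrix(electrodes$contacts[, c("x", "y", "z")])
  rownames(m) <- electrodes$contacts$label
  m
}
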