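#' Per-vertex surface areas (one-third rule)
#'
#' The area attributed to a vertex is one third of the summed area of all
#' triangles incident to it, so the vertex areas of a mesh conserve its
#' total surface area. Degenerate (zero-area) triangles contribute
#' nothing; isolated vertices get area 0.
#'
#' @param mesh A `vep_mesh` (fields `vertices`, `triangles`).
#' @return Numeric vector of per-vertex areas (mm^2).
#' @export
vertex_areas <- function(mesh) {
  V <- nrow(mesh$vertices)
  tri <- mesh$triangles
  if (is.null(tri) || nrow(tri) == 0) return(numeric(V))
  if (max(tri) > V) stop("triangle index exceeds vertex count")
  p1 <- mesh$vertices[tri[, 1], , drop = FALSE]
  p2 <- mesh$vertices[tri[, 2], , drop = FALSE]
  p3 <- mesh$vertices[tri[, 3], , drop = FALSE]
  u <- p2 - p1
  v <- p3 - p1
  cx <- u[, 2] * v[, 3] - u[, 3] * v[, 2]
  cy <- u[, 3] * v[, 1] - u[, 1] * v[, 3]
  cz <- u[, 1] * v[, 2] - u[, 2] * v[, 1]
  tarea <- 0.5 * sqrt(cx^2 + cy^2 + cz^2)
  a <- numeric(V)
  for (k in 1:3) {
    acc <- tapply(tarea, tri[, k], sum)
    idx <- as.integer(names(acc))
    a[idx] <- a[idx] + acc / 3
  }
  a
}

#' Source-to-sensor gain matrix
#'
#' Distance-based SEEG forward solution: the gain from region `j` to
#' sensor `k` is the sum over the region's surface vertices of the vertex
#' area divided by the squared Euclidean distance to the sensor,
#' `g_jk = sum_i a_i / d_ik^2`. Dipole orientation is not modelled; no
#' normalization is applied, so simulated SEEG amplitudes are in
#' arbitrary units.
#'
#' @param mesh A `vep_mesh` with `region_of_vertex` and `vertex_area`.
#' @param sensors N x 3 matrix of sensor positions (mm), row names used
#'   as sensor labels, or a `vep_electrodes` object.
#' @param region_labels Optional region labels for the row names.
#' @return R x N gain matrix (class `matrix`), regions in rows.
#' @export
compute_gain <- function(mesh, sensors, region_labels = NULL) {
  if (inherits(sensors, "vep_electrodes")) sensors <- contact_positions(sensors)
  stopifnot(is.matrix(sensors), ncol(sensors) == 3)
  reg <- mesh$region_of_vertex
  a <- mesh$vertex_area
  if (is.null(a)) a <- vertex_areas(mesh)
  R <- max(reg)
  N <- nrow(sensors)
  G <- matrix(0, R, N)
  for (k in seq_len(N)) {
    d2 <- rowSums(sweep(mesh$vertices, 2, sensors[k, ])^2)
    if (any(d2 == 0))
      stop("sensor ", k, " coincides with a source vertex (zero distance)")
    contrib <- a / d2
    s <- tapply(contrib, reg, sum)
    G[as.integer(names(s)), k] <- s
  }
  rownames(G) <- if (!is.null(region_labels)) region_labels
                 else sprintf("Region-%03d", seq_len(R))
  colnames(G) <- rownames(sensors)
  G
}

#' Project source activity to sensors
#'
#' Matrix multiplication of the simulated source activity with the gain
#' matrix yields the simulated SEEG signals: `sensor = t(gain) %*% source`.
#'
#' @param gain R x N gain matrix.
#' @param source R x T source time-series matrix.
#' @return N x T sensor time-series matrix.
#' @export
project_to_sensors <- function(gain, source) {
  if (!is.matrix(source)) source <- matrix(source, nrow = nrow(gain))
  if (nrow(source) != nrow(gain))
    stop("source has ", nrow(source), " regions but gain has ", nrow(gain))
  t(gain) %*% source
}

#' Bipolar montage from an implantation
#'
#' Builds the clinical bipolar montage: one channel per pair of adjacent
#' contacts on the same shaft, labelled like "B1-2", signal defined as
#' the positive contact minus the negative contact.
#'
#' @param electrodes A `vep_electrodes` object.
#' @return Data frame of class `vep_montage` with columns `channel`,
#'   `positive`, `negative`.
#' @export
bipolar_montage <- function(electrodes) {
  ct <- electrodes$contacts
  out <- NULL
  for (sh in unique(ct$shaft)) {
    rows <- ct[ct$shaft == sh, ]
    idx <- as.integer(sub("^.*?(\\d+)$", "\\1", rows$label))
    rows <- rows[order(idx), ]
    n <- nrow(rows)
    if (n < 2) next
    out <- rbind(out, data.frame(
      channel = paste0(rows$label[-n], "-", seq_len(n)[-1]),
      positive = rows$label[-n],
      negative = rows$label[-1],
      stringsAsFactors = FALSE))
  }
  class(out) <- c("vep_montage", class(out))
  out
}

#' Apply a bipolar montage to monopolar sensor signals
#'
#' @param sensor_ts N x T monopolar matrix with contact labels as row
#'   names.
#' @param montage A `vep_montage` data frame.
#' @return C x T bipolar matrix with channel labels as row names.
#' @export
apply_montage <- function(sensor_ts, montage) {
  labs <- rownames(sensor_ts)
  missing <- setdiff(c(montage$positive, montage$negative), labs)
  if (length(missing) > 0)
    stop("unknown contact label(s): ", paste(missing, collapse = ", "))
  out <- sensor_ts[montage$positive, , drop = FALSE] -
    sensor_ts[montage$negative, , drop = FALSE]
  rownames(out) <- montage$channel
  out
}
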