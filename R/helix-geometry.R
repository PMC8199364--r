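# Helix axis fitting and the four helix geometry metrics: rise per residue
# (d), total length (L = d * n), radius (r) and twist per residue (theta),
# plus the end-to-end distance of a helical segment.

#' Fit a straight axis to ordered C-alpha coordinates
#'
#' The axis direction is the principal (largest-variance) axis of the
#' centred coordinate cloud, oriented from the first towards the last
#' residue; the axis point is the centroid.
#'
#' @param ca_coords n x 3 matrix of C-alpha positions in residue order
#'   (n >= 5).
#' @return object of class `helix_axis`: list with unit `direction` and
#'   `point` (nm).
#' @export
fit_axis <- function(ca_coords) {
  x <- as.matrix(ca_coords)
  if (nrow(x) < 5L) stop("axis fitting needs at least 5 C-alpha positions")
  centroid <- colMeans(x)
  xc <- sweep(x, 2L, centroid)
  e <- eigen(crossprod(xc) / nrow(xc), symmetric = TRUE)
  if (e$values[1L] < 1e-12) stop("degenerate (point-like) coordinate cloud")
  if (e$values[1L] / max(e$values[2L], 1e-300) < 1.2) {
    stop("degenerate (near-spherical) coordinate cloud: no unique axis")
  }
  dir <- e$vectors[, 1L]
  if (sum(dir * (x[nrow(x), ] - x[1L, ])) < 0) dir <- -dir
  structure(list(direction = dir / vec_norm(dir), point = centroid),
            class = "helix_axis")
}

#' Helix geometry metrics from C-alpha coordinates
#'
#' After fitting the axis and transforming so the axis is z through the
#' origin: the rise d is the mean |z(i+1) - z(i)| between sequential
#' residues; the radius r = sqrt( (1/N) sum_i (x_i^2 + y_i^2) ), i.e. the
#' RMS distance of the C-alphas from the axis; the twist theta is the mean
#' absolute rotation about the axis between the (x, y) projections of
#' consecutive C-alphas; and L = d * n with n the number of residues (the
#' rise-times-count convention, slightly longer than the geometric span
#' d * (n - 1)).
#'
#' @param ca_coords n x 3 matrix of C-alpha positions in residue order
#'   (n >= 5, not collinear).
#' @return object of class `helix_metrics`: list with `d`, `L`, `r` (nm),
#'   `theta` (deg), `n`, `axis`.
#' @export
helix_metrics <- function(ca_coords) {
  x <- as.matrix(ca_coords)
  axis <- fit_axis(x)
  xc <- sweep(x, 2L, axis$point)
  z <- as.numeric(xc %*% axis$direction)
  # orthonormal frame perpendicular to the axis
  ref <- if (abs(axis$direction[1L]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  u <- unit(cross3(axis$direction, ref))
  v <- cross3(axis$direction, u)
  px <- as.numeric(xc %*% u)
  py <- as.numeric(xc %*% v)
  r <- sqrt(mean(px^2 + py^2))
  if (r < 1e-6) {
    stop("collinear C-alpha trace (radius < 1e-6 nm): twist undefined")
  }
  d <- mean(abs(diff(z)))
  az <- atan2(py, px) * 180 / pi
  theta <- mean(abs(wrap_angle(diff(az))))
  n <- nrow(x)
  structure(list(d = d, L = d * n, r = r, theta = theta, n = n, axis = axis),
            class = "helix_metrics")
}

#' @export
print.helix_metrics <- function(x, ...) {
  cat(sprintf("<helix_metrics> n=%d d=%.4f nm L=%.3f nm r=%.4f nm theta=%.2f deg\n",
              x$n, x$d, x$L, x$r, x$theta))
  invisible(x)
}

#' Block-averaged helix metrics over a trajectory
#'
#' Computes d, L, r, theta per helix per frame and block-averages each over
#' the trailing window.
#'
#' @param traj a `trajectory`.
#' @param annotation a `region_annotation` with helix ranges.
#' @param window trailing analysis window (ns); NULL = full trajectory.
#' @param n_blocks number of blocks.
#' @return data.frame, one row per helix and metric pair: columns
#'   `helix_id`, `n_res`, `d_mean`, `d_err`, `L_mean`, `L_err`, `r_mean`,
#'   `r_err`, `theta_mean`, `theta_err`.
#' @export
helix_metrics_series <- function(traj, annotation, window = NULL, n_blocks = 5L) {
  hr <- helix_ranges(annotation)
  if (nrow(hr) == 0L) stop("annotation contains no helix ranges")
  system <- traj$topology
  a <- system$atoms
  out <- lapply(seq_len(nrow(hr)), function(h) {
    rows <- which(a$chain_id == hr$chain_id[h] & a$name == "CA" &
                  a$res_index >= hr$res_start[h] & a$res_index <= hr$res_end[h])
    rows <- rows[order(a$res_index[rows])]
    per_frame <- t(vapply(seq_len(n_frames(traj)), function(k) {
      m <- helix_metrics(traj$frames[[k]][rows, , drop = FALSE])
      c(m$d, m$L, m$r, m$theta)
    }, numeric(4L)))
    b <- lapply(1:4, function(j) block_average(per_frame[, j], times = traj$times,
                                               window = window, n_blocks = n_blocks))
    data.frame(helix_id = hr$helix_id[h], n_res = length(rows),
               d_mean = b[[1L]]$mean, d_err = b[[1L]]$error,
               L_mean = b[[2L]]$mean, L_err = b[[2L]]$error,
               r_mean = b[[3L]]$mean, r_err = b[[3L]]$error,
               theta_mean = b[[4L]]$mean, theta_err = b[[4L]]$error,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' End-to-end distance of a helical segment
#'
#' Euclidean distance between the first atom (file order) of the first
#' residue and the last atom of the last residue of the range.
#'
#' @param system a `molecular_system`.
#' @param chain_id chain of the segment.
#' @param res_range integer vector (its range is used) of helix residues.
#' @param xyz optional coordinate matrix overriding the system coordinates.
#' @return distance in nm.
#' @export
end_to_end <- function(system, chain_id, res_range, xyz = NULL) {
  if (length(res_range) == 0L) stop("empty helix residue range")
  if (is.null(xyz)) xyz <- system$xyz
  a <- system$atoms
  lo <- min(res_range); hi <- max(res_range)
  first_rows <- which(a$chain_id == chain_id & a$res_index == lo)
  last_rows <- which(a$chain_id == chain_id & a$res_index == hi)
  if (length(first_rows) == 0L || length(last_rows) == 0L) {
    stop("helix range not present in chain ", chain_id)
  }
  p1 <- xyz[first_rows[1L], ]
  p2 <- xyz[last_rows[length(last_rows)], ]
  vec_norm(p2 - p1)
}
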