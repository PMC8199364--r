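# Rigid-body superposition (Kabsch) and the deviation metrics built on it:
# RMSD time series, the relative deviation contrast between two thermal
# conditions, and per-residue RMSF.

#' Least-squares rigid superposition (Kabsch)
#'
#' Finds the proper rotation R and translation t minimising
#' sum_i || R m_i + t - q_i ||^2; reflections are excluded by the usual
#' determinant sign correction.
#'
#' @param mobile,target n x 3 coordinate matrices (n >= 3, non-collinear).
#' @return object of class `rigid_transform`: list with `rotation` (3 x 3,
#'   det = +1) and `translation` (length 3).
#' @export
kabsch_fit <- function(mobile, target) {
  mobile <- as.matrix(mobile); target <- as.matrix(target)
  if (nrow(mobile) != nrow(target)) stop("point sets differ in size")
  if (nrow(mobile) < 3L) stop("at least 3 points are required")
  mc <- colMeans(mobile); qc <- colMeans(target)
  M <- sweep(mobile, 2L, mc)
  Q <- sweep(target, 2L, qc)
  H <- t(M) %*% Q
  s <- svd(H)
  if (s$d[2L] < 1e-12 * max(s$d[1L], 1e-300)) {
    stop("rank-deficient (collinear) point set")
  }
  d <- sign(det(s$v %*% t(s$u)))
  R <- s$v %*% diag(c(1, 1, d)) %*% t(s$u)
  structure(list(rotation = R, translation = as.numeric(qc - R %*% mc)),
            class = "rigid_transform")
}

#' Apply a rigid transform to coordinates
#'
#' @param transform a `rigid_transform`.
#' @param coords n x 3 matrix.
#' @return transformed n x 3 matrix.
#' @export
apply_transform <- function(transform, coords) {
  sweep(as.matrix(coords) %*% t(transform$rotation), 2L,
        transform$translation, "+")
}

rmsd_value <- function(x, ref) sqrt(mean(rowSums((x - ref)^2)))

#' RMSD time series against a reference structure
#'
#' For each frame, rmsd(t) = sqrt( (1/N) sum_i ||r_i(t) - r_i^ref||^2 )
#' over the selected atoms, optionally after least-squares superposition of
#' the frame onto the reference on the same selection.
#'
#' @param traj a `trajectory`.
#' @param reference a `molecular_system` (e.g. the native structure).
#' @param selection an `atom_selection` resolving in both topologies.
#' @param fit superpose each frame onto the reference first (default TRUE).
#' @return object of class `deviation_series`: list with `times`, `values`
#'   (nm), `fitted`, `n_atoms`.
#' @export
rmsd_series <- function(traj, reference, selection, fit = TRUE) {
  if (length(selection) == 0L) stop("empty selection")
  ref_idx <- resolve_selection(selection, reference)
  ref <- reference$xyz[ref_idx, , drop = FALSE]
  vals <- vapply(seq_len(n_frames(traj)), function(k) {
    x <- traj$frames[[k]][selection$index, , drop = FALSE]
    if (fit) x <- apply_transform(kabsch_fit(x, ref), x)
    rmsd_value(x, ref)
  }, numeric(1L))
  structure(list(times = traj$times, values = vals, fitted = fit,
                 n_atoms = length(selection)),
            class = "deviation_series")
}

#' @export
print.deviation_series <- function(x, ...) {
  cat(sprintf("<deviation_series> %d frames, %d atoms, fit=%s, mean %.4f nm\n",
              length(x$values), x$n_atoms, x$fitted, mean(x$values)))
  invisible(x)
}

#' Relative RMSD increase between two thermal conditions
#'
#' For matched series, D(t_i) = |rmsd_T(t_i) - rmsd_ref(t_i)| /
#' rmsd_ref(t_i), a unitless fraction (multiply by 100 for percent).
#' Points where the reference RMSD is zero are undefined; they are excluded
#' from the average and counted.
#'
#' @param series_t `deviation_series` at the condition of interest.
#' @param series_ref `deviation_series` at the reference condition, on the
#'   same time grid.
#' @return object of class `percent_d`: list with `times`, `values`
#'   (fractions; NA at undefined points), `mean`, `n_undefined`.
#' @export
percent_increase <- function(series_t, series_ref) {
  if (length(series_t$values) != length(series_ref$values) ||
      any(abs(series_t$times - series_ref$times) > 1e-9)) {
    stop("series must share one time grid")
  }
  undef <- series_ref$values == 0
  vals <- ifelse(undef, NA_real_,
                 abs(series_t$values - series_ref$values) / series_ref$values)
  if (any(undef)) {
    warning(sum(undef), " undefined point(s) (reference rmsd = 0) excluded")
  }
  structure(list(times = series_t$times, values = vals,
                 mean = mean(vals, na.rm = TRUE),
                 n_undefined = sum(undef)),
            class = "percent_d")
}

#' @export
print.percent_d <- function(x, ...) {
  cat(sprintf("<percent_d> mean %.1f%% over %d points (%d undefined)\n",
              100 * x$mean, sum(!is.na(x$values)), x$n_undefined))
  invisible(x)
}

#' Per-residue root mean square fluctuation
#'
#' rmsf_i = sqrt( (1/T) sum_j ||r_i(t_j) - r_i^ref||^2 ) per selected atom
#' (one atom per residue, conventionally C-alpha).  Frames are first
#' superposed onto the reference over the full selection unless
#' `superpose = FALSE`.  The reference is the time-mean structure (default),
#' the first frame, or a supplied `molecular_system`.
#'
#' @param traj a `trajectory` with >= 2 frames.
#' @param selection an `atom_selection` with one atom per residue.
#' @param reference `"time_mean"`, `"first_frame"`, or a `molecular_system`.
#' @param chain_average average values at the same residue index across
#'   chains (chains must then have matching selected residue indices).
#' @param superpose least-squares fit each frame onto the reference first.
#' @return data.frame with columns `chain_id` (dropped when
#'   `chain_average`), `res_index`, `rmsf` (nm).
#' @export
rmsf_per_residue <- function(traj, selection, reference = "time_mean",
                             chain_average = FALSE, superpose = TRUE) {
  if (n_frames(traj) < 2L) stop("rmsf needs at least 2 frames")
  if (length(selection) == 0L) stop("empty selection")
  refs <- selection$refs
  if (anyDuplicated(paste(refs$chain_id, refs$res_index))) {
    stop("selection must contain one atom per residue")
  }
  frames <- lapply(traj$frames, function(f) f[selection$index, , drop = FALSE])

  ref_coords <- if (inherits(reference, "molecular_system")) {
    reference$xyz[resolve_selection(selection, reference), , drop = FALSE]
  } else if (identical(reference, "first_frame")) {
    frames[[1L]]
  } else if (identical(reference, "time_mean")) {
    NULL  # computed after superposition below
  } else stop("reference must be 'time_mean', 'first_frame' or a molecular_system")

  if (superpose) {
    fit_target <- if (is.null(ref_coords)) frames[[1L]] else ref_coords
    frames <- lapply(frames, function(x) apply_transform(kabsch_fit(x, fit_target), x))
  }
  if (is.null(ref_coords)) {
    ref_coords <- Reduce(`+`, frames) / length(frames)
  }
  sq <- Reduce(`+`, lapply(frames, function(x) rowSums((x - ref_coords)^2)))
  rmsf <- sqrt(sq / length(frames))
  out <- data.frame(chain_id = refs$chain_id, res_index = refs$res_index,
                    rmsf = rmsf, stringsAsFactors = FALSE)
  rownames(out) <- NULL
  if (chain_average) {
    agg <- tapply(out$rmsf, out$res_index, mean)
    out <- data.frame(res_index = as.integer(names(agg)),
                      rmsf = as.numeric(agg))
    out <- out[order(out$res_index), ]
    rownames(out) <- NULL
  }
  out
}
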