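#' Time-lagged independent component analysis
#'
#' Solves the symmetrized time-lagged generalized eigenproblem
#' \eqn{C(\tau) v = \lambda C(0) v} over all trajectories pooled (joint mean
#' removal), where \eqn{C(\tau)} is the forward/backward-averaged time-lagged
#' covariance. Components are whitened (\eqn{v^T C(0) v = 1}), ordered by
#' eigenvalue, and sign-fixed so the largest-magnitude loading of each
#' component is positive.
#'
#' @param trajs A `traj_set` with feature columns (see [emit_features()]), or
#'   a data frame with `traj_id` and `feat_*` columns.
#' @param lag Lag time in ns (default 0.1).
#' @param n_components Number of retained components (default 2).
#' @param ridge Ridge added to the instantaneous covariance diagonal.
#' @param dt Frame interval in ns; taken from the `traj_set` if omitted.
#' @return A `tica_model`.
#' @export
estimate_tica <- function(trajs, lag = 0.1, n_components = 2,
                          ridge = 1e-10, dt = NULL) {
  frames <- if (inherits(trajs, "traj_set")) trajs$frames else as_tibble(trajs)
  if (is.null(dt)) {
    if (!inherits(trajs, "traj_set")) abort("dt required for plain data frames")
    dt <- trajs$dt
  }
  fc <- feature_cols(frames)
  if (length(fc) == 0) abort("no feature columns (feat_*) found")
  lag_frames <- max(1L, as.integer(round(lag / dt)))
  X <- as.matrix(frames[, fc])
  if (!all(is.finite(X))) abort("features must be finite")
  ids <- frames$traj_id
  mu <- colMeans(X)
  Xc <- sweep(X, 2, mu)

  D <- length(fc)
  C0 <- matrix(0, D, D); Ct <- matrix(0, D, D)
  n_pairs <- 0L
  for (id in unique(ids)) {
    idx <- which(ids == id)
    if (length(idx) <= lag_frames) {
      warn(sprintf("trajectory '%s' shorter than lag; skipped", id))
      next
    }
    a <- Xc[idx[seq_len(length(idx) - lag_frames)], , drop = FALSE]
    b <- Xc[idx[-seq_len(lag_frames)], , drop = FALSE]
    C0 <- C0 + crossprod(a) + crossprod(b)
    Ct <- Ct + crossprod(a, b) + crossprod(b, a)
    n_pairs <- n_pairs + nrow(a)
  }
  if (n_pairs == 0) abort("no trajectory longer than the lag")
  C0 <- C0 / (2 * n_pairs); Ct <- Ct / (2 * n_pairs)
  C0 <- C0 + diag(ridge, D)

  # whiten through the symmetric square root of C0
  e0 <- eigen(C0, symmetric = TRUE)
  pos <- e0$values > max(e0$values) * 1e-12
  L <- e0$vectors[, pos, drop = FALSE] %*%
    diag(1 / sqrt(e0$values[pos]), sum(pos))
  Wm <- crossprod(L, Ct %*% L)
  Wm <- (Wm + t(Wm)) / 2
  ew <- eigen(Wm, symmetric = TRUE)
  ncomp <- min(n_components, ncol(Wm))
  lam <- ew$values[seq_len(ncomp)]
  V <- L %*% ew$vectors[, seq_len(ncomp), drop = FALSE]
  for (m in seq_len(ncomp)) {
    k <- which.max(abs(V[, m]))
    if (V[k, m] < 0) V[, m] <- -V[, m]
  }
  rownames(V) <- fc
  structure(
    list(lag = lag, lag_frames = lag_frames, mean = setNames(mu, fc),
         eigenvalues = lam, loadings = V, features = fc,
         n_pairs = n_pairs, dt = dt),
    class = "tica_model")
}

#' @export
print.tica_model <- function(x, ...) {
  cat("<tica_model> lag =", x$lag, "ns,", length(x$eigenvalues),
      "components; eigenvalues:",
      paste(signif(x$eigenvalues, 4), collapse = ", "), "\n")
  invisible(x)
}

#' Project frames onto tICA components
#'
#' Adds columns `tic_1 ... tic_m` to the trajectory frames.
#'
#' @param trajs A `traj_set` or data frame with the model's feature columns.
#' @param model A `tica_model`.
#' @return Same type as `trajs`, with tIC columns appended.
#' @export
project_tica <- function(trajs, model) {
  frames <- if (inherits(trajs, "traj_set")) trajs$frames else as_tibble(trajs)
  X <- as.matrix(frames[, model$features])
  Y <- sweep(X, 2, model$mean) %*% model$loadings
  colnames(Y) <- paste0("tic_", seq_len(ncol(Y)))
  frames <- dplyr::bind_cols(frames[setdiff(names(frames), colnames(Y))],
                             as_tibble(Y))
  if (inherits(trajs, "traj_set")) { trajs$frames <- frames; trajs }
  else frames
}

#' Correlate features with tICA components and select the high-|r| set
#'
#' Pearson correlation of every feature against every retained tIC over all
#' pooled frames; a feature is selected when its maximum absolute correlation
#' exceeds `threshold` (default 0.6). Zero-variance features get |r| = 0 and a
#' warning.
#'
#' @param trajs A `traj_set` or data frame with feature columns.
#' @param model A `tica_model` fitted on the same feature space.
#' @param threshold Absolute-correlation selection threshold.
#' @return A tibble: `feature`, one `abs_r_tic_*` column per component,
#'   `max_abs_r`, `selected`.
#' @export
correlate_features_to_tics <- function(trajs, model, threshold = 0.6) {
  frames <- project_tica(trajs, model)
  if (inherits(frames, "traj_set")) frames <- frames$frames
  tc <- grep("^tic_", names(frames), value = TRUE)
  X <- as.matrix(frames[, model$features])
  Y <- as.matrix(frames[, tc])
  sds <- apply(X, 2, sd)
  if (any(sds == 0)) warn("zero-variance feature(s); |r| set to 0")
  R <- matrix(0, ncol(X), ncol(Y),
              dimnames = list(model$features, paste0("abs_r_", tc)))
  ok <- sds > 0
  R[ok, ] <- abs(cor(X[, ok, drop = FALSE], Y))
  out <- as_tibble(R, rownames = "feature")
  out$max_abs_r <- apply(R, 1, max)
  out$selected <- out$max_abs_r > threshold
  out
}

#' Rank entities by the number of selected feature pairs they appear in
#'
#' Features that represent pairwise observables can be mapped to the entities
#' (e.g. residues) they connect; entities are then ranked by how many selected
#' pairs involve them.
#'
#' @param selection Output of [correlate_features_to_tics()].
#' @param pairs Tibble with columns `feature`, `entity_a`, `entity_b`.
#' @return Tibble `entity`, `n_pairs`, sorted decreasing.
#' @export
rank_entities <- function(selection, pairs) {
  sel <- dplyr::filter(selection, .data$selected)
  hits <- dplyr::inner_join(pairs, sel["feature"], by = "feature")
  long <- tibble(entity = c(hits$entity_a, hits$entity_b))
  dplyr::arrange(dplyr::count(long, .data$entity, name = "n_pairs"),
                 dplyr::desc(.data$n_pairs))
}

#' Select features whose sensors sit near high-density grid points
#'
#' Returns the features whose sensor position lies within `cutoff` of any
#' grid point whose bulk-normalized density is at least `factor`.
#'
#' @param grid A `density_grid` (normalized to bulk; see
#'   [build_density_grid()]).
#' @param sensors Tibble with columns `feature` and coordinate column(s)
#'   (`z_sensor` for 1D grids, or `x`,`y`,`z` matching the grid axes).
#' @param cutoff Distance cutoff in angstrom (> 0); default 4.4.
#' @param factor Density threshold relative to bulk; default 7.
#' @return Character vector of selected feature ids.
#' @export
select_features_near_density <- function(grid, sensors, cutoff = 4.4,
                                         factor = 7) {
  stopifnot(inherits(grid, "density_grid"))
  if (cutoff <= 0) abort("cutoff must be positive")
  centers <- grid_centers(grid)
  hot <- which(as.vector(grid$normalized) >= factor)
  if (length(hot) == 0) return(character(0))
  hotc <- centers[hot, , drop = FALSE]
  coord_cols <- intersect(c("z_sensor", "x", "y", "z"), names(sensors))
  P <- as.matrix(sensors[, coord_cols, drop = FALSE])
  if (ncol(P) != ncol(hotc)) {
    abort("sensor coordinates do not match grid dimensionality")
  }
  d2 <- outer(rowSums(P^2), rep(1, nrow(hotc))) +
    outer(rep(1, nrow(P)), rowSums(hotc^2)) - 2 * P %*% t(hotc)
  sensors$feature[sqrt(pmax(apply(d2, 1, min), 0)) <= cutoff]
}
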