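#' Split trajectories at periodic-boundary crossings
#'
#' Frames whose consecutive z jump exceeds half the box length are treated as
#' periodic-image crossings; the trajectory is split there so no artificial
#' transition links the two sides. Frame count is conserved; a trajectory with
#' `n` crossings yields `n + 1` segments.
#'
#' @param frames A `traj_set` or frames data frame with `traj_id` and `z`.
#' @param box_length Box edge along z (angstrom), > 0.
#' @return Same type as the input, with `traj_id` updated to segment ids.
#' @export
split_on_boundary_crossings <- function(frames, box_length) {
  if (box_length <= 0) abort("box length must be positive")
  is_set <- inherits(frames, "traj_set")
  fr <- if (is_set) frames$frames else as_tibble(frames)
  fr <- fr |>
    group_by(.data$traj_id) |>
    mutate(.seg = cumsum(c(0, abs(diff(.data$z)) > box_length / 2))) |>
    ungroup() |>
    mutate(traj_id = ifelse(.data$.seg == 0, .data$traj_id,
                            paste0(.data$traj_id, "_s", .data$.seg))) |>
    select(-".seg")
  if (is_set) { frames$frames <- fr; frames } else fr
}

#' k-means clustering in tIC space
#'
#' k-means with k-means++ seeding at a fixed seed, then Lloyd refinement via
#' [stats::kmeans()]. Assignment is to the nearest center, ties to the lowest
#' index.
#'
#' @param frames Data frame or `traj_set` with `tic_*` columns, or a numeric
#'   matrix of coordinates.
#' @param k Number of clusters (1 <= k <= frames).
#' @param seed Integer seed for the seeding step.
#' @return A `tic_clusters` object: `centers` (k x d) and `assignment`.
#' @export
cluster_tic_space <- function(frames, k, seed = 1) {
  X <- tic_matrix(frames)
  if (k < 1) abort("k must be >= 1")
  if (k > nrow(X)) abort("k exceeds the number of frames")
  centers <- with_local_seed(seed, kmeanspp_init(X, k))
  if (k == 1) {
    centers <- matrix(colMeans(X), 1)
  } else {
    km <- suppressWarnings(
      stats::kmeans(X, centers = centers, iter.max = 100, algorithm = "Lloyd"))
    centers <- km$centers
  }
  colnames(centers) <- colnames(X)
  structure(list(centers = unname(as.matrix(centers)),
                 assignment = nearest_center(X, centers), k = k),
            class = "tic_clusters")
}

tic_matrix <- function(frames) {
  if (is.matrix(frames)) return(frames)
  fr <- if (inherits(frames, "traj_set")) frames$frames else as_tibble(frames)
  tc <- grep("^tic_", names(fr), value = TRUE)
  if (!length(tc)) abort("no tic_* columns; run project_tica() first")
  as.matrix(fr[, tc])
}

kmeanspp_init <- function(X, k) {
  n <- nrow(X)
  centers <- matrix(NA_real_, k, ncol(X))
  centers[1, ] <- X[sample.int(n, 1), ]
  if (k > 1) {
    d2 <- rowSums(sweep(X, 2, centers[1, ])^2)
    for (j in 2:k) {
      p <- d2 / sum(d2)
      centers[j, ] <- X[sample.int(n, 1, prob = p), ]
      d2 <- pmin(d2, rowSums(sweep(X, 2, centers[j, ])^2))
    }
  }
  centers
}

nearest_center <- function(X, centers) {
  centers <- as.matrix(centers)
  d2 <- outer(rowSums(X^2), rep(1, nrow(centers))) +
    outer(rep(1, nrow(X)), rowSums(centers^2)) - 2 * X %*% t(centers)
  max.col(-d2, ties.method = "first")
}

#' Microstate map: z bins crossed with conformational clusters
#'
#' Defines the microstate space as the product of `n_zbins` equal z bins over
#' the umbrella range and `N` tIC cluster centers. Microstate ids are 0-based
#' internally, `id = (z_bin - 1) * N + (cluster - 1)`, with 1-based `z_bin`
#' and `cluster` used in reports.
#'
#' @param z_range Length-2 numeric, binning range (angstrom).
#' @param n_zbins Number of z bins (default 100).
#' @param clusters Optional `tic_clusters`; omit for `N = 1` (z-only states).
#' @return A `microstate_map`.
#' @export
microstate_map <- function(z_range, n_zbins = 100, clusters = NULL) {
  z_range <- sort(as.numeric(z_range))
  edges <- seq(z_range[1], z_range[2], length.out = n_zbins + 1)
  centers <- if (is.null(clusters)) matrix(0, 1, 1) else clusters$centers
  structure(list(edges = edges, n_zbins = as.integer(n_zbins),
                 centers = centers, n_clusters = nrow(centers),
                 M = as.integer(n_zbins * nrow(centers))),
            class = "microstate_map")
}

#' @export
print.microstate_map <- function(x, ...) {
  cat("<microstate_map>", x$n_zbins, "z-bins x", x$n_clusters,
      "clusters =", x$M, "microstates\n")
  invisible(x)
}

#' Microstate id arithmetic
#'
#' `microstate_id()` maps 1-based (z_bin, cluster) to the 0-based microstate
#' id; `microstate_zbin()` and `microstate_cluster()` invert it.
#'
#' @param map A `microstate_map`.
#' @param z_bin,cluster 1-based indices.
#' @param id 0-based microstate ids.
#' @export
microstate_id <- function(map, z_bin, cluster = 1) {
  (z_bin - 1L) * map$n_clusters + (cluster - 1L)
}

#' @rdname microstate_id
#' @export
microstate_zbin <- function(map, id) id %/% map$n_clusters + 1L

#' @rdname microstate_id
#' @export
microstate_cluster <- function(map, id) id %% map$n_clusters + 1L

#' Assign frames to microstates
#'
#' Bins each frame's z coordinate (half-open bins, last bin closed) and
#' combines it with the nearest tIC cluster center into a microstate id.
#' Frames outside the binning range are dropped (count reported); segments are
#' re-split at drops so no spurious transition spans a gap.
#'
#' @param trajs A `traj_set` whose frames carry `z` (and `tic_*` columns when
#'   the map has clusters).
#' @param map A `microstate_map`.
#' @return A `dtraj_set`: discrete frames (`traj_id`, `ensemble_id`,
#'   `microstate`), the map, ensemble specs, frame interval, and the number
#'   of dropped frames.
#' @export
assign_microstates <- function(trajs, map) {
  stopifnot(inherits(trajs, "traj_set"), inherits(map, "microstate_map"))
  fr <- trajs$frames
  zb <- findInterval(fr$z, map$edges, rightmost.closed = TRUE)
  ok <- zb >= 1 & zb <= map$n_zbins
  n_dropped <- sum(!ok)
  if (n_dropped > 0) {
    message(n_dropped, " out-of-range frame(s) dropped")
  }
  cl <- if (map$n_clusters > 1) {
    nearest_center(tic_matrix(fr), map$centers)
  } else rep(1L, nrow(fr))
  d <- tibble(traj_id = fr$traj_id, ensemble_id = fr$ensemble_id,
              keep = ok, microstate = microstate_id(map, zb, cl))
  # split segments at dropped frames so no transition spans a gap
  d <- d |>
    group_by(.data$traj_id) |>
    mutate(.gap = cumsum(!.data$keep)) |>
    ungroup() |>
    filter(.data$keep) |>
    mutate(traj_id = paste0(.data$traj_id, ".", .data$.gap)) |>
    select("traj_id", "ensemble_id", "microstate")
  structure(list(frames = d, map = map, specs = trajs$specs, dt = trajs$dt,
                 n_dropped = n_dropped),
            class = "dtraj_set")
}

#' @export
print.dtraj_set <- function(x, ...) {
  cat("<dtraj_set>", nrow(x$frames), "frames,", x$map$M, "microstates,",
      nrow(x$specs), "ensembles,", x$n_dropped, "dropped\n")
  invisible(x)
}

#' Bias energies of every ensemble, in kBT units
#'
#' For an umbrella ensemble the bias of a configuration at `z` is
#' `0.5 * k_bias * (z - z0)^2 / kBT`; unbiased ensembles contribute zero.
#' Given a numeric vector of z values it is evaluated per frame. Given a
#' `microstate_map`, the state-level bias is the Boltzmann average over each
#' z bin, \eqn{b_i = -\ln \langle e^{-b(z)} \rangle_{bin}}, returned as a
#' K x M matrix (the TRAM/WHAM input): with a stiff umbrella the bias varies
#' by several kBT across a bin, so the bin-center value would misweight the
#' window tails badly.
#'
#' @param x A `microstate_map` or numeric z values (angstrom).
#' @param specs Ensemble specification tibble.
#' @param kBT Thermal energy (kcal/mol).
#' @return K x M (or K x length(z)) matrix of bias energies (kBT units),
#'   rows named by ensemble id.
#' @export
compute_bias_energies <- function(x, specs, kBT = KBT_310) {
  if (inherits(x, "microstate_map")) {
    # Boltzmann-averaged bias per z bin on a fine sub-grid, repeated per
    # cluster (microstate id = (zbin-1)*N + (cluster-1))
    m_sub <- 25
    nb <- x$n_zbins
    lo <- x$edges[-length(x$edges)]
    wdt <- diff(x$edges)
    sub <- outer(lo, rep(1, m_sub)) +
      outer(wdt, (seq_len(m_sub) - 0.5) / m_sub)       # nb x m_sub
    B <- matrix(0, nrow(specs), nb * x$n_clusters,
                dimnames = list(specs$ensemble_id, NULL))
    for (k in seq_len(nrow(specs))) {
      if (specs$kind[k] == "umbrella") {
        bs <- 0.5 * specs$k_bias[k] * (sub - specs$z0[k])^2 / kBT
        bmin <- apply(bs, 1, min)
        beff <- bmin - log(rowMeans(exp(-(bs - bmin))))
        B[k, ] <- rep(beff, each = x$n_clusters)
      }
    }
    return(B)
  }
  z <- as.numeric(x)
  B <- matrix(0, nrow(specs), length(z),
              dimnames = list(specs$ensemble_id, NULL))
  for (k in seq_len(nrow(specs))) {
    if (specs$kind[k] == "umbrella") {
      B[k, ] <- 0.5 * specs$k_bias[k] * (z - specs$z0[k])^2 / kBT
    }
  }
  B
}

#' Umbrella-window convergence score
#'
#' Symmetrized Kullback-Leibler divergence between the z histograms of the
#' first and second halves of a window trajectory, with one pseudo-count added
#' per occupied bin. Windows scoring below the threshold (default 0.2) are
#' flagged converged.
#'
#' @param z Numeric z series of one window (or a `traj_set` frames subset).
#' @param n_bins Number of histogram bins over the observed range.
#' @param threshold Acceptance threshold.
#' @return One-row tibble: `score`, `accept`.
#' @export
window_convergence_score <- function(z, n_bins = 30, threshold = 0.2) {
  if (is.data.frame(z)) z <- z$z
  n <- length(z)
  if (n < 4) abort("window too short to score")
  h1 <- z[seq_len(n %/% 2)]
  h2 <- z[(n %/% 2 + 1):n]
  br <- seq(min(z), max(z), length.out = n_bins + 1)
  c1 <- tabulate(findInterval(h1, br, rightmost.closed = TRUE), n_bins)
  c2 <- tabulate(findInterval(h2, br, rightmost.closed = TRUE), n_bins)
  occ <- c1 + c2 > 0
  if (!any(occ)) abort("empty histogram support")
  p <- (c1[occ] + 1) / sum(c1[occ] + 1)
  q <- (c2[occ] + 1) / sum(c2[occ] + 1)
  score <- 0.5 * sum(p * log(p / q)) + 0.5 * sum(q * log(q / p))
  tibble(score = score, accept = score < threshold)
}
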