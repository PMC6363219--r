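#' Build a bulk-normalized density grid
#'
#' Histograms (weighted) sample positions on a regular 1-3 dimensional grid
#' and converts voxel weights to number densities (particles/nm^3). Densities
#' are normalized to the mean density over a designated bulk region; empty
#' voxels are excluded from the bulk average and carry normalized density 0.
#'
#' The grid origin sits at the lower corner; a sample falls in voxel
#' `floor((x - origin)/spacing)` (half-open bins).
#'
#' @param samples Matrix or data frame of positions (angstrom), one column per
#'   axis.
#' @param extent Numeric vector, grid extent per axis (angstrom). `spacing`
#'   must divide each entry.
#' @param spacing Grid spacing (angstrom), scalar or per-axis.
#' @param origin Lower-corner coordinates; default `-extent/2`.
#' @param weights Optional non-negative per-sample weights.
#' @param bulk_region Logical vector/array flagging bulk voxels, or `NULL` for
#'   the default rule: the outermost 10% of the last axis on the upper
#'   (extracellular) side.
#' @return A `density_grid`: origin, spacing, dims, `values`
#'   (particles/nm^3), `bulk` (particles/nm^3) and `normalized`.
#' @export
#' @examples
#' g <- build_density_grid(matrix(runif(300, 0, 10), ncol = 3),
#'                         extent = c(10, 10, 10), spacing = 2.5,
#'                         origin = c(0, 0, 0))
#' prod(g$dims)
build_density_grid <- function(samples, extent, spacing, origin = NULL,
                               weights = NULL, bulk_region = NULL) {
  samples <- as.matrix(samples)
  nd <- ncol(samples)
  extent <- rep_len(as.numeric(extent), nd)
  spacing <- rep_len(as.numeric(spacing), nd)
  dims <- extent / spacing
  if (any(abs(dims - round(dims)) > 1e-8)) {
    abort("spacing must divide extent on every axis")
  }
  dims <- as.integer(round(dims))
  if (is.null(origin)) origin <- -extent / 2
  origin <- rep_len(as.numeric(origin), nd)
  if (is.null(weights)) weights <- rep(1, nrow(samples))
  if (any(weights < 0)) abort("weights must be non-negative")

  idx <- sweep(sweep(samples, 2, origin), 2, spacing, "/")
  idx <- floor(idx)
  keep <- rep(TRUE, nrow(samples))
  for (a in seq_len(nd)) keep <- keep & idx[, a] >= 0 & idx[, a] < dims[a]
  idx <- idx[keep, , drop = FALSE]
  w <- weights[keep]
  lin <- as.integer(idx %*% cumprod(c(1, dims[-nd]))) + 1L
  vox <- rep(0, prod(dims))
  if (length(lin)) {
    tab <- tapply(w, lin, sum)
    vox[as.integer(names(tab))] <- tab
  }
  voxel_nm3 <- prod(spacing) * 1e-3  # A^3 -> nm^3
  values <- array(vox / voxel_nm3, dim = dims)

  if (is.null(bulk_region)) {
    last <- nd
    cut <- dims[last] - max(1L, floor(dims[last] / 10L))
    bulk_region <- array(FALSE, dim = dims)
    ix <- slice.index(bulk_region, last)
    bulk_region[ix > cut] <- TRUE
  }
  bulk_region <- array(as.logical(bulk_region), dim = dims)
  nonempty_bulk <- bulk_region & values > 0
  if (!any(bulk_region)) abort("empty bulk region")
  if (!any(nonempty_bulk)) abort("zero bulk density")
  bulk <- mean(values[nonempty_bulk])
  structure(list(origin = origin, spacing = spacing, dims = dims,
                 values = values, bulk = bulk, normalized = values / bulk,
                 bulk_region = bulk_region),
            class = "density_grid")
}

#' @export
print.density_grid <- function(x, ...) {
  cat("<density_grid> dims", paste(x$dims, collapse = " x "),
      "| spacing", paste(x$spacing, collapse = ", "),
      "A | bulk", signif(x$bulk, 4), "particles/nm^3\n")
  invisible(x)
}

grid_centers <- function(grid) {
  axes <- lapply(seq_along(grid$dims), function(a) {
    grid$origin[a] + (seq_len(grid$dims[a]) - 0.5) * grid$spacing[a]
  })
  as.matrix(do.call(expand.grid, axes))
}

#' Self-consistent WHAM reweighting over binned multi-ensemble data
#'
#' Standard weighted-histogram estimator: given per-ensemble bin histograms
#' and per-(ensemble, bin) bias energies, iterates
#' \deqn{p_i \propto \sum_k h_{ki} \big/ \sum_k N_k e^{f_k - b_{ki}}, \quad
#'       e^{-f_k} = \sum_i p_i e^{-b_{ki}}}
#' until the largest free-energy-shift change falls below `tol`.
#'
#' @param histograms K x M matrix of per-ensemble bin counts (K ensembles).
#' @param bias K x M matrix of bias energies in kBT units.
#' @param tol Convergence tolerance on `max |delta f_k|` (kBT).
#' @param max_iter Iteration cap.
#' @return A `wham_result`: `p` (unbiased probabilities, summing to 1 over
#'   non-empty bins), `f` (per-ensemble shifts, first ensemble anchored at 0),
#'   `loglik` trace, `iterations`, `converged`.
#' @export
wham_weights <- function(histograms, bias, tol = 1e-8, max_iter = 1e5) {
  H <- as.matrix(histograms); B <- as.matrix(bias)
  if (!all(dim(H) == dim(B))) abort("histograms and bias must share dims")
  if (!all(is.finite(B))) abort("bias energies must be finite")
  K <- nrow(H); M <- ncol(H)
  Nk <- rowSums(H)
  Hi <- colSums(H)
  occupied <- Hi > 0

  check_overlap(H)

  # per-ensemble offsets keep exp() in range
  Boff <- B - apply(B, 1, min)
  G <- exp(-Boff)                     # K x M
  p <- ifelse(occupied, Hi / sum(Hi), 0)
  f <- rep(0, K)
  ll_trace <- numeric(0)
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    denom <- colSums(Nk * exp(f) * G)           # M
    p_new <- ifelse(occupied & denom > 0, Hi / denom, 0)
    p_new <- p_new / sum(p_new)
    zk <- as.vector(G %*% p_new)
    f_new <- -log(zk)
    ll_terms <- H * (log(pmax(rep(p_new, each = K), 1e-300)) - Boff +
                       rep(f_new, M))
    ll <- sum(ll_terms[H > 0])
    ll_trace <- c(ll_trace, ll)
    delta <- max(abs((f_new - f_new[1]) - (f - f[1])))
    p <- p_new; f <- f_new
    if (delta < tol) { converged <- TRUE; break }
  }
  if (!converged) warn("WHAM did not converge within max_iter")
  structure(list(p = p, f = f - f[1], loglik = ll_trace,
                 iterations = length(ll_trace), converged = converged),
            class = "wham_result")
}

# histogram-overlap connectivity: bins sampled by a common ensemble are
# linked; all non-empty bins must end up in one component
check_overlap <- function(H) {
  M <- ncol(H)
  parent <- seq_len(M)
  find <- function(i) { while (parent[i] != i) { parent[i] <<- parent[parent[i]]; i <- parent[i] }; i }
  for (k in seq_len(nrow(H))) {
    bins <- which(H[k, ] > 0)
    if (length(bins) > 1) {
      r <- find(bins[1])
      for (b in bins[-1]) parent[find(b)] <- r
    }
  }
  occ <- which(colSums(H) > 0)
  roots <- vapply(occ, find, integer(1))
  if (length(unique(roots)) > 1) {
    bad <- occ[roots != roots[1]]
    abort(paste0("disconnected histogram support: bins {",
                 paste(utils::head(bad, 5), collapse = ", "),
                 "} share no ensemble with the rest"))
  }
  invisible(TRUE)
}

#' Write a 3D density grid as an OpenDX scalar field
#'
#' @param grid A 3D `density_grid`.
#' @param path Output file path.
#' @param normalized Write bulk-normalized values (default) or raw densities.
#' @return `path`, invisibly.
#' @export
write_dx_grid <- function(grid, path, normalized = TRUE) {
  stopifnot(inherits(grid, "density_grid"))
  if (length(grid$dims) != 3) abort("OpenDX export requires a 3D grid")
  vals <- if (normalized) grid$normalized else grid$values
  n <- prod(grid$dims)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    "# OpenDX scalar field written by memmkin",
    sprintf("object 1 class gridpositions counts %d %d %d",
            grid$dims[1], grid$dims[2], grid$dims[3]),
    sprintf("origin %.6g %.6g %.6g",
            grid$origin[1], grid$origin[2], grid$origin[3]),
    sprintf("delta %.6g 0 0", grid$spacing[1]),
    sprintf("delta 0 %.6g 0", grid$spacing[2]),
    sprintf("delta 0 0 %.6g", grid$spacing[3]),
    sprintf("object 2 class gridconnections counts %d %d %d",
            grid$dims[1], grid$dims[2], grid$dims[3]),
    sprintf("object 3 class array type double rank 0 items %d data follows", n)
  ), con)
  # OpenDX order: last index varies fastest
  v <- as.vector(aperm(vals, c(3, 2, 1)))
  lines <- vapply(split(v, ceiling(seq_along(v) / 3)),
                  function(x) paste(sprintf("%.6g", x), collapse = " "),
                  character(1))
  writeLines(lines, con)
  writeLines(c('attribute "dep" string "positions"',
               'object "density" class field',
               'component "positions" value 1',
               'component "connections" value 2',
               'component "data" value 3'), con)
  invisible(path)
}

#' Read an OpenDX scalar field written by [write_dx_grid()]
#'
#' @param path File path.
#' @return A `density_grid` (values = file values; bulk set to 1).
#' @export
read_dx_grid <- function(path) {
  lines <- readLines(path)
  cline <- grep("class gridpositions counts", lines, value = TRUE)[1]
  dims <- as.integer(tail(strsplit(cline, "\\s+")[[1]], 3))
  origin <- as.numeric(tail(strsplit(
    grep("^origin", lines, value = TRUE)[1], "\\s+")[[1]], 3))
  deltas <- vapply(grep("^delta", lines, value = TRUE), function(l) {
    max(abs(as.numeric(tail(strsplit(l, "\\s+")[[1]], 3))))
  }, numeric(1))
  start <- grep("data follows", lines)[1] + 1
  end_markers <- grep("^attribute|^object \"", lines)
  end <- min(end_markers[end_markers >= start]) - 1
  v <- as.numeric(unlist(strsplit(trimws(lines[start:end]), "\\s+")))
  vals <- aperm(array(v, dim = rev(dims)), c(3, 2, 1))
  structure(list(origin = origin, spacing = unname(deltas), dims = dims,
                 values = vals, bulk = 1, normalized = vals,
                 bulk_region = array(FALSE, dims)),
            class = "density_grid")
}

#' One-dimensional density/free-energy profile from a 1D grid
#'
#' @param grid A 1D `density_grid`.
#' @param kBT Thermal energy (kcal/mol).
#' @return Tibble: `z` (bin centers), `density`, `normalized`,
#'   `G = -kBT log(normalized)` (Inf on empty bins).
#' @export
density_profile <- function(grid, kBT = KBT_310) {
  stopifnot(inherits(grid, "density_grid"), length(grid$dims) == 1)
  z <- as.vector(grid_centers(grid))
  nrm <- as.vector(grid$normalized)
  tibble(z = z, density = as.vector(grid$values), normalized = nrm,
         G = ifelse(nrm > 0, -kBT * log(nrm), Inf))
}
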