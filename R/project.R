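#' Forward-project an object into binned mean data
#'
#' Applies the system operator to a voxelized object: for each non-position
#' attribute bin b, the mean data is the depth sum of lateral (circular)
#' convolutions of the object slices with the corresponding PRF slices,
#' weighted by the voxel volume (unit exposure time). The object's lateral
#' voxel size must equal the PRF's lateral bin width (use [regrid_lateral()]
#' first if needed), and the object depth slices must match the PRF depths.
#' Convolutions are periodic on the object's lateral grid; the PRF support
#' must be small compared to the lateral extent for wrap-around to be
#' negligible, which holds for the standard setups.
#'
#' @param object a `voxel_object`.
#' @param prf a `prf_grid`.
#' @return an object of class `cpet_data`: `arrays` is an `nb x n x n` array
#'   of mean counts per attribute bin and lateral data bin, `b_table` the
#'   non-position bin indices for each row.
#' @export
forward_project <- function(object, prf) {
  stopifnot(inherits(object, "voxel_object"), inherits(prf, "prf_grid"))
  pieces <- projection_pieces(object, prf)
  n <- pieces$n
  nb <- nrow(pieces$b_table)
  arrays <- array(0, c(nb, n, n))
  dV <- object$voxel_size^2 * object$dz
  Fh <- lapply(seq_along(object$depths),
               function(iz) stats::fft(object$values[, , iz]))
  for (r in seq_len(nrow(pieces$index))) {
    bi <- pieces$index$b[r]; iz <- pieces$index$iz[r]
    h <- pieces$kernels[[r]]
    u <- Re(stats::fft(Fh[[iz]] * stats::fft(h), inverse = TRUE)) / (n * n)
    arrays[bi, , ] <- arrays[bi, , ] + u * dV[iz]
  }
  structure(list(arrays = arrays, b_table = pieces$b_table,
                 bins = prf$bins, attrs = prf$attrs,
                 lateral_width = object$voxel_size, n = n),
            class = "cpet_data")
}

#' @export
print.cpet_data <- function(x, ...) {
  cat(sprintf(
    "CPET mean data: %d non-position attribute bins x %d x %d lateral bins; total counts %.4g\n",
    dim(x$arrays)[1], x$n, x$n, sum(x$arrays)))
  invisible(x)
}

# L2 norm of binned data under the data-bin measure
data_norm <- function(u) {
  stopifnot(inherits(u, "cpet_data"))
  sqrt(sum(u$arrays^2) * u$lateral_width^2)
}

#' Adjoint (backprojection) operator
#'
#' For binned mean data, returns the object-space function obtained by
#' lateral correlation of the data with the PRF slices at each depth,
#' weighted by the lateral data-bin area, so that
#' `<u, L f>_data = <L^adj u, f>_object` exactly on matching grids. For a
#' [listmode_table()], returns `sum_j prf(A_j | R)` as a function of R: each
#' event contributes the PRF mass profile across depths at its attribute
#' bin (unit exposure time, no measure weighting).
#'
#' @param data a `cpet_data` (from [forward_project()]) or a
#'   [listmode_table()].
#' @param prf a `prf_grid` on the same bins.
#' @param origin lateral source-frame origin for list-mode input.
#' @return a `voxel_object` on the PRF's lateral grid.
#' @export
adjoint_backproject <- function(data, prf, origin = c(0, 0)) {
  stopifnot(inherits(prf, "prf_grid"))
  if (inherits(data, "listmode_table")) {
    counts <- histogram_listmode(data, prf$bins, prf$attrs, n_emitted = 1,
                                 origin = origin)
    # n_emitted = 1 makes masses equal event counts
    data <- counts_to_data(counts, prf)
    measure <- 1
  } else {
    stopifnot(inherits(data, "cpet_data"))
    measure <- data$lateral_width^2
  }
  obj0 <- new_voxel_object(
    array(0, c(data$n, data$n, length(prf$depths))),
    data$lateral_width, depth_grid(prf$depths, max(prf$depths),
                                   dz = rep(1, length(prf$depths))))
  pieces <- projection_pieces(obj0, prf, b_table = data$b_table)
  n <- pieces$n
  g <- array(0, c(n, n, length(prf$depths)))
  Uh <- lapply(seq_len(dim(data$arrays)[1]),
               function(b) stats::fft(data$arrays[b, , ]))
  for (r in seq_len(nrow(pieces$index))) {
    bi <- pieces$index$b[r]; iz <- pieces$index$iz[r]
    h <- pieces$kernels[[r]]
    g[, , iz] <- g[, , iz] +
      Re(stats::fft(Uh[[bi]] * Conj(stats::fft(h)), inverse = TRUE)) / (n * n)
  }
  dz0 <- if (length(prf$depths) > 1) mean(diff(prf$depths)) else 1
  grid <- depth_grid(prf$depths, max(prf$depths),
                     dz = rep(dz0, length(prf$depths)))
  new_voxel_object(g * measure, data$lateral_width, grid)
}

counts_to_data <- function(counts, prf) {
  bcols <- intersect(c("ith", "iph", "iE"), names(counts$cells))
  pieces_b <- unique(counts$cells[bcols])
  n <- counts$bins$n_lateral
  arrays <- array(0, c(max(nrow(pieces_b), 1L), n, n))
  for (b in seq_len(nrow(pieces_b))) {
    sel <- counts$cells
    for (cl in bcols) sel <- sel[sel[[cl]] == pieces_b[b, cl], , drop = FALSE]
    arrays[b, , ][cbind(sel$ix + 1L, sel$iy + 1L)] <- sel$mass
  }
  if (nrow(pieces_b) == 0L) pieces_b <- as.data.frame(matrix(0L, 0, length(bcols)))
  structure(list(arrays = arrays, b_table = pieces_b, bins = counts$bins,
                 attrs = counts$attrs, lateral_width = counts$bins$lateral_width,
                 n = n), class = "cpet_data")
}

# shared plumbing: checks grid compatibility, enumerates non-position bins,
# and materializes each (b, depth) PRF slice as an n x n circulant kernel
# with the zero offset at element [1, 1]
projection_pieces <- function(object, prf, b_table = NULL) {
  if (abs(object$voxel_size - prf$bins$lateral_width) > 1e-9)
    stop_domain("object voxel size must equal the PRF lateral bin width")
  if (length(object$depths) != length(prf$depths) ||
      max(abs(object$depths - prf$depths)) > 1e-9)
    stop_domain("object depth slices do not match the PRF depths")
  n <- dim(object$values)[1]
  cells <- prf$cells
  bcols <- intersect(c("ith", "iph", "iE"), names(cells))
  bkey <- if (length(bcols)) interaction_key(cells[bcols]) else rep("0", nrow(cells))
  if (is.null(b_table)) {
    first <- !duplicated(bkey)
    b_table <- cells[first, bcols, drop = FALSE]
    rownames(b_table) <- NULL
  }
  tkey <- if (length(bcols)) interaction_key(b_table) else "0"
  bi <- match(bkey, tkey)
  known <- !is.na(bi)
  cells <- cells[known, , drop = FALSE]; bi <- bi[known]
  mx <- lateral_centers(prf$bins)[cells$ix + 1L] / prf$bins$lateral_width
  my <- lateral_centers(prf$bins)[cells$iy + 1L] / prf$bins$lateral_width
  px <- (as.integer(round(mx)) %% n) + 1L
  py <- (as.integer(round(my)) %% n) + 1L
  grp <- paste(bi, cells$iz)
  ugrp <- !duplicated(grp)
  index <- data.frame(b = bi[ugrp], iz = cells$iz[ugrp])
  kernels <- vector("list", nrow(index))
  gid <- match(grp, grp[ugrp])
  for (r in seq_len(nrow(index))) {
    sel <- which(gid == r)
    h <- matrix(0, n, n)
    lin <- (py[sel] - 1L) * n + px[sel]
    a <- rowsum(cells$mass[sel], lin)      # duplicates can wrap together
    h[as.integer(rownames(a))] <- a[, 1]
    kernels[[r]] <- h
  }
  list(n = n, b_table = b_table, index = index, kernels = kernels)
}
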