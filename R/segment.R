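#' Global Otsu threshold of a numeric array
#'
#' Maximises between-class variance over a fixed-width histogram of the
#' whole volume (a single global threshold, as appropriate for clean /
#' synthetic scans where bone and background intensities are bimodal).
#'
#' @param x numeric vector or array.
#' @param n_bins number of histogram bins.
#' @return the threshold value (on the intensity scale).
#' @export
otsu_threshold <- function(x, n_bins = 256L) {
  x <- as.vector(x)
  rng <- range(x)
  if (diff(rng) <= 0)
    stop("constant-intensity volume: Otsu threshold undefined")
  edges <- seq(rng[1], rng[2], length.out = n_bins + 1L)
  h <- tabulate(pmin(findInterval(x, edges, rightmost.closed = TRUE), n_bins),
                nbins = n_bins)
  mids <- (edges[-1] + edges[-(n_bins + 1L)]) / 2
  w <- cumsum(h); m <- cumsum(h * mids)
  n <- w[n_bins]; mt <- m[n_bins]
  w0 <- w[-n_bins]; w1 <- n - w0
  valid <- w0 > 0 & w1 > 0
  mu0 <- m[-n_bins] / w0; mu1 <- (mt - m[-n_bins]) / w1
  bc <- w0 * w1 * (mu0 - mu1)^2
  bc[!valid] <- -Inf
  k <- which.max(bc)
  edges[k + 1L]
}

#' Threshold-based bone segmentation
#'
#' Bone = intensity >= threshold, with the threshold either computed by
#' global Otsu or supplied.  Optionally removes 6-connected bone
#' components smaller than `min_component_voxels` (speckle cleanup).
#'
#' @param gray a grayscale `bone_volume`.
#' @param method `"otsu"` or `"fixed"`.
#' @param threshold intensity threshold when `method = "fixed"`.
#' @param min_component_voxels components smaller than this are removed
#'   (0 disables cleanup).
#' @return a binary `bone_volume`; the applied threshold is attached as
#'   attribute `"threshold"`.
#' @export
segment_threshold <- function(gray, method = c("otsu", "fixed"),
                              threshold = NULL, min_component_voxels = 0L) {
  method <- match.arg(method)
  stopifnot(inherits(gray, "bone_volume"))
  t0 <- if (method == "otsu") otsu_threshold(gray$voxels) else {
    if (is.null(threshold)) stop("`threshold` required for method = \"fixed\"")
    threshold
  }
  bone <- array(as.integer(gray$voxels >= t0), dim(gray$voxels))
  if (min_component_voxels > 0L && sum(bone) > 0L) {
    lab <- label_components(bone == 1L)
    small <- which(lab$sizes < min_component_voxels)
    if (length(small)) bone[lab$labels %in% small] <- 0L
  }
  out <- bone_volume(bone, gray$voxel_mm, gray$origin_mm, "binary",
                     gray$axes, gray$outer_mask)
  attr(out, "threshold") <- t0
  out
}

#' 6-connected component labelling of a 3D logical array
#'
#' @param mask logical (or 0/1) 3D array.
#' @return list with `labels` (integer array, 0 = background, components
#'   numbered in decreasing size) and `sizes` (voxel count per label).
#' @export
label_components <- function(mask) {
  mask <- array(as.logical(mask), dim(mask))
  n <- dim(mask)
  idx <- which(mask)
  labels <- array(0L, n)
  if (length(idx) == 0L) return(list(labels = labels, sizes = integer(0)))
  pos <- arrayInd(idx, n)
  key <- array(0L, n); key[idx] <- seq_along(idx)
  edges <- NULL
  for (d in 1:3) {
    ok <- pos[, d] < n[d]
    nb <- pos[ok, , drop = FALSE]; nb[, d] <- nb[, d] + 1L
    nb_key <- key[nb]
    has <- nb_key > 0L
    edges <- rbind(edges, cbind(key[idx][ok][has], nb_key[has]))
  }
  g <- igraph::graph_from_edgelist(
    rbind(edges, cbind(seq_along(idx), seq_along(idx))), directed = FALSE)
  comp <- igraph::components(g)
  ord <- order(comp$csize, decreasing = TRUE)
  relabel <- integer(comp$no); relabel[ord] <- seq_len(comp$no)
  labels[idx] <- relabel[comp$membership]
  list(labels = labels, sizes = as.integer(comp$csize[ord]))
}
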