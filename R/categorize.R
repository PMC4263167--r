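#' Categorization configuration
#'
#' @param downscale_factor integer >= 1; images are reduced by block
#'   averaging before region merging.
#' @param merge_threshold RGB Euclidean distance (0-255 units) under which
#'   adjacent regions are merged; also the distance beyond which a pixel
#'   is flagged unresolved during categorization.
#' @param class_centroids matrix of reference RGB triplets (0-255), one
#'   row per class, first row background.
#' @param min_region_px regions smaller than this are absorbed into the
#'   neighbouring region with the nearest mean colour.
#' @return a `categorization_config` object.
#' @export
categorization_config <- function(downscale_factor = 1, merge_threshold = 60,
                                  class_centroids = cpm_centroids(),
                                  min_region_px = 8) {
  stopifnot(downscale_factor >= 1, merge_threshold >= 0, min_region_px >= 0)
  if (anyDuplicated(class_centroids)) stop("class centroids must be pairwise distinct")
  structure(list(downscale_factor = as.integer(downscale_factor),
                 merge_threshold = merge_threshold,
                 class_centroids = class_centroids,
                 min_region_px = min_region_px),
            class = "categorization_config")
}

#' Extract the wing outline from the background
#'
#' Thresholds the RGB distance to the (reserved or estimated) background
#' colour, then keeps the largest connected foreground component, so
#' off-wing dust and specks are dropped.
#'
#' @param image RGB array in \[0, 1\].
#' @param bg_colour background RGB triplet (0-255); default the reserved
#'   background colour.
#' @param bg_threshold RGB distance above which a pixel counts as wing.
#' @return logical wing mask.
#' @export
extract_outline <- function(image, bg_colour = cpm_centroids()["background", ],
                            bg_threshold = 80) {
  d2 <- (image[, , 1] - bg_colour[1] / 255)^2 +
        (image[, , 2] - bg_colour[2] / 255)^2 +
        (image[, , 3] - bg_colour[3] / 255)^2
  fg <- sqrt(d2) > bg_threshold / 255
  if (!any(fg)) stop("no wing detected (empty foreground)")
  lab <- cpm_label(fg)
  counts <- tabulate(lab[lab > 0])
  lab == which.max(counts)
}

#' Simplify an image by size reduction and region merging
#'
#' Downscales by block averaging, merges adjacent pixels whose RGB
#' distance is below the threshold into regions (single linkage), sets
#' each region to its area-weighted mean colour, and absorbs regions
#' smaller than `min_region_px` into the adjacent region with the nearest
#' mean colour.  With `downscale_factor = 1` and `merge_threshold = 0`
#' this is the identity.
#'
#' @param image RGB array in \[0, 1\].
#' @param config a [categorization_config].
#' @return simplified RGB array (possibly smaller).
#' @export
simplify <- function(image, config = categorization_config()) {
  f <- config$downscale_factor
  if (f > 1) {
    nr <- floor(dim(image)[1] / f); nc <- floor(dim(image)[2] / f)
    out <- array(0, c(nr, nc, 3))
    for (ch in 1:3) {
      m <- image[seq_len(nr * f), seq_len(nc * f), ch]
      # block mean via two rowsum passes
      m <- rowsum(m, rep(seq_len(nr), each = f)) / f
      m <- t(rowsum(t(m), rep(seq_len(nc), each = f)) / f)
      out[, , ch] <- m
    }
    image <- out
  }
  if (config$merge_threshold <= 0) return(image)
  lab <- cpm_merge_labels(image, config$merge_threshold / 255)
  image <- flatten_regions(image, lab, config$min_region_px)
  image
}

# set each region to its mean colour; absorb small regions into the
# adjacent region with nearest mean colour
flatten_regions <- function(image, lab, min_region_px) {
  repeat {
    nreg <- max(lab)
    size <- tabulate(lab, nreg)
    means <- vapply(1:3, function(ch) {
      as.vector(rowsum(as.vector(image[, , ch]), as.vector(lab))) / size
    }, numeric(nreg))
    small <- which(size > 0 & size < min_region_px)
    if (!length(small)) {
      for (ch in 1:3) image[, , ch] <- means[lab, ch]
      return(image)
    }
    # region adjacency from neighbouring label pairs
    nr <- nrow(lab); nc <- ncol(lab)
    pairs <- rbind(cbind(as.vector(lab[-nr, ]), as.vector(lab[-1, ])),
                   cbind(as.vector(lab[, -nc]), as.vector(lab[, -1])))
    pairs <- pairs[pairs[, 1] != pairs[, 2], , drop = FALSE]
    pairs <- unique(rbind(pairs, pairs[, 2:1]))
    remap <- seq_len(nreg)
    for (r in small) {
      nb <- pairs[pairs[, 1] == r, 2]
      nb <- setdiff(nb, small)   # prefer absorbing into a large region
      if (!length(nb)) nb <- setdiff(pairs[pairs[, 1] == r, 2], r)
      if (!length(nb)) next
      d <- colSums((t(means[nb, , drop = FALSE]) - means[r, ])^2)
      remap[r] <- nb[which.min(d)]
    }
    if (all(remap == seq_len(nreg))) {
      for (ch in 1:3) image[, , ch] <- means[lab, ch]
      return(image)
    }
    lab2 <- matrix(remap[lab], nr, nc)
    # renumber contiguously
    keep <- sort(unique(as.vector(lab2)))
    lab <- matrix(match(lab2, keep), nr, nc)
  }
}

#' Categorize a wing image into colour classes
#'
#' Assigns every masked pixel to the nearest class centroid in RGB
#' distance (background excluded from the candidates).  Pixels farther
#' than `merge_threshold` from every colour centroid, or exactly tied
#' between two centroids, are flagged unresolved and deterministically
#' assigned (ties break to the class declared earlier); their count goes
#' to the QC attribute in place of manual checking.
#'
#' @param image RGB array in \[0, 1\].
#' @param mask logical wing mask (e.g. from [extract_outline()]).
#' @param config a [categorization_config].
#' @return a [colour_pattern] in native space with attribute `"qc"`
#'   (list: `n_unresolved`, `unresolved_fraction`).
#' @export
categorize <- function(image, mask, config = categorization_config()) {
  if (!any(mask)) stop("empty wing mask")
  cen <- config$class_centroids[-1, , drop = FALSE] / 255  # colour classes only
  idx <- which(mask)
  npx <- prod(dim(mask))
  px <- cbind(image[idx], image[idx + npx], image[idx + 2 * npx])
  d2 <- vapply(seq_len(nrow(cen)),
               function(k) (px[, 1] - cen[k, 1])^2 + (px[, 2] - cen[k, 2])^2 +
                           (px[, 3] - cen[k, 3])^2,
               numeric(length(idx)))
  d2 <- matrix(d2, ncol = nrow(cen))
  assign <- max.col(-d2, ties.method = "first")
  dmin2 <- d2[cbind(seq_along(idx), assign)]
  tie <- rowSums(d2 <= dmin2 + 1e-12) > 1
  unresolved <- sqrt(dmin2) > config$merge_threshold / 255 | tie
  g <- matrix(0L, nrow(mask), ncol(mask))
  g[idx] <- assign  # codes 1..K (background = 0)
  out <- colour_pattern(g, rownames(config$class_centroids), "native")
  attr(out, "qc") <- list(n_unresolved = sum(unresolved),
                          unresolved_fraction = mean(unresolved))
  out
}

#' Unsupervised colour categorization (k-means)
#'
#' Optional mode that does not constrain the number of colours: k-means
#' over masked pixel RGB values for k in `k_range`, choosing k by average
#' silhouette width, then mapping each cluster to the nearest declared
#' class centroid.
#'
#' @inheritParams categorize
#' @param k_range candidate cluster counts.
#' @param seed RNG seed for k-means starts.
#' @return as [categorize()]; attribute `"k"` holds the chosen k.
#' @export
categorize_unsupervised <- function(image, mask, config = categorization_config(),
                                    k_range = 2:5, seed = 1) {
  if (!any(mask)) stop("empty wing mask")
  idx <- which(mask)
  npx <- prod(dim(mask))
  px <- cbind(image[idx], image[idx + npx], image[idx + 2 * npx])
  # subsample for silhouette cost
  with_seed(seed, {
    sub <- if (nrow(px) > 2000) sample.int(nrow(px), 2000) else seq_len(nrow(px))
    best <- NULL; best_sil <- -Inf; best_k <- NA
    for (k in k_range) {
      if (k > nrow(unique(px))) next
      km <- stats::kmeans(px, centers = k, nstart = 5, iter.max = 50)
      sil <- silhouette_width(px[sub, , drop = FALSE], km$cluster[sub])
      if (is.finite(sil) && sil > best_sil) { best <- km; best_sil <- sil; best_k <- k }
    }
  })
  if (is.null(best)) stop("k-means failed for all candidate k")
  cen <- config$class_centroids[-1, , drop = FALSE] / 255
  map <- apply(best$centers, 1, function(c0)
    which.min(colSums((t(cen) - c0)^2)))
  g <- matrix(0L, nrow(mask), ncol(mask))
  g[idx] <- as.integer(map[best$cluster])
  out <- colour_pattern(g, rownames(config$class_centroids), "native")
  attr(out, "k") <- best_k
  out
}

# mean silhouette width for small samples (plain Euclidean)
silhouette_width <- function(x, cl) {
  if (length(unique(cl)) < 2) return(-Inf)
  d <- as.matrix(stats::dist(x))
  n <- nrow(x)
  s <- vapply(seq_len(n), function(i) {
    own <- cl == cl[i]; own[i] <- FALSE
    a <- if (any(own)) mean(d[i, own]) else 0
    b <- min(vapply(setdiff(unique(cl), cl[i]),
                    function(k) mean(d[i, cl == k]), 0))
    if (max(a, b) == 0) 0 else (b - a) / max(a, b)
  }, 0)
  mean(s)
}
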