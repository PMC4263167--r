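#' Mask moments: centroid, area, principal-axis angle
#'
#' @param mask logical matrix.
#' @return list with `cx`, `cy` (centroid relative to the image centre,
#'   pixels), `area` and `angle` (degrees, representative nearest 0).
#' @keywords internal
mask_moments <- function(mask) {
  idx <- which(mask)
  if (!length(idx)) stop("empty mask")
  nr <- nrow(mask)
  i <- (idx - 1) %% nr; j <- (idx - 1) %/% nr
  cy0 <- (nr - 1) / 2; cx0 <- (ncol(mask) - 1) / 2
  x <- j - cx0; y <- i - cy0
  cx <- mean(x); cy <- mean(y)
  mu20 <- mean((x - cx)^2); mu02 <- mean((y - cy)^2)
  mu11 <- mean((x - cx) * (y - cy))
  ang <- 0.5 * atan2(2 * mu11, mu20 - mu02) * 180 / pi
  # principal axis is defined mod 180; take the representative nearest 0
  if (ang > 90) ang <- ang - 180
  if (ang < -90) ang <- ang + 180
  if (ang > 45) ang <- ang - 90 * 0   # keep within (-90, 90]
  list(cx = cx, cy = cy, area = length(idx), angle = ang)
}

#' Initial alignment from wing outlines
#'
#' Centres every wing mask on its centroid, scales it to the common
#' (geometric mean) mask area, and rotates its principal axis to the
#' common (mean) orientation.  This is the coarse alignment from which
#' the first wing model is built.
#'
#' @param patterns list of [colour_pattern]s of one wing type.
#' @param min_area masks smaller than this are excluded (degenerate).
#' @param frame_scale ratio of model-frame to native resolution; the
#'   common target area is scaled by `frame_scale^2` so wings land in the
#'   model frame at the right size.
#' @return list of [similarity_transform]s (native -> model), one per
#'   pattern; excluded specimens carry `NULL` and are listed in attribute
#'   `"excluded"`.
#' @export
initial_outline_alignment <- function(patterns, min_area = 50,
                                      frame_scale = 1) {
  if (length(patterns) < 2) stop("need >= 2 patterns")
  mom <- vector("list", length(patterns))
  excluded <- integer()
  for (k in seq_along(patterns)) {
    m <- wing_mask(patterns[[k]])
    if (sum(m) < min_area) { excluded <- c(excluded, k); next }
    mom[[k]] <- mask_moments(m)
  }
  keep <- setdiff(seq_along(patterns), excluded)
  if (length(keep) < 2) stop("fewer than 2 usable masks after exclusion")
  target_area <- exp(mean(log(vapply(mom[keep], `[[`, 0, "area")))) *
    frame_scale^2
  target_angle <- mean(vapply(mom[keep], `[[`, 0, "angle"))
  tfs <- vector("list", length(patterns))
  for (k in keep) {
    m <- mom[[k]]
    s <- sqrt(target_area / m$area)
    theta <- target_angle - m$angle
    # native -> model: rotate/scale about centre, then translate the
    # (transformed) centroid to the frame centre
    th <- theta * pi / 180
    R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2)
    t2 <- -s * (R %*% c(m$cx, m$cy))
    tfs[[k]] <- similarity_transform(t2[1], t2[2], theta, s)
  }
  attr(tfs, "excluded") <- excluded
  tfs
}

#' Build a wing model from transformed patterns
#'
#' The wing model is the per-pixel colour-class frequency raster over all
#' contributing wings (background included as a class).  A wing
#' contributes to a model pixel whenever that pixel maps inside the
#' wing's source raster.
#'
#' @param patterns list of [colour_pattern]s (native space).
#' @param transforms list of [similarity_transform]s (native -> model),
#'   `NULL` entries skipped.
#' @param dim_model model frame dimensions; default the first pattern's.
#' @param iteration iteration index stored on the model.
#' @return a `wing_model`: list with `freq` (rows x cols x n_classes
#'   array), `support` (integer matrix), `classes`, `iteration`.
#' @export
build_wing_model <- function(patterns, transforms,
                             dim_model = dim(patterns[[1]]$grid),
                             iteration = 0L) {
  K <- length(patterns[[1]]$classes)
  counts <- array(0, c(dim_model[1], dim_model[2], K))
  support <- matrix(0L, dim_model[1], dim_model[2])
  for (k in seq_along(patterns)) {
    tf <- transforms[[k]]
    if (is.null(tf)) next
    p <- tf_apply(patterns[[k]], tf, dim_model, vote = 5)
    inb <- attr(p, "in_bounds")
    support <- support + inb
    for (cl in seq_len(K) - 1L)
      counts[, , cl + 1L] <- counts[, , cl + 1L] + (p$grid == cl & inb)
  }
  freq <- counts
  pos <- support > 0L
  for (cl in seq_len(K)) {
    f <- counts[, , cl]
    f[pos] <- f[pos] / support[pos]
    freq[, , cl] <- f
  }
  structure(list(freq = freq, support = support,
                 classes = patterns[[1]]$classes, iteration = iteration),
            class = "wing_model")
}

#' @export
print.wing_model <- function(x, ...) {
  cat(sprintf("<wing_model> %dx%d, %d classes, iteration %d, %d supported px\n",
              dim(x$support)[1], dim(x$support)[2], length(x$classes),
              x$iteration, sum(x$support > 0)))
  invisible(x)
}

# mask of the model's consensus wing (background not the majority class)
model_wing_mask <- function(model) {
  model$support > 0 & model$freq[, , 1] < 0.5
}

#' Categorical similarity between a pattern and a wing model
#'
#' The score is the mean, over model pixels with support > 0, of the
#' model frequency of the class observed in the transformed pattern at
#' that pixel (nearest-neighbour lookup; out-of-frame sources count as
#' background).  It is 1 when the pattern reproduces a deterministic
#' model exactly and tends to the class mixing rate otherwise.
#'
#' @param pattern a [colour_pattern] (native space).
#' @param model a `wing_model`.
#' @param transform [similarity_transform] (native -> model).
#' @return score in \[0, 1\].
#' @export
similarity_score <- function(pattern, model, transform = similarity_transform()) {
  cand <- matrix(c(transform$tx, transform$ty, transform$theta * pi / 180,
                   transform$s), 1)
  cpm_score_batch(pattern$grid, model$freq, model$support, cand)[1]
}

#' Registration search specification
#'
#' @param grid_tx,grid_ty,grid_theta,grid_s coarse grid offsets applied
#'   around the moment-based initialization (pixels, pixels, degrees,
#'   multiplicative scale).
#' @param step_px,step_deg,step_scale initial local-refinement steps.
#' @param shrink step shrink factor per refinement round.
#' @param min_step_px,min_step_deg,min_step_scale stopping resolution.
#' @return a `search_spec` list.
#' @export
search_spec <- function(grid_tx = seq(-6, 6, by = 2),
                        grid_ty = seq(-6, 6, by = 2),
                        grid_theta = seq(-6, 6, by = 2),
                        grid_s = c(0.94, 1, 1.06),
                        step_px = 1, step_deg = 1, step_scale = 0.02,
                        shrink = 0.5,
                        min_step_px = 0.04, min_step_deg = 0.04,
                        min_step_scale = 0.001) {
  if (!length(grid_tx) || !length(grid_ty) || !length(grid_theta) || !length(grid_s))
    stop("empty search grid")
  structure(list(grid_tx = grid_tx, grid_ty = grid_ty,
                 grid_theta = grid_theta, grid_s = grid_s,
                 step_px = step_px, step_deg = step_deg,
                 step_scale = step_scale, shrink = shrink,
                 min_step_px = min_step_px, min_step_deg = min_step_deg,
                 min_step_scale = min_step_scale),
            class = "search_spec")
}

#' Register a pattern to a wing model
#'
#' Maximizes [similarity_score()] over similarity transforms: the search
#' is initialized from mask moments (pattern vs model consensus mask),
#' refined over a coarse grid and then by deterministic pattern search
#' with shrinking steps.  Ties are broken toward the candidate evaluated
#' first, with candidates ordered by increasing parameter magnitude, so a
#' pattern identical to the model consensus keeps the identity transform.
#'
#' @param pattern a [colour_pattern] (native space).
#' @param model a `wing_model` with non-empty support.
#' @param search a [search_spec].
#' @param init optional [similarity_transform] overriding the moment
#'   initialization.
#' @return the best [similarity_transform] (native -> model), with the
#'   achieved score in attribute `"score"`.
#' @export
register_to_model <- function(pattern, model, search = search_spec(),
                              init = NULL) {
  if (!any(model$support > 0)) stop("model support is empty")
  if (is.null(init)) {
    mm <- tryCatch(mask_moments(model_wing_mask(model)), error = function(e) NULL)
    pm <- tryCatch(mask_moments(wing_mask(pattern)), error = function(e) NULL)
    init <- if (is.null(mm) || is.null(pm)) similarity_transform() else {
      s <- sqrt(mm$area / pm$area)
      theta <- mm$angle - pm$angle
      th <- theta * pi / 180
      R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2)
      t2 <- c(mm$cx, mm$cy) - s * (R %*% c(pm$cx, pm$cy))
      similarity_transform(t2[1], t2[2], theta, s)
    }
  }
  # coarse grid around init, ordered by offset magnitude (tie-break rule)
  g <- expand.grid(dtx = search$grid_tx, dty = search$grid_ty,
                   dth = search$grid_theta, ds = search$grid_s)
  ord <- order(g$dtx^2 + g$dty^2 + g$dth^2 + (100 * log(g$ds))^2)
  g <- g[ord, , drop = FALSE]
  cand <- cbind(init$tx + g$dtx, init$ty + g$dty,
                (init$theta + g$dth) * pi / 180, init$s * g$ds)
  sc <- cpm_score_batch(pattern$grid, model$freq, model$support, cand)
  best_i <- which.max(sc)   # first max wins -> smallest offset among ties
  best <- cand[best_i, ]
  best_score <- sc[best_i]
  # deterministic pattern search with shrinking steps
  step <- c(search$step_px, search$step_px, search$step_deg * pi / 180,
            search$step_scale)
  min_step <- c(search$min_step_px, search$min_step_px,
                search$min_step_deg * pi / 180, search$min_step_scale)
  repeat {
    moved <- FALSE
    for (d in 1:4) {
      for (sgn in c(-1, 1)) {
        trial <- best
        if (d == 4) trial[4] <- best[4] * (1 + sgn * step[4])
        else trial[d] <- best[d] + sgn * step[d]
        s2 <- cpm_score_batch(pattern$grid, model$freq, model$support,
                              matrix(trial, 1))[1]
        if (s2 > best_score + 1e-12) {
          best <- trial; best_score <- s2; moved <- TRUE
        }
      }
    }
    if (!moved) {
      step <- step * search$shrink
      if (all(step < min_step)) break
    }
  }
  out <- similarity_transform(best[1], best[2], best[3] * 180 / pi, best[4])
  attr(out, "score") <- best_score
  out
}

#' Recursive alignment to an iteratively refined wing model
#'
#' Starting from the outline-based initial alignment, repeatedly (1)
#' builds the wing model from the current transforms and (2) re-registers
#' every wing to it, until the mean per-pixel absolute change in model
#' frequencies falls below `tol` or `n_iter` is reached.  The mean
#' similarity score is enforced non-decreasing: if an iteration lowers
#' it, the previous transforms are kept and iteration stops.
#'
#' @param patterns list of [colour_pattern]s (native space) of one wing
#'   type.
#' @param n_iter maximum number of model refinement iterations (>= 1).
#' @param tol convergence threshold on the mean absolute model-frequency
#'   change.
#' @param search a [search_spec].
#' @param model_factor ratio of model-frame to native resolution (default
#'   1/2).  Categorization runs at full native resolution while homology
#'   and all downstream statistics live in the coarser model frame, so
#'   that area-majority resampling sees several native pixels per model
#'   pixel and patch boundaries are recovered at sub-model-pixel
#'   precision instead of being re-quantized per specimen.
#' @param dim_model model frame dimensions; default the first pattern's
#'   scaled by `model_factor`.
#' @return list with `aligned` (patterns resampled into model space),
#'   `transforms`, `model` (final `wing_model`), and `trace` (data.frame:
#'   iteration, mean_score, model_change).
#' @export
align_recursive <- function(patterns, n_iter = 10, tol = 1e-3,
                            search = search_spec(), model_factor = 0.5,
                            dim_model = round(dim(patterns[[1]]$grid) *
                                              model_factor)) {
  if (n_iter < 1) stop("n_iter must be >= 1")
  if (length(patterns) < 2) stop("need >= 2 patterns")
  frame_scale <- sqrt(prod(dim_model) / prod(dim(patterns[[1]]$grid)))
  transforms <- initial_outline_alignment(patterns,
                                          frame_scale = frame_scale)
  excluded <- attr(transforms, "excluded")
  model <- build_wing_model(patterns, transforms, dim_model, iteration = 0L)
  mean_score <- function(tfs) {
    sc <- vapply(seq_along(patterns), function(k) {
      if (is.null(tfs[[k]])) return(NA_real_)
      similarity_score(patterns[[k]], model, tfs[[k]])
    }, 0)
    mean(sc, na.rm = TRUE)
  }
  prev_score <- mean_score(transforms)
  trace <- data.frame(iteration = 0L, mean_score = prev_score,
                      model_change = NA_real_)
  for (it in seq_len(n_iter)) {
    new_tfs <- transforms
    for (k in seq_along(patterns)) {
      if (k %in% excluded) next
      new_tfs[[k]] <- register_to_model(patterns[[k]], model, search,
                                        init = transforms[[k]])
    }
    new_model <- build_wing_model(patterns, new_tfs, dim_model, iteration = it)
    new_score <- {
      sc <- vapply(seq_along(patterns), function(k) {
        if (is.null(new_tfs[[k]])) return(NA_real_)
        attr(new_tfs[[k]], "score") %||% similarity_score(patterns[[k]], model, new_tfs[[k]])
      }, 0)
      mean(sc, na.rm = TRUE)
    }
    if (new_score < prev_score - 1e-9) break  # keep previous transforms
    change <- mean(abs(new_model$freq - model$freq))
    transforms <- new_tfs
    model <- new_model
    trace <- rbind(trace, data.frame(iteration = it, mean_score = new_score,
                                     model_change = change))
    prev_score <- new_score
    if (change < tol) break
  }
  aligned <- lapply(seq_along(patterns), function(k) {
    if (is.null(transforms[[k]])) return(NULL)
    tf_apply(patterns[[k]], transforms[[k]], dim_model, vote = 5)
  })
  names(aligned) <- names(patterns)
  names(transforms) <- names(patterns)
  list(aligned = aligned, transforms = transforms, model = model,
       trace = trace)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
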