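#' Canonical wing outline
#'
#' Rasterizes the fixed parametric forewing silhouette used as the
#' canonical frame for synthetic wings: a superellipse elongated along x,
#' with a rounder base (left) than apex (right) and a slanted costal cut,
#' so that centroid, scale and principal axis are all well defined.
#'
#' @param resolution side length in pixels of the square canonical frame.
#' @return logical matrix (`TRUE` inside the wing).
#' @export
wing_outline <- function(resolution = 256) {
  stopifnot(resolution >= 16)
  c0 <- (resolution - 1) / 2
  u <- outer(rep(1, resolution), ((seq_len(resolution) - 1) - c0) / c0)
  v <- outer(((seq_len(resolution) - 1) - c0) / c0, rep(1, resolution))
  p <- ifelse(u < 0, 2.8, 1.8)
  inside <- (abs(u) / 0.90)^p + (abs(v) / 0.62)^p <= 1
  inside & (v <= 0.62 - 0.22 * (u + 0.9))
}

# normalized wing coordinates (u = x, v = y in [-1, 1]) for every pixel
wing_coords <- function(resolution) {
  c0 <- (resolution - 1) / 2
  list(u = outer(rep(1, resolution), ((seq_len(resolution) - 1) - c0) / c0),
       v = outer(((seq_len(resolution) - 1) - c0) / c0, rep(1, resolution)))
}

#' Allele colour-pattern definition
#'
#' Describes the wing pattern controlled by one supergene allele: a base
#' colour filling the wing outline and an ordered list of patches painted
#' over it (later patches overwrite earlier ones).  Patch shapes live in
#' normalized wing coordinates (u right, v down, both in \[-1, 1\]).
#'
#' @param allele_id short label (e.g. `"tar"`).
#' @param class `"ancestral"` or `"derived"` (inversion status).
#' @param base_colour colour class filling the outline.
#' @param patches list of patches from [patch_ellipse()] / [patch_polygon()].
#' @return an `allele_pattern` object.
#' @export
allele_pattern <- function(allele_id, class = c("derived", "ancestral"),
                           base_colour = "yellow", patches = list()) {
  class <- match.arg(class)
  if (!base_colour %in% CPM_CLASSES[-1]) stop("unknown base colour: ", base_colour)
  for (p in patches)
    if (!inherits(p, "cpm_patch")) stop("patches must be cpm_patch objects")
  structure(list(allele_id = allele_id, class = class,
                 base_colour = base_colour, patches = patches),
            class = "allele_pattern")
}

#' Patch shapes for allele patterns
#'
#' @param centre,radii ellipse centre and semi-axes in wing coordinates.
#' @param angle ellipse rotation, degrees.
#' @param vertices two-column matrix of polygon vertices (u, v).
#' @param colour colour class of the patch.
#' @return a `cpm_patch` object.
#' @export
patch_ellipse <- function(centre, radii, colour, angle = 0) {
  structure(list(shape = "ellipse", centre = centre, radii = radii,
                 angle = angle, colour = colour), class = "cpm_patch")
}

#' @rdname patch_ellipse
#' @export
patch_polygon <- function(vertices, colour) {
  vertices <- as.matrix(vertices)
  stopifnot(ncol(vertices) == 2, nrow(vertices) >= 3)
  structure(list(shape = "polygon", vertices = vertices, colour = colour),
            class = "cpm_patch")
}

# point-in-patch test, vectorized over normalized coordinates
patch_inside <- function(patch, u, v) {
  if (patch$shape == "ellipse") {
    th <- patch$angle * pi / 180
    du <- u - patch$centre[1]; dv <- v - patch$centre[2]
    ru <- cos(th) * du + sin(th) * dv
    rv <- -sin(th) * du + cos(th) * dv
    (ru / patch$radii[1])^2 + (rv / patch$radii[2])^2 <= 1
  } else {
    cpm_in_polygon(u, v, patch$vertices[, 1], patch$vertices[, 2])
  }
}

# point-in-outline test (same geometry as wing_outline), vectorized
outline_inside <- function(u, v) {
  p <- ifelse(u < 0, 2.8, 1.8)
  (abs(u) / 0.90)^p + (abs(v) / 0.62)^p <= 1 & (v <= 0.62 - 0.22 * (u + 0.9))
}

# evaluate one allele pattern at arbitrary normalized coordinates:
# class code and topmost covering patch index (0 = base) per point
allele_eval <- function(allele, u, v) {
  inside <- outline_inside(u, v)
  code <- ifelse(inside, class_code(CPM_CLASSES, allele$base_colour), 0L)
  owner <- integer(length(u))
  for (i in seq_along(allele$patches)) {
    p <- allele$patches[[i]]
    hit <- patch_inside(p, u, v) & inside
    code[hit] <- class_code(CPM_CLASSES, p$colour)
    owner[hit] <- i
  }
  list(code = as.integer(code), owner = owner)
}

# evaluate the resolved genotype phenotype at arbitrary normalized
# coordinates; the continuous-geometry core shared by the canonical truth
# raster and the native renderer
genotype_eval <- function(allele_a, allele_b, mechanism, u, v) {
  ea <- allele_eval(allele_a, u, v)
  if (identical(allele_a$allele_id, allele_b$allele_id))
    return(list(code = ea$code, disagree = logical(length(u)),
                code_a = ea$code))
  eb <- allele_eval(allele_b, u, v)
  dis <- ea$code != eb$code
  code <- ea$code
  idx <- which(dis)
  if (length(idx)) {
    if (is.null(mechanism)) stop("heterozygote requires a dominance mechanism")
    ka <- ea$code[idx]; kb <- eb$code[idx]
    win <- switch(mechanism$kind,
      colour_hierarchy = {
        rank <- match(CPM_CLASSES, c("background", mechanism$hierarchy))
        if (anyNA(rank[unique(c(ka, kb)) + 1L]))
          stop("hierarchy does not order all colours present")
        ifelse(rank[ka + 1L] <= rank[kb + 1L], ka, kb)
      },
      full_dominance = {
        dom <- mechanism$dominant_allele
        if (!dom %in% c(allele_a$allele_id, allele_b$allele_id))
          stop("unknown dominant allele id: ", dom)
        if (dom == allele_a$allele_id) ka else kb
      },
      mosaic = {
        own <- pmax(ea$owner[idx], eb$owner[idx])
        map <- mechanism$patch_dominance_map
        key <- as.character(own)
        miss <- setdiff(unique(key), names(map))
        if (length(miss))
          stop("mosaic patch_dominance_map missing patch index: ",
               paste(miss, collapse = ", "))
        winner <- unlist(map)[key]
        bad <- !winner %in% c(allele_a$allele_id, allele_b$allele_id)
        if (any(bad)) stop("mosaic map names unknown allele id")
        ifelse(winner == allele_a$allele_id, ka, kb)
      })
    code[idx] <- win
  }
  list(code = as.integer(code), disagree = dis, code_a = ea$code)
}

#' Rasterize an allele pattern in the canonical frame
#'
#' @param allele an [allele_pattern].
#' @param resolution canonical frame size in pixels.
#' @return a [colour_pattern] in model space.  Attribute `"owner"` is an
#'   integer matrix giving, per pixel, the index of the topmost patch
#'   covering it (0 = base colour), used by the mosaic mechanism.
#' @export
render_allele <- function(allele, resolution = 256) {
  coords <- wing_coords(resolution)
  ev <- allele_eval(allele, as.vector(coords$u), as.vector(coords$v))
  out <- colour_pattern(matrix(ev$code, resolution, resolution),
                        space = "model")
  attr(out, "owner") <- matrix(ev$owner, resolution, resolution)
  out
}

#' Dominance mechanism for heterozygote resolution
#'
#' Defines how a heterozygote's phenotype is produced at pixels where the
#' two allele patterns disagree: `colour_hierarchy` expresses the colour
#' highest in a strict hierarchy (default black > orange > yellow);
#' `full_dominance` expresses one allele's whole pattern regardless of
#' colour; `mosaic` resolves each patch independently via a map from patch
#' index to the winning allele.
#'
#' @param kind mechanism kind.
#' @param hierarchy ordered colour vector, most dominant first
#'   (`colour_hierarchy` only).
#' @param dominant_allele winning allele id (`full_dominance` only).
#' @param patch_dominance_map named list/vector: patch index (as character,
#'   `"0"` for the base colour region) to winning allele id (`mosaic` only).
#' @return a `dominance_mechanism` object.
#' @export
dominance_mechanism <- function(kind = c("colour_hierarchy", "full_dominance", "mosaic"),
                                hierarchy = CPM_HIERARCHY,
                                dominant_allele = NULL,
                                patch_dominance_map = NULL) {
  kind <- match.arg(kind)
  if (kind == "colour_hierarchy") {
    if (anyDuplicated(hierarchy) || !all(hierarchy %in% CPM_CLASSES[-1]))
      stop("hierarchy must be a strict order over declared colour classes")
  }
  if (kind == "full_dominance" && is.null(dominant_allele))
    stop("full_dominance requires dominant_allele")
  if (kind == "mosaic" && is.null(patch_dominance_map))
    stop("mosaic requires patch_dominance_map")
  structure(list(kind = kind, hierarchy = hierarchy,
                 dominant_allele = dominant_allele,
                 patch_dominance_map = patch_dominance_map),
            class = "dominance_mechanism")
}

#' Nuisance noise model for synthetic specimens
#'
#' @param boundary_jitter_sd standard deviation (pixels) of the smooth
#'   random displacement field applied to patch boundaries.
#' @param colour_sd per-channel Gaussian RGB noise, 0-255 units.
#' @param transform_ranges list with `translation` (max |t| in px),
#'   `rotation` (max |angle| in degrees) and `scale` (interval containing 1).
#' @param pixel_noise_rate fraction of pixels replaced by uniform RGB noise.
#' @return a `noise_model` object.
#' @export
noise_model <- function(boundary_jitter_sd = 1.5, colour_sd = 8,
                        transform_ranges = list(translation = 10, rotation = 8,
                                                scale = c(0.95, 1.05)),
                        pixel_noise_rate = 0.002) {
  stopifnot(boundary_jitter_sd >= 0, colour_sd >= 0, pixel_noise_rate >= 0,
            transform_ranges$translation >= 0, transform_ranges$rotation >= 0)
  sc <- transform_ranges$scale
  if (length(sc) != 2 || sc[1] > 1 || sc[2] < 1)
    stop("scale interval must contain 1")
  structure(list(boundary_jitter_sd = boundary_jitter_sd, colour_sd = colour_sd,
                 transform_ranges = transform_ranges,
                 pixel_noise_rate = pixel_noise_rate),
            class = "noise_model")
}

#' @rdname noise_model
#' @export
noise_model_zero <- function() {
  noise_model(0, 0, list(translation = 0, rotation = 0, scale = c(1, 1)), 0)
}

# evaluate expr with a temporary RNG seed, restoring the caller's stream
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit(if (is.null(old)) rm(".Random.seed", envir = globalenv())
          else assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  expr
}

# deterministic per-specimen seed from (master seed, specimen id)
specimen_seed <- function(master_seed, specimen_id) {
  h <- as.double(master_seed %% 2147480009)
  for (code in utf8ToInt(specimen_id)) h <- (h * 31 + code) %% 2147480009
  as.integer(h)
}

#' Resolve a genotype to its noise-free canonical pattern
#'
#' Renders both allele patterns and resolves every disagreeing pixel via
#' the dominance mechanism.  For homozygotes the mechanism is irrelevant.
#'
#' @param allele_a,allele_b [allele_pattern] objects (order as given).
#' @param mechanism a [dominance_mechanism]; may be `NULL` for homozygotes.
#' @param resolution canonical frame size.
#' @return a [colour_pattern] in model space.  Attributes: `"disagree"`
#'   (logical matrix of pixels where the two allele rasters disagree) and
#'   `"frac_first"` (fraction of disagreement pixels expressing
#'   `allele_a`'s colour — the programmed dominance of `allele_a`).
#' @export
resolve_genotype <- function(allele_a, allele_b, mechanism = NULL,
                             resolution = 256) {
  coords <- wing_coords(resolution)
  ev <- genotype_eval(allele_a, allele_b, mechanism,
                      as.vector(coords$u), as.vector(coords$v))
  out <- colour_pattern(matrix(ev$code, resolution, resolution),
                        space = "model")
  dis <- matrix(ev$disagree, resolution, resolution)
  attr(out, "disagree") <- dis
  attr(out, "frac_first") <- if (any(dis))
    mean(ev$code[ev$disagree] == ev$code_a[ev$disagree]) else NA_real_
  out
}

# smooth random displacement field (boundary jitter): returns a function
# evaluating the displacement (in canonical pixels) at arbitrary pixel
# coordinates, by bilinear interpolation of a coarse Gaussian knot grid
jitter_field <- function(n, sd_px, knots = 8) {
  kx <- matrix(rnorm(knots^2, 0, sd_px), knots)
  ky <- matrix(rnorm(knots^2, 0, sd_px), knots)
  interp <- function(m, x, y) {
    # x, y in pixel units 1..n mapped onto the knot lattice
    gx <- 1 + (x - 1) * (knots - 1) / (n - 1)
    gy <- 1 + (y - 1) * (knots - 1) / (n - 1)
    gx <- pmin(pmax(gx, 1), knots); gy <- pmin(pmax(gy, 1), knots)
    x0 <- pmin(floor(gx), knots - 1); y0 <- pmin(floor(gy), knots - 1)
    fx <- gx - x0; fy <- gy - y0
    m[cbind(y0, x0)] * (1 - fx) * (1 - fy) +
      m[cbind(y0, x0 + 1)] * fx * (1 - fy) +
      m[cbind(y0 + 1, x0)] * (1 - fx) * fy +
      m[cbind(y0 + 1, x0 + 1)] * fx * fy
  }
  function(x, y) list(dx = interp(kx, x, y), dy = interp(ky, x, y))
}

#' Render one synthetic specimen
#'
#' Produces an RGB photograph-like image of the deformed, noised wing,
#' together with the noise-free categorized truth in model space and the
#' similarity transform mapping the specimen back into model space.
#' Deterministic given `seed`.
#'
#' @param genotype character vector of two allele ids.
#' @param alleles named list of [allele_pattern] objects.
#' @param mechanism a [dominance_mechanism].
#' @param noise a [noise_model].
#' @param seed integer RNG seed for this specimen.
#' @param resolution canonical frame size.
#' @return list with `rgb` (array rows x cols x 3 in \[0, 1\]), `mask`
#'   (native-space wing mask), `truth` (noise-free [colour_pattern] in
#'   model space), `to_model` (the [similarity_transform] specimen ->
#'   model) and `frac_first` (programmed dominance, heterozygotes only).
#' @export
render_individual <- function(genotype, alleles, mechanism = NULL,
                              noise = noise_model(), seed = 1,
                              resolution = 256) {
  miss <- setdiff(genotype, names(alleles))
  if (length(miss)) stop("unknown allele id: ", paste(miss, collapse = ", "))
  aA <- alleles[[genotype[1]]]; aB <- alleles[[genotype[2]]]
  truth <- resolve_genotype(aA, aB, mechanism, resolution)
  with_seed(seed, {
    tr <- noise$transform_ranges
    fwd <- similarity_transform(
      tx = runif(1, -tr$translation, tr$translation),
      ty = runif(1, -tr$translation, tr$translation),
      theta = runif(1, -tr$rotation, tr$rotation),
      s = runif(1, tr$scale[1], tr$scale[2]))
    # native pixel centres mapped back into the canonical frame, jittered,
    # then evaluated against the continuous wing geometry (no intermediate
    # rasterization)
    c0 <- (resolution - 1) / 2
    inv <- tf_invert(fwd)
    xs <- as.vector(outer(rep(1, resolution), seq_len(resolution) - 1)) - c0
    ys <- as.vector(outer(seq_len(resolution) - 1, rep(1, resolution))) - c0
    th <- inv$theta * pi / 180
    qx <- inv$s * (cos(th) * xs - sin(th) * ys) + inv$tx + c0 + 1
    qy <- inv$s * (sin(th) * xs + cos(th) * ys) + inv$ty + c0 + 1
    if (noise$boundary_jitter_sd > 0) {
      jf <- jitter_field(resolution, noise$boundary_jitter_sd)
      d <- jf(qx, qy)
      qx <- qx + d$dx; qy <- qy + d$dy
    }
    u <- (qx - 1 - c0) / c0; v <- (qy - 1 - c0) / c0
    ev <- genotype_eval(aA, aB, mechanism, u, v)
    native <- colour_pattern(matrix(ev$code, resolution, resolution),
                             space = "native")
    rgb <- pattern_to_rgb(native)
    if (noise$colour_sd > 0) {
      rgb <- rgb + array(rnorm(length(rgb), 0, noise$colour_sd / 255), dim(rgb))
    }
    if (noise$pixel_noise_rate > 0) {
      npx <- resolution^2
      hit <- which(runif(npx) < noise$pixel_noise_rate)
      for (ch in 1:3) rgb[hit + (ch - 1) * npx] <- runif(length(hit))
    }
    rgb[rgb < 0] <- 0; rgb[rgb > 1] <- 1
    list(rgb = rgb, mask = wing_mask(native), truth = truth,
         to_model = tf_invert(fwd), frac_first = attr(truth, "frac_first"))
  })
}

#' Map a categorized pattern to reference RGB colours
#' @param pattern a [colour_pattern].
#' @return numeric array rows x cols x 3 in \[0, 1\].
#' @export
pattern_to_rgb <- function(pattern) {
  pal <- CPM_CENTROIDS[pattern$classes, , drop = FALSE] / 255
  n <- nrow(pattern$grid); m <- ncol(pattern$grid)
  array(pal[pattern$grid + 1L, ], c(n, m, 3))
}

#' Simulate a full crossing dataset with ground truth
#'
#' Writes one wing image (plus background mask) per specimen, a specimen
#' metadata table, and a truth bundle holding the applied transforms and
#' the programmed dominance of every heterozygous pair.  Re-running with
#' the same master seed reproduces all files bit-exactly; each specimen
#' draws from its own RNG stream derived from (master seed, specimen id).
#'
#' @param out_dir output directory (created).
#' @param alleles named list of [allele_pattern] objects.
#' @param n_per_genotype specimens per genotype (scalar or named by
#'   genotype label `"a/b"`).
#' @param mechanism a [dominance_mechanism].
#' @param noise a [noise_model].
#' @param seed master seed.
#' @param pair_class named character vector mapping pair labels `"a/b"`
#'   (alphabetical) to `"sympatric"`/`"parapatric"`; unnamed pairs get `NA`.
#' @param genotypes optional list of two-element allele-id vectors; default
#'   all unordered pairs including homozygotes.
#' @param resolution canonical frame size.
#' @param wing,side labels written to the specimen table.
#' @return invisibly, a list with `table` (data.frame of specimen records)
#'   and `truth` (the truth bundle, also written as JSON).
#' @export
simulate_cross_dataset <- function(out_dir, alleles, n_per_genotype = 10,
                                   mechanism = dominance_mechanism(),
                                   noise = noise_model(), seed = 1,
                                   pair_class = character(),
                                   genotypes = NULL, resolution = 256,
                                   wing = "forewing", side = "dorsal") {
  ids <- names(alleles)
  if (is.null(genotypes)) {
    genotypes <- list()
    for (i in seq_along(ids)) for (j in i:length(ids))
      genotypes[[length(genotypes) + 1L]] <- c(ids[[i]], ids[[j]])
  }
  glab <- vapply(genotypes, function(g) paste(sort(g), collapse = "/"), "")
  counts <- if (length(n_per_genotype) == 1) setNames(rep(n_per_genotype, length(glab)), glab)
            else n_per_genotype[glab]
  if (any(is.na(counts))) stop("n_per_genotype missing a genotype")
  if (any(counts < 2)) stop("need >= 2 individuals per requested genotype")
  dir.create(file.path(out_dir, "images"), recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(out_dir, "masks"), showWarnings = FALSE)
  qc_log <- character()
  zero <- glab[counts == 0]
  if (length(zero)) qc_log <- c(qc_log, paste("zero-count genotype:", zero))

  rows <- list(); transforms <- list(); prog <- list()
  for (gi in seq_along(genotypes)) {
    g <- sort(genotypes[[gi]])
    for (k in seq_len(counts[[glab[gi]]])) {
      sid <- sprintf("%s_%s_%02d", g[1], g[2], k)
      rec <- render_individual(g, alleles, mechanism, noise,
                               seed = specimen_seed(seed, sid),
                               resolution = resolution)
      img_path <- file.path("images", paste0(sid, ".png"))
      png::writePNG(rec$rgb, file.path(out_dir, img_path))
      png::writePNG(rec$mask * 1, file.path(out_dir, "masks", paste0(sid, ".png")))
      transforms[[sid]] <- rec$to_model[c("tx", "ty", "theta", "s")]
      rows[[sid]] <- data.frame(
        specimen_id = sid, wing = wing, side = side,
        allele_1 = g[1], allele_2 = g[2],
        pair_class = if (g[1] == g[2]) NA_character_
                     else if (glab[gi] %in% names(pair_class)) unname(pair_class[glab[gi]])
                     else NA_character_,
        image_path = img_path, stringsAsFactors = FALSE)
      if (g[1] != g[2] && is.null(prog[[glab[gi]]])) {
        f <- rec$frac_first
        prog[[glab[gi]]] <- list(
          first_allele = g[1], frac_first = f,
          dominant = if (f >= 0.5) g[1] else g[2],
          programmed_h = max(f, 1 - f))
      }
    }
  }
  tab <- do.call(rbind, rows[order(names(rows))])
  rownames(tab) <- NULL
  write.table(tab, file.path(out_dir, "specimens.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  truth <- list(mechanism = mechanism$kind, seed = seed, resolution = resolution,
                transforms = transforms, programmed_dominance = prog)
  jsonlite::write_json(truth, file.path(out_dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  if (length(qc_log))
    writeLines(qc_log, file.path(out_dir, "qc_log.txt"))
  invisible(list(table = tab, truth = truth))
}

#' Demonstration allele set
#'
#' Three derived-class alleles with distinct patch layouts over the three
#' wing colours, plus (optionally) one ancestral allele with a mostly
#' melanic pattern.  Used throughout examples and tests as a stand-in for
#' field-collected mimicry alleles.
#'
#' @param ancestral also include the ancestral allele `"sil"`.
#' @return named list of [allele_pattern] objects.
#' @export
demo_alleles <- function(ancestral = FALSE) {
  out <- list(
    arc = allele_pattern("arc", "derived", base_colour = "orange", patches = list(
      patch_ellipse(c(-0.35, -0.15), c(0.28, 0.22), "black"),
      patch_ellipse(c(0.45, 0.05), c(0.25, 0.18), "yellow", angle = -20),
      patch_polygon(rbind(c(-0.75, 0.1), c(-0.2, 0.28), c(-0.25, 0.45),
                          c(-0.78, 0.3)), "yellow"))),
    bic = allele_pattern("bic", "derived", base_colour = "yellow", patches = list(
      patch_ellipse(c(-0.3, 0.1), c(0.35, 0.3), "black", angle = 15),
      patch_ellipse(c(0.5, -0.1), c(0.3, 0.2), "black", angle = -15),
      patch_ellipse(c(0.1, -0.25), c(0.25, 0.15), "orange"))),
    tar = allele_pattern("tar", "derived", base_colour = "orange", patches = list(
      patch_polygon(rbind(c(-0.85, -0.3), c(0.1, -0.45), c(0.15, -0.05),
                          c(-0.8, 0.1)), "black"),
      patch_ellipse(c(0.45, 0.12), c(0.3, 0.22), "yellow", angle = 10))))
  if (ancestral)
    out$sil <- allele_pattern("sil", "ancestral", base_colour = "black",
      patches = list(patch_ellipse(c(0.2, 0), c(0.35, 0.3), "yellow")))
  out
}

#' Striped allele pair for programmed mosaic dominance
#'
#' Builds two alleles that agree everywhere except on `n_stripes`
#' equal-width vertical stripes (allele `a` paints them black, allele `b`
#' orange, on a shared yellow base).  Because each stripe is its own patch,
#' a mosaic [dominance_mechanism] can dial the area fraction of
#' disagreement pixels won by `a` to (approximately) any target.
#'
#' @param n_stripes number of stripe patches.
#' @return named list of the two [allele_pattern] objects `a` and `b`.
#' @export
make_mosaic_pair <- function(n_stripes = 20) {
  edges <- seq(-0.7, 0.7, length.out = n_stripes + 1)
  stripe <- function(i, colour) {
    patch_polygon(rbind(c(edges[i], -0.25), c(edges[i + 1], -0.25),
                        c(edges[i + 1], 0.2), c(edges[i], 0.2)), colour)
  }
  list(
    a = allele_pattern("a", "derived", base_colour = "yellow",
                       patches = lapply(seq_len(n_stripes), stripe, colour = "black")),
    b = allele_pattern("b", "derived", base_colour = "yellow",
                       patches = lapply(seq_len(n_stripes), stripe, colour = "orange")))
}

#' Mosaic map targeting a programmed dominance fraction
#'
#' Chooses per-patch winners so that the area-weighted fraction of
#' disagreement pixels assigned to `allele_a` is as close as possible to
#' `target`, by greedy accumulation over patches in index order.
#'
#' @param allele_a,allele_b the two [allele_pattern]s (parallel patch lists).
#' @param target desired fraction in \[0, 1\] won by `allele_a`.
#' @param resolution canonical frame size used for area measurement.
#' @return named list mapping patch index to winning allele id, with the
#'   realized fraction in attribute `"realized"`.
#' @export
mosaic_map_for_target <- function(allele_a, allele_b, target, resolution = 256) {
  ra <- render_allele(allele_a, resolution)
  rb <- render_allele(allele_b, resolution)
  dis <- ra$grid != rb$grid
  own <- pmax(attr(ra, "owner"), attr(rb, "owner"))
  idx <- sort(unique(own[dis]))
  area <- vapply(idx, function(i) sum(dis & own == i), 0)
  total <- sum(area)
  win <- rep(allele_b$allele_id, length(idx))
  acc <- 0
  for (k in seq_along(idx)) {
    if (abs((acc + area[k]) / total - target) <= abs(acc / total - target)) {
      win[k] <- allele_a$allele_id
      acc <- acc + area[k]
    }
  }
  map <- as.list(setNames(win, as.character(idx)))
  attr(map, "realized") <- acc / total
  map
}
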