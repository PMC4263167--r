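#' Surface-based heterozygote trait T
#'
#' T is the number of pixels in an individual that are similar to one
#' homozygote modal pattern and different from the other, normalized by
#' the wing surface in pixels.  The surface is the set of pixels where
#' the individual and both modal patterns are all non-background; pixels
#' where the two modals agree cannot contribute to T.
#'
#' @param individual a [colour_pattern] in model space.
#' @param modal_a,modal_b modal patterns of the two homozygotes.
#' @return list with `T_a` (trait toward `modal_a`), `T_b` (toward
#'   `modal_b`), `neither` (fraction of surface matching neither modal),
#'   `informative_fraction` (fraction of surface where the modals
#'   differ) and `surface` (pixel count).
#' @export
trait_T <- function(individual, modal_a, modal_b) {
  gi <- individual$grid; ga <- modal_a$grid; gb <- modal_b$grid
  stopifnot(identical(dim(gi), dim(ga)), identical(dim(gi), dim(gb)))
  surf <- gi > 0L & ga > 0L & gb > 0L
  n <- sum(surf)
  if (n == 0) stop("empty wing surface")
  gi <- gi[surf]; ga <- ga[surf]; gb <- gb[surf]
  differ <- ga != gb
  list(T_a = sum(gi == ga & differ) / n,
       T_b = sum(gi == gb & differ) / n,
       neither = sum(gi != ga & gi != gb) / n,
       informative_fraction = mean(differ),
       surface = n)
}

#' Dominance coefficient of an allele pair
#'
#' The dominance of allele `a` relative to allele `b` is the linear
#' interpolation position of the heterozygote mean trait between the two
#' homozygote means, `h_raw = (T_ab - T_bb) / (T_aa - T_bb)`; strict
#' dominance of `a` gives `h = 1`, co-dominance `h ~ 0.5`.  `h` is
#' normalized so the more dominant allele is reported, constraining it to
#' \[0.5, 1\]: `h = max(h_raw, 1 - h_raw)`.
#'
#' @param T_aa,T_ab,T_bb numeric vectors of per-individual trait values
#'   (trait measured toward allele `a`) for the three genotype groups.
#' @param pair character vector of the two allele ids `c(a, b)`.
#' @return a `dominance_result`: list with `pair`, `T_means`, `h_raw`
#'   (clipped to \[0, 1\]; clipping flagged), `h`, `dominant_allele`,
#'   per-group `n`, and the per-individual heterozygote values.
#' @export
dominance_coefficient <- function(T_aa, T_ab, T_bb, pair = c("a", "b")) {
  if (!length(T_aa) || !length(T_ab) || !length(T_bb))
    stop("all three genotype groups must be non-empty")
  m <- c(aa = mean(T_aa), ab = mean(T_ab), bb = mean(T_bb))
  if (m["aa"] == m["bb"])
    stop("uninformative pair: homozygote trait means are equal")
  h_raw <- unname((m["ab"] - m["bb"]) / (m["aa"] - m["bb"]))
  clipped <- h_raw < 0 || h_raw > 1
  h_raw_clipped <- min(max(h_raw, 0), 1)
  h <- max(h_raw_clipped, 1 - h_raw_clipped)
  structure(list(pair = pair, T_means = m,
                 h_raw = h_raw_clipped, h_raw_unclipped = h_raw,
                 clipped = clipped, h = h,
                 dominant_allele = if (h_raw_clipped >= 0.5) pair[1] else pair[2],
                 n = c(aa = length(T_aa), ab = length(T_ab), bb = length(T_bb)),
                 T_het = T_ab),
            class = "dominance_result")
}

#' @export
print.dominance_result <- function(x, ...) {
  cat(sprintf("<dominance_result> %s/%s: h = %.3f (raw %.3f), dominant = %s\n",
              x$pair[1], x$pair[2], x$h, x$h_raw, x$dominant_allele))
  invisible(x)
}

#' Dominance heat map for one allele pair
#'
#' For every model-space pixel, the proportions over heterozygous
#' individuals of matching the dominant modal only, the recessive modal
#' only, both (where the modals agree), or neither.  The four proportions
#' sum to 1 at every pixel.
#'
#' @param hets list of heterozygote [colour_pattern]s in model space.
#' @param modal_dom,modal_rec modal patterns of the dominant and
#'   recessive homozygotes.
#' @return a `dominance_heatmap`: list with `prop` (rows x cols x 4 array,
#'   categories dominant/recessive/both/neither), `mask` (pixels where
#'   both modals are wing surface) and `n_het`.
#' @export
dominance_heatmap <- function(hets, modal_dom, modal_rec) {
  if (!length(hets)) stop("need >= 1 heterozygote")
  gd <- modal_dom$grid; gr <- modal_rec$grid
  dims <- dim(gd)
  acc <- array(0, c(dims[1], dims[2], 4))
  for (p in hets) {
    g <- p$grid
    match_d <- g == gd & gd > 0L
    match_r <- g == gr & gr > 0L
    both <- match_d & match_r          # modals agree there
    acc[, , 1] <- acc[, , 1] + (match_d & !both)
    acc[, , 2] <- acc[, , 2] + (match_r & !both)
    acc[, , 3] <- acc[, , 3] + both
    acc[, , 4] <- acc[, , 4] + (!match_d & !match_r)
  }
  structure(list(prop = acc / length(hets), mask = gd > 0L & gr > 0L,
                 n_het = length(hets)),
            class = "dominance_heatmap")
}

#' Render a dominance heat map to RGB
#'
#' Matching the dominant modal maps to red, the recessive to blue,
#' agreement with both to grey and neither to white; pixels outside the
#' shared wing surface are black.
#'
#' @param hm a `dominance_heatmap`.
#' @return RGB array in \[0, 1\].
#' @export
heatmap_to_rgb <- function(hm) {
  pal <- rbind(dominant = c(0.85, 0.1, 0.1), recessive = c(0.1, 0.2, 0.85),
               both = c(0.55, 0.55, 0.55), neither = c(1, 1, 1))
  dims <- dim(hm$prop)
  out <- array(0, c(dims[1], dims[2], 3))
  for (k in 1:4) for (ch in 1:3)
    out[, , ch] <- out[, , ch] + hm$prop[, , k] * pal[k, ch]
  for (ch in 1:3) out[, , ch] <- out[, , ch] * hm$mask
  out
}

# --- pooled pixel-observation statistics over allele pairs ---------------
#
# Several statistics pool "pixel-observations": one observation is (one
# heterozygous individual, one informative pixel), pooled with equal
# weight across allele pairs.  A pair group is
#   list(hets = <list of patterns>, modal_a = , modal_b = )
# and most functions below accept one group or a list of groups.

as_pair_groups <- function(groups) {
  if (!is.null(groups$hets)) list(groups) else groups
}

# iterate pixel-observations: returns data.frame-ish list of vectors
# (observed class, modal class a, modal class b) over informative pixels
pool_observations <- function(groups, restrict = NULL) {
  obs <- list(o = integer(), a = integer(), b = integer())
  for (g in as_pair_groups(groups)) {
    ga <- g$modal_a$grid; gb <- g$modal_b$grid
    inf <- ga > 0L & gb > 0L & ga != gb
    if (!is.null(restrict)) inf <- inf & restrict(ga, gb)
    idx <- which(inf)
    if (!length(idx)) next
    for (h in g$hets) {
      obs$o <- c(obs$o, h$grid[idx])
      obs$a <- c(obs$a, ga[idx])
      obs$b <- c(obs$b, gb[idx])
    }
  }
  obs
}

#' Conformity of heterozygotes to the colour hierarchy
#'
#' Over all pixels where the two homozygote modal patterns show distinct
#' colours, the fraction of heterozygote pixel-observations expressing
#' the hierarchy-dominant of the two colours.
#'
#' @param groups one pair group or a list of groups (see Details in
#'   [colour_expression_probability()]): each group has `hets`,
#'   `modal_a`, `modal_b`.
#' @param hierarchy ordered colour vector, most dominant first.
#' @param classes class table (defaults to the package classes).
#' @return fraction in \[0, 1\] with attribute `"n"` (number of
#'   pixel-observations).
#' @export
hierarchy_conformity <- function(groups, hierarchy = CPM_HIERARCHY,
                                 classes = cpm_classes()) {
  obs <- pool_observations(groups)
  if (!length(obs$o)) stop("no informative pixels")
  rank <- match(classes, c("background", hierarchy))
  pred <- ifelse(rank[obs$a + 1L] <= rank[obs$b + 1L], obs$a, obs$b)
  structure(mean(obs$o == pred), n = length(obs$o))
}

#' Conformity to complete dominance of one allele
#'
#' The fraction of informative heterozygote pixel-observations equal to
#' one homozygote modal's colour, computed in both directions; the larger
#' is returned with its direction.
#'
#' @inheritParams hierarchy_conformity
#' @param allele_a,allele_b labels for the two directions (used in the
#'   report); defaults `"a"`, `"b"`.
#' @return fraction in \[0, 1\]; attributes `"direction"` (which modal's
#'   allele predicts best), `"toward_a"`, `"toward_b"`, `"n"`.
#' @export
full_dominance_conformity <- function(groups, allele_a = "a", allele_b = "b") {
  obs <- pool_observations(groups)
  if (!length(obs$o)) stop("no informative pixels")
  fa <- mean(obs$o == obs$a)
  fb <- mean(obs$o == obs$b)
  structure(max(fa, fb),
            direction = if (fa >= fb) allele_a else allele_b,
            toward_a = fa, toward_b = fb, n = length(obs$o))
}

#' Colour expression probabilities for a colour pair
#'
#' Over all pixel-observations where the two homozygote modals show the
#' two given colours (in either orientation), the probabilities that the
#' heterozygote expresses the first colour, the second, the third wing
#' colour, or none of the three.
#'
#' @inheritParams hierarchy_conformity
#' @param colour_pair character vector of two colour class names.
#' @return named probability vector `c(<c1>, <c2>, other, neither)` with
#'   attribute `"n"`; all zero (with a warning) when no pixel-observation
#'   matches.
#' @export
colour_expression_probability <- function(groups, colour_pair,
                                          classes = cpm_classes()) {
  k1 <- class_code(classes, colour_pair[1])
  k2 <- class_code(classes, colour_pair[2])
  obs <- pool_observations(groups, restrict = function(ga, gb)
    (ga == k1 & gb == k2) | (ga == k2 & gb == k1))
  out <- setNames(numeric(4), c(colour_pair, "other", "neither"))
  if (!length(obs$o)) {
    warning("no pixel-observations for colour pair ",
            paste(colour_pair, collapse = "/"))
    attr(out, "n") <- 0L
    return(out)
  }
  third <- setdiff(seq_along(classes) - 1L, c(0L, k1, k2))
  out[1] <- mean(obs$o == k1)
  out[2] <- mean(obs$o == k2)
  out[3] <- mean(obs$o %in% third)
  out[4] <- 1 - out[1] - out[2] - out[3]
  attr(out, "n") <- length(obs$o)
  out
}

#' Colour hierarchy map for a colour pair
#'
#' Per-pixel version of [colour_expression_probability()]: at each model
#' pixel, over all allele pairs whose homozygote modals show the two
#' colours there, the proportions of heterozygous individuals expressing
#' each of the three wing colours (pooled with equal weight per
#' heterozygote individual).
#'
#' @inheritParams colour_expression_probability
#' @return a `colour_hierarchy_map`: list with `prop` (rows x cols x 4
#'   array: c1, c2, other, neither), `included` (pixels where at least
#'   one pair contributes; elsewhere no variation was observed) and
#'   `summary` (the pooled probabilities).  Empty map (all excluded) with
#'   a warning when no pixel contributes.
#' @export
colour_hierarchy_map <- function(groups, colour_pair, classes = cpm_classes()) {
  groups <- as_pair_groups(groups)
  k1 <- class_code(classes, colour_pair[1])
  k2 <- class_code(classes, colour_pair[2])
  third <- setdiff(seq_along(classes) - 1L, c(0L, k1, k2))
  dims <- dim(groups[[1]]$modal_a$grid)
  cnt <- array(0, c(dims[1], dims[2], 4))
  denom <- matrix(0, dims[1], dims[2])
  for (g in groups) {
    ga <- g$modal_a$grid; gb <- g$modal_b$grid
    sel <- (ga == k1 & gb == k2) | (ga == k2 & gb == k1)
    if (!any(sel)) next
    for (h in g$hets) {
      o <- h$grid
      cnt[, , 1] <- cnt[, , 1] + (sel & o == k1)
      cnt[, , 2] <- cnt[, , 2] + (sel & o == k2)
      cnt[, , 3] <- cnt[, , 3] + (sel & matrix(o %in% third, dims[1], dims[2]))
      cnt[, , 4] <- cnt[, , 4] + (sel & o != k1 & o != k2 &
                                  !matrix(o %in% third, dims[1], dims[2]))
      denom <- denom + sel
    }
  }
  included <- denom > 0
  if (!any(included))
    warning("no contributing pixels for colour pair ",
            paste(colour_pair, collapse = "/"))
  prop <- cnt
  for (k in 1:4) {
    f <- cnt[, , k]
    f[included] <- f[included] / denom[included]
    prop[, , k] <- f
  }
  summary <- suppressWarnings(
    colour_expression_probability(groups, colour_pair, classes))
  structure(list(prop = prop, included = included, colour_pair = colour_pair,
                 summary = summary),
            class = "colour_hierarchy_map")
}

#' Render a colour hierarchy map to RGB
#'
#' Expressed-colour proportions are translated into gradients of the
#' actual wing colours; pixels where no variation was observed are grey.
#'
#' @param chm a `colour_hierarchy_map`.
#' @param classes class table used to resolve colours.
#' @return RGB array in \[0, 1\].
#' @export
hierarchy_map_to_rgb <- function(chm, classes = cpm_classes()) {
  dims <- dim(chm$prop)
  cols <- rbind(CPM_CENTROIDS[chm$colour_pair[1], ] / 255,
                CPM_CENTROIDS[chm$colour_pair[2], ] / 255,
                c(0.3, 0.8, 0.3),    # third colour rendered as green accent
                c(1, 1, 1))
  third <- setdiff(classes[-1], chm$colour_pair)
  if (length(third) == 1) cols[3, ] <- CPM_CENTROIDS[third, ] / 255
  out <- array(0, c(dims[1], dims[2], 3))
  for (k in 1:4) for (ch in 1:3)
    out[, , ch] <- out[, , ch] + chm$prop[, , k] * cols[k, ch]
  for (ch in 1:3) {
    f <- out[, , ch]
    f[!chm$included] <- 0.5
    out[, , ch] <- f
  }
  out
}
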