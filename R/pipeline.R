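#' Per-pair dominance analysis over an aligned dataset
#'
#' For every unordered allele pair with both homozygotes and the
#' heterozygote present, builds the homozygote modal patterns, computes
#' the per-individual trait values for all three genotype groups, the
#' dominance coefficient, and the dominance heat map inputs.
#'
#' @param aligned named list of model-space [colour_pattern]s (names =
#'   specimen ids).
#' @param meta data.frame with columns `specimen_id`, `allele_1`,
#'   `allele_2`, `genotype` (`"a/b"`), and optionally `pair_class`.
#' @return list with `table` (one row per analysed pair: n's, trait
#'   means, `h_raw`, `h`, `dominant_allele`, `pair_class`, mean
#'   neither-modal fraction) and `groups` (per pair: `hets`, `modal_a`,
#'   `modal_b`, `modal_dom`, `modal_rec`, `result`).  Pairs whose
#'   homozygote modals nowhere differ are skipped with a warning.
#' @export
dominance_table <- function(aligned, meta) {
  stopifnot(all(meta$specimen_id %in% names(aligned)))
  homo <- meta$allele_1 == meta$allele_2
  alleles <- sort(unique(c(meta$allele_1, meta$allele_2)))
  modal_cache <- list()
  modal_of <- function(allele) {
    if (!is.null(modal_cache[[allele]])) return(modal_cache[[allele]])
    ids <- meta$specimen_id[homo & meta$allele_1 == allele]
    if (length(ids) < 2) return(NULL)
    m <- modal_pattern(aligned[ids], paste(allele, allele, sep = "/"))
    modal_cache[[allele]] <<- m
    m
  }
  rows <- list(); groups <- list()
  for (i in seq_along(alleles)) for (j in seq_along(alleles)) {
    if (j <= i) next
    a <- alleles[i]; b <- alleles[j]
    pair_lab <- paste(a, b, sep = "/")
    het_ids <- meta$specimen_id[meta$genotype == pair_lab]
    ma <- modal_of(a); mb <- modal_of(b)
    if (is.null(ma) || is.null(mb) || !length(het_ids)) next
    if (!any(ma$grid != mb$grid & ma$grid > 0L & mb$grid > 0L)) {
      warning("pair ", pair_lab, " skipped: homozygote modals nowhere differ")
      next
    }
    aa_ids <- meta$specimen_id[homo & meta$allele_1 == a]
    bb_ids <- meta$specimen_id[homo & meta$allele_1 == b]
    Tv <- function(ids) vapply(ids, function(id)
      trait_T(aligned[[id]], ma, mb)$T_a, 0)
    neither <- vapply(het_ids, function(id)
      trait_T(aligned[[id]], ma, mb)$neither, 0)
    res <- dominance_coefficient(Tv(aa_ids), Tv(het_ids), Tv(bb_ids),
                                 pair = c(a, b))
    dom_first <- res$dominant_allele == a
    groups[[pair_lab]] <- list(
      hets = aligned[het_ids], modal_a = ma, modal_b = mb,
      modal_dom = if (dom_first) ma else mb,
      modal_rec = if (dom_first) mb else ma,
      result = res)
    pc <- if ("pair_class" %in% names(meta))
      unique(stats::na.omit(meta$pair_class[meta$genotype == pair_lab]))
    else character()
    rows[[pair_lab]] <- data.frame(
      pair = pair_lab, allele_a = a, allele_b = b,
      n_aa = length(aa_ids), n_ab = length(het_ids), n_bb = length(bb_ids),
      T_aa = res$T_means["aa"], T_ab = res$T_means["ab"],
      T_bb = res$T_means["bb"], h_raw = res$h_raw, h = res$h,
      dominant_allele = res$dominant_allele,
      pair_class = if (length(pc) == 1) pc else NA_character_,
      neither_fraction = mean(neither),
      stringsAsFactors = FALSE)
  }
  tab <- if (length(rows)) do.call(rbind, rows) else
    data.frame(pair = character())
  rownames(tab) <- NULL
  list(table = tab, groups = groups)
}

# ---- pipeline configuration --------------------------------------------

pipeline_schema <- list(
  out_dir = TRUE, seed = TRUE,
  simulate = list(preset = FALSE, n_per_genotype = FALSE, mechanism = FALSE,
                  dominant_allele = FALSE, target_dominance = FALSE,
                  resolution = FALSE, pair_class = FALSE,
                  hierarchy = FALSE, ancestral = FALSE,
                  noise = list(boundary_jitter_sd = FALSE, colour_sd = FALSE,
                               translation = FALSE, rotation = FALSE,
                               scale = FALSE, pixel_noise_rate = FALSE)),
  input = list(dir = TRUE),
  categorization = list(downscale_factor = FALSE, merge_threshold = FALSE,
                        min_region_px = FALSE),
  alignment = list(n_iter = FALSE, tol = FALSE),
  analysis = list(min_var_fraction = FALSE, n_perm = FALSE,
                  loo_components = FALSE))

check_keys <- function(block, schema, path) {
  unknown <- setdiff(names(block), names(schema))
  if (length(unknown))
    stop("unknown config key(s) under '", path, "': ",
         paste(unknown, collapse = ", "))
  for (nm in names(schema)) {
    if (is.list(schema[[nm]]) && !is.null(block[[nm]])) {
      if (!is.list(block[[nm]]))
        stop("config block '", path, ".", nm, "' must be a mapping")
      check_keys(block[[nm]], schema[[nm]], paste0(path, ".", nm))
    }
  }
}

#' Validate a pipeline configuration
#'
#' Checks the YAML/list configuration against the pipeline schema:
#' unknown keys are rejected, required blocks (`out_dir`, `seed`,
#' `categorization`, `alignment`, `analysis`, and one of
#' `simulate`/`input`) must be present.
#'
#' @param config list (parsed YAML) or path to a YAML file.
#' @return the validated config list, invisibly usable downstream.
#' @export
validate_config <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  check_keys(config, pipeline_schema, "config")
  required <- c("out_dir", "seed", "categorization", "alignment", "analysis")
  miss <- required[!required %in% names(config)]
  if (length(miss))
    stop("config missing required block(s): ", paste(miss, collapse = ", "))
  if (is.null(config$simulate) && is.null(config$input))
    stop("config needs either a 'simulate' or an 'input' block")
  config
}

simulate_from_config <- function(cfg, data_dir, seed) {
  sim <- cfg$simulate
  preset <- sim$preset %||% "demo"
  resolution <- sim$resolution %||% 256
  nz <- sim$noise %||% list()
  noise <- noise_model(
    boundary_jitter_sd = nz$boundary_jitter_sd %||% 1.5,
    colour_sd = nz$colour_sd %||% 8,
    transform_ranges = list(translation = nz$translation %||% 10,
                            rotation = nz$rotation %||% 8,
                            scale = nz$scale %||% c(0.95, 1.05)),
    pixel_noise_rate = nz$pixel_noise_rate %||% 0.002)
  if (preset == "demo") {
    alleles <- demo_alleles(ancestral = isTRUE(sim$ancestral))
    mech <- switch(sim$mechanism %||% "colour_hierarchy",
      colour_hierarchy = dominance_mechanism("colour_hierarchy",
        hierarchy = sim$hierarchy %||% CPM_HIERARCHY),
      full_dominance = dominance_mechanism("full_dominance",
        dominant_allele = sim$dominant_allele %||% names(alleles)[1]),
      stop("mosaic mechanism requires preset: mosaic"))
  } else if (preset == "mosaic") {
    alleles <- make_mosaic_pair()
    map <- mosaic_map_for_target(alleles$a, alleles$b,
                                 sim$target_dominance %||% 0.7, resolution)
    mech <- dominance_mechanism("mosaic", patch_dominance_map = map)
  } else stop("unknown simulate preset: ", preset)
  pc <- unlist(sim$pair_class %||% list())
  simulate_cross_dataset(data_dir, alleles,
                         n_per_genotype = sim$n_per_genotype %||% 10,
                         mechanism = mech, noise = noise, seed = seed,
                         pair_class = pc, resolution = resolution)
}

#' Run the full CPM pipeline
#'
#' Orchestrates simulate (or load) -> categorize -> align -> phenotype
#' space -> modal patterns -> dominance analysis, writing all stage
#' outputs, a QC report and a provenance record into the run directory.
#' Re-running with an identical config reproduces all tabular and JSON
#' reports bit-exactly.
#'
#' @param config list or YAML path (see [validate_config()]).
#' @return the run directory path, invisibly; stage results are also
#'   returned as attribute `"results"`.
#' @export
run_pipeline <- function(config) {
  cfg <- validate_config(config)
  run_dir <- cfg$out_dir
  dir.create(run_dir, recursive = TRUE, showWarnings = FALSE)
  log_path <- file.path(run_dir, "log.txt")
  logmsg <- function(...) cat(sprintf(...), "\n", sep = "", file = log_path,
                              append = TRUE)
  stage <- function(name, expr) {
    logmsg("[stage %s] start", name)
    tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }

  # -- data ---------------------------------------------------------------
  data_dir <- if (!is.null(cfg$simulate)) {
    d <- file.path(run_dir, "data")
    stage("simulate", simulate_from_config(cfg, d, cfg$seed))
    d
  } else cfg$input$dir
  meta <- stage("read_table",
                read_specimen_table(file.path(data_dir, "specimens.tsv")))

  # -- categorize ---------------------------------------------------------
  cc <- cfg$categorization
  cat_cfg <- categorization_config(
    downscale_factor = cc$downscale_factor %||% 1,
    merge_threshold = cc$merge_threshold %||% 60,
    min_region_px = cc$min_region_px %||% 8)
  pat_dir <- file.path(run_dir, "patterns")
  dir.create(pat_dir, showWarnings = FALSE)
  qc_cat <- list()
  patterns <- stage("categorize", {
    out <- list()
    for (r in seq_len(nrow(meta))) {
      id <- meta$specimen_id[r]
      img <- read_wing_image(file.path(data_dir, meta$image_path[r]))
      mask <- extract_outline(img)
      img <- simplify(img, cat_cfg)
      if (cat_cfg$downscale_factor > 1)
        stop("downscale_factor > 1 not supported inside the pipeline ",
             "(mask and image frames would diverge)")
      p <- categorize(img, mask, cat_cfg)
      qc_cat[[id]] <- attr(p, "qc")$unresolved_fraction
      write_pattern(p, file.path(pat_dir, paste0(id, ".png")))
      out[[id]] <- p
    }
    out
  })

  # -- align (per wing x side group) --------------------------------------
  al <- cfg$alignment
  aligned_all <- list(); transforms_all <- list(); traces <- list()
  scores <- list()
  stage("align", {
    grp <- paste(meta$wing, meta$side)
    for (g in unique(grp)) {
      ids <- meta$specimen_id[grp == g]
      res <- align_recursive(patterns[ids], n_iter = al$n_iter %||% 6,
                             tol = al$tol %||% 1e-3)
      aligned_all[ids] <- res$aligned
      transforms_all[ids] <- res$transforms
      traces[[g]] <- res$trace
      for (id in ids)
        scores[[id]] <- attr(res$transforms[[id]], "score") %||% NA_real_
    }
  })
  write_transforms(transforms_all, file.path(run_dir, "transforms.json"))

  # -- phenotype space ----------------------------------------------------
  an <- cfg$analysis
  tm <- stage("phenospace", build_trait_matrix(aligned_all))
  pca <- pca_summary(tm, min_var_fraction = an$min_var_fraction %||% 0.01)
  sc_tab <- data.frame(specimen_id = rownames(pca$scores),
                       genotype = meta$genotype[match(rownames(pca$scores),
                                                      meta$specimen_id)],
                       pca$scores, check.names = FALSE)
  write.table(sc_tab, file.path(run_dir, "scores.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)

  # -- dominance ----------------------------------------------------------
  dom <- stage("dominance", dominance_table(aligned_all, meta))
  write.table(dom$table, file.path(run_dir, "dominance.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  hm_dir <- file.path(run_dir, "heatmaps")
  dir.create(hm_dir, showWarnings = FALSE)
  for (pair in names(dom$groups)) {
    g <- dom$groups[[pair]]
    hm <- dominance_heatmap(g$hets, g$modal_dom, g$modal_rec)
    safe <- gsub("/", "_", pair)
    png::writePNG(heatmap_to_rgb(hm), file.path(hm_dir, paste0(safe, ".png")))
    jsonlite::write_json(list(pair = pair, n_het = hm$n_het),
                         file.path(hm_dir, paste0(safe, ".json")),
                         auto_unbox = TRUE, digits = NA)
    write_pattern(g$modal_a, file.path(run_dir, "patterns",
                                       paste0("modal_", gsub("/", "_", attr(g$modal_a, "genotype")), ".png")))
  }

  conf <- list()
  if (length(dom$groups)) {
    conf$hierarchy_conformity <- as.numeric(hierarchy_conformity(dom$groups))
    for (cp in list(c("black", "orange"), c("black", "yellow"),
                    c("orange", "yellow"))) {
      key <- paste(cp, collapse = "_")
      pr <- tryCatch(colour_expression_probability(dom$groups, cp),
                     warning = function(w) NULL)
      if (!is.null(pr)) conf[[key]] <- as.list(pr)
    }
  }

  perm <- list()
  tab <- dom$table
  if (nrow(tab) && "pair_class" %in% names(tab)) {
    has <- !is.na(tab$pair_class)
    if (length(unique(tab$pair_class[has])) == 2) {
      pt <- permutation_test_mean_difference(tab$h[has], tab$pair_class[has],
                                             n_perm = an$n_perm %||% 999,
                                             seed = cfg$seed)
      perm$sympatric_vs_parapatric <- pt[c("observed", "p", "method")]
    }
  }
  if (nrow(tab) >= 3) {
    d <- vapply(seq_len(nrow(tab)), function(r) {
      tryCatch(genotype_distance(pca$scores,
                                 meta$genotype[match(rownames(pca$scores),
                                                     meta$specimen_id)],
                                 paste(tab$allele_a[r], tab$allele_a[r], sep = "/"),
                                 paste(tab$allele_b[r], tab$allele_b[r], sep = "/")),
               error = function(e) NA_real_)
    }, 0)
    ok <- !is.na(d)
    if (sum(ok) >= 3 && sd(tab$h[ok]) > 0 && sd(d[ok]) > 0) {
      perm$h_vs_distance <- correlate_h_distance(tab$h[ok], d[ok],
                                                 n_perm = an$n_perm %||% 999,
                                                 seed = cfg$seed)
    }
  }
  jsonlite::write_json(c(conf, perm), file.path(run_dir, "analysis.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)

  # -- QC + provenance ----------------------------------------------------
  neither <- list()
  for (pair in names(dom$groups)) {
    g <- dom$groups[[pair]]
    for (id in names(g$hets))
      neither[[id]] <- trait_T(g$hets[[id]], g$modal_a, g$modal_b)$neither
  }
  qc <- list(unresolved_fraction = qc_cat,
             alignment_score = scores,
             neither_modal_fraction = neither)
  jsonlite::write_json(qc, file.path(run_dir, "qc.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  cfg_json <- jsonlite::toJSON(cfg, auto_unbox = TRUE, digits = NA)
  prov <- list(config = cfg, config_md5 = {
    tf <- tempfile(); writeLines(cfg_json, tf)
    unname(tools::md5sum(tf))
  }, seed = cfg$seed,
  package_version = as.character(utils::packageVersion("cpmr")))
  jsonlite::write_json(prov, file.path(run_dir, "provenance.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  logmsg("[done]")
  out <- run_dir
  attr(out, "results") <- list(meta = meta, patterns = patterns,
                               aligned = aligned_all, pca = pca,
                               dominance = dom, analysis = c(conf, perm),
                               qc = qc, traces = traces)
  invisible(out)
}

#' QC report over a completed run directory
#'
#' Aggregates per-specimen unresolved-pixel fractions, alignment scores
#' and neither-modal fractions from the run's `qc.json`, flagging
#' specimens more than 3 MAD from the median of any metric.
#'
#' @param run_dir directory produced by [run_pipeline()].
#' @return list with `metrics` (data.frame) and `outliers` (specimen
#'   ids); also writes `qc_report.json` and a readable summary.
#' @export
qc_report <- function(run_dir) {
  qc_path <- file.path(run_dir, "qc.json")
  if (!file.exists(qc_path)) stop("not a completed run directory: ", run_dir)
  qc <- jsonlite::read_json(qc_path, simplifyVector = TRUE)
  ids <- names(qc$unresolved_fraction)
  metrics <- data.frame(
    specimen_id = ids,
    unresolved_fraction = unlist(qc$unresolved_fraction[ids]),
    alignment_score = unlist(qc$alignment_score[ids]),
    neither_modal_fraction = vapply(ids, function(id)
      qc$neither_modal_fraction[[id]] %||% NA_real_, 0),
    stringsAsFactors = FALSE)
  flag <- rep(FALSE, nrow(metrics))
  for (col in c("unresolved_fraction", "alignment_score",
                "neither_modal_fraction")) {
    v <- metrics[[col]]
    ok <- !is.na(v)
    if (sum(ok) < 3) next
    m <- median(v[ok]); s <- mad(v[ok])
    if (s == 0) next
    flag[ok] <- flag[ok] | abs(v[ok] - m) > 3 * s
  }
  out <- list(metrics = metrics, outliers = metrics$specimen_id[flag])
  jsonlite::write_json(
    list(outliers = out$outliers,
         summary = lapply(metrics[-1], function(v)
           list(median = median(v, na.rm = TRUE),
                mad = mad(v, na.rm = TRUE)))),
    file.path(run_dir, "qc_report.json"), auto_unbox = TRUE, digits = NA,
    pretty = TRUE)
  writeLines(c(sprintf("specimens: %d", nrow(metrics)),
               sprintf("outliers (>3 MAD): %s",
                       if (length(out$outliers))
                         paste(out$outliers, collapse = ", ") else "none")),
             file.path(run_dir, "qc_report.txt"))
  out
}
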