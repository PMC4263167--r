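#' Read and validate a specimen metadata table
#'
#' Reads a TSV/CSV table of specimen records (columns `specimen_id`,
#' `wing`, `side`, `allele_1`, `allele_2`, `pair_class`, `image_path`),
#' validates it, and reports problems.  The genotype is treated as an
#' unordered allele pair and stored alphabetically.
#'
#' @param path table path; comma- or tab-separated (sniffed from the
#'   header line).
#' @param alleles optional declared allele set; unknown alleles are
#'   reported in the QC attribute.
#' @param base_dir directory that `image_path` entries are relative to
#'   (default: the table's directory).  Records whose image file is
#'   missing are excluded and listed in the QC attribute.
#' @return data.frame of validated records with a `genotype` column
#'   (`"a/b"`, alphabetical).  Attribute `"qc"` lists excluded records and
#'   unknown alleles.
#' @export
read_specimen_table <- function(path, alleles = NULL, base_dir = dirname(path)) {
  if (!file.exists(path)) stop("specimen table not found: ", path)
  header <- readLines(path, n = 1)
  sep <- if (grepl("\t", header)) "\t" else ","
  tab <- read.delim(path, sep = sep, stringsAsFactors = FALSE)
  required <- c("specimen_id", "wing", "side", "allele_1", "allele_2",
                "pair_class", "image_path")
  miss <- setdiff(required, names(tab))
  if (length(miss))
    stop("specimen table missing column(s): ", paste(miss, collapse = ", "))
  key <- paste(tab$specimen_id, tab$wing, tab$side)
  if (anyDuplicated(key))
    stop("duplicated specimen_id x wing x side: ",
         paste(unique(key[duplicated(key)]), collapse = "; "))
  # unordered genotype, alphabetical storage
  a <- pmin(tab$allele_1, tab$allele_2)
  b <- pmax(tab$allele_1, tab$allele_2)
  tab$allele_1 <- a; tab$allele_2 <- b
  tab$genotype <- paste(a, b, sep = "/")
  qc <- list(unknown_alleles = character(), excluded = character())
  if (!is.null(alleles)) {
    bad <- setdiff(unique(c(a, b)), alleles)
    qc$unknown_alleles <- bad
  }
  ok <- file.exists(file.path(base_dir, tab$image_path))
  qc$excluded <- tab$specimen_id[!ok]
  tab <- tab[ok, , drop = FALSE]
  rownames(tab) <- NULL
  attr(tab, "qc") <- qc
  tab
}

#' Parse an unordered genotype label
#' @param x genotype string `"a/b"`.
#' @param alleles optional declared allele set to validate against.
#' @return sorted character vector of the two allele ids.
#' @export
parse_genotype <- function(x, alleles = NULL) {
  g <- sort(strsplit(x, "/", fixed = TRUE)[[1]])
  if (length(g) == 1) g <- c(g, g)
  if (length(g) != 2) stop("genotype must be 'a/b': ", x)
  if (!is.null(alleles)) {
    bad <- setdiff(g, alleles)
    if (length(bad)) stop("unknown allele(s): ", paste(bad, collapse = ", "))
  }
  g
}

#' Lossless pattern raster I/O
#'
#' Patterns are stored as a code-valued grayscale PNG (pixel value =
#' class code / 255) with a JSON sidecar (`<path>.json`) carrying the
#' ordered class table and the raster space, so the round trip is exact
#' cell-for-cell.  Reading fails loudly if the sidecar is missing or the
#' codes in the PNG exceed the declared class table.
#'
#' @param pattern a [colour_pattern].
#' @param path PNG path; the sidecar is written next to it.
#' @return `write_pattern`: the path, invisibly.  `read_pattern`: a
#'   [colour_pattern].  A pattern with an empty wing mask is valid; it is
#'   flagged in the sidecar (`empty_mask`) and on read via a warning.
#' @export
write_pattern <- function(pattern, path) {
  stopifnot(inherits(pattern, "colour_pattern"))
  png::writePNG(pattern$grid / 255, path)
  jsonlite::write_json(
    list(classes = pattern$classes, space = pattern$space,
         resolution = dim(pattern$grid),
         empty_mask = !any(pattern$grid > 0L)),
    paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_pattern
#' @export
read_pattern <- function(path) {
  sidecar <- paste0(path, ".json")
  if (!file.exists(sidecar))
    stop("pattern sidecar not found (refusing to guess the class table): ",
         sidecar)
  meta <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
  g <- round(png::readPNG(path) * 255)
  if (length(dim(g)) == 3) stop("pattern PNG must be single-channel: ", path)
  if (max(g) >= length(meta$classes))
    stop("pattern codes exceed the declared class table: ", path)
  if (isTRUE(meta$empty_mask)) warning("pattern has an empty wing mask: ", path)
  colour_pattern(g, meta$classes, meta$space)
}

#' Read an RGB wing image
#' @param path PNG path.
#' @param mirror flip the image left-right before use, to bring left and
#'   right wings to a common chirality.
#' @return numeric array rows x cols x 3 in \[0, 1\].
#' @export
read_wing_image <- function(path, mirror = FALSE) {
  img <- png::readPNG(path)
  if (length(dim(img)) == 2) img <- array(rep(img, 3), c(dim(img), 3))
  if (dim(img)[3] > 3) img <- img[, , 1:3, drop = FALSE]
  if (mirror) img <- img[, rev(seq_len(ncol(img))), , drop = FALSE]
  img
}

# write a similarity transform list as JSON
write_transforms <- function(transforms, path) {
  jsonlite::write_json(
    lapply(transforms, function(tf) tf[c("tx", "ty", "theta", "s")]),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

read_transforms <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  lapply(raw, function(x) similarity_transform(x$tx, x$ty, x$theta, x$s))
}
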