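## UMI deduplication and sparse count-matrix output.

#' Deduplicate UMIs and build the feature-by-pixel count matrix
#'
#' Reads sharing an identical (pixel, feature, layer, UMI) tuple collapse
#' to one molecule; distinct UMIs count separately.  Composite
#' multi-mapping names get their own rows and are never redistributed.
#' Columns cover every whitelist-defined pixel (including empty ones) so
#' matrices from different runs align.
#'
#' @param assignments data.frame from [assign_reads()] (or the same
#'   columns read back from TSV); only rows with `status == "assigned"`
#'   are counted.
#' @param pixels character vector of all pixel keys (`"x"x"y"`); defaults
#'   to the pixels observed in `assignments`.
#' @param feature_meta optional data.frame (`name`, `rna_class`) used to
#'   annotate rows; composite rows get class `NA`.
#' @return object of class `count_matrix`: `layers` (named list of
#'   `dgCMatrix`, rows = features, columns = pixels), `features`
#'   (metadata data.frame), `pixels`.
#' @export
dedup_and_count <- function(assignments, pixels = NULL,
                            feature_meta = NULL) {
  a <- assignments[assignments$status == "assigned", , drop = FALSE]
  if (is.null(pixels)) pixels <- sort(unique(a$pixel))
  if (anyDuplicated(pixels)) stop("pixel keys must be unique")
  tup <- unique(a[, c("pixel", "feature", "layer", "umi")])
  fnames <- sort(unique(tup$feature))
  layers <- list()
  for (ly in c("exon", "intron")) {
    t_ly <- tup[tup$layer == ly, , drop = FALSE]
    cnt <- if (nrow(t_ly)) {
      agg <- rowsum(rep(1L, nrow(t_ly)),
                    paste0(t_ly$feature, "\r", t_ly$pixel))
      parts <- strsplit(rownames(agg), "\r", fixed = TRUE)
      data.frame(feature = vapply(parts, `[`, character(1), 1L),
                 pixel = vapply(parts, `[`, character(1), 2L),
                 n = as.integer(agg[, 1]))
    } else data.frame(feature = character(0), pixel = character(0),
                      n = integer(0))
    layers[[ly]] <- Matrix::sparseMatrix(
      i = match(cnt$feature, fnames), j = match(cnt$pixel, pixels),
      x = cnt$n, dims = c(length(fnames), length(pixels)),
      dimnames = list(fnames, pixels))
  }
  meta <- data.frame(name = fnames,
                     rna_class = rep(NA_character_, length(fnames)),
                     stringsAsFactors = FALSE)
  if (!is.null(feature_meta)) {
    m <- match(fnames, feature_meta$name)
    meta$rna_class <- feature_meta$rna_class[m]
  }
  structure(list(layers = layers, features = meta, pixels = pixels),
            class = "count_matrix")
}

#' @export
print.count_matrix <- function(x, ...) {
  cat("count_matrix:", nrow(x$features), "features x", length(x$pixels),
      "pixels\n")
  for (ly in names(x$layers))
    cat(sprintf("  %s layer: %d UMIs in %d nonzero cells\n", ly,
                sum(x$layers[[ly]]), length(x$layers[[ly]]@x)))
  invisible(x)
}

#' Total UMI count across layers
#' @param x a `count_matrix`.
#' @export
total_counts <- function(x) sum(vapply(x$layers, sum, numeric(1)))

#' Write a count matrix as Matrix Market files plus sidecars
#'
#' Per layer a coordinate `.mtx` with integer entries; shared
#' `features.tsv` (name, rna_class) and `pixels.tsv`; and a combined
#' long-form `counts_long.tsv` (feature, pixel, layer, count).  Reading
#' the directory back with [read_count_matrix()] reproduces the matrix
#' exactly.
#'
#' @param x a `count_matrix`.
#' @param outdir output directory (created if needed).
#' @param prefix optional filename prefix (e.g. `"curated_"`).
#' @export
write_count_matrix <- function(x, outdir, prefix = "") {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  for (ly in names(x$layers)) {
    mm <- file.path(outdir, paste0(prefix, ly, ".mtx"))
    m <- x$layers[[ly]]
    s <- Matrix::summary(m)
    # emitted directly: writeMM downgrades all-ones matrices to
    # "pattern" (and square ones to "symmetric"), losing integer entries
    con <- file(mm, "w")
    writeLines(c("%%MatrixMarket matrix coordinate integer general",
                 paste(nrow(m), ncol(m), nrow(s))), con)
    if (nrow(s))
      writeLines(paste(s$i, s$j, as.integer(s$x)), con)
    close(con)
  }
  write.table(x$features, file.path(outdir, paste0(prefix, "features.tsv")),
              sep = "\t", quote = FALSE, row.names = FALSE)
  writeLines(x$pixels, file.path(outdir, paste0(prefix, "pixels.tsv")))
  long <- do.call(rbind, lapply(names(x$layers), function(ly) {
    m <- x$layers[[ly]]
    s <- Matrix::summary(m)
    if (nrow(s) == 0L)
      return(data.frame(feature = character(0), pixel = character(0),
                        layer = character(0), count = integer(0)))
    data.frame(feature = rownames(m)[s$i], pixel = colnames(m)[s$j],
               layer = ly, count = as.integer(s$x))
  }))
  long <- long[order(long$feature, long$pixel, long$layer), , drop = FALSE]
  write.table(long, file.path(outdir, paste0(prefix, "counts_long.tsv")),
              sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(outdir)
}

#' @rdname write_count_matrix
#' @export
read_count_matrix <- function(outdir, prefix = "") {
  feats <- read.table(file.path(outdir, paste0(prefix, "features.tsv")),
                      sep = "\t", header = TRUE, stringsAsFactors = FALSE,
                      colClasses = c("character", "character"))
  pixels <- readLines(file.path(outdir, paste0(prefix, "pixels.tsv")))
  layers <- list()
  for (ly in c("exon", "intron")) {
    m <- methods::as(Matrix::readMM(file.path(outdir,
                                              paste0(prefix, ly, ".mtx"))),
                     "CsparseMatrix")
    dimnames(m) <- list(feats$name, pixels)
    layers[[ly]] <- m
  }
  structure(list(layers = layers, features = feats, pixels = pixels),
            class = "count_matrix")
}
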