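## Feature validation by read-depth enrichment over flanking background.
##
## A genuine compact RNA (a miRNA arm, a tRNA, a snoRNA) shows a step in
## read depth over its body; a spurious annotation sitting in randomly
## fragmented background RNA does not.  Each candidate feature is tested
## by comparing the number of same-strand alignment midpoints falling
## inside the feature against the number falling in flanking background
## windows, with a one-sided exact binomial test whose null success
## probability is the length share of the feature
## (p0 = L_in / (L_in + L_bg)).  Midpoint counting makes each read one
## Bernoulli trial, so the binomial model is exact.  Validation is
## computed on pseudo-bulk (all pixels pooled); the curated feature set
## then filters every pixel's column identically.

## RNA classes validated by default: compact non-coding structures.
VALIDATED_CLASSES <- c("miRNA", "tRNA", "snoRNA", "snRNA", "scaRNA",
                       "piRNA", "Y_RNA", "miscRNA")

#' Depth profile of one feature against its flanking background
#'
#' The background is one upstream plus one downstream window, each of
#' length `flank_mult * L_in`, clipped at chromosome bounds and masked
#' where any *other* same-strand annotated feature lies (masked bases
#' reduce `L_bg`).
#'
#' @param feature one-row slice of a feature table (`start`, `end`,
#'   `chrom`, `strand`, `name`).
#' @param midpoints data.frame of alignment midpoints with columns
#'   `chrom`, `strand`, `pos` (0-based).
#' @param mask optional data.frame (`chrom`, `strand`, `start`, `end`) of
#'   intervals to exclude from the background (typically every other
#'   feature span).
#' @param flank_mult background window length as a multiple of the
#'   feature length, default 1.
#' @param chrom_length chromosome length for right clipping (NA = no
#'   clipping).
#' @return list of class `depth_profile`: `name`, `in_count`, `bg_count`,
#'   `L_in`, `L_bg`.
#' @export
profile_feature <- function(feature, midpoints, mask = NULL,
                            flank_mult = 1, chrom_length = NA) {
  stopifnot(flank_mult > 0)
  L_in <- feature$end - feature$start
  w <- ceiling(flank_mult * L_in)
  up <- c(max(0, feature$start - w), feature$start)
  dn <- c(feature$end, feature$end + w)
  if (!is.na(chrom_length)) dn[2] <- min(dn[2], chrom_length)
  bg <- IRanges::IRanges(start = c(up[1], dn[1]) + 1L,
                         end = c(up[2], dn[2]))
  bg <- bg[IRanges::width(bg) > 0]
  if (!is.null(mask) && nrow(mask)) {
    m <- mask[mask$chrom == feature$chrom & mask$strand == feature$strand &
                !(mask$start == feature$start & mask$end == feature$end), ,
              drop = FALSE]
    if (nrow(m))
      bg <- IRanges::setdiff(bg, IRanges::IRanges(m$start + 1L, m$end))
  }
  L_bg <- sum(IRanges::width(bg))
  mp <- midpoints[midpoints$chrom == feature$chrom &
                    midpoints$strand == feature$strand, , drop = FALSE]
  in_count <- sum(mp$pos >= feature$start & mp$pos < feature$end)
  bg_count <- if (length(bg) && nrow(mp))
    sum(IRanges::overlapsAny(IRanges::IRanges(mp$pos + 1L, mp$pos + 1L), bg))
  else 0L
  structure(list(name = feature$name, in_count = in_count,
                 bg_count = as.integer(bg_count), L_in = L_in,
                 L_bg = as.integer(L_bg)),
            class = "depth_profile")
}

#' One-sided exact binomial enrichment p-value for a depth profile
#'
#' Tests whether in-feature read depth exceeds the length-proportional
#' expectation: with n = in_count + bg_count trials and null success
#' probability p0 = L_in / (L_in + L_bg), the p-value is
#' P(X >= in_count).
#'
#' @param profile a `depth_profile`.
#' @return the p-value, or NA for untestable profiles (no background
#'   length or no reads at all).
#' @export
enrichment_pvalue <- function(profile) {
  n <- profile$in_count + profile$bg_count
  if (profile$L_bg == 0L || n == 0L) return(NA_real_)
  p0 <- profile$L_in / (profile$L_in + profile$L_bg)
  stats::pbinom(profile$in_count - 1L, n, p0, lower.tail = FALSE)
}

#' Validate features by depth enrichment over background
#'
#' Profiles and tests every feature of the validated RNA classes,
#' BH-adjusts the p-values across tested features, and issues verdicts:
#' `valid` iff q <= alpha and fold enrichment >= min_fold and
#' in_count >= min_reads; `untestable` iff the background has zero length
#' or the feature region saw no reads at all; `invalid` otherwise.
#' Fold enrichment is the depth ratio (in_count/L_in)/(bg_count/L_bg),
#' infinite when reads fall only inside.
#'
#' @param index an [annotation_index()].
#' @param aln result of [read_alignments()] (midpoints are taken from the
#'   fragment envelopes, same strand as each feature).
#' @param classes RNA classes to validate (default: compact ncRNA
#'   classes).
#' @param alpha FDR level, default 0.05.
#' @param min_fold minimum fold enrichment, default 2.
#' @param min_reads minimum in-feature reads, default 5.
#' @param flank_mult background window multiple, default 1.
#' @return data.frame (one row per tested feature): `feature`,
#'   `in_count`, `bg_count`, `L_in`, `L_bg`, `fold`, `p`, `q`, `verdict`.
#' @export
validate_features <- function(index, aln, classes = VALIDATED_CLASSES,
                              alpha = 0.05, min_fold = 2, min_reads = 5,
                              flank_mult = 1) {
  feats <- index$features
  targets <- feats[feats$record_kind == "exon" &
                     feats$rna_class %in% classes, , drop = FALSE]
  if (nrow(targets) == 0L)
    return(data.frame(feature = character(0), in_count = integer(0),
                      bg_count = integer(0), L_in = integer(0),
                      L_bg = integer(0), fold = numeric(0), p = numeric(0),
                      q = numeric(0), verdict = character(0)))
  frag <- aln$fragments
  midpoints <- data.frame(chrom = frag$chrom, strand = frag$strand,
                          pos = (frag$start + frag$end) %/% 2L)
  mask <- feats[feats$record_kind %in% c("exon", "transcript"),
                c("chrom", "strand", "start", "end"), drop = FALSE]
  cl <- aln$chrom_lengths
  profs <- lapply(seq_len(nrow(targets)), function(i) {
    f <- targets[i, , drop = FALSE]
    profile_feature(f, midpoints, mask = mask, flank_mult = flank_mult,
                    chrom_length = if (!is.null(cl) && f$chrom %in% names(cl))
                      cl[[f$chrom]] else NA)
  })
  res <- data.frame(
    feature = vapply(profs, `[[`, character(1), "name"),
    in_count = vapply(profs, `[[`, integer(1), "in_count"),
    bg_count = vapply(profs, `[[`, integer(1), "bg_count"),
    L_in = vapply(profs, function(p) as.integer(p$L_in), integer(1)),
    L_bg = vapply(profs, `[[`, integer(1), "L_bg"),
    stringsAsFactors = FALSE)
  res$fold <- ifelse(res$bg_count > 0,
                     (res$in_count / res$L_in) /
                       (res$bg_count / pmax(res$L_bg, 1L)),
                     ifelse(res$in_count > 0, Inf, NaN))
  res$p <- vapply(profs, enrichment_pvalue, numeric(1))
  testable <- !is.na(res$p)
  res$q <- NA_real_
  res$q[testable] <- stats::p.adjust(res$p[testable], method = "BH")
  res$verdict <- ifelse(!testable, "untestable",
                 ifelse(res$q <= alpha & res$fold >= min_fold &
                          res$in_count >= min_reads, "valid", "invalid"))
  res
}

#' Drop invalid features from a count matrix
#'
#' Rows whose feature was judged `invalid` are removed; `untestable`
#' features are kept and flagged in the returned metadata; features never
#' tested (e.g. mRNA genes, composite rows) are kept untouched.  The
#' uncurated matrix is left as-is by the caller — curation is optional.
#'
#' @param x a `count_matrix`.
#' @param results validation table from [validate_features()].
#' @return a curated `count_matrix`; feature metadata gains a `verdict`
#'   column.
#' @export
curate_matrix <- function(x, results) {
  if (nrow(results) == 0L) {
    warning("empty validation results; returning matrix unchanged")
    x$features$verdict <- "untested"
    return(x)
  }
  m <- match(x$features$name, results$feature)
  verdict <- ifelse(is.na(m), "untested", results$verdict[m])
  keep <- verdict != "invalid"
  out <- x
  out$features <- x$features[keep, , drop = FALSE]
  out$features$verdict <- verdict[keep]
  rownames(out$features) <- NULL
  for (ly in names(out$layers))
    out$layers[[ly]] <- x$layers[[ly]][keep, , drop = FALSE]
  out
}
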