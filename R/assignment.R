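## Read-to-feature assignment by overlap score.
##
## Each aligned fragment is scored against every exon/intron record it
## overlaps: score = (L_o - L_no) / L_a, with L_o the aligned bases inside
## the feature, L_no = L_read - L_o the aligned bases outside it, and L_a
## the feature length.  The highest-scoring feature wins; exact ties are
## reported as one composite multi-mapping feature named by plus-joining
## the tied names.  Tie detection uses exact integer cross-multiplication,
## never floating-point equality: n1/d1 == n2/d2 iff n1*d2 == n2*d1, and
## all products stay far below 2^53.

#' Overlap score between an aligned fragment and a feature
#'
#' @param blocks two-column matrix (start, end) of 0-based half-open
#'   aligned blocks (match/deletion runs; insertions and skips excluded).
#' @param feature_start,feature_end feature interval, 0-based half-open.
#' @return the score (L_o - L_no) / L_a as a double.
#' @examples
#' overlap_score(cbind(150, 250), 0, 1000)   # 0.1
#' overlap_score(cbind(140, 240), 200, 400)  # -0.1
#' @export
overlap_score <- function(blocks, feature_start, feature_end) {
  L_read <- sum(blocks[, 2] - blocks[, 1])
  L_o <- sum(pmax(0, pmin(blocks[, 2], feature_end) -
                    pmax(blocks[, 1], feature_start)))
  L_a <- feature_end - feature_start
  stopifnot(L_a > 0, L_read >= 1)
  (L_o - (L_read - L_o)) / L_a
}

#' Read primary alignments with pixel/UMI metadata
#'
#' Accepts SAM (converted on the fly) or BAM.  Secondary, supplementary
#' and unmapped records are dropped: each fragment gets exactly one vote.
#' Pixel and UMI are recovered from the read name when it carries
#' `|PX:<x>x<y>|UMI:<umi>` metadata, or joined from a demultiplexing table
#' (`read_id`, `x`, `y`, `umi`); reads with neither are dropped and
#' counted.
#'
#' @param path SAM or BAM file.
#' @param demux optional data.frame with columns `read_id`, `x`, `y`,
#'   `umi`.
#' @return list with `fragments` (data.frame: read_id, chrom, strand,
#'   start, end, cigar, n_softclip, L_read, pixel, umi), `blocks`
#'   (data.frame: frag (row index), start, end), `chrom_lengths` (named
#'   integer), and `n_dropped` (named counts).
#' @export
read_alignments <- function(path, demux = NULL) {
  bam <- path
  if (grepl("\\.sam$", path, ignore.case = TRUE)) {
    bam <- Rsamtools::asBam(path, tempfile(), overwrite = TRUE,
                            indexDestination = FALSE)
  }
  param <- Rsamtools::ScanBamParam(
    what = c("qname", "flag"),
    flag = Rsamtools::scanBamFlag(isUnmappedQuery = FALSE,
                                  isSecondaryAlignment = FALSE,
                                  isSupplementaryAlignment = FALSE))
  gal <- GenomicAlignments::readGAlignments(bam, param = param)
  hdr <- Rsamtools::scanBamHeader(bam)[[1]]$targets
  qname <- S4Vectors::mcols(gal)$qname
  cig <- GenomicAlignments::cigar(gal)
  ops <- GenomicAlignments::cigarOpTable(cig)
  n_soft <- ops[, "S"]
  # aligned blocks: M/D/=/X runs on the reference; N splits blocks
  blk <- GenomicAlignments::cigarRangesAlongReferenceSpace(
    cig, pos = GenomicAlignments::start(gal),
    ops = c("M", "D", "=", "X"), reduce.ranges = TRUE)
  nblk <- S4Vectors::elementNROWS(blk)
  blk_flat <- unlist(blk)
  blocks <- data.frame(frag = rep(seq_along(gal), nblk),
                       start = IRanges::start(blk_flat) - 1L,
                       end = IRanges::end(blk_flat))
  frag <- data.frame(
    read_id = qname,
    chrom = as.character(GenomicAlignments::seqnames(gal)),
    strand = as.character(GenomicAlignments::strand(gal)),
    start = GenomicAlignments::start(gal) - 1L,
    end = GenomicAlignments::end(gal),
    cigar = cig,
    n_softclip = as.integer(n_soft),
    stringsAsFactors = FALSE)
  frag$L_read <- as.integer(rowsum(blocks$end - blocks$start,
                                   blocks$frag)[, 1])
  # pixel / UMI metadata
  n_dropped <- c(no_metadata = 0L)
  px <- regmatches(frag$read_id,
                   regexpr("\\|PX:[0-9]+x[0-9]+\\|UMI:[ACGTN]+", frag$read_id))
  has_inline <- grepl("\\|PX:[0-9]+x[0-9]+\\|UMI:[ACGTN]+", frag$read_id)
  frag$pixel <- NA_character_
  frag$umi <- NA_character_
  if (any(has_inline)) {
    meta <- frag$read_id[has_inline]
    frag$pixel[has_inline] <- sub(".*\\|PX:([0-9]+x[0-9]+)\\|.*", "\\1", meta)
    frag$umi[has_inline] <- sub(".*\\|UMI:([ACGTN]+).*", "\\1", meta)
    frag$read_id[has_inline] <- sub("\\|PX:.*$", "", frag$read_id[has_inline])
  }
  if (!is.null(demux)) {
    m <- match(frag$read_id, demux$read_id)
    use <- !has_inline & !is.na(m)
    frag$pixel[use] <- pixel_key(demux$x[m[use]], demux$y[m[use]])
    frag$umi[use] <- demux$umi[m[use]]
  }
  keep <- !is.na(frag$pixel)
  n_dropped["no_metadata"] <- sum(!keep)
  if (any(!keep)) {
    keep_frag <- which(keep)
    blocks <- blocks[blocks$frag %in% keep_frag, , drop = FALSE]
    blocks$frag <- match(blocks$frag, keep_frag)
    frag <- frag[keep, , drop = FALSE]
    rownames(frag) <- NULL
  }
  list(fragments = frag, blocks = blocks,
       chrom_lengths = hdr, n_dropped = n_dropped)
}

#' Assign aligned fragments to features by overlap score
#'
#' Candidates are every exon and intron record overlapping any aligned
#' block (so a spliced fragment never collects the intron it jumps over),
#' filtered by the strand policy.  A fragment is assigned when the maximal
#' score is positive; an exact score tie across different feature names
#' yields a composite multi-mapping name (sorted, plus-joined), whose
#' layer is exon if any tied feature is an exon.
#'
#' Post-alignment filters for degraded (FFPE-grade) libraries: fragments
#' with fewer than `min_align_len` aligned bases or with more than
#' `max_softclip_frac` of the read soft-clipped are discarded as invalid.
#'
#' @param aln result of [read_alignments()].
#' @param index an [annotation_index()].
#' @param strand_policy `"same"` (default: candidate features must lie on
#'   the fragment's strand), `"opposite"`, or `"both"`.
#' @param min_align_len minimum aligned length, default 20.
#' @param max_softclip_frac maximum soft-clipped fraction, default 0.5.
#' @return data.frame with one row per retained fragment: `read_id`,
#'   `pixel`, `umi`, `feature`, `layer`, `score`, `status`; counts of
#'   filtered fragments in attribute `n_filtered`.
#' @export
assign_reads <- function(aln, index, strand_policy = c("same", "opposite",
                                                       "both"),
                         min_align_len = 20L, max_softclip_frac = 0.5) {
  strand_policy <- match.arg(strand_policy)
  frag <- aln$fragments
  blocks <- aln$blocks
  n_filtered <- c(short_alignment = 0L, softclipped = 0L)
  readlen <- frag$L_read + frag$n_softclip
  ok <- frag$L_read >= min_align_len &
    frag$n_softclip / readlen <= max_softclip_frac
  n_filtered["short_alignment"] <- sum(frag$L_read < min_align_len)
  n_filtered["softclipped"] <- sum(frag$n_softclip / readlen >
                                     max_softclip_frac &
                                     frag$L_read >= min_align_len)
  # filtered fragments stay in the table as unassigned; only surviving
  # fragments are scored
  blocks <- blocks[ok[blocks$frag], , drop = FALSE]

  n <- nrow(frag)
  out <- data.frame(read_id = frag$read_id, pixel = frag$pixel,
                    umi = frag$umi, feature = rep(NA_character_, n),
                    layer = rep(NA_character_, n),
                    score = rep(NA_real_, n),
                    status = rep("unassigned", n),
                    stringsAsFactors = FALSE)
  if (nrow(blocks) == 0L) {
    attr(out, "n_filtered") <- n_filtered
    return(out)
  }

  feats <- index$features
  scorable <- which(feats$record_kind %in% c("exon", "intron"))
  bgr <- GenomicRanges::GRanges(
    frag$chrom[blocks$frag],
    IRanges::IRanges(blocks$start + 1L, blocks$end))
  hits <- GenomicRanges::findOverlaps(bgr, index$gr[scorable],
                                      ignore.strand = TRUE)
  bi <- S4Vectors::queryHits(hits)
  fi <- scorable[S4Vectors::subjectHits(hits)]
  # strand policy filter
  fs <- frag$strand[blocks$frag[bi]]
  keep <- switch(strand_policy,
                 same = feats$strand[fi] == fs,
                 opposite = feats$strand[fi] != fs,
                 both = rep(TRUE, length(fi)))
  bi <- bi[keep]; fi <- fi[keep]
  if (length(bi) == 0L) {
    attr(out, "n_filtered") <- n_filtered
    return(out)
  }
  # per-(fragment, feature) overlapped length, exact integers
  ov <- pmin(blocks$end[bi], feats$end[fi]) -
    pmax(blocks$start[bi], feats$start[fi])
  fragi <- blocks$frag[bi]
  key <- paste0(fragi, ":", fi)
  agg <- rowsum(ov, key)
  ukey <- rownames(agg)
  parts <- strsplit(ukey, ":", fixed = TRUE)
  cand <- data.frame(
    frag = as.integer(vapply(parts, `[`, character(1), 1L)),
    feat = as.integer(vapply(parts, `[`, character(1), 2L)),
    L_o = as.numeric(agg[, 1]))
  cand$L_read <- frag$L_read[cand$frag]
  cand$num <- 2 * cand$L_o - cand$L_read        # L_o - L_no
  cand$L_a <- feats$end[cand$feat] - feats$start[cand$feat]

  by_frag <- split(seq_len(nrow(cand)), cand$frag)
  for (fr_chr in names(by_frag)) {
    rows <- by_frag[[fr_chr]]
    fr <- cand$frag[rows[1L]]
    num <- cand$num[rows]; den <- cand$L_a[rows]
    # exact maximum by cross-multiplication
    best <- 1L
    for (j in seq_along(rows)[-1L]) {
      if (num[j] * den[best] > num[best] * den[j]) best <- j
    }
    if (num[best] <= 0) next
    tied <- which(num * den[best] == num[best] * den)
    tf <- cand$feat[rows[tied]]
    nms <- sort(unique(feats$name[tf]))
    out$feature[fr] <- paste(nms, collapse = "+")
    out$layer[fr] <- if (any(feats$record_kind[tf] == "exon"))
      "exon" else "intron"
    out$score[fr] <- num[best] / den[best]
    out$status[fr] <- "assigned"
  }
  attr(out, "n_filtered") <- n_filtered
  out
}

#' Write / read an assignment table
#'
#' @param assignments data.frame from [assign_reads()].
#' @param path TSV output path.
#' @export
write_assignments <- function(assignments, path) {
  write.table(assignments, path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}

#' @rdname write_assignments
#' @export
read_assignments <- function(path) {
  read.table(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE,
             colClasses = c(read_id = "character", pixel = "character",
                            umi = "character", feature = "character",
                            layer = "character", score = "numeric",
                            status = "character"))
}
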