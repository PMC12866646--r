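#' Declare the structure of read 1
#'
#' Read 1 of a spatial library carries the pixel address and the UMI as a
#' fixed arrangement of segments: spatial barcodes, a UMI, literal linker
#' sequences between them, and optionally ignored filler.  A `read_layout`
#' records that arrangement so parsing is configuration, not code.
#'
#' Because archival (FFPE) libraries accumulate indels in read 1, each
#' barcode segment is extracted as an *expanded window*: the nominal span
#' widened by `flank` bases on both sides.  Downstream barcode calling is
#' indel-tolerant inside that window; the parser itself never edits the
#' read.
#'
#' @param segments list of segment descriptors, each a list with `kind`
#'   (`"barcode"`, `"umi"`, `"linker"` or `"ignore"`), `expected_length`
#'   (bases), `sequence` (literal bases, linkers only) and `slot_id`
#'   (barcode/umi only).
#' @param flank non-negative integer, expansion of each barcode window on
#'   both sides (default 2, covering +/-2 indels).
#' @param max_linker_mismatch maximum substitutions tolerated when locating
#'   a linker (default 1).  Linkers are located by substitution-only
#'   matching; indel recovery is delegated to the widened barcode windows.
#' @return an object of class `read_layout`.
#' @export
read_layout <- function(segments, flank = 2L, max_linker_mismatch = 1L) {
  stopifnot(is.list(segments), length(segments) >= 1)
  flank <- as.integer(flank)
  if (is.na(flank) || flank < 0) stop("flank must be a non-negative integer")
  kinds <- vapply(segments, function(s) s$kind %||% "", character(1))
  if (!all(kinds %in% c("barcode", "umi", "linker", "ignore")))
    stop("segment kind must be barcode, umi, linker or ignore")
  lens <- vapply(segments, function(s) as.integer(s$expected_length %||% NA),
                 integer(1))
  if (any(is.na(lens)) || any(lens < 1))
    stop("every segment needs expected_length >= 1")
  slot_ids <- vapply(segments, function(s) s$slot_id %||% NA_character_,
                     character(1))
  need_slot <- kinds %in% c("barcode", "umi")
  if (any(is.na(slot_ids[need_slot])))
    stop("barcode and umi segments need a slot_id")
  if (anyDuplicated(slot_ids[need_slot]))
    stop("slot_ids must be unique")
  if (sum(kinds == "umi") != 1L)
    stop("layout needs exactly one umi segment")
  if (sum(kinds == "barcode") < 1L)
    stop("layout needs at least one barcode segment")
  for (i in which(kinds == "linker")) {
    sq <- segments[[i]]$sequence %||% ""
    if (nchar(sq) != lens[i])
      stop("linker sequence length must equal its expected_length")
  }
  structure(list(segments = segments, flank = flank,
                 max_linker_mismatch = as.integer(max_linker_mismatch)),
            class = "read_layout")
}

#' @export
print.read_layout <- function(x, ...) {
  cat("read_layout:", length(x$segments), "segments, flank", x$flank, "\n")
  for (s in x$segments) {
    cat(sprintf("  [%s%s: %d nt%s]\n", s$kind,
                if (!is.null(s$slot_id)) paste0(" ", s$slot_id) else "",
                s$expected_length,
                if (!is.null(s$sequence)) paste0(" '", s$sequence, "'") else ""))
  }
  invisible(x)
}

## substitution count between two equal-length strings
n_mismatch <- function(a, b) {
  av <- utf8ToInt(a); bv <- utf8ToInt(b)
  sum(av != bv)
}

#' Parse read 1 into UMI and expanded barcode windows
#'
#' Segments are walked in layout order.  Linkers are re-located by best
#' approximate occurrence (substitutions only, at most
#' `layout$max_linker_mismatch`) within `flank + 2` bases of their expected
#' offset, nearest-to-expected wins ties; every later segment shifts with
#' the located linker.  Barcode windows are the (possibly shifted) nominal
#' span widened by `flank` on both sides and clipped to the read.
#'
#' @param seq read-1 sequence (character scalar).
#' @param layout a [read_layout()].
#' @param read_id optional identifier carried through.
#' @return a list of class `parsed_read`: `read_id`, `umi`,
#'   `barcode_windows` (named by slot), `status` (`"ok"` or
#'   `"structure_fail"`) and `fail_reason`.
#' @examples
#' lay <- read_layout(list(
#'   list(kind = "barcode", expected_length = 8, slot_id = "A"),
#'   list(kind = "linker",  expected_length = 4, sequence = "ACGT"),
#'   list(kind = "barcode", expected_length = 8, slot_id = "B"),
#'   list(kind = "umi",     expected_length = 6, slot_id = "U")))
#' parse_read1(paste0("AAAAAAAA", "ACGT", "CCCCCCCC", "TTTTTT"), lay)
#' @export
parse_read1 <- function(seq, layout, read_id = "") {
  stopifnot(is.character(seq), length(seq) == 1L, nzchar(seq))
  if (!inherits(layout, "read_layout")) stop("layout must be a read_layout")
  n <- nchar(seq)
  segs <- layout$segments
  lens <- vapply(segs, function(s) as.integer(s$expected_length), integer(1))
  kinds <- vapply(segs, function(s) s$kind, character(1))

  fail <- function(reason) {
    structure(list(read_id = read_id, umi = NULL,
                   barcode_windows = list(), status = "structure_fail",
                   fail_reason = reason), class = "parsed_read")
  }

  # the read must be able to reach the end of the UMI even if every
  # linker shifts maximally left; a later check catches shifted overruns
  radius <- layout$flank + 2L
  umi_seg <- which(kinds == "umi")
  nominal_umi_end <- sum(lens[seq_len(umi_seg)])
  if (n < nominal_umi_end - radius) return(fail("read_too_short"))
  pos <- 0L  # 0-based offset of the next segment
  windows <- list()
  umi <- NULL
  for (i in seq_along(segs)) {
    s <- segs[[i]]
    if (kinds[i] == "linker") {
      loc <- locate_linker(seq, s$sequence, expected = pos,
                           radius = radius,
                           max_mismatch = layout$max_linker_mismatch)
      if (is.na(loc)) return(fail("linker_not_found"))
      pos <- loc + lens[i]
    } else if (kinds[i] == "umi") {
      if (pos + lens[i] > n) return(fail("read_too_short"))
      umi <- substr(seq, pos + 1L, pos + lens[i])
      pos <- pos + lens[i]
    } else if (kinds[i] == "barcode") {
      w_start <- max(0L, pos - layout$flank)
      w_end <- min(n, pos + lens[i] + layout$flank)
      windows[[s$slot_id]] <- substr(seq, w_start + 1L, w_end)
      pos <- pos + lens[i]
    } else { # ignore
      pos <- pos + lens[i]
    }
  }
  structure(list(read_id = read_id, umi = umi, barcode_windows = windows,
                 status = "ok", fail_reason = ""), class = "parsed_read")
}

## best approximate occurrence of a linker near its expected 0-based offset;
## substitutions only.  Candidates ranked by (mismatches, |shift|, shift) so
## the result is deterministic.  Returns the located 0-based start, or NA.
locate_linker <- function(seq, linker, expected, radius, max_mismatch) {
  n <- nchar(seq); m <- nchar(linker)
  starts <- (expected - radius):(expected + radius)
  starts <- starts[starts >= 0 & starts + m <= n]
  if (length(starts) == 0L) return(NA_integer_)
  mm <- vapply(starts, function(st)
    n_mismatch(substr(seq, st + 1L, st + m), linker), numeric(1))
  ok <- mm <= max_mismatch
  if (!any(ok)) return(NA_integer_)
  starts <- starts[ok]; mm <- mm[ok]
  shift <- abs(starts - expected)
  o <- order(mm, shift, starts)
  starts[o[1L]]
}

#' Parse a batch of read-1 sequences
#'
#' Applies [parse_read1()] to each read and tabulates failure reasons.
#'
#' @param seqs character vector of read-1 sequences, optionally named by
#'   read id.
#' @param layout a [read_layout()].
#' @return list with `parsed` (list of `parsed_read`) and `discards`
#'   (named integer vector of per-reason counts).
#' @export
parse_reads <- function(seqs, layout) {
  ids <- names(seqs) %||% as.character(seq_along(seqs))
  parsed <- lapply(seq_along(seqs), function(i)
    parse_read1(seqs[[i]], layout, read_id = ids[i]))
  reasons <- vapply(parsed, function(p) p$fail_reason, character(1))
  discards <- table(factor(reasons[nzchar(reasons)]))
  list(parsed = parsed,
       discards = setNames(as.integer(discards), names(discards)))
}

#' Read a FASTQ file as a named vector of sequences
#'
#' Plain or gzip FASTQ; quality strings are not used anywhere in parsing.
#'
#' @param path FASTQ file.
#' @return character vector of sequences named by the first token of each
#'   record id.
#' @export
read_fastq <- function(path) {
  x <- Biostrings::readDNAStringSet(path, format = "fastq")
  seqs <- as.character(x)
  names(seqs) <- vapply(strsplit(names(x), "[ \t]"), `[`, character(1), 1L)
  seqs
}
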