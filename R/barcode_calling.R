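#' Load a spatial-barcode whitelist
#'
#' Plain text, one barcode per line; the line number is the spatial index
#' along that axis of the pixel grid (DBiT-style designs pre-define every
#' barcode, so the whitelist is authoritative).
#'
#' @param path text file, one barcode per line.
#' @param slot_id the barcode slot this whitelist serves.
#' @return object of class `barcode_whitelist` with fields `slot_id`,
#'   `sequences` (character), `indices` (1-based integer).
#' @export
read_whitelist <- function(path, slot_id = "A") {
  seqs <- toupper(trimws(readLines(path)))
  seqs <- seqs[nzchar(seqs)]
  barcode_whitelist(seqs, slot_id)
}

#' @rdname read_whitelist
#' @param sequences character vector of barcode sequences (uniform length,
#'   unique).
#' @export
barcode_whitelist <- function(sequences, slot_id = "A") {
  if (length(sequences) == 0L) stop("whitelist is empty")
  if (length(unique(nchar(sequences))) != 1L)
    stop("whitelist barcodes must have uniform length")
  if (anyDuplicated(sequences))
    stop("whitelist barcodes must be unique")
  structure(list(slot_id = slot_id, sequences = sequences,
                 indices = seq_along(sequences)),
            class = "barcode_whitelist")
}

#' Call one barcode window against a whitelist
#'
#' The window is the expanded span extracted by [parse_read1()]; the true
#' barcode may sit anywhere inside it and may carry substitutions or
#' indels.  Each whitelist entry is scored by semi-global Levenshtein
#' distance (the barcode fully consumed, the window flanks free).  Only the
#' best match is retained; a window whose minimal distance is attained by
#' two or more entries is ambiguous and the read is discarded downstream —
#' there is no tie-breaking.
#'
#' @param window base string (expanded barcode window).
#' @param whitelist a [barcode_whitelist()].
#' @param max_edit maximum edit distance for an assignment (default 2 for
#'   8-mer barcodes).
#' @return list of class `barcode_call`: `slot_id`, `status`
#'   (`"assigned"`, `"ambiguous"` or `"unmatched"`), `barcode_index`,
#'   `edit_distance`.
#' @export
call_barcode <- function(window, whitelist, max_edit = 2L) {
  res <- call_barcodes(window, whitelist, max_edit)
  structure(list(slot_id = whitelist$slot_id, status = res$status[1L],
                 barcode_index = res$index[1L],
                 edit_distance = res$distance[1L]),
            class = "barcode_call")
}

#' Call many barcode windows at once
#'
#' Vectorized form of [call_barcode()]; one row per window.
#'
#' @inheritParams call_barcode
#' @param windows character vector of windows.
#' @return data.frame with columns `status`, `index` (NA unless assigned),
#'   `distance`.
#' @export
call_barcodes <- function(windows, whitelist, max_edit = 2L) {
  stopifnot(max_edit >= 0)
  n <- length(windows)
  status <- rep("unmatched", n)
  index <- rep(NA_integer_, n)
  distance <- rep(NA_integer_, n)
  nz <- nzchar(windows)
  if (any(!nz)) stop("empty barcode window")
  best <- semiglobal_best_call(windows, whitelist$sequences)
  within <- best$distance <= max_edit
  amb <- within & best$n_min >= 2L
  asn <- within & best$n_min == 1L
  status[amb] <- "ambiguous"
  status[asn] <- "assigned"
  index[asn] <- best$index[asn]
  distance[within] <- best$distance[within]
  data.frame(status = status, index = index, distance = distance,
             stringsAsFactors = FALSE)
}

#' Resolve per-slot barcode calls into a pixel coordinate
#'
#' A pixel is addressed by (barcode-A index, barcode-B index).  The read
#' survives only if every slot call is assigned; otherwise it is discarded
#' with a reason naming the first failing slot.
#'
#' @param calls named list of `barcode_call` objects (names are slot ids;
#'   slot "A" gives x, slot "B" gives y).
#' @return list with `pixel` (list(x, y)) and `discard_reason` (empty
#'   string when the pixel resolves).
#' @export
resolve_pixel <- function(calls) {
  for (slot in names(calls)) {
    st <- calls[[slot]]$status
    if (st != "assigned")
      return(list(pixel = NULL,
                  discard_reason = sprintf("barcode_%s_%s", slot, st)))
  }
  list(pixel = list(x = calls[["A"]]$barcode_index,
                    y = calls[["B"]]$barcode_index),
       discard_reason = "")
}

#' Format a pixel key
#'
#' Pixels are keyed `"<x>x<y>"` everywhere (matrix columns, read-name
#' metadata, sidecar files).
#'
#' @param x,y integer barcode indices.
#' @return character key.
#' @export
pixel_key <- function(x, y) paste0(x, "x", y)
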