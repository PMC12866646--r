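## small shared helpers

DNA_BASES <- c("A", "C", "G", "T")

revcomp <- function(x) {
  chartr("ACGTacgt", "TGCAtgca", vapply(strsplit(x, "", fixed = TRUE),
    function(s) paste(rev(s), collapse = ""), character(1)))
}

random_dna <- function(n, len) {
  vapply(seq_len(n), function(i)
    paste(sample(DNA_BASES, len, replace = TRUE), collapse = ""),
    character(1))
}

#' Derive a per-stream seed from a master seed
#'
#' One master seed drives every random stream in the package; each named
#' stream gets its own deterministic 32-bit sub-seed so adding a stream
#' never perturbs the others.
#'
#' @param master integer master seed.
#' @param stream character stream label.
#' @return an integer seed below 2^31.
#' @keywords internal
derive_seed <- function(master, stream) {
  h <- sum(utf8ToInt(stream) * seq_along(utf8ToInt(stream)))
  as.integer((as.numeric(master) * 48271 + h * 9973) %% 2147483629L)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

log_msg <- function(..., file = NULL) {
  line <- paste0(format(Sys.time(), "%H:%M:%S"), " ", paste0(...))
  if (!is.null(file)) cat(line, "\n", file = file, append = TRUE, sep = "")
  invisible(line)
}
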