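# Independent reference implementations used to cross-check the package:
# a pure-R semi-global edit-distance DP, a brute-force overlap-score
# assigner, and a hand-rolled Benjamini-Hochberg step-up.  These never
# call the code paths they validate.

# semi-global distance of one barcode against many windows, row-by-row DP
# vectorized across windows of equal length
oracle_semiglobal_one_length <- function(windows, barcode) {
  L <- nchar(windows[1]); m <- nchar(barcode)
  n <- length(windows)
  wm <- matrix(unlist(strsplit(windows, "")), nrow = n, byrow = TRUE)
  bc <- strsplit(barcode, "")[[1]]
  prev <- matrix(0L, n, L + 1L)
  for (i in seq_len(m)) {
    cur <- matrix(0L, n, L + 1L)
    cur[, 1] <- i
    for (j in seq_len(L) + 1L) {
      sub <- prev[, j - 1L] + (wm[, j - 1L] != bc[i])
      cur[, j] <- pmin(sub, prev[, j] + 1L, cur[, j - 1L] + 1L)
    }
    prev <- cur
  }
  apply(prev, 1, min)
}

# distance matrix (windows x whitelist), any window lengths
oracle_semiglobal <- function(windows, barcodes) {
  out <- matrix(NA_integer_, length(windows), length(barcodes))
  for (len in unique(nchar(windows))) {
    rows <- which(nchar(windows) == len)
    for (b in seq_along(barcodes))
      out[rows, b] <- oracle_semiglobal_one_length(windows[rows],
                                                   barcodes[b])
  }
  out
}

# full exhaustive barcode call from the oracle distances
oracle_call <- function(windows, barcodes, max_edit) {
  d <- oracle_semiglobal(windows, barcodes)
  res <- data.frame(status = character(length(windows)),
                    index = NA_integer_, distance = NA_integer_)
  for (i in seq_along(windows)) {
    mn <- min(d[i, ])
    if (mn > max_edit) {
      res$status[i] <- "unmatched"
    } else if (sum(d[i, ] == mn) > 1L) {
      res$status[i] <- "ambiguous"
      res$distance[i] <- mn
    } else {
      res$status[i] <- "assigned"
      res$index[i] <- which.min(d[i, ])
      res$distance[i] <- mn
    }
  }
  res
}

# brute-force read assignment: linear scan over every feature, per-block
# intersection loops, exact rational score comparison by cross products
oracle_assign <- function(blocks, chrom, strand, features,
                          strand_policy = "same") {
  L_read <- sum(blocks[, 2] - blocks[, 1])
  best <- NULL
  for (k in seq_len(nrow(features))) {
    f <- features[k, ]
    if (!f$record_kind %in% c("exon", "intron")) next
    if (f$chrom != chrom) next
    if (strand_policy == "same" && f$strand != strand) next
    if (strand_policy == "opposite" && f$strand == strand) next
    L_o <- 0L
    for (b in seq_len(nrow(blocks)))
      L_o <- L_o + max(0L, min(blocks[b, 2], f$end) -
                         max(blocks[b, 1], f$start))
    if (L_o == 0L) next
    cand <- list(num = 2 * L_o - L_read, den = f$end - f$start,
                 name = f$name, kind = f$record_kind)
    if (is.null(best)) {
      best <- list(cand)
    } else {
      cmp <- cand$num * best[[1]]$den - best[[1]]$num * cand$den
      if (cmp > 0) best <- list(cand)
      else if (cmp == 0) best <- c(best, list(cand))
    }
  }
  if (is.null(best) || best[[1]]$num <= 0)
    return(list(status = "unassigned", feature = NA_character_,
                layer = NA_character_))
  nms <- sort(unique(vapply(best, `[[`, character(1), "name")))
  list(status = "assigned", feature = paste(nms, collapse = "+"),
       layer = if (any(vapply(best, `[[`, character(1), "kind") == "exon"))
         "exon" else "intron")
}

# Benjamini-Hochberg step-up, written from the definition
oracle_bh <- function(p) {
  n <- length(p)
  o <- order(p)
  q <- numeric(n)
  prev <- 1
  for (i in n:1) {
    prev <- min(prev, p[o[i]] * n / i)
    q[o[i]] <- prev
  }
  q
}

# random feature table on one chromosome for oracle comparisons
random_feature_table <- function(n, chrom_len = 2000L, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  start <- sample.int(chrom_len - 200L, n, replace = TRUE)
  len <- sample(20:200, n, replace = TRUE)
  data.frame(
    feat_id = paste0("f", seq_len(n)),
    name = paste0("F", sample(ceiling(n / 2), n, replace = TRUE)),
    rna_class = sample(c("mRNA", "miRNA", "snoRNA"), n, replace = TRUE),
    chrom = "chr1", start = start,
    end = pmin(start + len, chrom_len),
    strand = sample(c("+", "-"), n, replace = TRUE),
    record_kind = sample(c("exon", "intron"), n, replace = TRUE),
    parent = "tx", source_rank = 1L, stringsAsFactors = FALSE)
}
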