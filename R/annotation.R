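## Whole-RNA annotation: multiple GTF/BED sources merged into one feature
## set with derived introns, indexed for strand-aware interval queries.
## Internal representation is a plain data.frame ("feature frame") with
## 0-based half-open coordinates; GRanges is used for all interval work.

RNA_CLASSES <- c("mRNA", "lncRNA", "miRNA", "tRNA", "rRNA", "snoRNA",
                 "snRNA", "scaRNA", "piRNA", "Y_RNA", "miscRNA", "other")

## GENCODE gene_type / gene_biotype vocabulary -> internal class
GENCODE_CLASS_MAP <- c(
  protein_coding = "mRNA", lncRNA = "lncRNA", lincRNA = "lncRNA",
  miRNA = "miRNA", tRNA = "tRNA", Mt_tRNA = "tRNA", rRNA = "rRNA",
  Mt_rRNA = "rRNA", snoRNA = "snoRNA", snRNA = "snRNA", scaRNA = "scaRNA",
  piRNA = "piRNA", Y_RNA = "Y_RNA", misc_RNA = "miscRNA")

normalize_rna_class <- function(x) {
  out <- ifelse(x %in% RNA_CLASSES, x,
                unname(GENCODE_CLASS_MAP[x]))
  out[is.na(out)] <- "other"
  out
}

feature_frame <- function(feat_id, name, rna_class, chrom, start, end,
                          strand, record_kind, parent,
                          source_rank = 1L) {
  df <- data.frame(feat_id = as.character(feat_id),
                   name = as.character(name),
                   rna_class = as.character(rna_class),
                   chrom = as.character(chrom),
                   start = as.integer(start), end = as.integer(end),
                   strand = as.character(strand),
                   record_kind = as.character(record_kind),
                   parent = as.character(parent),
                   source_rank = rep(as.integer(source_rank),
                                     length.out = length(feat_id)),
                   stringsAsFactors = FALSE)
  check_feature_frame(df)
  df
}

check_feature_frame <- function(df) {
  stopifnot(all(df$start < df$end),
            all(df$strand %in% c("+", "-")),
            all(df$record_kind %in% c("exon", "transcript", "intron")))
  if (anyDuplicated(df$feat_id)) stop("feat_id values must be unique")
  child <- df$record_kind %in% c("exon", "intron")
  if (any(child & !nzchar(df$parent)))
    stop("every exon/intron needs a parent transcript")
  invisible(df)
}

features_to_granges <- function(df) {
  gr <- GenomicRanges::GRanges(
    seqnames = df$chrom,
    ranges = IRanges::IRanges(start = df$start + 1L, end = df$end),
    strand = df$strand)
  S4Vectors::mcols(gr) <- df[, c("feat_id", "name", "rna_class",
                                 "record_kind", "parent")]
  gr
}

#' Load annotation sources into a normalized feature table
#'
#' Ingests one or more annotation files and normalizes every record to a
#' common feature table: 0-based half-open coordinates, an RNA class from a
#' controlled vocabulary, a record kind (`transcript` or `exon`; introns
#' are derived later), and parent links from exons to their transcript.
#' Mature miRNA arms stay distinct features (`...-5p` / `...-3p`) with the
#' hairpin as their parent transcript, so arm-level expression is
#' quantified separately.  tRNA features are expected to be keyed by
#' isotype-codon name in their source.
#'
#' Supported dialects:
#' \describe{
#'   \item{`gencode`}{GENCODE-style GTF; `transcript`/`exon` rows, class
#'     from `gene_type`/`gene_biotype`, name from `gene_name` (falling
#'     back to `gene_id`).}
#'   \item{`gtf`}{generic GTF as written by [write_merged_gtf()]:
#'     `feature_name`, `rna_class`, `feat_id`, `parent` attributes; also
#'     accepts miRBase-style `miRNA_primary_transcript`/`miRNA` types with
#'     `Name` and `Derives_from`.}
#'   \item{`bed6`}{BED6 plus a 7th RNA-class column; each row becomes an
#'     exon with an implicit same-span transcript.}
#' }
#'
#' @param sources list of `list(path =, dialect =)` entries; list order is
#'   the source priority used later by [merge_similar()].
#' @return feature table (data.frame) with columns `feat_id`, `name`,
#'   `rna_class`, `chrom`, `start`, `end`, `strand`, `record_kind`,
#'   `parent`, `source_rank`.
#' @export
load_annotation_sources <- function(sources) {
  out <- list()
  for (i in seq_along(sources)) {
    src <- sources[[i]]
    dialect <- src$dialect %||% "gtf"
    df <- switch(dialect,
      gencode = load_gencode_gtf(src$path),
      gtf     = load_generic_gtf(src$path),
      bed6    = load_bed6(src$path),
      stop("unknown annotation dialect: ", dialect))
    if (nrow(df) == 0L) {
      warning("annotation source is empty: ", src$path)
      next
    }
    df$source_rank <- i
    # keep feat_ids unique across sources
    df$feat_id <- paste0("s", i, ":", df$feat_id)
    df$parent <- ifelse(nzchar(df$parent), paste0("s", i, ":", df$parent), "")
    out[[length(out) + 1L]] <- df
  }
  if (length(out) == 0L)
    return(feature_frame(character(0), character(0), character(0),
                         character(0), integer(0), integer(0),
                         character(0), character(0), character(0)))
  df <- do.call(rbind, out)
  rownames(df) <- NULL
  check_feature_frame(df)
  df
}

import_gtf_granges <- function(path) {
  has_data <- any(!grepl("^(#|$)", readLines(path, warn = FALSE)))
  if (!has_data) return(GenomicRanges::GRanges())
  tryCatch(rtracklayer::import(path, format = "gtf"),
           error = function(e) stop("failed to parse GTF ", path,
                                    ": ", conditionMessage(e)))
}

mcol_or <- function(gr, nm, default = NA_character_) {
  m <- S4Vectors::mcols(gr)
  if (nm %in% colnames(m)) as.character(m[[nm]]) else
    rep(default, length(gr))
}

first_non_na <- function(...) {
  args <- list(...)
  out <- args[[1L]]
  for (a in args[-1L]) out <- ifelse(is.na(out) | !nzchar(out), a, out)
  out
}

load_gencode_gtf <- function(path) {
  gr <- import_gtf_granges(path)
  type <- as.character(gr$type)
  keep <- type %in% c("transcript", "exon")
  gr <- gr[keep]; type <- type[keep]
  if (length(gr) == 0L) return(empty_feature_frame())
  gene_name <- first_non_na(mcol_or(gr, "gene_name"), mcol_or(gr, "gene_id"))
  tx_id <- mcol_or(gr, "transcript_id")
  cls <- normalize_rna_class(first_non_na(mcol_or(gr, "gene_type"),
                                          mcol_or(gr, "gene_biotype")))
  feat_id <- ifelse(type == "transcript", tx_id,
                    paste0(tx_id, ":exon", seq_along(gr)))
  parent <- ifelse(type == "transcript", "", tx_id)
  feature_frame(feat_id, gene_name, cls,
                as.character(GenomicRanges::seqnames(gr)),
                GenomicRanges::start(gr) - 1L, GenomicRanges::end(gr),
                as.character(GenomicRanges::strand(gr)), type, parent)
}

load_generic_gtf <- function(path) {
  gr <- import_gtf_granges(path)
  type <- as.character(gr$type)
  kind <- ifelse(type %in% c("transcript", "miRNA_primary_transcript"),
                 "transcript",
          ifelse(type %in% c("exon", "miRNA"), "exon",
          ifelse(type == "intron", "intron", NA_character_)))
  keep <- !is.na(kind)
  gr <- gr[keep]; kind <- kind[keep]
  if (length(gr) == 0L) return(empty_feature_frame())
  nm <- first_non_na(mcol_or(gr, "feature_name"), mcol_or(gr, "Name"),
                     mcol_or(gr, "gene_name"), mcol_or(gr, "gene_id"),
                     mcol_or(gr, "ID"))
  cls <- normalize_rna_class(first_non_na(mcol_or(gr, "rna_class"),
                                          mcol_or(gr, "gene_type"),
                                          mcol_or(gr, "gene_biotype")))
  id <- first_non_na(mcol_or(gr, "feat_id"), mcol_or(gr, "ID"),
                     paste0(nm, ":", seq_along(gr)))
  parent <- first_non_na(mcol_or(gr, "parent"),
                         mcol_or(gr, "Derives_from"),
                         mcol_or(gr, "transcript_id"))
  parent[is.na(parent)] <- ""
  parent[kind == "transcript"] <- ""
  feature_frame(id, nm, cls,
                as.character(GenomicRanges::seqnames(gr)),
                GenomicRanges::start(gr) - 1L, GenomicRanges::end(gr),
                as.character(GenomicRanges::strand(gr)), kind, parent)
}

load_bed6 <- function(path) {
  df <- tryCatch(
    read.table(path, sep = "\t", header = FALSE, comment.char = "#",
               stringsAsFactors = FALSE),
    error = function(e) {
      if (grepl("no lines available", conditionMessage(e)))
        return(data.frame())
      stop("failed to parse BED ", path, ": ", conditionMessage(e))
    })
  if (nrow(df) == 0L) return(empty_feature_frame())
  if (ncol(df) < 7L)
    stop("BED6+class needs 7 columns in ", path)
  # BED is already 0-based half-open; each row gets an implicit transcript
  tx_id <- paste0(df[[4L]], ":tx")
  tx <- feature_frame(tx_id, df[[4L]], normalize_rna_class(df[[7L]]),
                      df[[1L]], df[[2L]], df[[3L]], df[[6L]],
                      "transcript", "")
  ex <- feature_frame(paste0(df[[4L]], ":ex"), df[[4L]],
                      normalize_rna_class(df[[7L]]),
                      df[[1L]], df[[2L]], df[[3L]], df[[6L]],
                      "exon", tx_id)
  rbind(tx, ex)
}

empty_feature_frame <- function() {
  feature_frame(character(0), character(0), character(0), character(0),
                integer(0), integer(0), character(0), character(0),
                character(0))
}

#' Merge similar annotation records into single entries
#'
#' Two records are similar iff they share RNA class, strand and record
#' kind and overlap reciprocally by at least `min_reciprocal_overlap`
#' (intersection length over each record's own length).  Similar sets are
#' closed transitively and collapse to one record spanning the union
#' interval; the retained name and id come from the highest-priority
#' source (lowest `source_rank`, input order breaking ties).  Parent links
#' of surviving children are remapped onto merged transcripts.
#'
#' @param features feature table from [load_annotation_sources()].
#' @param min_reciprocal_overlap similarity threshold in (0, 1], default
#'   0.9.
#' @return merged feature table; the number of collapsed records per RNA
#'   class is attached as attribute `merge_log`.
#' @export
merge_similar <- function(features, min_reciprocal_overlap = 0.9) {
  stopifnot(min_reciprocal_overlap > 0, min_reciprocal_overlap <= 1)
  if (nrow(features) <= 1L) return(features)
  gr <- features_to_granges(features)
  hits <- GenomicRanges::findOverlaps(gr, drop.self = TRUE,
                                      drop.redundant = TRUE)
  q <- S4Vectors::queryHits(hits); s <- S4Vectors::subjectHits(hits)
  same <- features$rna_class[q] == features$rna_class[s] &
    features$strand[q] == features$strand[s] &
    features$record_kind[q] == features$record_kind[s]
  q <- q[same]; s <- s[same]
  if (length(q)) {
    ov <- pmin(features$end[q], features$end[s]) -
      pmax(features$start[q], features$start[s])
    len_q <- features$end[q] - features$start[q]
    len_s <- features$end[s] - features$start[s]
    recip <- ov / len_q >= min_reciprocal_overlap &
      ov / len_s >= min_reciprocal_overlap
    q <- q[recip]; s <- s[recip]
  }
  # transitive closure by union-find
  comp <- seq_len(nrow(features))
  find <- function(i) { while (comp[i] != i) { comp[i] <<- comp[comp[i]]; i <- comp[i] }; i }
  for (k in seq_along(q)) {
    a <- find(q[k]); b <- find(s[k])
    if (a != b) comp[max(a, b)] <- min(a, b)
  }
  root <- vapply(seq_len(nrow(features)), find, integer(1))
  keep <- !duplicated(root)
  merged <- features[keep, , drop = FALSE]
  id_map <- character(0)
  n_merged_by_class <- integer(0)
  for (r in unique(root[duplicated(root) | !keep])) {
    members <- which(root == r)
    if (length(members) == 1L) next
    winner <- members[order(features$source_rank[members], members)][1L]
    out_row <- match(r, root[keep])
    merged$start[out_row] <- min(features$start[members])
    merged$end[out_row] <- max(features$end[members])
    merged[out_row, c("feat_id", "name", "parent", "source_rank")] <-
      features[winner, c("feat_id", "name", "parent", "source_rank")]
    losers <- setdiff(members, winner)
    id_map[features$feat_id[losers]] <- features$feat_id[winner]
    cls <- features$rna_class[winner]
    prev <- n_merged_by_class[cls]
    if (length(prev) == 0L || is.na(prev)) prev <- 0L
    n_merged_by_class[cls] <- prev + length(losers)
  }
  # remap orphaned parent links onto merge winners
  hit <- merged$parent %in% names(id_map)
  merged$parent[hit] <- unname(id_map[merged$parent[hit]])
  rownames(merged) <- NULL
  attr(merged, "merge_log") <- n_merged_by_class
  merged
}

#' Derive intron features from transcripts and their exons
#'
#' Per transcript, introns are the transcript interval minus the union of
#' its exons, one feature per gap.  Intron features are named after the
#' parent gene (the transcript's feature name), so intron evidence is
#' aggregated per gene in the count matrix's intron layer.
#'
#' @param features feature table containing transcripts and exons.
#' @return the input table with intron rows appended.
#' @export
derive_introns <- function(features) {
  tx <- features[features$record_kind == "transcript", , drop = FALSE]
  ex <- features[features$record_kind == "exon", , drop = FALSE]
  introns <- list()
  for (i in seq_len(nrow(tx))) {
    kids <- ex[ex$parent == tx$feat_id[i], , drop = FALSE]
    if (nrow(kids) == 0L) next
    if (any(kids$start < tx$start[i] | kids$end > tx$end[i]))
      stop("exon outside its transcript span: ", tx$feat_id[i])
    tx_rng <- IRanges::IRanges(tx$start[i] + 1L, tx$end[i])
    ex_rng <- IRanges::reduce(IRanges::IRanges(kids$start + 1L, kids$end))
    gaps <- IRanges::setdiff(tx_rng, ex_rng)
    if (length(gaps) == 0L) next
    introns[[length(introns) + 1L]] <- feature_frame(
      paste0(tx$feat_id[i], ":intron", seq_along(gaps)),
      tx$name[i], tx$rna_class[i], tx$chrom[i],
      IRanges::start(gaps) - 1L, IRanges::end(gaps),
      tx$strand[i], "intron", tx$feat_id[i],
      tx$source_rank[i])
  }
  if (length(introns) == 0L) return(features)
  out <- rbind(features, do.call(rbind, introns))
  rownames(out) <- NULL
  out
}

#' Build a strand-aware interval index over features
#'
#' @param features feature table (typically merged, with introns derived).
#' @return object of class `annotation_index` wrapping the table and a
#'   GRanges used for overlap queries.
#' @export
annotation_index <- function(features) {
  check_feature_frame(features)
  structure(list(features = features, gr = features_to_granges(features)),
            class = "annotation_index")
}

#' @export
print.annotation_index <- function(x, ...) {
  cat("annotation_index:", nrow(x$features), "features (",
      sum(x$features$record_kind == "exon"), "exons,",
      sum(x$features$record_kind == "intron"), "introns,",
      sum(x$features$record_kind == "transcript"), "transcripts )\n")
  invisible(x)
}

#' Query features overlapping an interval
#'
#' @param index an [annotation_index()].
#' @param chrom chromosome name.
#' @param start,end 0-based half-open interval.
#' @param strand `"+"`, `"-"`, or NULL for both strands.
#' @param kinds record kinds to return (default exon and intron, the
#'   records that compete for reads).
#' @return integer row indices into `index$features` of every feature
#'   overlapping the interval by at least one base.
#' @export
query_features <- function(index, chrom, start, end, strand = NULL,
                           kinds = c("exon", "intron")) {
  qr <- GenomicRanges::GRanges(chrom,
                               IRanges::IRanges(start + 1L, end),
                               strand = strand %||% "*")
  hits <- GenomicRanges::findOverlaps(
    qr, index$gr, ignore.strand = is.null(strand))
  idx <- S4Vectors::subjectHits(hits)
  idx[index$features$record_kind[idx] %in% kinds]
}

#' Write the merged annotation as GTF plus a sidecar table
#'
#' The GTF is 1-based closed with the record kind in the feature column
#' and `feature_name`, `rna_class`, `feat_id`, `parent` attributes; the
#' sidecar TSV lists name, class, kind and parent per record.  Reading the
#' GTF back with dialect `"gtf"` reproduces the feature table.
#'
#' @param features feature table.
#' @param gtf_path,sidecar_path output paths.
#' @export
write_merged_gtf <- function(features, gtf_path,
                             sidecar_path = sub("\\.gtf$", ".tsv", gtf_path)) {
  attrs <- sprintf(
    'feature_name "%s"; rna_class "%s"; feat_id "%s"; parent "%s";',
    features$name, features$rna_class, features$feat_id, features$parent)
  lines <- paste(features$chrom, "spotrna", features$record_kind,
                 features$start + 1L, features$end, ".", features$strand,
                 ".", attrs, sep = "\t")
  writeLines(lines, gtf_path)
  write.table(features[, c("name", "rna_class", "record_kind", "parent")],
              sidecar_path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(gtf_path)
}

#' Build the whole-RNA reference in one call
#'
#' Convenience wrapper: load sources, merge similar records, derive
#' introns, and index.
#'
#' @inheritParams load_annotation_sources
#' @inheritParams merge_similar
#' @return an [annotation_index()].
#' @export
build_reference <- function(sources, min_reciprocal_overlap = 0.9) {
  feats <- load_annotation_sources(sources)
  feats <- merge_similar(feats, min_reciprocal_overlap)
  feats <- derive_introns(feats)
  annotation_index(feats)
}
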