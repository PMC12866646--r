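## Stage orchestration: build-ref -> demux -> assign -> count ->
## (optional) validate.  Each stage writes its artifact plus a JSON
## summary and is skipped on rerun when its outputs already exist.

#' Read a pipeline configuration
#'
#' @param path JSON config file (see [simulate_dataset()] for a generated
#'   example); relative paths are resolved against the config file's
#'   directory.
#' @return config list.
#' @export
read_config <- function(path) {
  cfg <- jsonlite::read_json(path, simplifyVector = FALSE)
  base <- dirname(normalizePath(path))
  fix <- function(p) {
    if (is.null(p)) return(NULL)
    if (!grepl("^/", p)) file.path(base, p) else p
  }
  for (k in c("outdir", "fastq_r1", "fastq_r2", "alignments",
              "whitelist_a", "whitelist_b"))
    cfg[[k]] <- fix(cfg[[k]])
  cfg$annotation_sources <- lapply(cfg$annotation_sources, function(s) {
    s$path <- fix(s$path); s
  })
  validate_config(cfg)
  cfg
}

validate_config <- function(cfg) {
  for (k in c("fastq_r1", "alignments", "whitelist_a", "whitelist_b")) {
    if (is.null(cfg[[k]])) stop("config is missing ", k)
    if (!file.exists(cfg[[k]])) stop("config path does not exist: ",
                                     cfg[[k]], " (", k, ")")
  }
  for (s in cfg$annotation_sources)
    if (!file.exists(s$path)) stop("annotation source missing: ", s$path)
  if (!is.null(cfg$strand_policy) &&
      !cfg$strand_policy %in% c("same", "opposite", "both"))
    stop("strand_policy must be same, opposite or both")
  if (!is.null(cfg$max_edit) && cfg$max_edit < 0)
    stop("max_edit must be >= 0")
  invisible(cfg)
}

config_layout <- function(cfg) {
  read_layout(cfg$layout$segments,
              flank = cfg$layout$flank %||% 2L,
              max_linker_mismatch = cfg$layout$max_linker_mismatch %||% 1L)
}

stage_done <- function(outdir, stage) {
  file.exists(file.path(outdir, paste0(stage, ".summary.json")))
}

write_summary <- function(outdir, stage, summary) {
  jsonlite::write_json(summary,
                       file.path(outdir, paste0(stage, ".summary.json")),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(summary)
}

#' Demultiplex read 1 into a pixel/UMI table
#'
#' Parses every read-1 record against the layout, calls both barcode
#' slots against their whitelists, and writes `demux.tsv`
#' (`read_id`, `x`, `y`, `umi`) for the surviving reads plus per-reason
#' discard counts.  Work is partitioned into read chunks across
#' `threads` workers; chunk boundaries and result order are fixed, so
#' the output is identical for any worker count.
#'
#' @param cfg config list.
#' @param force rerun even if the stage is complete.
#' @return (invisibly) the stage summary list.
#' @export
stage_demux <- function(cfg, force = FALSE) {
  outdir <- cfg$outdir
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  if (!force && stage_done(outdir, "demux")) return(invisible(NULL))
  layout <- config_layout(cfg)
  wla <- read_whitelist(cfg$whitelist_a, "A")
  wlb <- read_whitelist(cfg$whitelist_b, "B")
  seqs <- read_fastq(cfg$fastq_r1)
  threads <- cfg$threads %||% 1L
  chunk_size <- 20000L   # fixed so partitioning never depends on threads
  idx <- split(seq_along(seqs),
               (seq_along(seqs) - 1L) %/% chunk_size)
  worker <- function(ii) {
    pr <- parse_reads(seqs[ii], layout)
    ok <- vapply(pr$parsed, function(p) p$status == "ok", logical(1))
    res <- data.frame(read_id = names(seqs)[ii], x = NA_integer_,
                      y = NA_integer_, umi = NA_character_,
                      reason = "", stringsAsFactors = FALSE)
    res$reason[!ok] <- vapply(pr$parsed[!ok], `[[`, character(1),
                              "fail_reason")
    if (any(ok)) {
      win_a <- vapply(pr$parsed[ok], function(p)
        p$barcode_windows[["A"]], character(1))
      win_b <- vapply(pr$parsed[ok], function(p)
        p$barcode_windows[["B"]], character(1))
      ca <- call_barcodes(win_a, wla, cfg$max_edit %||% 2L)
      cb <- call_barcodes(win_b, wlb, cfg$max_edit %||% 2L)
      good <- ca$status == "assigned" & cb$status == "assigned"
      okidx <- which(ok)
      res$x[okidx[good]] <- ca$index[good]
      res$y[okidx[good]] <- cb$index[good]
      res$umi[okidx[good]] <- vapply(pr$parsed[ok][good], `[[`,
                                     character(1), "umi")
      bad_a <- ca$status != "assigned"
      res$reason[okidx[bad_a]] <- paste0("barcode_A_", ca$status[bad_a])
      bad_b <- !bad_a & cb$status != "assigned"
      res$reason[okidx[bad_b]] <- paste0("barcode_B_", cb$status[bad_b])
    }
    res
  }
  parts <- if (threads > 1L)
    parallel::mclapply(idx, worker, mc.cores = threads)
  else lapply(idx, worker)
  res <- do.call(rbind, parts)
  rownames(res) <- NULL
  keep <- res[!is.na(res$x), c("read_id", "x", "y", "umi")]
  write.table(keep, file.path(outdir, "demux.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  reasons <- table(res$reason[nzchar(res$reason)])
  write_summary(outdir, "demux", list(
    reads_in = length(seqs), reads_barcoded = nrow(keep),
    discarded = as.list(setNames(as.integer(reasons), names(reasons)))))
}

#' Build the merged whole-RNA reference
#'
#' Loads every annotation source, merges similar records, derives
#' introns, and writes `reference.gtf` + `reference.tsv`.
#'
#' @inheritParams stage_demux
#' @export
stage_build_ref <- function(cfg, force = FALSE) {
  outdir <- cfg$outdir
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  if (!force && stage_done(outdir, "build_ref")) return(invisible(NULL))
  feats <- load_annotation_sources(cfg$annotation_sources)
  feats <- merge_similar(feats, cfg$min_reciprocal_overlap %||% 0.9)
  feats <- derive_introns(feats)
  write_merged_gtf(feats, file.path(outdir, "reference.gtf"),
                   file.path(outdir, "reference.tsv"))
  write_summary(outdir, "build_ref", list(
    n_features = nrow(feats),
    n_exon = sum(feats$record_kind == "exon"),
    n_intron = sum(feats$record_kind == "intron"),
    n_transcript = sum(feats$record_kind == "transcript"),
    n_merged = as.list(attr(feats, "merge_log") %||% list())))
}

load_reference <- function(outdir) {
  feats <- load_generic_gtf(file.path(outdir, "reference.gtf"))
  annotation_index(feats)
}

#' Assign aligned reads to features
#'
#' Reads the alignments, attaches pixel/UMI metadata from `demux.tsv`,
#' scores candidates, and writes `assignments.tsv`.
#'
#' @inheritParams stage_demux
#' @export
stage_assign <- function(cfg, force = FALSE) {
  outdir <- cfg$outdir
  if (!force && stage_done(outdir, "assign")) return(invisible(NULL))
  demux <- read.table(file.path(outdir, "demux.tsv"), sep = "\t",
                      header = TRUE, stringsAsFactors = FALSE,
                      colClasses = c(read_id = "character",
                                     x = "integer", y = "integer",
                                     umi = "character"))
  aln <- read_alignments(cfg$alignments, demux = demux)
  index <- load_reference(outdir)
  asn <- assign_reads(aln, index,
                      strand_policy = cfg$strand_policy %||% "same",
                      min_align_len = cfg$min_align_len %||% 20L,
                      max_softclip_frac = cfg$max_softclip_frac %||% 0.5)
  write_assignments(asn, file.path(outdir, "assignments.tsv"))
  write_summary(outdir, "assign", list(
    reads_aligned = nrow(aln$fragments) + unname(aln$n_dropped[1]),
    reads_with_pixel = nrow(aln$fragments),
    reads_assigned = sum(asn$status == "assigned"),
    reads_unassigned = sum(asn$status == "unassigned"),
    filtered = as.list(attr(asn, "n_filtered"))))
}

#' Deduplicate UMIs and write the count matrices
#'
#' @inheritParams stage_demux
#' @export
stage_count <- function(cfg, force = FALSE) {
  outdir <- cfg$outdir
  if (!force && stage_done(outdir, "count")) return(invisible(NULL))
  asn <- read_assignments(file.path(outdir, "assignments.tsv"))
  wla <- read_whitelist(cfg$whitelist_a, "A")
  wlb <- read_whitelist(cfg$whitelist_b, "B")
  pixels <- as.character(outer(wla$indices, wlb$indices, pixel_key))
  index <- load_reference(outdir)
  meta <- unique(index$features[index$features$record_kind != "transcript",
                                c("name", "rna_class")])
  cm <- dedup_and_count(asn, pixels = sort(pixels), feature_meta = meta)
  write_count_matrix(cm, outdir)
  write_summary(outdir, "count", list(
    n_features = nrow(cm$features), n_pixels = length(cm$pixels),
    umis_exon = sum(cm$layers$exon), umis_intron = sum(cm$layers$intron)))
}

#' Validate features and write the curated matrices
#'
#' @inheritParams stage_demux
#' @export
stage_validate <- function(cfg, force = FALSE) {
  outdir <- cfg$outdir
  if (!force && stage_done(outdir, "validate")) return(invisible(NULL))
  index <- load_reference(outdir)
  demux <- read.table(file.path(outdir, "demux.tsv"), sep = "\t",
                      header = TRUE, stringsAsFactors = FALSE)
  aln <- read_alignments(cfg$alignments, demux = demux)
  v <- cfg$validation %||% list()
  res <- validate_features(index, aln,
                           alpha = v$alpha %||% 0.05,
                           min_fold = v$min_fold %||% 2,
                           min_reads = v$min_reads %||% 5,
                           flank_mult = v$flank_mult %||% 1)
  write.table(res, file.path(outdir, "validation.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  cm <- read_count_matrix(outdir)
  curated <- curate_matrix(cm, res)
  write_count_matrix(curated, outdir, prefix = "curated_")
  write_summary(outdir, "validate", list(
    n_tested = nrow(res),
    n_valid = sum(res$verdict == "valid"),
    n_invalid = sum(res$verdict == "invalid"),
    n_untestable = sum(res$verdict == "untestable")))
}

#' Run the full pipeline
#'
#' Executes build-ref, demux, assign, count and (optionally) validate in
#' order, each stage writing its artifacts and JSON summary into
#' `cfg$outdir`; completed stages are skipped unless `force`.  A final
#' `run.summary.json` collates the per-stage read conservation counters.
#'
#' @param cfg config list or path to a JSON config.
#' @param validate run the optional feature-validation stage (default
#'   TRUE).
#' @param force rerun all stages.
#' @return (invisibly) the collated run summary.
#' @export
run_pipeline <- function(cfg, validate = TRUE, force = FALSE) {
  if (is.character(cfg)) cfg <- read_config(cfg)
  validate_config(cfg)
  stage_build_ref(cfg, force)
  stage_demux(cfg, force)
  stage_assign(cfg, force)
  stage_count(cfg, force)
  if (validate) stage_validate(cfg, force)
  outdir <- cfg$outdir
  stages <- c("build_ref", "demux", "assign", "count",
              if (validate) "validate")
  summary <- lapply(setNames(stages, stages), function(s)
    jsonlite::read_json(file.path(outdir, paste0(s, ".summary.json"))))
  jsonlite::write_json(summary, file.path(outdir, "run.summary.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(summary)
}
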