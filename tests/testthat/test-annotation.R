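write_tmp <- function(lines, ext) {
  f <- tempfile(fileext = ext)
  writeLines(lines, f)
  f
}

test_that("GTF coordinates convert to 0-based half-open", {
  f <- write_tmp(paste0("chr1\tsrc\ttranscript\t101\t200\t.\t+\t.\t",
                        'gene_id "G1"; gene_name "G1"; ',
                        'gene_type "protein_coding"; transcript_id "T1";'),
                 ".gtf")
  feats <- load_annotation_sources(list(list(path = f,
                                             dialect = "gencode")))
  expect_equal(feats$start, 100L)
  expect_equal(feats$end, 200L)
  expect_equal(feats$rna_class, "mRNA")
})

test_that("miRNA hairpin with mature products yields arm features", {
  f <- write_tmp(c(
    paste0("chr1\tsrc\tmiRNA_primary_transcript\t1001\t1070\t.\t+\t.\t",
           'ID "mir-9"; Name "mir-9"; rna_class "miRNA";'),
    paste0("chr1\tsrc\tmiRNA\t1001\t1022\t.\t+\t.\t",
           'ID "miR-9-5p"; Name "miR-9-5p"; Derives_from "mir-9"; ',
           'rna_class "miRNA";'),
    paste0("chr1\tsrc\tmiRNA\t1049\t1070\t.\t+\t.\t",
           'ID "miR-9-3p"; Name "miR-9-3p"; Derives_from "mir-9"; ',
           'rna_class "miRNA";')), ".gtf")
  feats <- load_annotation_sources(list(list(path = f, dialect = "gtf")))
  expect_equal(nrow(feats), 3L)
  expect_setequal(feats$name, c("mir-9", "miR-9-5p", "miR-9-3p"))
  tx <- feats[feats$record_kind == "transcript", ]
  arms <- feats[feats$record_kind == "exon", ]
  expect_equal(nrow(arms), 2L)
  expect_true(all(arms$parent == tx$feat_id))
})

test_that("empty annotation source warns and contributes nothing", {
  f <- tempfile(fileext = ".gtf")
  file.create(f)
  expect_warning(feats <- load_annotation_sources(
    list(list(path = f, dialect = "gtf"))), "empty")
  expect_equal(nrow(feats), 0L)
})

test_that("BED6+class rows become exon features with implicit transcripts", {
  f <- write_tmp("chr2\t500\t600\ttRNA-Ala-AGC\t0\t-\ttRNA", ".bed")
  feats <- load_annotation_sources(list(list(path = f, dialect = "bed6")))
  expect_equal(nrow(feats), 2L)
  expect_equal(feats$start, c(500L, 500L))
  expect_setequal(feats$record_kind, c("transcript", "exon"))
  expect_true(all(feats$rna_class == "tRNA"))
  expect_error(load_annotation_sources(list(list(
    path = write_tmp("chr1\t1\t2\tx\t0\t+", ".bed"), dialect = "bed6"))),
    "7 columns")
})

mk_feats <- function(...) do.call(rbind, list(...))
row_f <- function(id, name, cls, start, end, strand = "+", kind = "exon",
                  parent = "tx", rank = 1L) {
  data.frame(feat_id = id, name = name, rna_class = cls, chrom = "chr1",
             start = start, end = end, strand = strand,
             record_kind = kind, parent = parent, source_rank = rank,
             stringsAsFactors = FALSE)
}

test_that("identical records from two sources merge to one", {
  tx <- row_f("t1", "snoA", "snoRNA", 100L, 200L, kind = "transcript",
              parent = "")
  dup <- row_f("t2", "snoA2", "snoRNA", 100L, 200L, kind = "transcript",
               parent = "", rank = 2L)
  m <- merge_similar(rbind(tx, dup), 0.9)
  expect_equal(nrow(m), 1L)
  expect_equal(m$name, "snoA")        # priority = source order
  # idempotent
  expect_equal(nrow(merge_similar(m, 0.9)), 1L)
})

test_that("reciprocal overlap threshold controls merging", {
  a <- row_f("a", "A", "snoRNA", 0L, 100L, kind = "transcript", parent = "")
  b <- row_f("b", "B", "snoRNA", 5L, 107L, kind = "transcript", parent = "",
             rank = 2L)
  # overlap 95: 95/100 and 95/102 both >= 0.9 -> merged to union span
  m <- merge_similar(rbind(a, b), 0.9)
  expect_equal(nrow(m), 1L)
  expect_equal(m$start, 0L)
  expect_equal(m$end, 107L)
  # at 0.96 neither ratio passes
  expect_equal(nrow(merge_similar(rbind(a, b), 0.96)), 2L)
  # opposite strands never merge
  b2 <- b; b2$strand <- "-"
  expect_equal(nrow(merge_similar(rbind(a, b2), 0.9)), 2L)
  # different classes never merge
  b3 <- b; b3$rna_class <- "miRNA"
  expect_equal(nrow(merge_similar(rbind(a, b3), 0.9)), 2L)
})

test_that("merging is order-insensitive up to naming", {
  set.seed(406)
  rows <- do.call(rbind, lapply(1:30, function(i) {
    st <- sample(0:500, 1)
    row_f(paste0("f", i), paste0("N", i), "snoRNA", st,
          st + sample(50:80, 1), kind = "transcript", parent = "")
  }))
  m1 <- merge_similar(rows, 0.8)
  perm <- sample(nrow(rows))
  m2 <- merge_similar(rows[perm, ], 0.8)
  key <- function(m) {
    k <- m[, c("chrom", "start", "end", "strand")]
    k[order(k$start, k$end), ]
  }
  expect_equal(unname(as.matrix(key(m1))), unname(as.matrix(key(m2))))
})

test_that("introns are the transcript minus its exon union", {
  tx <- row_f("t", "G", "mRNA", 0L, 300L, kind = "transcript", parent = "")
  e1 <- row_f("e1", "G", "mRNA", 0L, 100L, parent = "t")
  e2 <- row_f("e2", "G", "mRNA", 200L, 300L, parent = "t")
  out <- derive_introns(rbind(tx, e1, e2))
  introns <- out[out$record_kind == "intron", ]
  expect_equal(nrow(introns), 1L)
  expect_equal(introns$start, 100L)
  expect_equal(introns$end, 200L)
  expect_equal(introns$name, "G")     # intron rows are named per gene
  expect_equal(introns$parent, "t")
  # single exon covering the transcript: no introns
  out2 <- derive_introns(rbind(tx, row_f("e", "G", "mRNA", 0L, 300L,
                                         parent = "t")))
  expect_equal(sum(out2$record_kind == "intron"), 0L)
  # abutting exons leave no gap
  out3 <- derive_introns(rbind(tx,
                               row_f("e1", "G", "mRNA", 0L, 150L,
                                     parent = "t"),
                               row_f("e2", "G", "mRNA", 150L, 300L,
                                     parent = "t")))
  expect_equal(sum(out3$record_kind == "intron"), 0L)
  # exon outside the transcript span is an error naming the transcript
  expect_error(derive_introns(rbind(tx, row_f("e", "G", "mRNA", 250L,
                                              350L, parent = "t"))),
               "t")
})

test_that("exon and intron unions partition every transcript", {
  set.seed(407)
  rows <- list()
  for (g in 1:10) {
    n_ex <- sample(1:4, 1)
    ex_st <- cumsum(c(1000 * g, sample(50:150, n_ex * 2 - 1, TRUE)))
    tx_start <- ex_st[1]; tx_end <- ex_st[2 * n_ex - 1] + 50L
    rows[[length(rows) + 1]] <- row_f(paste0("t", g), paste0("G", g),
                                      "mRNA", tx_start, tx_end,
                                      kind = "transcript", parent = "")
    for (e in seq_len(n_ex)) {
      st <- ex_st[2 * e - 1]
      en <- if (e == n_ex) tx_end else ex_st[2 * e]
      rows[[length(rows) + 1]] <- row_f(paste0("t", g, "e", e),
                                        paste0("G", g), "mRNA", st, en,
                                        parent = paste0("t", g))
    }
  }
  feats <- do.call(rbind, rows)
  out <- derive_introns(feats)
  for (g in 1:10) {
    tid <- paste0("t", g)
    tx <- out[out$feat_id == tid, ]
    kids <- out[out$parent == tid, ]
    cov <- IRanges::reduce(IRanges::IRanges(kids$start + 1L, kids$end))
    expect_equal(IRanges::start(cov), tx$start + 1L)
    expect_equal(IRanges::end(cov), tx$end)
    ex <- kids[kids$record_kind == "exon", ]
    int <- kids[kids$record_kind == "intron", ]
    if (nrow(int)) {
      ov <- IRanges::intersect(
        IRanges::IRanges(ex$start + 1L, ex$end),
        IRanges::IRanges(int$start + 1L, int$end))
      expect_equal(length(ov), 0L)
    }
  }
})

test_that("interval index agrees with a brute-force scan", {
  set.seed(408)
  feats <- random_feature_table(200, seed = 408)
  idx <- annotation_index(feats)
  for (rep in 1:50) {
    qs <- sample.int(1900, 1); qe <- qs + sample(10:150, 1)
    strand <- sample(c("+", "-"), 1)
    got <- sort(query_features(idx, "chr1", qs, qe, strand = strand))
    want <- which(feats$strand == strand &
                    feats$start < qe & feats$end > qs &
                    feats$record_kind %in% c("exon", "intron"))
    expect_equal(got, want)
    # strand-blind query
    got2 <- sort(query_features(idx, "chr1", qs, qe))
    want2 <- which(feats$start < qe & feats$end > qs &
                     feats$record_kind %in% c("exon", "intron"))
    expect_equal(got2, want2)
  }
})

test_that("merged GTF round-trips through write and load", {
  fix <- small_fixture()
  ref_gtf <- file.path(fix$cfg$outdir, "reference.gtf")
  feats <- load_annotation_sources(fix$cfg$annotation_sources)
  feats <- merge_similar(feats)
  feats <- derive_introns(feats)
  back <- load_annotation_sources(list(list(path = ref_gtf,
                                            dialect = "gtf")))
  cols <- c("name", "rna_class", "chrom", "start", "end", "strand",
            "record_kind")
  o1 <- feats[order(feats$chrom, feats$start, feats$end,
                    feats$record_kind, feats$name), cols]
  o2 <- back[order(back$chrom, back$start, back$end,
                   back$record_kind, back$name), cols]
  rownames(o1) <- rownames(o2) <- NULL
  expect_equal(o1, o2)
})
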