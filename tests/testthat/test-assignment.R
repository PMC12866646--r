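test_that("overlap score reproduces the defining arithmetic", {
  # fragment fully inside a long feature
  expect_equal(overlap_score(cbind(150, 250), 0, 1000), 0.1)
  # partial overlap penalizes outside bases
  expect_equal(overlap_score(cbind(140, 240), 200, 400), -0.1)
  # spliced fragment: blocks sum, the skipped gap never counts
  expect_equal(overlap_score(rbind(c(10, 30), c(70, 90)), 0, 100), 0.4)
  # upper bound L_read / L_a reached iff fully contained
  expect_equal(overlap_score(cbind(10, 60), 0, 100), 50 / 100)
  expect_lt(overlap_score(cbind(10, 60), 20, 120), 50 / 100)
})

test_that("score grows by 2/L_a per extra overlapped base", {
  for (shift in 0:9) {
    s <- overlap_score(cbind(180 + shift, 280 + shift), 200, 500)
    s0 <- overlap_score(cbind(180, 280), 200, 500)
    expect_equal(s, s0 + shift * 2 / 300)
  }
})

mk_index <- function(feats) annotation_index(feats)

row_af <- function(id, name, cls, start, end, strand = "+", kind = "exon",
                   parent = "tx") {
  data.frame(feat_id = id, name = name, rna_class = cls, chrom = "chr1",
             start = start, end = end, strand = strand,
             record_kind = kind, parent = parent, source_rank = 1L,
             stringsAsFactors = FALSE)
}

mk_aln <- function(blocks_list, strand = "+") {
  n <- length(blocks_list)
  frag <- data.frame(
    read_id = paste0("r", seq_len(n)), chrom = "chr1", strand = strand,
    start = vapply(blocks_list, function(b) b[1, 1], numeric(1)),
    end = vapply(blocks_list, function(b) b[nrow(b), 2], numeric(1)),
    cigar = "", n_softclip = 0L,
    L_read = vapply(blocks_list, function(b) sum(b[, 2] - b[, 1]),
                    numeric(1)),
    pixel = "1x1", umi = "AAAAAA", stringsAsFactors = FALSE)
  blocks <- do.call(rbind, lapply(seq_len(n), function(i)
    data.frame(frag = i, start = blocks_list[[i]][, 1],
               end = blocks_list[[i]][, 2])))
  list(fragments = frag, blocks = blocks, chrom_lengths = c(chr1 = 10000L),
       n_dropped = c(no_metadata = 0L))
}

test_that("winner, layer and composite naming follow the score rule", {
  feats <- rbind(
    row_af("a", "A", "mRNA", 0L, 1000L),
    row_af("b", "B", "mRNA", 250L, 750L),
    row_af("ai", "A", "mRNA", 2000L, 2400L, kind = "intron"))
  idx <- mk_index(feats)
  # sole candidate
  asn <- assign_reads(mk_aln(list(cbind(50, 150))), idx)
  expect_equal(asn$feature, "A")
  expect_equal(asn$layer, "exon")
  expect_equal(asn$status, "assigned")
  # nested features: the shorter feature scores higher
  asn <- assign_reads(mk_aln(list(cbind(300, 400))), idx)
  expect_equal(asn$feature, "B")
  expect_equal(asn$score, (100 - 0) / 500)
  # intron-only evidence lands in the intron layer
  asn <- assign_reads(mk_aln(list(cbind(2100, 2200))), idx)
  expect_equal(asn$feature, "A")
  expect_equal(asn$layer, "intron")
  # no positive score: unassigned status, not an error
  asn <- assign_reads(mk_aln(list(cbind(900, 1100))), idx)
  expect_equal(asn$status, "unassigned")
})

test_that("exact score ties become plus-joined multimap features", {
  feats <- rbind(
    row_af("a", "A", "mRNA", 0L, 500L),
    row_af("b", "B", "mRNA", 300L, 800L))
  idx <- mk_index(feats)
  # fragment inside both same-length exons: exact tie
  asn <- assign_reads(mk_aln(list(cbind(350, 450))), idx)
  expect_equal(asn$feature, "A+B")
  expect_equal(asn$layer, "exon")
  # tied records sharing one name collapse to a plain assignment
  feats2 <- rbind(
    row_af("e1", "G", "mRNA", 0L, 200L),
    row_af("e2", "G", "mRNA", 600L, 800L))
  asn2 <- assign_reads(mk_aln(list(rbind(c(170, 200), c(600, 620)))),
                       mk_index(feats2))
  expect_equal(asn2$feature, "G")
})

test_that("strand policy controls the candidate set", {
  feats <- rbind(row_af("p", "PLUS", "mRNA", 0L, 500L, strand = "+"),
                 row_af("m", "MINUS", "mRNA", 0L, 500L, strand = "-"))
  idx <- mk_index(feats)
  fr <- mk_aln(list(cbind(100, 200)), strand = "+")
  expect_equal(assign_reads(fr, idx, strand_policy = "same")$feature,
               "PLUS")
  expect_equal(assign_reads(fr, idx, strand_policy = "opposite")$feature,
               "MINUS")
  expect_equal(assign_reads(fr, idx, strand_policy = "both")$feature,
               "MINUS+PLUS")
  fr_m <- mk_aln(list(cbind(100, 200)), strand = "-")
  expect_equal(assign_reads(fr_m, idx, strand_policy = "same")$feature,
               "MINUS")
})

test_that("post-alignment filters drop short and soft-clipped fragments", {
  feats <- row_af("a", "A", "mRNA", 0L, 1000L)
  idx <- mk_index(feats)
  short <- mk_aln(list(cbind(100, 110)))
  asn <- assign_reads(short, idx, min_align_len = 20)
  expect_equal(asn$status, "unassigned")
  expect_equal(attr(asn, "n_filtered")[["short_alignment"]], 1L)
  clipped <- mk_aln(list(cbind(100, 140)))
  clipped$fragments$n_softclip <- 60L
  asn2 <- assign_reads(clipped, idx, max_softclip_frac = 0.5)
  expect_equal(attr(asn2, "n_filtered")[["softclipped"]], 1L)
})

test_that("assignment matches the brute-force scorer on random cases", {
  set.seed(409)
  for (rep in 1:8) {
    feats <- random_feature_table(sample(10:50, 1))
    feats <- feats[!duplicated(feats$feat_id), ]
    idx <- mk_index(feats)
    for (q in 1:40) {
      n_blk <- sample(1:2, 1)
      st <- sample.int(1800, 1)
      if (n_blk == 1) {
        blocks <- cbind(st, st + sample(20:120, 1))
      } else {
        w1 <- sample(15:50, 1); gap <- sample(30:200, 1)
        w2 <- sample(15:50, 1)
        blocks <- rbind(c(st, st + w1),
                        c(st + w1 + gap, st + w1 + gap + w2))
      }
      strand <- sample(c("+", "-"), 1)
      got <- assign_reads(mk_aln(list(blocks), strand = strand), idx,
                          min_align_len = 1)
      want <- oracle_assign(blocks, "chr1", strand, feats)
      expect_equal(got$status, want$status)
      if (want$status == "assigned") {
        expect_equal(got$feature, want$feature)
        expect_equal(got$layer, want$layer)
      }
    }
  }
})

test_that("SAM alignments round-trip with metadata from read names", {
  dir <- tempfile(); dir.create(dir)
  sam <- file.path(dir, "t.sam")
  writeLines(c(
    "@HD\tVN:1.6\tSO:coordinate",
    "@SQ\tSN:chr1\tLN:5000",
    paste("r1|PX:3x7|UMI:ACGTAC", 0, "chr1", 101, 60, "50M", "*", 0, 0,
          strrep("A", 50), strrep("I", 50), sep = "\t"),
    paste("r2", 16, "chr1", 201, 60, "20M100N30M", "*", 0, 0,
          strrep("A", 50), strrep("I", 50), sep = "\t"),
    paste("r3", 0, "chr1", 301, 60, "50M", "*", 0, 0,
          strrep("A", 50), strrep("I", 50), sep = "\t")),
    sam)
  demux <- data.frame(read_id = "r2", x = 5L, y = 9L, umi = "TTTTGG",
                      stringsAsFactors = FALSE)
  aln <- read_alignments(sam, demux = demux)
  expect_equal(nrow(aln$fragments), 2L)     # r3 has no metadata
  expect_equal(aln$n_dropped[["no_metadata"]], 1L)
  r1 <- aln$fragments[aln$fragments$read_id == "r1", ]
  expect_equal(r1$pixel, "3x7")
  expect_equal(r1$umi, "ACGTAC")
  expect_equal(r1$start, 100L)
  r2 <- aln$fragments[aln$fragments$read_id == "r2", ]
  expect_equal(r2$pixel, "5x9")
  expect_equal(r2$strand, "-")
  b2 <- aln$blocks[aln$blocks$frag == which(aln$fragments$read_id == "r2"), ]
  expect_equal(b2$start, c(200L, 320L))     # N splits the blocks
  expect_equal(b2$end, c(220L, 350L))
  expect_equal(aln$chrom_lengths[["chr1"]], 5000L)
})
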