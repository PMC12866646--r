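one_feature <- function(start, end, chrom = "chr1", strand = "+") {
  data.frame(name = "F", chrom = chrom, start = start, end = end,
             strand = strand, stringsAsFactors = FALSE)
}

test_that("background windows clip at chromosome ends and mask neighbors", {
  mids <- data.frame(chrom = character(0), strand = character(0),
                     pos = integer(0))
  p <- profile_feature(one_feature(1000L, 1100L), mids, flank_mult = 1)
  expect_equal(p$L_in, 100L)
  expect_equal(p$L_bg, 200L)
  # feature at the chromosome start has no upstream flank
  p2 <- profile_feature(one_feature(0L, 100L), mids, flank_mult = 1)
  expect_equal(p2$L_bg, 100L)
  # right clipping at the chromosome end
  p3 <- profile_feature(one_feature(1000L, 1100L), mids, flank_mult = 1,
                        chrom_length = 1150L)
  expect_equal(p3$L_bg, 100L + 50L)
  # a same-strand neighbor masks part of the downstream flank
  mask <- data.frame(chrom = "chr1", strand = "+", start = 1100L,
                     end = 1150L)
  p4 <- profile_feature(one_feature(1000L, 1100L), mids, mask = mask,
                        flank_mult = 1)
  expect_equal(p4$L_bg, 100L + 50L)
  # opposite-strand neighbors do not mask
  mask$strand <- "-"
  p5 <- profile_feature(one_feature(1000L, 1100L), mids, mask = mask,
                        flank_mult = 1)
  expect_equal(p5$L_bg, 200L)
})

test_that("midpoints are counted by region and strand", {
  mids <- data.frame(chrom = "chr1", strand = c("+", "+", "+", "-"),
                     pos = c(1050L, 950L, 1150L, 1050L))
  p <- profile_feature(one_feature(1000L, 1100L), mids, flank_mult = 1)
  expect_equal(p$in_count, 1L)
  expect_equal(p$bg_count, 2L)
})

test_that("enrichment p-values match the exact binomial tail", {
  prof <- function(ic, bc, L_in = 100L, L_bg = 200L)
    structure(list(name = "F", in_count = ic, bg_count = bc, L_in = L_in,
                   L_bg = L_bg), class = "depth_profile")
  # no reads inside: no evidence at all
  expect_equal(enrichment_pvalue(prof(0L, 10L)), 1.0)
  # all 10 reads inside at p0 = 1/3: closed form (1/3)^10
  expect_equal(enrichment_pvalue(prof(10L, 0L)), (1 / 3)^10)
  # 8 of 10 inside: tail sum from the binomial pmf, written out
  want <- sum(choose(10, 8:10) * (1 / 3)^(8:10) * (2 / 3)^(2:0))
  expect_equal(enrichment_pvalue(prof(8L, 2L)), want)
  # untestable profiles get NA
  expect_true(is.na(enrichment_pvalue(prof(5L, 0L, L_bg = 0L))))
  expect_true(is.na(enrichment_pvalue(prof(0L, 0L))))
  # monotone: more inside reads never weakens the evidence
  ps <- vapply(0:10, function(k) enrichment_pvalue(prof(k, 10L - k)),
               numeric(1))
  expect_true(all(diff(ps) <= 0))
})

test_that("BH adjustment equals the reference step-up procedure", {
  set.seed(412)
  for (rep in 1:5) {
    p <- runif(sample(c(3, 20, 100), 1))^2
    expect_equal(p.adjust(p, "BH"), oracle_bh(p))
  }
})

test_that("verdicts combine FDR, fold and read-count gates", {
  sim <- simulate_depth_features(40, n_reads = 60, enrichment = 12,
                                 seed = 77)
  aln <- list(fragments = data.frame(
    read_id = paste0("m", seq_len(nrow(sim$midpoints))),
    chrom = sim$midpoints$chrom, strand = sim$midpoints$strand,
    start = sim$midpoints$pos, end = sim$midpoints$pos + 1L,
    cigar = "1M", n_softclip = 0L, L_read = 1L, pixel = "1x1",
    umi = "A", stringsAsFactors = FALSE),
    blocks = NULL, chrom_lengths = c(chrV = sim$chrom_length),
    n_dropped = c(no_metadata = 0L))
  idx <- annotation_index(rbind(sim$features,
    within(sim$features, {feat_id <- paste0(feat_id, ":tx");
                          record_kind <- "transcript"; parent <- ""})[
      , names(sim$features)]))
  res <- validate_features(idx, aln)
  expect_true(all(res$verdict %in% c("valid", "invalid", "untestable")))
  expect_gt(mean(res$verdict == "valid"), 0.8)
  # every valid verdict satisfies all three gates
  v <- res[res$verdict == "valid", ]
  expect_true(all(v$q <= 0.05 & v$fold >= 2 & v$in_count >= 5))
})

test_that("curation drops invalid rows and keeps the rest", {
  a <- data.frame(read_id = paste0("r", 1:30),
                  pixel = pixel_key(rep(1:3, 10), rep(1:3, 10)),
                  feature = rep(c("GOOD", "BAD", "UNTESTED"), 10),
                  layer = "exon",
                  umi = paste0(rep(c("A", "C", "G"), 10),
                               rep(1:10, each = 3)),
                  score = 1, status = "assigned",
                  stringsAsFactors = FALSE)
  cm <- dedup_and_count(a)
  res <- data.frame(feature = c("GOOD", "BAD"),
                    in_count = c(20L, 4L), bg_count = c(1L, 20L),
                    L_in = 100L, L_bg = 200L, fold = c(40, 0.4),
                    p = c(1e-9, 0.9), q = c(1e-8, 0.9),
                    verdict = c("valid", "invalid"),
                    stringsAsFactors = FALSE)
  bad_total <- sum(cm$layers$exon["BAD", ])
  cur <- curate_matrix(cm, res)
  expect_false("BAD" %in% cur$features$name)
  expect_true(all(c("GOOD", "UNTESTED") %in% cur$features$name))
  expect_equal(total_counts(cur), total_counts(cm) - bad_total)
  expect_equal(cur$features$verdict[cur$features$name == "UNTESTED"],
               "untested")
  # all-valid results leave the matrix unchanged
  res2 <- res[1, ]
  cur2 <- curate_matrix(cm, res2)
  expect_equal(total_counts(cur2), total_counts(cm))
  # empty results warn and change nothing
  expect_warning(cur3 <- curate_matrix(cm, res[0, ]), "empty")
  expect_equal(total_counts(cur3), total_counts(cm))
})
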