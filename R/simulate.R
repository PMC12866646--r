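## Fully synthetic, ground-truthed fixture data: toy genome, whole-RNA
## annotation across three source dialects, barcode whitelists, reads with
## planted pixels/UMIs/features, exact-placement SAM (a trivial built-in
## aligner substitute for testing), and truth tables.  One master seed
## drives named sub-streams so every output is byte-reproducible.

#' Specify a synthetic spatial whole-transcriptome dataset
#'
#' Defaults describe the standard fixture conditions used throughout the
#' test-suite: 2 chromosomes of 100 kb, 20 multi-exon genes, 10 miRNA
#' hairpins with distinct 5p/3p mature arms, 4 spurious compact ncRNA
#' annotations receiving only length-uniform background reads, a 16 x 16
#' pixel grid of 8-mer barcodes, and 5 UMIs per planted (pixel, feature)
#' pair with zero read errors.
#'
#' @param seed master seed; every random stream derives from it.
#' @param n_chroms,chrom_length toy genome shape.
#' @param n_genes multi-exon protein-coding genes (GENCODE-dialect GTF).
#' @param exons_per_gene exons per gene (length 200 nt, introns 150 nt).
#' @param n_mirnas miRNA hairpins; each contributes a 70 nt primary
#'   transcript plus 22 nt 5p/3p mature arms (generic-GTF dialect).
#' @param n_spurious spurious snoRNA-class annotations (BED6+class
#'   dialect) that receive only background reads.
#' @param n_barcodes_a,n_barcodes_b,barcode_length pixel grid definition.
#' @param umi_length UMI length in read 1.
#' @param linker literal linker sequence between the two barcode slots.
#' @param flank barcode-window expansion used when parsing.
#' @param pixels_per_feature planted pixels per expressed feature.
#' @param umis_per_pair planted UMIs per (pixel, feature) pair.
#' @param fragment_length cDNA fragment length for gene reads.
#' @param frac_intronic,frac_spliced fraction of each gene's planted
#'   reads drawn from introns / spliced across an exon junction.
#' @param antisense_per_gene extra antisense reads per gene (expected to
#'   stay unassigned under the same-strand policy).
#' @param barcode_sub_rate,barcode_ins_rate,barcode_del_rate per-barcode
#'   probabilities of one substitution / insertion / deletion.
#' @param background_reads_per_spurious reads scattered length-uniformly
#'   over each spurious feature plus its two flanks.
#' @return list of class `simulation_spec`.
#' @export
simulation_spec <- function(seed = 1L, n_chroms = 2L,
                            chrom_length = 100000L, n_genes = 20L,
                            exons_per_gene = 3L, n_mirnas = 10L,
                            n_spurious = 4L, n_barcodes_a = 16L,
                            n_barcodes_b = 16L, barcode_length = 8L,
                            umi_length = 8L, linker = "GTCGGCGT",
                            flank = 2L, pixels_per_feature = 6L,
                            umis_per_pair = 5L, fragment_length = 50L,
                            frac_intronic = 0.2, frac_spliced = 0.2,
                            antisense_per_gene = 2L,
                            barcode_sub_rate = 0, barcode_ins_rate = 0,
                            barcode_del_rate = 0,
                            background_reads_per_spurious = 60L) {
  spec <- as.list(environment())
  stopifnot(spec$n_chroms >= 1, spec$chrom_length >= 2000,
            spec$fragment_length >= 1,
            spec$fragment_length < spec$chrom_length,
            spec$frac_intronic + spec$frac_spliced <= 1)
  structure(spec, class = "simulation_spec")
}

## reject whitelists in which one barcode could mimic another inside an
## expanded window: any shifted full-overlap agreement (unknown flank
## bases assumed adversarial) or Hamming distance < 3.
whitelist_safe <- function(seqs, max_shift = 2L) {
  n <- length(seqs); L <- nchar(seqs[1])
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i == j) next
    a <- utf8ToInt(seqs[i]); b <- utf8ToInt(seqs[j])
    if (sum(a != b) < 3L) return(FALSE)
    for (s in seq_len(max_shift)) {   # b shifted right by s over a
      if (all(a[(s + 1):L] == b[1:(L - s)])) return(FALSE)
      if (all(b[(s + 1):L] == a[1:(L - s)])) return(FALSE)
    }
  }
  TRUE
}

sim_whitelist <- function(n, len, seed) {
  set.seed(seed)
  repeat {
    seqs <- unique(random_dna(4L * n, len))
    # greedily grow a mutually safe subset
    keep <- character(0)
    for (s in seqs) {
      if (whitelist_safe(c(keep, s))) keep <- c(keep, s)
      if (length(keep) == n) break
    }
    if (length(keep) == n) return(keep)
  }
}

## lay out gene / miRNA / spurious loci round-robin across chromosomes
## with 500 nt spacing so validation flanks never collide
sim_annotation_plan <- function(spec) {
  exon_len <- 200L; intron_len <- 150L
  hairpin_len <- 70L; arm_len <- 22L; spur_len <- 100L
  gap <- 500L
  cursor <- rep(1000L, spec$n_chroms)
  place <- function(len, k) {
    chrom <- (k - 1L) %% spec$n_chroms + 1L
    st <- cursor[chrom]
    cursor[chrom] <<- st + len + gap
    if (cursor[chrom] > spec$chrom_length - 1000L)
      stop("chromosome too short for the requested annotation")
    list(chrom = paste0("chr", chrom), start = st)
  }
  strands <- c("+", "-")
  genes <- lapply(seq_len(spec$n_genes), function(g) {
    span <- spec$exons_per_gene * exon_len +
      (spec$exons_per_gene - 1L) * intron_len
    p <- place(span, g)
    ex_start <- p$start + (seq_len(spec$exons_per_gene) - 1L) *
      (exon_len + intron_len)
    list(name = sprintf("GENE%02d", g), chrom = p$chrom,
         start = p$start, end = p$start + span,
         strand = strands[g %% 2L + 1L],
         exon_start = ex_start, exon_end = ex_start + exon_len)
  })
  mirnas <- lapply(seq_len(spec$n_mirnas), function(m) {
    p <- place(hairpin_len, spec$n_genes + m)
    list(name = sprintf("mir-%d", m), chrom = p$chrom,
         start = p$start, end = p$start + hairpin_len,
         strand = strands[m %% 2L + 1L],
         arm5 = c(p$start, p$start + arm_len),
         arm3 = c(p$start + hairpin_len - arm_len, p$start + hairpin_len))
  })
  spurious <- lapply(seq_len(spec$n_spurious), function(s) {
    p <- place(spur_len, spec$n_genes + spec$n_mirnas + s)
    list(name = sprintf("SNO-SP%d", s), chrom = p$chrom,
         start = p$start, end = p$start + spur_len,
         strand = strands[s %% 2L + 1L])
  })
  list(genes = genes, mirnas = mirnas, spurious = spurious,
       exon_len = exon_len, intron_len = intron_len, arm_len = arm_len,
       spur_len = spur_len)
}

sim_write_annotation <- function(plan, outdir) {
  gtf <- file.path(outdir, "genes.gtf")
  lines <- unlist(lapply(plan$genes, function(g) {
    tx <- sprintf("%s\tsim\ttranscript\t%d\t%d\t.\t%s\t.\tgene_id \"%s\"; gene_name \"%s\"; gene_type \"protein_coding\"; transcript_id \"%s.t1\";",
                  g$chrom, g$start + 1L, g$end, g$strand, g$name, g$name,
                  g$name)
    ex <- sprintf("%s\tsim\texon\t%d\t%d\t.\t%s\t.\tgene_id \"%s\"; gene_name \"%s\"; gene_type \"protein_coding\"; transcript_id \"%s.t1\";",
                  g$chrom, g$exon_start + 1L, g$exon_end, g$strand,
                  g$name, g$name, g$name)
    c(tx, ex)
  }))
  writeLines(lines, gtf)
  mir <- file.path(outdir, "mirna.gtf")
  lines <- unlist(lapply(plan$mirnas, function(m) {
    base <- sub("^mir-", "miR-", m$name)
    c(sprintf("%s\tsim\tmiRNA_primary_transcript\t%d\t%d\t.\t%s\t.\tID \"%s\"; Name \"%s\"; rna_class \"miRNA\";",
              m$chrom, m$start + 1L, m$end, m$strand, m$name, m$name),
      sprintf("%s\tsim\tmiRNA\t%d\t%d\t.\t%s\t.\tID \"%s-5p\"; Name \"%s-5p\"; Derives_from \"%s\"; rna_class \"miRNA\";",
              m$chrom, m$arm5[1] + 1L, m$arm5[2], m$strand, base, base,
              m$name),
      sprintf("%s\tsim\tmiRNA\t%d\t%d\t.\t%s\t.\tID \"%s-3p\"; Name \"%s-3p\"; Derives_from \"%s\"; rna_class \"miRNA\";",
              m$chrom, m$arm3[1] + 1L, m$arm3[2], m$strand, base, base,
              m$name))
  }))
  writeLines(lines, mir)
  bed <- file.path(outdir, "smallrna.bed")
  writeLines(vapply(plan$spurious, function(s)
    sprintf("%s\t%d\t%d\t%s\t0\t%s\tsnoRNA", s$chrom, s$start, s$end,
            s$name, s$strand), character(1)), bed)
  list(list(path = gtf, dialect = "gencode"),
       list(path = mir, dialect = "gtf"),
       list(path = bed, dialect = "bed6"))
}

## corrupt a barcode with at most one edit per process, per the spec'd rates
sim_corrupt_barcode <- function(bc, spec) {
  if (spec$barcode_sub_rate > 0 && runif(1) < spec$barcode_sub_rate) {
    i <- sample(nchar(bc), 1L)
    old <- substr(bc, i, i)
    substr(bc, i, i) <- sample(setdiff(DNA_BASES, old), 1L)
  }
  if (spec$barcode_ins_rate > 0 && runif(1) < spec$barcode_ins_rate) {
    i <- sample(nchar(bc) + 1L, 1L)
    bc <- paste0(substr(bc, 1L, i - 1L), sample(DNA_BASES, 1L),
                 substr(bc, i, nchar(bc)))
  }
  if (spec$barcode_del_rate > 0 && runif(1) < spec$barcode_del_rate) {
    i <- sample(nchar(bc), 1L)
    bc <- paste0(substr(bc, 1L, i - 1L), substr(bc, i + 1L, nchar(bc)))
  }
  bc
}

#' Generate a complete synthetic dataset with ground truth
#'
#' Writes into `outdir`: `genome.fasta`; three annotation sources
#' (`genes.gtf` GENCODE dialect, `mirna.gtf` generic dialect,
#' `smallrna.bed` BED6+class); barcode whitelists; `reads_R1.fastq` /
#' `reads_R2.fastq`; an exact-placement `aligned.sam` (the built-in toy
#' aligner: every read is placed at its true locus, spliced reads with N
#' skips); a ready-to-run `config.json`; and truth tables
#' (`truth_reads.tsv` with the expected per-read assignment,
#' `truth_counts.tsv` with the expected exon/intron matrices,
#' `truth_validation.tsv` marking genuine vs spurious features).
#'
#' @param spec a [simulation_spec()].
#' @param outdir target directory.
#' @return (invisibly) a list of all written paths plus the truth tables.
#' @export
simulate_dataset <- function(spec, outdir) {
  stopifnot(inherits(spec, "simulation_spec"))
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)

  set.seed(derive_seed(spec$seed, "genome"))
  chroms <- paste0("chr", seq_len(spec$n_chroms))
  genome <- setNames(random_dna(spec$n_chroms, spec$chrom_length), chroms)
  fa <- file.path(outdir, "genome.fasta")
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(genome), fa)

  plan <- sim_annotation_plan(spec)
  sources <- sim_write_annotation(plan, outdir)

  wl_a <- sim_whitelist(spec$n_barcodes_a, spec$barcode_length,
                        derive_seed(spec$seed, "whitelist_a"))
  wl_b <- sim_whitelist(spec$n_barcodes_b, spec$barcode_length,
                        derive_seed(spec$seed, "whitelist_b"))
  writeLines(wl_a, file.path(outdir, "whitelist_a.txt"))
  writeLines(wl_b, file.path(outdir, "whitelist_b.txt"))

  ## ---- plant reads -----------------------------------------------------
  set.seed(derive_seed(spec$seed, "reads"))
  fragment_of <- function(chrom, start, end, strand) {
    s <- substr(genome[[chrom]], start + 1L, end)
    if (strand == "-") revcomp(s) else s
  }
  reads <- list()
  add_read <- function(px, umi, chrom, strand, blocks, feature, layer,
                       expect) {
    cig <- character(0)
    seqs <- character(0)
    for (b in seq_len(nrow(blocks))) {
      if (b > 1L) {
        gap <- blocks[b, 1] - blocks[b - 1L, 2]
        cig <- c(cig, paste0(gap, "N"))
      }
      cig <- c(cig, paste0(blocks[b, 2] - blocks[b, 1], "M"))
      seqs <- c(seqs, substr(genome[[chrom]], blocks[b, 1] + 1L,
                             blocks[b, 2]))
    }
    seq2 <- paste(seqs, collapse = "")
    if (strand == "-") seq2 <- revcomp(seq2)
    reads[[length(reads) + 1L]] <<- list(
      x = px[1], y = px[2], umi = umi, chrom = chrom, strand = strand,
      start = blocks[1, 1], cigar = paste(cig, collapse = ""),
      seq2 = seq2, feature = feature, layer = layer, expect = expect)
  }
  all_px <- as.matrix(expand.grid(x = seq_len(spec$n_barcodes_a),
                                  y = seq_len(spec$n_barcodes_b)))
  plant_pixels <- function() {
    all_px[sample(nrow(all_px), spec$pixels_per_feature), , drop = FALSE]
  }
  new_umi <- function() paste(sample(DNA_BASES, spec$umi_length,
                                     replace = TRUE), collapse = "")
  fl <- spec$fragment_length

  for (g in plan$genes) {
    px_set <- plant_pixels()
    n_spl <- round(spec$frac_spliced * spec$umis_per_pair)
    n_int <- round(spec$frac_intronic * spec$umis_per_pair)
    n_exn <- spec$umis_per_pair - n_spl - n_int
    for (p in seq_len(nrow(px_set))) {
      px <- px_set[p, ]
      for (k in seq_len(n_exn)) {   # fragment inside one exon
        e <- sample(length(g$exon_start), 1L)
        st <- g$exon_start[e] +
          sample.int(plan$exon_len - fl + 1L, 1L) - 1L
        add_read(px, new_umi(), g$chrom, g$strand,
                 cbind(st, st + fl), g$name, "exon", "assigned")
      }
      for (k in seq_len(n_int)) {   # fragment inside one intron
        i <- sample(length(g$exon_start) - 1L, 1L)
        int_st <- g$exon_end[i]
        st <- int_st + sample.int(plan$intron_len - fl + 1L, 1L) - 1L
        add_read(px, new_umi(), g$chrom, g$strand,
                 cbind(st, st + fl), g$name, "intron", "assigned")
      }
      for (k in seq_len(n_spl)) {   # junction read, asymmetric 30/20 split
        i <- sample(length(g$exon_start) - 1L, 1L)
        b1 <- c(g$exon_end[i] - 30L, g$exon_end[i])
        b2 <- c(g$exon_start[i + 1L], g$exon_start[i + 1L] + 20L)
        add_read(px, new_umi(), g$chrom, g$strand,
                 rbind(b1, b2), g$name, "exon", "assigned")
      }
    }
    for (k in seq_len(spec$antisense_per_gene)) {
      px <- all_px[sample(nrow(all_px), 1L), ]
      e <- sample(length(g$exon_start), 1L)
      st <- g$exon_start[e] + sample.int(plan$exon_len - fl + 1L, 1L) - 1L
      add_read(px, new_umi(), g$chrom,
               if (g$strand == "+") "-" else "+",
               cbind(st, st + fl), "", "", "unassigned")
    }
  }
  for (m in plan$mirnas) {
    base <- sub("^mir-", "miR-", m$name)
    for (arm in c("5p", "3p")) {
      span <- if (arm == "5p") m$arm5 else m$arm3
      px_set <- plant_pixels()
      for (p in seq_len(nrow(px_set))) {
        px <- px_set[p, ]
        for (k in seq_len(spec$umis_per_pair))
          add_read(px, new_umi(), m$chrom, m$strand,
                   cbind(span[1], span[2]), paste0(base, "-", arm),
                   "exon", "assigned")
      }
    }
  }
  for (s in plan$spurious) {
    L <- plan$spur_len
    for (k in seq_len(spec$background_reads_per_spurious)) {
      px <- all_px[sample(nrow(all_px), 1L), ]
      region <- sample(3L, 1L)   # upstream / inside / downstream, 1/3 each
      frag <- min(fl, L)
      st <- switch(region,
                   s$start - L + sample.int(L - frag + 1L, 1L) - 1L,
                   s$start + sample.int(L - frag + 1L, 1L) - 1L,
                   s$end + sample.int(L - frag + 1L, 1L) - 1L)
      inside <- region == 2L
      add_read(px, new_umi(), s$chrom, s$strand, cbind(st, st + frag),
               if (inside) s$name else "",
               if (inside) "exon" else "",
               if (inside) "assigned" else "unassigned")
    }
  }

  ## ---- write FASTQ / SAM ----------------------------------------------
  set.seed(derive_seed(spec$seed, "errors"))
  n <- length(reads)
  ids <- sprintf("r%06d", seq_len(n))
  r1 <- character(n); r2 <- character(n); sam <- character(n)
  for (i in seq_len(n)) {
    rd <- reads[[i]]
    bca <- sim_corrupt_barcode(wl_a[rd$x], spec)
    bcb <- sim_corrupt_barcode(wl_b[rd$y], spec)
    r1[i] <- paste0(bca, spec$linker, bcb, rd$umi)
    r2[i] <- rd$seq2
    flag <- if (rd$strand == "-") 16L else 0L
    sam[i] <- paste(ids[i], flag, rd$chrom, rd$start + 1L, 60L, rd$cigar,
                    "*", 0L, 0L, rd$seq2,
                    strrep("I", nchar(rd$seq2)), sep = "\t")
  }
  fq1 <- file.path(outdir, "reads_R1.fastq")
  fq2 <- file.path(outdir, "reads_R2.fastq")
  writeLines(paste0("@", ids, "\n", r1, "\n+\n",
                    strrep("I", nchar(r1))), fq1)
  writeLines(paste0("@", ids, "\n", r2, "\n+\n",
                    strrep("I", nchar(r2))), fq2)
  sam_path <- file.path(outdir, "aligned.sam")
  writeLines(c("@HD\tVN:1.6\tSO:coordinate",
               sprintf("@SQ\tSN:%s\tLN:%d", chroms, spec$chrom_length),
               sam[order(vapply(reads, `[[`, character(1), "chrom"),
                         vapply(reads, `[[`, numeric(1), "start"))]),
             sam_path)

  ## ---- truth tables ----------------------------------------------------
  truth_reads <- data.frame(
    read_id = ids,
    x = vapply(reads, `[[`, numeric(1), "x"),
    y = vapply(reads, `[[`, numeric(1), "y"),
    umi = vapply(reads, `[[`, character(1), "umi"),
    feature = vapply(reads, `[[`, character(1), "feature"),
    layer = vapply(reads, `[[`, character(1), "layer"),
    expect = vapply(reads, `[[`, character(1), "expect"),
    chrom = vapply(reads, `[[`, character(1), "chrom"),
    start = vapply(reads, `[[`, numeric(1), "start"),
    cigar = vapply(reads, `[[`, character(1), "cigar"),
    strand = vapply(reads, `[[`, character(1), "strand"),
    stringsAsFactors = FALSE)
  write.table(truth_reads, file.path(outdir, "truth_reads.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  tr <- truth_reads[truth_reads$expect == "assigned", , drop = FALSE]
  tr$pixel <- pixel_key(tr$x, tr$y)
  tup <- unique(tr[, c("pixel", "feature", "layer", "umi")])
  cnt <- rowsum(rep(1L, nrow(tup)),
                paste(tup$feature, tup$pixel, tup$layer, sep = "\r"))
  parts <- strsplit(rownames(cnt), "\r", fixed = TRUE)
  truth_counts <- data.frame(
    feature = vapply(parts, `[`, character(1), 1L),
    pixel = vapply(parts, `[`, character(1), 2L),
    layer = vapply(parts, `[`, character(1), 3L),
    count = as.integer(cnt[, 1]), stringsAsFactors = FALSE)
  truth_counts <- truth_counts[order(truth_counts$feature,
                                     truth_counts$pixel,
                                     truth_counts$layer), , drop = FALSE]
  write.table(truth_counts, file.path(outdir, "truth_counts.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  truth_val <- data.frame(
    feature = c(unlist(lapply(plan$mirnas, function(m) {
      base <- sub("^mir-", "miR-", m$name)
      paste0(base, c("-5p", "-3p"))
    })), vapply(plan$spurious, `[[`, character(1), "name")),
    truth = c(rep("genuine", 2L * spec$n_mirnas),
              rep("spurious", spec$n_spurious)),
    stringsAsFactors = FALSE)
  write.table(truth_val, file.path(outdir, "truth_validation.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)

  ## ---- pipeline config -------------------------------------------------
  # paths relative to the config file so the directory is relocatable
  config <- list(
    outdir = "out",
    fastq_r1 = basename(fq1), fastq_r2 = basename(fq2),
    alignments = basename(sam_path),
    whitelist_a = "whitelist_a.txt",
    whitelist_b = "whitelist_b.txt",
    annotation_sources = lapply(sources, function(s)
      list(path = basename(s$path), dialect = s$dialect)),
    layout = list(
      segments = list(
        list(kind = "barcode", expected_length = spec$barcode_length,
             slot_id = "A"),
        list(kind = "linker", expected_length = nchar(spec$linker),
             sequence = spec$linker),
        list(kind = "barcode", expected_length = spec$barcode_length,
             slot_id = "B"),
        list(kind = "umi", expected_length = spec$umi_length,
             slot_id = "U")),
      flank = spec$flank, max_linker_mismatch = 1L),
    max_edit = 2L, strand_policy = "same", min_align_len = 20L,
    max_softclip_frac = 0.5, min_reciprocal_overlap = 0.9,
    validation = list(alpha = 0.05, min_fold = 2, min_reads = 5,
                      flank_mult = 1),
    threads = 1L, seed = spec$seed)
  cfg_path <- file.path(outdir, "config.json")
  jsonlite::write_json(config, cfg_path, auto_unbox = TRUE, pretty = TRUE)

  invisible(list(outdir = outdir, config = cfg_path, genome = fa,
                 sources = sources, fastq_r1 = fq1, fastq_r2 = fq2,
                 sam = sam_path, whitelists = list(A = wl_a, B = wl_b),
                 truth_reads = truth_reads, truth_counts = truth_counts,
                 truth_validation = truth_val, plan = plan))
}

#' Simulate isolated features with controllable depth enrichment
#'
#' Generates `n_features` same-length features far apart on one toy
#' chromosome and scatters read midpoints over each feature plus its two
#' flanks.  Under `enrichment = 1` a read lands inside the feature with
#' exactly the null probability p0 = L_in/(L_in + L_bg); larger values
#' multiply the inside depth accordingly.  Used to check the calibration
#' and power of the depth-enrichment validation test.
#'
#' @param n_features number of features.
#' @param L_in feature length (nt).
#' @param flank_mult flank window multiple (as in validation).
#' @param n_reads reads per feature.
#' @param enrichment inside-vs-flank depth ratio (1 = null).
#' @param seed RNG seed.
#' @return list with `features` (feature table slice per row),
#'   `midpoints` (chrom, strand, pos), `chrom_length`.
#' @export
simulate_depth_features <- function(n_features, L_in = 100L,
                                    flank_mult = 1, n_reads = 30L,
                                    enrichment = 1, seed = 1L) {
  set.seed(seed)
  w <- ceiling(flank_mult * L_in)
  pitch <- (L_in + 2L * w) * 5L
  start <- 1000L + (seq_len(n_features) - 1L) * pitch
  features <- data.frame(
    feat_id = paste0("vf", seq_len(n_features)),
    name = paste0("vf", seq_len(n_features)),
    rna_class = "snoRNA", chrom = "chrV",
    start = start, end = start + L_in, strand = "+",
    record_kind = "exon",
    parent = paste0("vf", seq_len(n_features), ":tx"), source_rank = 1L,
    stringsAsFactors = FALSE)
  L_bg <- 2L * w
  p_in <- enrichment * L_in / (enrichment * L_in + L_bg)
  mids <- lapply(seq_len(n_features), function(i) {
    inside <- runif(n_reads) < p_in
    pos <- integer(n_reads)
    pos[inside] <- features$start[i] + sample.int(L_in, sum(inside),
                                                  replace = TRUE) - 1L
    off <- sample.int(L_bg, sum(!inside), replace = TRUE) - 1L
    pos[!inside] <- ifelse(off < w, features$start[i] - w + off,
                           features$end[i] + off - w)
    data.frame(chrom = "chrV", strand = "+", pos = pos)
  })
  list(features = features, midpoints = do.call(rbind, mids),
       chrom_length = max(features$end) + 10L * w)
}
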