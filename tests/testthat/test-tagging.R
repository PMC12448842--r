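aln <- function(pos, cigar, seq, qual = 30L) {
  list(pos = pos, cigar = cigar, seq = seq,
       qual = rep_len(as.integer(qual), nchar(seq) + 20L))
}

site_row <- function(pos, ref, alt) {
  data.frame(chrom = "chr1", pos = pos, ref = ref, alt = alt,
             vtype = if (nchar(ref) == 1 && nchar(alt) == 1) "SNV" else "INDEL",
             genotype = "het", qual = 30, vcf_index = 1L,
             multiallelic = FALSE, stringsAsFactors = FALSE)
}

test_that("SNV tagging reads the aligned base, third alleles are no-calls", {
  s <- site_row(105, "A", "G")
  rd <- aln(101, "10M", "CCCCGCCCCC")        # base G at pos 105
  expect_equal(as.integer(tag_read_at_site(rd, s)), 1L)
  rd0 <- aln(101, "10M", "CCCCACCCCC")       # ref base A
  expect_equal(as.integer(tag_read_at_site(rd0, s)), 0L)
  rd3 <- aln(101, "10M", "CCCCTCCCCC")       # third allele
  expect_true(is.na(tag_read_at_site(rd3, s)))
  # low base quality masks the call
  low <- aln(101, "10M", "CCCCGCCCCC", qual = 3L)
  expect_true(is.na(tag_read_at_site(low, s, tagging_config(min_baseq = 7))))
  # soft clips and deletions shift/remove the aligned base
  clip <- aln(103, "2S8M", "TTCCGCCCCC")     # pos 105 -> read offset 5
  expect_equal(as.integer(tag_read_at_site(clip, s)), 1L)
  del <- aln(101, "4M2D6M", "CCCCCCCCCC")    # pos 105 deleted
  expect_true(is.na(tag_read_at_site(del, s)))
})

test_that("INDEL tagging compares the CIGAR-implied locus sequence to the allele paths", {
  del_site <- site_row(110, "ACC", "A")
  # read spanning with the 2bp deletion -> ALT
  rd_alt <- aln(100, "11M2D9M", "GGGGGGGGGGAGGGGGGGGG")
  expect_equal(as.integer(tag_read_at_site(rd_alt, del_site)), 1L)
  # plain match across the locus -> REF
  rd_ref <- aln(100, "22M", "GGGGGGGGGGACCGGGGGGGG")
  expect_equal(as.integer(tag_read_at_site(rd_ref, del_site)), 0L)
  # a different deletion length is neither path -> no call
  rd_odd <- aln(100, "11M1D10M", "GGGGGGGGGGAGGGGGGGGG")
  expect_true(is.na(tag_read_at_site(rd_odd, del_site)))

  ins_site <- site_row(110, "A", "ATT")
  rd_ins <- aln(100, "11M2I9M", "GGGGGGGGGGATTGGGGGGGG")
  expect_equal(as.integer(tag_read_at_site(rd_ins, ins_site)), 1L)
  rd_noins <- aln(100, "20M", "GGGGGGGGGGAGGGGGGGGG")
  expect_equal(as.integer(tag_read_at_site(rd_noins, ins_site)), 0L)
})

test_that("reads not spanning an INDEL locus with flanks make no call", {
  del_site <- site_row(110, "ACC", "A")
  cfg <- tagging_config(require_full_span_bp = 5)
  # alignment ends 3bp past the locus: not enough right flank
  short <- aln(100, "16M", "GGGGGGGGGGACCGGG")
  expect_true(is.na(tag_read_at_site(short, del_site, cfg)))
  # starts 2bp before the locus: not enough left flank
  late <- aln(108, "15M", "GGACCGGGGGGGGGG")
  expect_true(is.na(tag_read_at_site(late, del_site, cfg)))
  # with a 1bp requirement the same reads are taggable
  cfg1 <- tagging_config(require_full_span_bp = 1)
  expect_equal(as.integer(tag_read_at_site(short, del_site, cfg1)), 0L)
})

test_that("BAM extraction reproduces the simulated truth matrix at error rate 0", {
  sim <- simulate_phasing(sim_config(
    n_true_sites = 30, n_fp_sites = 6, region_length = 1.5e5, coverage = 10,
    read_length_mean = 12000, allele_error_rate = 0, seed = 19))
  d <- tempfile()
  paths <- emit_fixtures(sim, d)
  fm <- extract_fragment_matrix(paths$bam, read_vcf(paths$vcf))
  key <- function(m) m$calls[order(m$calls$read_id, m$calls$vcf_index),
                             c("read_id", "vcf_index", "allele")]
  a <- key(sim$truth_fm)
  b <- key(fm)
  rownames(a) <- rownames(b) <- NULL
  expect_identical(a, b)
})

test_that("extraction validates index and contig names, and filters by MAPQ", {
  sim <- simulate_phasing(sim_config(
    n_true_sites = 10, n_fp_sites = 0, region_length = 6e4, coverage = 6,
    read_length_mean = 10000, allele_error_rate = 0, seed = 3))
  d <- tempfile()
  paths <- emit_fixtures(sim, d)
  sites <- read_vcf(paths$vcf)

  noidx <- file.path(d, "noindex.bam")
  file.copy(paths$bam, noidx)
  expect_error(extract_fragment_matrix(noidx, sites), "index")

  bad <- sites
  bad$chrom <- "chrZ"
  expect_error(extract_fragment_matrix(paths$bam, bad), "chrZ")

  # impossibly high MAPQ threshold removes every call
  fm_hi <- extract_fragment_matrix(paths$bam, sites,
                                   tagging_config(min_mapq = 99))
  expect_equal(nrow(fm_hi$calls), 0L)

  # raising min_baseq never adds calls (monotone subset)
  fm_lo <- extract_fragment_matrix(paths$bam, sites,
                                   tagging_config(min_baseq = 0))
  fm_hi_bq <- extract_fragment_matrix(paths$bam, sites,
                                      tagging_config(min_baseq = 35))
  k <- function(m) paste(m$calls$read_id, m$calls$vcf_index)
  expect_true(all(k(fm_hi_bq) %in% k(fm_lo)))
})
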