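test_that("filter_config enforces ordered thresholds", {
  expect_error(filter_config(p1 = 0.8, p2 = 0.7, p3 = 0.9), "p1 < p2 < p3")
  expect_error(filter_config(p1 = 0.4, p2 = 0.8, p3 = 0.9), "p1 < p2 < p3")
  expect_error(filter_config(p1 = 0.7, p2 = 0.8, p3 = 1.1), "p1 < p2 < p3")
  expect_s3_class(filter_config(), "filter_config")
})

test_that("mode mask selects INDELs or all het biallelic sites", {
  sites <- snv_sites(3)
  sites$vtype <- c("SNV", "INDEL", "SNV")
  expect_equal(apply_mode_mask(sites, "indels_only"), c(FALSE, TRUE, FALSE))
  expect_equal(apply_mode_mask(sites, "all_variants"), rep(TRUE, 3))
  expect_equal(apply_mode_mask(sites[0, ], "indels_only"), logical(0))
})

test_that("an injected haplotype-independent site is removed and true sites survive", {
  # 4 true het sites in perfect cis/trans over 30 reads; site 3 is a planted
  # false call with haplotype-independent alleles
  set.seed(42)
  hap <- rep(0:1, 15)
  patt <- vapply(seq_along(hap), function(r) {
    t <- as.character(hap[r])
    f <- as.character(rbinom(1, 1, 0.5))
    paste0(t, t, f, t, t)
  }, "")
  fm <- pattern_fm(patt)
  vf <- filter_variants(fm, filter_config(mode = "all_variants"))
  expect_false(vf$decisions$kept[3])
  expect_true(all(vf$decisions$kept[c(1, 2, 4, 5)]))
  # after removal and recomputation the survivors are perfectly consistent
  expect_equal(vf$summaries$mean_score, rep(1, 4))
  pr <- precision_recall(vf, data.frame(vcf_index = 1:5,
                                        label = c("true", "true", "fp",
                                                  "true", "true")))
  expect_equal(c(pr$tp, pr$fp, pr$fn), c(4, 0, 0))
})

test_that("zero-pair sites fall back to the QUAL threshold at 15", {
  sites <- snv_sites(3)
  sites$qual <- c(30, 30, 20)
  # site 3 never co-covered
  fm <- pattern_fm(c("00.", "11.", "00.", "11.", "00.", "11."), sites = sites,
                   drop_singletons = FALSE)
  vf <- filter_variants(fm, filter_config(mode = "all_variants"))
  expect_true(vf$decisions$kept[3])                   # qual 20 >= 15 rescued
  expect_equal(vf$decisions$reason[3], "kept")

  sites$qual[3] <- 10
  fm <- pattern_fm(c("00.", "11.", "00.", "11.", "00.", "11."), sites = sites,
                   drop_singletons = FALSE)
  vf <- filter_variants(fm, filter_config(mode = "all_variants"))
  expect_false(vf$decisions$kept[3])                  # qual 10 < 15 removed
  expect_equal(vf$decisions$reason[3], "qual_fallback_removed")

  # missing QUAL counts as 0: removed
  sites$qual[3] <- NA
  fm <- pattern_fm(c("00.", "11.", "00.", "11.", "00.", "11."), sites = sites,
                   drop_singletons = FALSE)
  vf <- filter_variants(fm, filter_config(mode = "all_variants"))
  expect_false(vf$decisions$kept[3])
})

test_that("mutually perfect sites see zero removals at every step", {
  fm <- pattern_fm(rep(c("0101", "1010"), 8))
  vf <- filter_variants(fm, filter_config(mode = "all_variants"))
  expect_true(all(vf$decisions$kept))
  expect_equal(unique(vf$decisions$reason), "kept")
})

test_that("indels_only mode never removes an SNV but still pairs through them", {
  set.seed(7)
  sites <- snv_sites(5)
  sites$vtype <- c("SNV", "INDEL", "SNV", "INDEL", "SNV")
  sites$ref[c(2, 4)] <- "AT"
  hap <- rep(0:1, 20)
  patt <- vapply(seq_along(hap), function(r) {
    t <- as.character(hap[r])
    f <- as.character(rbinom(1, 1, 0.5))       # site 2: false INDEL
    paste0(t, f, t, t, t)
  }, "")
  fm <- pattern_fm(patt, sites = sites)
  vf <- filter_variants(fm, filter_config(mode = "indels_only"))
  removed <- vf$decisions[!vf$decisions$kept, ]
  expect_true(all(vf$sites$vtype[removed$vcf_index] == "INDEL"))
  expect_false(vf$decisions$kept[2])
  expect_true(vf$decisions$kept[4])
})

test_that("unscored records pass through and are labeled", {
  p <- write_mini_vcf(c(
    vcf_rec("chr1", 100, "A", "G", 30, "0/1"),
    vcf_rec("chr1", 200, "C", "T", 30, "1/1"),
    vcf_rec("chr1", 300, "G", "A,T", 30, "1/2"),
    vcf_rec("chr1", 400, "T", "C", 30, "0/1")
  ))
  sites <- read_vcf(p)
  calls <- data.frame(frag = rep(1:6, each = 2), read_id = rep(paste0("r", 1:6), each = 2),
                      vcf_index = rep(c(1L, 4L), 6),
                      allele = rep(c(0L, 0L), 6), qual = 30L)
  fm <- fragment_matrix(sites, calls)
  vf <- filter_variants(fm, filter_config(mode = "all_variants"))
  expect_equal(vf$decisions$reason,
               c("kept", "unscored_passthrough", "unscored_multiallelic", "kept"))
  expect_true(all(vf$decisions$kept))
})

test_that("decisions are deterministic and kept sets shrink monotonically per step", {
  sim <- simulate_phasing(sim_config(n_true_sites = 60, n_fp_sites = 15,
                                     region_length = 4e5, coverage = 20,
                                     read_length_mean = 20000, seed = 77))
  cfg <- filter_config(mode = "all_variants")
  v1 <- filter_variants(sim$fm, cfg)
  v2 <- filter_variants(sim$fm, cfg)
  expect_identical(v1$decisions, v2$decisions)

  # survivor sets nest across steps: every site active at step k+1 was active at k
  act <- lapply(v1$steps, function(s) s$vcf_index)
  expect_true(all(act[[2]] %in% act[[1]]))
  expect_true(all(act[[3]] %in% act[[2]]))
  expect_true(all(v1$summaries$vcf_index %in% act[[3]]))

  # for fixed summaries, raising a threshold removes a superset at that step
  s1 <- v1$steps[[1]]
  judged <- s1[s1$sufficient_coverage, ]
  rm_lo <- judged$vcf_index[judged$max_score <= 0.6]
  rm_hi <- judged$vcf_index[judged$max_score <= 0.75]
  expect_true(all(rm_lo %in% rm_hi))
})
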