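# In-code fixture builders.

# minimal het-SNV site table with n sites at positions 100, 200, ...
snv_sites <- function(n, qual = 30) {
  data.frame(chrom = "chr1", pos = 100L * seq_len(n), ref = "A", alt = "G",
             vtype = "SNV", genotype = "het",
             qual = rep_len(qual, n), vcf_index = seq_len(n),
             multiallelic = FALSE, stringsAsFactors = FALSE)
}

# fragment matrix from read allele patterns: one string per read over the
# sites, characters 0/1 or "." for no call; e.g. c("01", "10", "0.")
pattern_fm <- function(patterns, sites = NULL, qual = 30, drop_singletons = TRUE) {
  ns <- nchar(patterns[1L])
  if (is.null(sites)) sites <- snv_sites(ns, qual = qual)
  calls <- do.call(rbind, lapply(seq_along(patterns), function(r) {
    ch <- strsplit(patterns[r], "")[[1L]]
    keep <- ch != "."
    if (!any(keep)) return(NULL)
    data.frame(frag = r, read_id = sprintf("read%03d", r),
               vcf_index = which(keep), allele = as.integer(ch[keep]),
               qual = 30L, stringsAsFactors = FALSE)
  }))
  fragment_matrix(sites, calls, drop_singletons = drop_singletons)
}

# random fragment matrix for property tests
random_fm <- function(seed, max_sites = 10L, max_reads = 50L) {
  set.seed(seed)
  ns <- sample(2:max_sites, 1L)
  nr <- sample(2:max_reads, 1L)
  calls <- do.call(rbind, lapply(seq_len(nr), function(r) {
    k <- sample(0:ns, 1L)
    if (k == 0L) return(NULL)
    idx <- sort(sample(ns, k))
    data.frame(frag = r, read_id = sprintf("r%03d", r), vcf_index = idx,
               allele = rbinom(k, 1L, 0.5), qual = 30L,
               stringsAsFactors = FALSE)
  }))
  if (is.null(calls)) calls <- phasefilt:::empty_calls()
  fragment_matrix(snv_sites(ns), calls)
}

# write a small VCF; records = character vector of tab-joined record lines
write_mini_vcf <- function(records, path = tempfile(fileext = ".vcf"),
                           sample = "S1") {
  writeLines(c("##fileformat=VCFv4.2",
               "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
               paste0("#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\t",
                      sample),
               records), path)
  path
}

vcf_rec <- function(chrom, pos, ref, alt, qual, gt, fmt = "GT") {
  paste(chrom, pos, ".", ref, alt, qual, "PASS", ".", fmt, gt, sep = "\t")
}
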