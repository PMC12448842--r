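# Truth-labeled synthetic data: a diploid individual over one chromosome,
# het variant sites (SNVs and short INDELs), long reads drawn from either
# haplotype, and two classes of planted artifacts:
#   * haplotype-independent false sites -- each read shows ALT with
#     probability fp_alt_prob regardless of haplotype (the worst case for
#     co-segregation, what the consistency filter is built to catch);
#   * "hom-as-het" false sites -- every read carries ALT (plus noise).  These
#     are perfectly self-consistent and therefore NOT removable by a
#     consistency criterion; they exist to document that limitation.

#' Simulation configuration
#'
#' Defaults emulate a nanopore-style experiment: ~25 kb reads at 30-fold
#' coverage over a 1 Mb region, 200 true het sites plus 40 haplotype-
#' independent false calls, and a 5% per-call allele error rate (the lower
#' end of nanopore raw error, as seen by the tagger after base-quality
#' screening).
#'
#' @param n_true_sites,n_fp_sites,n_fp_hom_sites Counts of true het sites,
#'   haplotype-independent false sites, and hom-as-het false sites.
#' @param indel_fraction Fraction of sites (of every class) that are INDELs.
#' @param region_length Chromosome length in bp.
#' @param coverage Fold coverage (determines read count).
#' @param read_length_mean Mean read length (bp); lengths are
#'   `Normal(mean, 0.1 mean)` truncated below.
#' @param allele_error_rate Probability that a read's call at a true (or
#'   hom-as-het) site is flipped.
#' @param fp_alt_prob Probability a read shows ALT at a false site.
#' @param qual_true,qual_fp `c(mean, sd)` of the Normal used for VCF QUAL of
#'   true and false sites (truncated at 1).
#' @param min_site_gap Minimum bp between sites (keeps INDEL loci disjoint).
#' @param indel_flank Bases a read must span past both ends of an INDEL locus
#'   for the simulator to emit a call there (mirrors the tagger's
#'   `require_full_span_bp`).
#' @param seed Integer seed; a seeded run is bit-reproducible.
#' @return A `sim_config` list.
#' @export
sim_config <- function(n_true_sites = 200L, n_fp_sites = 40L,
                       n_fp_hom_sites = 0L, indel_fraction = 0.25,
                       region_length = 1e6, coverage = 30,
                       read_length_mean = 25000,
                       allele_error_rate = 0.05, fp_alt_prob = 0.5,
                       qual_true = c(30, 8), qual_fp = c(10, 6),
                       min_site_gap = 50L, indel_flank = 5L, seed = NULL) {
  stopifnot(allele_error_rate >= 0, allele_error_rate <= 1,
            fp_alt_prob >= 0, fp_alt_prob <= 1,
            indel_fraction >= 0, indel_fraction <= 1,
            coverage > 0, read_length_mean > 0)
  structure(as.list(environment()), class = "sim_config")
}

#' Simulate a phased diploid dataset
#'
#' @param config A [sim_config()].
#' @return An object of class `phasing_sim`: list with `sites` (VCF-style
#'   table, all GT 0/1), `fm` (observed [fragment_matrix()]), `truth_fm`
#'   (calls before error injection), `truth` (per-site `label` in
#'   `{"true","fp","fp_hom"}` and `alt_hap` in `{1,2}`, `NA` for false
#'   sites), `reads` (read windows and haplotypes), `calls`/`truth_calls`
#'   (long call tables over all reads) and `refseq` (character).
#' @export
simulate_phasing <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  if (!is.null(config$seed)) set.seed(config$seed)
  L <- as.integer(config$region_length)
  n <- config$n_true_sites + config$n_fp_sites + config$n_fp_hom_sites
  gap <- as.integer(config$min_site_gap)
  margin <- 200L
  avail <- L - 2L * margin - (n - 1L) * gap
  if (avail < n) {
    stop("region too small for ", n, " sites with minimum gap ", gap)
  }
  pos <- margin + sort(sample.int(avail, n)) + (seq_len(n) - 1L) * gap

  refseq <- sample(c("A", "C", "G", "T"), L, replace = TRUE)

  label <- rep("true", n)
  label[sample.int(n, config$n_fp_sites + config$n_fp_hom_sites)] <-
    rep(c("fp", "fp_hom"), c(config$n_fp_sites, config$n_fp_hom_sites))
  is_indel <- runif(n) < config$indel_fraction

  ref <- alt <- character(n)
  for (i in seq_len(n)) {
    base <- refseq[pos[i]]
    if (!is_indel[i]) {
      ref[i] <- base
      alt[i] <- sample(setdiff(c("A", "C", "G", "T"), base), 1L)
    } else if (runif(1) < 0.5) {  # deletion
      k <- sample(1:4, 1L)
      ref[i] <- paste(refseq[pos[i]:(pos[i] + k)], collapse = "")
      alt[i] <- base
    } else {                      # insertion
      k <- sample(1:4, 1L)
      ref[i] <- base
      alt[i] <- paste(c(base, sample(c("A", "C", "G", "T"), k, replace = TRUE)),
                      collapse = "")
    }
  }
  alt_hap <- ifelse(label == "true", sample(1:2, n, replace = TRUE), NA)
  qmu <- ifelse(label == "true", config$qual_true[1L], config$qual_fp[1L])
  qsd <- ifelse(label == "true", config$qual_true[2L], config$qual_fp[2L])
  qual <- pmax(1, round(rnorm(n, qmu, qsd), 1))

  sites <- data.frame(
    chrom = "chr1", pos = pos, ref = ref, alt = alt,
    vtype = ifelse(is_indel, "INDEL", "SNV"), genotype = "het",
    qual = qual, vcf_index = seq_len(n), multiallelic = FALSE,
    stringsAsFactors = FALSE
  )

  # reads
  n_reads <- max(1L, round(config$coverage * L / config$read_length_mean))
  start <- sample.int(L, n_reads, replace = TRUE)
  len <- pmax(200L, round(rnorm(n_reads, config$read_length_mean,
                                0.1 * config$read_length_mean)))
  end <- pmin(L, start + len - 1L)
  hap <- sample(1:2, n_reads, replace = TRUE)
  reads <- data.frame(read_id = sprintf("read%05d", seq_len(n_reads)),
                      start = start, end = end, hap = hap,
                      stringsAsFactors = FALSE)

  reflen <- nchar(ref)
  flank <- as.integer(config$indel_flank)
  lo_need <- ifelse(is_indel, pos - flank, pos)
  hi_need <- ifelse(is_indel, pos + reflen - 1L + flank, pos)

  obs <- truth <- vector("list", n_reads)
  for (r in seq_len(n_reads)) {
    cov <- which(lo_need >= start[r] & hi_need <= end[r])
    if (length(cov) == 0L) next
    a_true <- integer(length(cov))
    for (jj in seq_along(cov)) {
      s <- cov[jj]
      a_true[jj] <- switch(label[s],
        true = as.integer(hap[r] == alt_hap[s]),
        fp = rbinom(1L, 1L, config$fp_alt_prob),
        fp_hom = 1L)
    }
    flip <- label[cov] %in% c("true", "fp_hom") &
      runif(length(cov)) < config$allele_error_rate
    a_obs <- ifelse(flip, 1L - a_true, a_true)
    truth[[r]] <- data.frame(frag = r, read_id = reads$read_id[r],
                             vcf_index = cov, allele = a_true, qual = 30L,
                             stringsAsFactors = FALSE)
    obs[[r]] <- data.frame(frag = r, read_id = reads$read_id[r],
                           vcf_index = cov, allele = a_obs, qual = 30L,
                           stringsAsFactors = FALSE)
  }
  obs <- if (length(obs)) do.call(rbind, obs) else empty_calls()
  truth <- if (length(truth)) do.call(rbind, truth) else empty_calls()

  structure(
    list(sites = sites,
         fm = suppressWarnings(fragment_matrix(sites, obs)),
         truth_fm = suppressWarnings(fragment_matrix(sites, truth)),
         truth = data.frame(vcf_index = seq_len(n), pos = pos, label = label,
                            alt_hap = alt_hap, stringsAsFactors = FALSE),
         reads = reads, calls = obs, truth_calls = truth,
         refseq = paste(refseq, collapse = ""), config = config),
    class = "phasing_sim"
  )
}

#' @export
print.phasing_sim <- function(x, ...) {
  cat("phasing_sim:", nrow(x$sites), "sites (",
      sum(x$truth$label == "true"), "true /", sum(x$truth$label == "fp"),
      "fp /", sum(x$truth$label == "fp_hom"), "fp_hom ),",
      nrow(x$reads), "reads over", nchar(x$refseq), "bp\n")
  invisible(x)
}

#' Write simulator output as on-disk fixtures
#'
#' Emits a toy reference FASTA, a VCF (GT 0/1, simulated QUALs), a fragment
#' file, a truth TSV and a coordinate-sorted indexed BAM whose CIGARs and
#' sequences encode each read's observed alleles, so that
#' [extract_fragment_matrix()] on the fixtures reproduces the simulated
#' matrix when `allele_error_rate = 0`.
#'
#' @param sim A [simulate_phasing()] result.
#' @param out_dir Output directory (created if needed).
#' @return Named list of paths (`fasta`, `vcf`, `fragments`, `truth`, `bam`,
#'   `sam`).
#' @export
emit_fixtures <- function(sim, out_dir) {
  stopifnot(inherits(sim, "phasing_sim"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  L <- nchar(sim$refseq)

  fasta <- file.path(out_dir, "ref.fa")
  dna <- Biostrings::DNAStringSet(sim$refseq)
  names(dna) <- "chr1"
  Biostrings::writeXStringSet(dna, fasta)

  vcf <- file.path(out_dir, "sim.vcf")
  s <- sim$sites
  writeLines(c(
    "##fileformat=VCFv4.2",
    sprintf("##contig=<ID=chr1,length=%d>", L),
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\tSIM",
    sprintf("chr1\t%d\t.\t%s\t%s\t%s\tPASS\t.\tGT\t0/1",
            s$pos, s$ref, s$alt, format(s$qual, trim = TRUE))
  ), vcf)

  frag <- file.path(out_dir, "fragments.txt")
  write_fragment_file(sim$fm, frag)

  truth <- file.path(out_dir, "truth.tsv")
  write.table(sim$truth, truth, sep = "\t", quote = FALSE, row.names = FALSE)

  sam <- file.path(out_dir, "reads.sam")
  emit_sam(sim, sam)
  bam <- Rsamtools::asBam(sam, file.path(out_dir, "reads"),
                          overwrite = TRUE, indexDestination = TRUE)

  list(fasta = fasta, vcf = vcf, fragments = frag, truth = truth,
       bam = bam, sam = sam)
}

emit_sam <- function(sim, path) {
  refchars <- strsplit(sim$refseq, "")[[1L]]
  s <- sim$sites
  reads <- sim$reads
  o <- order(reads$start)
  recs <- character(nrow(reads))
  for (k in seq_len(nrow(reads))) {
    r <- o[k]
    calls <- sim$calls[sim$calls$frag == r & sim$calls$allele == 1L, , drop = FALSE]
    vars <- s[calls$vcf_index, , drop = FALSE]
    built <- build_read_alignment(refchars, reads$start[r], reads$end[r], vars)
    recs[k] <- paste(reads$read_id[r], 0L, "chr1", reads$start[r], 60L,
                     built$cigar, "*", 0L, 0L, built$seq,
                     strrep("?", nchar(built$seq)), sep = "\t")
  }
  writeLines(c("@HD\tVN:1.6\tSO:coordinate",
               sprintf("@SQ\tSN:chr1\tLN:%d", nchar(sim$refseq)),
               recs), path)
}

# build SEQ/CIGAR for one read carrying the ALT allele at `vars`
build_read_alignment <- function(refchars, wstart, wend, vars) {
  vars <- vars[order(vars$pos), , drop = FALSE]
  parts <- character(0)
  ops <- character(0)
  lens <- integer(0)
  push <- function(op, len) {
    if (len > 0L) {
      ops <<- c(ops, op)
      lens <<- c(lens, len)
    }
  }
  cur <- wstart
  for (i in seq_len(nrow(vars))) {
    p <- vars$pos[i]
    rl <- nchar(vars$ref[i])
    al <- nchar(vars$alt[i])
    if (rl == 1L && al == 1L) {            # SNV substitution
      if (p > cur) parts <- c(parts, paste(refchars[cur:(p - 1L)], collapse = ""))
      parts <- c(parts, vars$alt[i])
      push("M", p - cur + 1L)
      cur <- p + 1L
    } else if (rl > al) {                  # deletion (alt = anchor base)
      parts <- c(parts, paste(refchars[cur:p], collapse = ""))
      push("M", p - cur + 1L)
      push("D", rl - 1L)
      cur <- p + rl
    } else {                               # insertion after anchor base
      parts <- c(parts, paste(refchars[cur:p], collapse = ""),
                 substr(vars$alt[i], 2L, al))
      push("M", p - cur + 1L)
      push("I", al - 1L)
      cur <- p + 1L
    }
  }
  if (cur <= wend) {
    parts <- c(parts, paste(refchars[cur:wend], collapse = ""))
    push("M", wend - cur + 1L)
  }
  # merge adjacent identical ops
  keep_ops <- character(0)
  keep_lens <- integer(0)
  for (j in seq_along(ops)) {
    if (j > 1L && ops[j] == keep_ops[length(keep_ops)]) {
      keep_lens[length(keep_lens)] <- keep_lens[length(keep_lens)] + lens[j]
    } else {
      keep_ops <- c(keep_ops, ops[j])
      keep_lens <- c(keep_lens, lens[j])
    }
  }
  list(seq = paste(parts, collapse = ""),
       cigar = paste0(keep_lens, keep_ops, collapse = ""))
}
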