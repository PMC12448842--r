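# Read tagging: decide, per alignment x het site, whether the read carries
# REF (0), ALT (1) or makes no usable call.  All genomic arithmetic below is
# on 1-based VCF coordinates; CIGAR walking keeps separate reference and
# query cursors.

#' Tagging configuration
#'
#' @param min_mapq Minimum mapping quality for an alignment to contribute.
#' @param min_baseq Minimum base quality for a call (SNV base; all read bases
#'   inside an INDEL locus).
#' @param require_full_span_bp Flanking bases a read must align past both ends
#'   of an INDEL locus to be tagged there; short partial overlaps cannot
#'   distinguish the alleles.
#' @param skip_flags Alignment classes to skip; subset of
#'   `c("secondary", "supplementary", "duplicate", "qcfail")`.
#' @return A `tagging_config` list.
#' @export
tagging_config <- function(min_mapq = 20L, min_baseq = 7L,
                           require_full_span_bp = 5L,
                           skip_flags = c("secondary", "supplementary",
                                          "duplicate", "qcfail")) {
  stopifnot(min_mapq >= 0L, require_full_span_bp >= 1L,
            all(skip_flags %in% c("secondary", "supplementary",
                                  "duplicate", "qcfail")))
  structure(list(min_mapq = as.integer(min_mapq),
                 min_baseq = as.integer(min_baseq),
                 require_full_span_bp = as.integer(require_full_span_bp),
                 skip_flags = skip_flags),
            class = "tagging_config")
}

# explode a CIGAR string into op letters and lengths
parse_cigar <- function(cigar) {
  toks <- regmatches(cigar, gregexpr("[0-9]+[MIDNSHP=X]", cigar))[[1L]]
  list(op = substr(toks, nchar(toks), nchar(toks)),
       len = as.integer(substr(toks, 1L, nchar(toks) - 1L)))
}

cigar_ref_span <- function(cigar) {
  cg <- parse_cigar(cigar)
  sum(cg$len[cg$op %in% c("M", "D", "N", "=", "X")])
}

#' Tag one alignment at one heterozygous site
#'
#' SNV: the read base aligned at the site position decides (REF base -> 0,
#' ALT base -> 1, any third base, deletion or low base quality -> no call).
#' INDEL: the read must align at least `require_full_span_bp` past both ends
#' of the REF allele span; the CIGAR-implied read sequence over the locus
#' (aligned bases over `[pos, pos + nchar(ref))` plus insertions anchored
#' inside it) must match the REF or ALT allele string exactly, anything else
#' is no call.
#'
#' @param aln A list with elements `pos` (1-based leftmost aligned position),
#'   `cigar`, `seq` (read sequence, character) and `qual` (integer Phred
#'   vector, one per read base).
#' @param site One row of a [read_vcf()] table (het biallelic).
#' @param config A [tagging_config()].
#' @return Integer `0`/`1`, or `NA` for no call, with attribute `"qual"`
#'   (Phred quality attached to the call).
#' @export
tag_read_at_site <- function(aln, site, config = tagging_config()) {
  pos <- site$pos
  ref <- site$ref
  alt <- site$alt
  reflen <- nchar(ref)
  cg <- parse_cigar(aln$cigar)
  none <- structure(NA_integer_, qual = NA_integer_)

  if (site$vtype == "SNV") {
    hit <- query_offset_at(cg, aln$pos, pos)
    if (is.na(hit)) return(none)
    base <- substr(aln$seq, hit, hit)
    bq <- aln$qual[hit]
    if (is.na(bq) || bq < config$min_baseq) return(none)
    if (base == ref) return(structure(0L, qual = bq))
    if (base == alt) return(structure(1L, qual = bq))
    return(none)
  }

  # INDEL: full-span requirement
  span <- config$require_full_span_bp
  ref_end <- aln$pos + cigar_ref_span(aln$cigar) - 1L
  if (aln$pos > pos - span || ref_end < pos + reflen - 1L + span) return(none)
  imp <- implied_sequence(cg, aln$pos, aln$seq, aln$qual, pos, pos + reflen - 1L)
  if (length(imp$qual) && any(imp$qual < config$min_baseq)) return(none)
  q <- if (length(imp$qual)) min(imp$qual) else 30L
  if (imp$seq == ref) return(structure(0L, qual = as.integer(q)))
  if (imp$seq == alt) return(structure(1L, qual = as.integer(q)))
  none
}

# query offset (1-based in read) of the base aligned to reference `pos`,
# NA if pos falls in a deletion/intron or outside the alignment
query_offset_at <- function(cg, aln_start, pos) {
  r <- aln_start
  q <- 1L
  for (k in seq_along(cg$op)) {
    op <- cg$op[k]
    len <- cg$len[k]
    if (op %in% c("M", "=", "X")) {
      if (pos < r + len && pos >= r) return(q + (pos - r))
      r <- r + len
      q <- q + len
    } else if (op %in% c("D", "N")) {
      if (pos < r + len && pos >= r) return(NA_integer_)
      r <- r + len
    } else if (op %in% c("I", "S")) {
      q <- q + len
    }
  }
  NA_integer_
}

# read sequence implied over reference window [wstart, wend]: bases aligned to
# positions in the window plus insertions anchored after a base inside it
implied_sequence <- function(cg, aln_start, seq, qual, wstart, wend) {
  r <- aln_start
  q <- 1L
  parts <- character(0)
  quals <- integer(0)
  for (k in seq_along(cg$op)) {
    op <- cg$op[k]
    len <- cg$len[k]
    if (op %in% c("M", "=", "X")) {
      lo <- max(r, wstart)
      hi <- min(r + len - 1L, wend)
      if (lo <= hi) {
        qs <- q + (lo - r)
        parts <- c(parts, substr(seq, qs, qs + (hi - lo)))
        quals <- c(quals, qual[qs:(qs + (hi - lo))])
      }
      r <- r + len
      q <- q + len
    } else if (op %in% c("D", "N")) {
      r <- r + len
    } else if (op == "I") {
      # insertion sits between r-1 and r
      if ((r - 1L) >= wstart && (r - 1L) <= wend) {
        parts <- c(parts, substr(seq, q, q + len - 1L))
        quals <- c(quals, qual[q:(q + len - 1L)])
      }
      q <- q + len
    } else if (op == "S") {
      q <- q + len
    }
  }
  list(seq = paste(parts, collapse = ""), qual = quals)
}

#' Extract a fragment matrix from a BAM file
#'
#' Tags every kept primary alignment at every het biallelic site it overlaps
#' and assembles the resulting 0/1 calls into a [fragment_matrix()]. Output is
#' deterministic given identical inputs (alignments are visited in coordinate
#' order).
#'
#' @param bam_path Coordinate-sorted, indexed BAM.
#' @param sites Site table from [read_vcf()].
#' @param config A [tagging_config()].
#' @return A [fragment_matrix()].
#' @export
extract_fragment_matrix <- function(bam_path, sites, config = tagging_config()) {
  if (!file.exists(bam_path)) stop("BAM not found: ", bam_path)
  bai <- paste0(bam_path, ".bai")
  bai2 <- sub("\\.bam$", ".bai", bam_path)
  if (!file.exists(bai) && !file.exists(bai2)) {
    stop("BAM index (.bai) not found for ", bam_path)
  }
  targets <- Rsamtools::scanBamHeader(bam_path)[[1L]]$targets
  scored <- sites[scorable_mask(sites), , drop = FALSE]
  if (nrow(scored) == 0L) return(fragment_matrix(sites, empty_calls()))
  missing_chroms <- setdiff(unique(scored$chrom), names(targets))
  if (length(missing_chroms)) {
    stop("VCF contigs absent from BAM header: ",
         paste(missing_chroms, collapse = ", "))
  }

  skip <- config$skip_flags
  flag <- Rsamtools::scanBamFlag(
    isUnmappedQuery = FALSE,
    isSecondaryAlignment = if ("secondary" %in% skip) FALSE else NA,
    isSupplementaryAlignment = if ("supplementary" %in% skip) FALSE else NA,
    isDuplicate = if ("duplicate" %in% skip) FALSE else NA,
    isNotPassingQualityControls = if ("qcfail" %in% skip) FALSE else NA
  )
  param <- Rsamtools::ScanBamParam(
    what = c("qname", "rname", "pos", "mapq", "cigar", "seq", "qual"),
    flag = flag
  )
  bm <- Rsamtools::scanBam(bam_path, param = param)[[1L]]
  n <- length(bm$qname)
  chrom_of <- as.character(bm$rname)
  seqs <- as.character(bm$seq)
  quals <- as(bm$qual, "IntegerList")

  calls <- vector("list", n)
  for (i in seq_len(n)) {
    if (is.na(bm$mapq[i]) || bm$mapq[i] < config$min_mapq) next
    if (is.na(bm$pos[i]) || is.na(bm$cigar[i])) next
    start <- bm$pos[i]
    end <- start + cigar_ref_span(bm$cigar[i]) - 1L
    cand <- scored[scored$chrom == chrom_of[i] &
                     scored$pos >= start & scored$pos <= end, , drop = FALSE]
    if (nrow(cand) == 0L) next
    aln <- list(pos = start, cigar = bm$cigar[i], seq = seqs[i],
                qual = as.integer(quals[[i]]))
    alle <- integer(0)
    qs <- integer(0)
    idx <- integer(0)
    for (s in seq_len(nrow(cand))) {
      tg <- tag_read_at_site(aln, cand[s, ], config)
      if (!is.na(tg)) {
        idx <- c(idx, cand$vcf_index[s])
        alle <- c(alle, as.integer(tg))
        qs <- c(qs, attr(tg, "qual"))
      }
    }
    if (length(idx)) {
      calls[[i]] <- data.frame(frag = i, read_id = bm$qname[i],
                               vcf_index = idx, allele = alle, qual = qs,
                               stringsAsFactors = FALSE)
    }
  }
  calls <- do.call(rbind, calls)
  if (is.null(calls)) calls <- empty_calls()
  fragment_matrix(sites, calls)
}
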