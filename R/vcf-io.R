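# VCF reading/writing.
#
# The filter must (a) index variants by their 1-based ordinal over ALL records
# of the file -- the index space HapCUT2 fragment files use -- and (b) emit
# kept record lines byte-identical to the input.  Both requirements are about
# the text of the file, so records are kept as parsed fields alongside their
# raw lines rather than loaded into a container that re-serializes them.

#' Read a VCF into a variant site table
#'
#' Parses a VCF 4.x file (plain or gzip/bgzip compressed) into one row per
#' record with the fields the consistency filter needs. `vcf_index` is the
#' 1-based ordinal of the record over the whole file, regardless of `region`,
#' so indices in HapCUT2-style fragment files remain valid after subsetting.
#'
#' @param path Path to a VCF file. The first sample column is used for GT.
#' @param region Optional `"chrom"` or `"chrom:start-end"` restriction applied
#'   to the returned rows (not to `vcf_index` assignment).
#' @return A `data.frame` with columns `chrom`, `pos`, `ref`, `alt`, `vtype`
#'   (`"SNV"`/`"INDEL"`), `genotype` (`"het"`/`"hom"`/`"other"`), `qual`
#'   (numeric, `NA` for "."), `vcf_index`, and `multiallelic` (logical).
#'   Het means exactly one REF and one ALT allele (0/1, 1/0, 0|1 or 1|0).
#' @examples
#' vcf <- tempfile(fileext = ".vcf")
#' writeLines(c("##fileformat=VCFv4.2",
#'   "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\tS1",
#'   "chr1\t100\t.\tA\tG\t30\tPASS\t.\tGT\t0/1"), vcf)
#' read_vcf(vcf)
#' @export
read_vcf <- function(path, region = NULL) {
  if (!file.exists(path)) stop("VCF not found: ", path)
  lines <- readLines(path, warn = FALSE)
  is_hdr <- startsWith(lines, "#")
  body <- lines[!is_hdr]
  if (length(body) == 0L) {
    return(empty_sites())
  }
  fields <- strsplit(body, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 10L)) {
    stop("VCF record ", which(nf < 10L)[1L],
         " has no FORMAT/sample columns (GT required)")
  }
  chrom <- vapply(fields, `[[`, "", 1L)
  pos <- as.integer(vapply(fields, `[[`, "", 2L))
  ref <- vapply(fields, `[[`, "", 4L)
  alt <- vapply(fields, `[[`, "", 5L)
  qual_chr <- vapply(fields, `[[`, "", 6L)
  format <- vapply(fields, `[[`, "", 9L)
  sample1 <- vapply(fields, `[[`, "", 10L)

  # sorted check: each chromosome one contiguous run, positions non-decreasing
  runs <- rle(chrom)
  if (anyDuplicated(runs$values)) {
    stop("VCF is not coordinate-sorted: chromosome ",
         runs$values[duplicated(runs$values)][1L], " appears in multiple runs")
  }
  bad <- which(diff(pos) < 0 & chrom[-1L] == chrom[-length(chrom)])
  if (length(bad)) {
    stop("VCF is not coordinate-sorted at record ", bad[1L] + 1L,
         " (", chrom[bad[1L] + 1L], ":", pos[bad[1L] + 1L], ")")
  }

  gt <- character(length(body))
  for (i in seq_along(body)) {
    keys <- strsplit(format[i], ":", fixed = TRUE)[[1L]]
    k <- match("GT", keys)
    if (is.na(k)) {
      stop("record ", i, " (", chrom[i], ":", pos[i], ") has no GT field")
    }
    gt[i] <- strsplit(sample1[i], ":", fixed = TRUE)[[1L]][k]
  }
  genotype <- rep("other", length(gt))
  genotype[gt %in% c("0/1", "1/0", "0|1", "1|0")] <- "het"
  genotype[gt %in% c("1/1", "1|1")] <- "hom"
  multiallelic <- grepl(",", alt, fixed = TRUE)

  vtype <- ifelse(nchar(ref) == 1L & nchar(alt) == 1L & !multiallelic,
                  "SNV", "INDEL")
  qual <- suppressWarnings(as.numeric(qual_chr))

  sites <- data.frame(
    chrom = chrom, pos = pos, ref = ref, alt = alt,
    vtype = vtype, genotype = genotype, qual = qual,
    vcf_index = seq_along(body), multiallelic = multiallelic,
    stringsAsFactors = FALSE
  )
  if (!is.null(region)) {
    sites <- sites[region_mask(sites, region), , drop = FALSE]
    rownames(sites) <- NULL
  }
  sites
}

empty_sites <- function() {
  data.frame(chrom = character(), pos = integer(), ref = character(),
             alt = character(), vtype = character(), genotype = character(),
             qual = numeric(), vcf_index = integer(),
             multiallelic = logical(), stringsAsFactors = FALSE)
}

region_mask <- function(sites, region) {
  m <- regmatches(region, regexec("^([^:]+)(?::([0-9]+)-([0-9]+))?$", region))[[1L]]
  if (length(m) == 0L) stop("cannot parse region: ", region)
  keep <- sites$chrom == m[2L]
  if (nzchar(m[3L])) {
    keep <- keep & sites$pos >= as.integer(m[3L]) & sites$pos <= as.integer(m[4L])
  }
  keep
}

# which rows of a site table enter consistency scoring
scorable_mask <- function(sites) {
  sites$genotype == "het" & !sites$multiallelic
}

#' Write a filtered VCF
#'
#' Copies the input VCF, deleting the records marked removed. The header is
#' preserved verbatim with one provenance line added, and kept record lines
#' are byte-identical to the input.
#'
#' @param decisions A decision table as returned in the `decisions` element of
#'   [filter_variants()] (columns `vcf_index`, `kept`), a logical vector over
#'   records in file order, or a `variant_filter` object.
#' @param in_path Input VCF path (the file that produced the decisions).
#' @param out_path Output path.
#' @return `out_path`, invisibly.
#' @export
write_filtered_vcf <- function(decisions, in_path, out_path) {
  if (inherits(decisions, "variant_filter")) decisions <- decisions$decisions
  if (is.data.frame(decisions)) {
    o <- order(decisions$vcf_index)
    keep <- decisions$kept[o]
    idx <- decisions$vcf_index[o]
  } else {
    keep <- as.logical(decisions)
    idx <- seq_along(keep)
  }
  lines <- readLines(in_path, warn = FALSE)
  is_hdr <- startsWith(lines, "#")
  body <- lines[!is_hdr]
  hdr <- lines[is_hdr]
  if (length(body) != length(keep) || !identical(idx, seq_along(body))) {
    stop("decisions do not cover every VCF record: ", length(body),
         " records, ", length(keep), " decisions")
  }
  prov <- sprintf("##consistency_filter=phasefilt %s; kept=%d/%d",
                  as.character(utils::packageVersion("phasefilt")),
                  sum(keep), length(keep))
  chrom_line <- startsWith(hdr, "#CHROM")
  if (any(chrom_line)) {
    k <- which(chrom_line)[1L]
    hdr <- append(hdr, prov, after = k - 1L)
  } else {
    hdr <- c(hdr, prov)
  }
  writeLines(c(hdr, body[keep]), out_path)
  invisible(out_path)
}

#' Write a per-site filtering report
#'
#' One TSV row per scored (het biallelic) site -- plus pass-through rows for
#' unscored records -- with the neighborhood consistency summary and the
#' decision that was applied.
#'
#' @param x A `variant_filter` object from [filter_variants()] or
#'   [consistency_filter()].
#' @param out_path Output TSV path.
#' @return The report `data.frame`, invisibly.
#' @export
write_report <- function(x, out_path) {
  stopifnot(inherits(x, "variant_filter"))
  rep <- x$report
  write.table(rep, out_path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(rep)
}
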