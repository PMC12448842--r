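# HapCUT2-style fragment files and the in-memory fragment matrix.
#
# A fragment line is whitespace-delimited:
#   <nblocks> <read_id> {<start_vcf_index> <allele_string>}*nblocks <qual_string>
# where allele strings are over {0,1}, a block starting at s with k alleles
# calls indices s, s+1, ..., s+k-1, and the quality string (Phred+33, one char
# per allele across all blocks, left to right) closes the line.

#' Read a HapCUT2-style fragment file
#'
#' @param path Path to a fragment file (e.g. extractHAIRS output in its basic
#'   form, or [write_fragment_file()] output).
#' @return A long-format `data.frame` with columns `frag` (1-based fragment
#'   ordinal in file order), `read_id`, `vcf_index`, `allele` (0/1 integer)
#'   and `qual` (Phred integer).
#' @export
read_fragment_file <- function(path) {
  if (!file.exists(path)) stop("fragment file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  out <- vector("list", length(lines))
  for (i in seq_along(lines)) {
    tok <- strsplit(trimws(lines[i]), "[[:space:]]+")[[1L]]
    nb <- suppressWarnings(as.integer(tok[1L]))
    if (is.na(nb) || nb < 1L || length(tok) != 2L + 2L * nb + 1L) {
      stop("malformed fragment line ", i, ": expected ", 2L + 2L * nb + 1L,
           " fields, got ", length(tok))
    }
    read_id <- tok[2L]
    starts <- as.integer(tok[seq(3L, by = 2L, length.out = nb)])
    alleles <- tok[seq(4L, by = 2L, length.out = nb)]
    if (any(grepl("[^01]", alleles))) {
      stop("fragment line ", i, " (", read_id, "): allele characters must be 0/1")
    }
    qual_str <- tok[length(tok)]
    total <- sum(nchar(alleles))
    if (nchar(qual_str) != total) {
      stop("fragment line ", i, " (", read_id, "): quality string length ",
           nchar(qual_str), " != allele count ", total)
    }
    idx <- unlist(lapply(seq_len(nb), function(b) {
      starts[b] + seq_len(nchar(alleles[b])) - 1L
    }))
    if (is.unsorted(idx, strictly = TRUE)) {
      stop("fragment line ", i, " (", read_id,
           "): vcf indices not strictly increasing")
    }
    out[[i]] <- data.frame(
      frag = i, read_id = read_id, vcf_index = idx,
      allele = as.integer(strsplit(paste(alleles, collapse = ""), "")[[1L]]),
      qual = utf8ToInt(qual_str) - 33L,
      stringsAsFactors = FALSE
    )
  }
  if (length(out) == 0L) return(empty_calls())
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

empty_calls <- function() {
  data.frame(frag = integer(), read_id = character(), vcf_index = integer(),
             allele = integer(), qual = integer(), stringsAsFactors = FALSE)
}

#' Write a fragment matrix to HapCUT2-style fragment format
#'
#' Consecutive `vcf_index` runs within a fragment are merged into blocks;
#' qualities are emitted Phred+33, capped at char `~`.
#'
#' @param fm A [fragment_matrix()] object.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fragment_file <- function(fm, path) {
  stopifnot(inherits(fm, "fragment_matrix"))
  calls <- fm$calls
  lines <- character(length(fm$read_id))
  for (f in seq_along(fm$read_id)) {
    cc <- calls[calls$frag == f, , drop = FALSE]
    cc <- cc[order(cc$vcf_index), , drop = FALSE]
    run <- cumsum(c(1L, diff(cc$vcf_index) != 1L))
    starts <- tapply(cc$vcf_index, run, `[[`, 1L)
    blocks <- tapply(cc$allele, run, paste, collapse = "")
    qual <- intToUtf8(pmin(cc$qual, 93L) + 33L)
    lines[f] <- paste(length(starts), fm$read_id[f],
                      paste(rbind(as.character(starts), blocks), collapse = " "),
                      qual)
  }
  writeLines(lines, path)
  invisible(path)
}

#' Build a fragment matrix
#'
#' The substrate of all consistency computation: a sparse read-by-site allele
#' matrix over {0,1}, restricted to heterozygous biallelic sites. Calls at
#' VCF indices that are not scorable (hom, multi-allelic, non-0/1 genotypes)
#' are dropped with a counted warning -- fragment files index over all VCF
#' records, scoring uses only het biallelic ones. Fragments left with fewer
#' than two calls carry no pairwise information and are dropped.
#'
#' @param sites Site table from [read_vcf()] (all records).
#' @param calls Long-format call table (columns `frag` or `read_id`,
#'   `vcf_index`, `allele`, `qual`) from [read_fragment_file()] or
#'   [extract_fragment_matrix()] internals.
#' @param drop_singletons Drop fragments with < 2 calls (default `TRUE`).
#' @return An object of class `fragment_matrix`: list with `sites` (all
#'   records), `scored` (het biallelic subset), `read_id` (per fragment) and
#'   `calls` (long format, `frag` renumbered 1..n).
#' @export
fragment_matrix <- function(sites, calls, drop_singletons = TRUE) {
  stopifnot(is.data.frame(sites), is.data.frame(calls))
  scored <- sites[scorable_mask(sites), , drop = FALSE]
  rownames(scored) <- NULL
  if (is.null(calls$frag)) {
    calls$frag <- match(calls$read_id, unique(calls$read_id))
  }
  if (is.null(calls$read_id)) calls$read_id <- paste0("frag", calls$frag)
  ok <- calls$vcf_index %in% scored$vcf_index
  n_ignored <- sum(!ok)
  if (n_ignored > 0L) {
    warning(n_ignored, " call(s) at unscored VCF indices ignored")
  }
  calls <- calls[ok, , drop = FALSE]
  if (nrow(calls)) {
    keep_frag <- names(which(table(calls$frag) >= if (drop_singletons) 2L else 1L))
    calls <- calls[calls$frag %in% as.integer(keep_frag), , drop = FALSE]
  }
  ids <- calls$read_id[!duplicated(calls$frag)]
  old <- calls$frag[!duplicated(calls$frag)]
  calls$frag <- match(calls$frag, old)
  calls <- calls[order(calls$frag, calls$vcf_index), , drop = FALSE]
  rownames(calls) <- NULL
  structure(
    list(sites = sites, scored = scored, read_id = ids,
         calls = calls[, c("frag", "read_id", "vcf_index", "allele", "qual")]),
    class = "fragment_matrix"
  )
}

#' @export
print.fragment_matrix <- function(x, ...) {
  cat("fragment_matrix:", length(x$read_id), "fragments x",
      nrow(x$scored), "het biallelic sites (", nrow(x$sites),
      "VCF records,", nrow(x$calls), "allele calls )\n")
  invisible(x)
}

#' @export
dim.fragment_matrix <- function(x) {
  c(length(x$read_id), nrow(x$scored))
}

# 0/1 indicator matrices (fragments x active sites), columns in the order of
# `active` (which must be sorted by vcf_index)
indicator_matrices <- function(fm, active) {
  stopifnot(!is.unsorted(active))
  calls <- fm$calls[fm$calls$vcf_index %in% active, , drop = FALSE]
  nr <- length(fm$read_id)
  nc <- length(active)
  j <- match(calls$vcf_index, active)
  ref <- calls$allele == 0L
  list(
    R = Matrix::sparseMatrix(i = calls$frag[ref], j = j[ref], x = 1,
                             dims = c(nr, nc)),
    A = Matrix::sparseMatrix(i = calls$frag[!ref], j = j[!ref], x = 1,
                             dims = c(nr, nc))
  )
}
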