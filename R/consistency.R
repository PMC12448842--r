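# Pairwise allele co-segregation consistency.
#
# For a pair of het sites, over the N reads calling both: x reads show a
# discordant pattern (01/10), y a concordant one (00/11), and the score is
# max(x, y) / (x + y).  Two true het variants yield score 1 in the error-free
# limit (whichever of cis/trans they are in); a haplotype-independent false
# call drives the score toward 1/2.

#' Consistency scoring configuration
#'
#' @param min_pair_support Minimum number of co-covering reads for a pair to
#'   count toward a site's summary.
#' @param neighbor_window Each site is paired with at most this many scored
#'   active sites on each side, in VCF-index order. Read length bounds
#'   co-coverage naturally; the window bounds compute.
#' @param weight_by_support If `TRUE`, `mean_score` weights each pair by its
#'   read support `n` instead of the default unweighted mean.
#' @return A `consistency_config` list.
#' @export
consistency_config <- function(min_pair_support = 3L, neighbor_window = 20L,
                               weight_by_support = FALSE) {
  stopifnot(min_pair_support >= 1L, neighbor_window >= 1L)
  structure(list(min_pair_support = as.integer(min_pair_support),
                 neighbor_window = as.integer(neighbor_window),
                 weight_by_support = isTRUE(weight_by_support)),
            class = "consistency_config")
}

#' Pairwise consistency score
#'
#' @param x Count of reads with discordant allele pattern (01 or 10).
#' @param y Count of reads with concordant pattern (00 or 11).
#' @return `max(x, y) / (x + y)`; always in `[0.5, 1]`, exactly 0.5 when
#'   `x == y` and 1 iff one of the counts is zero.
#' @examples
#' consistency_score(5, 0)  # 1
#' consistency_score(3, 3)  # 0.5
#' @export
consistency_score <- function(x, y) {
  if (any(x + y < 1)) stop("consistency score undefined for x + y = 0")
  pmax(x, y) / (x + y)
}

#' Allele pattern counts for one site pair
#'
#' Counts over exactly the fragments carrying a call at both sites.
#'
#' @param fm A [fragment_matrix()].
#' @param site_a,site_b VCF indices of two scored sites.
#' @return Named integer vector `c(x = discordant, y = concordant)`.
#' @export
pair_counts <- function(fm, site_a, site_b) {
  calls <- fm$calls
  a <- calls[calls$vcf_index == site_a, c("frag", "allele")]
  b <- calls[calls$vcf_index == site_b, c("frag", "allele")]
  m <- merge(a, b, by = "frag")
  disc <- m$allele.x != m$allele.y
  c(x = sum(disc), y = sum(!disc))
}

# all-pairs x/y count matrices over the active sites, via sparse cross
# products of the REF/ALT indicator matrices
pair_count_matrices <- function(fm, active) {
  ind <- indicator_matrices(fm, active)
  Y <- Matrix::crossprod(ind$R) + Matrix::crossprod(ind$A)
  XX <- Matrix::crossprod(ind$R, ind$A)
  X <- XX + Matrix::t(XX)
  list(x = as.matrix(X), y = as.matrix(Y))
}

#' Per-site neighborhood consistency summaries
#'
#' For each active site, pairs are formed with the other active sites within
#' `neighbor_window` positions (in active-site order) and retained when at
#' least `min_pair_support` reads call both sites; the summary aggregates the
#' retained pair scores.
#'
#' @param fm A [fragment_matrix()].
#' @param config A [consistency_config()].
#' @param active VCF indices of the sites currently in play (default: all
#'   scored sites). Must be a subset of `fm$scored$vcf_index`.
#' @return A `data.frame` with one row per active site: `vcf_index`,
#'   `n_pairs`, `max_score`, `mean_score` (both `NA` when `n_pairs` is 0) and
#'   `sufficient_coverage` (`n_pairs >= 1`). The retained pairs are attached
#'   as attribute `"pairs"` (`site_a`, `site_b`, `x`, `y`, `n`, `score`,
#'   upper triangle only).
#' @export
summarize_sites <- function(fm, config = consistency_config(), active = NULL) {
  scored_idx <- fm$scored$vcf_index
  if (is.null(active)) active <- scored_idx
  if (!all(active %in% scored_idx)) {
    stop("active set contains indices that are not scored sites")
  }
  active <- sort(unique(as.integer(active)))
  m <- length(active)
  empty <- data.frame(vcf_index = active, n_pairs = integer(m),
                      max_score = rep(NA_real_, m),
                      mean_score = rep(NA_real_, m),
                      sufficient_coverage = logical(m))
  if (m < 2L) {
    attr(empty, "pairs") <- empty_pairs()
    return(empty)
  }
  pc <- pair_count_matrices(fm, active)
  n <- pc$x + pc$y
  band <- abs(row(n) - col(n)) >= 1 & abs(row(n) - col(n)) <= config$neighbor_window
  ok <- band & n >= config$min_pair_support
  score <- matrix(NA_real_, m, m)
  score[ok] <- pmax(pc$x[ok], pc$y[ok]) / n[ok]

  n_pairs <- rowSums(ok)
  max_score <- suppressWarnings(apply(score, 1L, max, na.rm = TRUE))
  max_score[n_pairs == 0L] <- NA_real_
  if (config$weight_by_support) {
    w <- ifelse(ok, n, 0)
    mean_score <- rowSums(score * w, na.rm = TRUE) / rowSums(w)
  } else {
    mean_score <- rowMeans(score, na.rm = TRUE)
  }
  mean_score[n_pairs == 0L] <- NA_real_

  res <- data.frame(vcf_index = active, n_pairs = as.integer(n_pairs),
                    max_score = max_score, mean_score = mean_score,
                    sufficient_coverage = n_pairs >= 1L)
  up <- ok & upper.tri(ok)
  w <- which(up, arr.ind = TRUE)
  attr(res, "pairs") <- data.frame(
    site_a = active[w[, 1L]], site_b = active[w[, 2L]],
    x = pc$x[up], y = pc$y[up], n = n[up], score = score[up]
  )
  res
}

empty_pairs <- function() {
  data.frame(site_a = integer(), site_b = integer(), x = numeric(),
             y = numeric(), n = numeric(), score = numeric())
}
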