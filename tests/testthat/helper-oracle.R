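# Independent brute-force oracle for pairwise consistency: plain loops over
# every site pair and every fragment, no sparse algebra, no shared code with
# summarize_sites().

oracle_site_summaries <- function(fm, min_pair_support = 3L,
                                  neighbor_window = 20L, active = NULL) {
  scored <- sort(if (is.null(active)) fm$scored$vcf_index else active)
  byfrag <- split(fm$calls[c("vcf_index", "allele")], fm$calls$frag)
  m <- length(scored)
  out <- data.frame(vcf_index = scored, n_pairs = 0L,
                    max_score = NA_real_, mean_score = NA_real_,
                    sufficient_coverage = FALSE)
  for (i in seq_len(m)) {
    scores <- numeric(0)
    for (j in seq_len(m)) {
      if (j == i || abs(j - i) > neighbor_window) next
      x <- 0L
      y <- 0L
      for (fr in byfrag) {
        ai <- fr$allele[fr$vcf_index == scored[i]]
        aj <- fr$allele[fr$vcf_index == scored[j]]
        if (length(ai) == 1L && length(aj) == 1L) {
          if (ai == aj) y <- y + 1L else x <- x + 1L
        }
      }
      if (x + y >= min_pair_support) scores <- c(scores, max(x, y) / (x + y))
    }
    if (length(scores)) {
      out$n_pairs[i] <- length(scores)
      out$max_score[i] <- max(scores)
      out$mean_score[i] <- mean(scores)
      out$sufficient_coverage[i] <- TRUE
    }
  }
  out
}

oracle_pair_counts <- function(fm, a, b) {
  x <- 0L
  y <- 0L
  for (fr in split(fm$calls[c("vcf_index", "allele")], fm$calls$frag)) {
    ai <- fr$allele[fr$vcf_index == a]
    aj <- fr$allele[fr$vcf_index == b]
    if (length(ai) == 1L && length(aj) == 1L) {
      if (ai == aj) y <- y + 1L else x <- x + 1L
    }
  }
  c(x = x, y = y)
}
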