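# Evaluation against simulation truth: filtering quality (precision/recall
# over filterable sites) and the downstream phasing effect, measured with a
# deliberately simple greedy reference phaser -- enough to expose how planted
# false sites corrupt phase chains, not a reimplementation of production
# phasers.

#' Precision and recall of filtering decisions
#'
#' Over the filterable sites: tp = kept true sites, fp = kept false sites,
#' fn = removed true sites.
#'
#' @param decisions Decision table (`vcf_index`, `kept`) or a
#'   `variant_filter` object.
#' @param truth Truth table with `vcf_index` and `label`
#'   (`"true"` vs anything else = false).
#' @param filterable VCF indices the filter was allowed to remove (defaults
#'   to the `variant_filter` object's own set, or all decision rows).
#' @return A list of class `filter_eval`: `tp`, `fp`, `fn`, `precision`,
#'   `recall`, `n`.
#' @export
precision_recall <- function(decisions, truth, filterable = NULL) {
  if (inherits(decisions, "variant_filter")) {
    if (is.null(filterable)) filterable <- decisions$filterable
    decisions <- decisions$decisions
  }
  if (is.null(filterable)) filterable <- decisions$vcf_index
  d <- decisions[decisions$vcf_index %in% filterable, , drop = FALSE]
  lab <- truth$label[match(d$vcf_index, truth$vcf_index)]
  if (anyNA(lab)) {
    stop("truth label missing for ", sum(is.na(lab)), " filterable site(s)")
  }
  is_true <- lab == "true"
  tp <- sum(d$kept & is_true)
  fp <- sum(d$kept & !is_true)
  fn <- sum(!d$kept & is_true)
  structure(list(tp = tp, fp = fp, fn = fn,
                 precision = if (tp + fp > 0) tp / (tp + fp) else NA_real_,
                 recall = if (tp + fn > 0) tp / (tp + fn) else NA_real_,
                 n = nrow(d)),
            class = "filter_eval")
}

#' @export
print.filter_eval <- function(x, ...) {
  cat(sprintf("filter_eval: tp=%d fp=%d fn=%d  precision=%.4f recall=%.4f (n=%d)\n",
              x$tp, x$fp, x$fn, x$precision, x$recall, x$n))
  invisible(x)
}

#' Greedy reference phaser
#'
#' Chain-links consecutive sites (in position order) that share at least
#' `min_pair_support` co-covering reads, orienting each link by the majority
#' allele pattern (concordant 00/11 majority -> same phase, discordant ->
#' opposite; ties toward same phase). The chain breaks where no qualifying
#' link exists, starting a new block.
#'
#' @param fm A [fragment_matrix()].
#' @param site_idx VCF indices of the sites to phase (subset of scored sites).
#' @param min_pair_support Minimum reads linking consecutive sites.
#' @return A `data.frame` with `vcf_index`, `pos`, `block` (1-based) and
#'   `hap` (0/1 orientation relative to the block start).
#' @export
greedy_phase <- function(fm, site_idx, min_pair_support = 3L) {
  site_idx <- sort(unique(as.integer(site_idx)))
  stopifnot(all(site_idx %in% fm$scored$vcf_index))
  pos <- fm$scored$pos[match(site_idx, fm$scored$vcf_index)]
  o <- order(pos)
  site_idx <- site_idx[o]
  pos <- pos[o]
  k <- length(site_idx)
  block <- integer(k)
  hap <- integer(k)
  if (k == 0L) {
    return(data.frame(vcf_index = integer(), pos = integer(),
                      block = integer(), hap = integer()))
  }
  pc <- if (k >= 2L) pair_count_matrices(fm, site_idx) else NULL
  block[1L] <- 1L
  hap[1L] <- 0L
  for (i in seq_len(k - 1L)) {
    x <- pc$x[i, i + 1L]
    y <- pc$y[i, i + 1L]
    if (x + y >= min_pair_support) {
      block[i + 1L] <- block[i]
      hap[i + 1L] <- if (x > y) 1L - hap[i] else hap[i]
    } else {
      block[i + 1L] <- block[i] + 1L
      hap[i + 1L] <- 0L
    }
  }
  data.frame(vcf_index = site_idx, pos = pos, block = block, hap = hap)
}

#' Count switch errors against truth phase
#'
#' Within each predicted block, consecutive phased sites (restricted to sites
#' present in the truth) are compared by relative orientation: a switch error
#' is a position where predicted and true relative phase between consecutive
#' sites disagree. This count is invariant under flipping all haplotype
#' labels of a block (or of the truth).
#'
#' @param assignment Output of [greedy_phase()].
#' @param truth_phase Table with `vcf_index` and `alt_hap` (1/2) or `hap`
#'   (0/1); sites with `NA` phase are ignored.
#' @return Integer switch-error count.
#' @export
switch_errors <- function(assignment, truth_phase) {
  th <- if (!is.null(truth_phase$hap)) truth_phase$hap
        else as.integer(truth_phase$alt_hap) - 1L
  tmap <- setNames(th, truth_phase$vcf_index)
  a <- assignment[assignment$vcf_index %in%
                    truth_phase$vcf_index[!is.na(th)], , drop = FALSE]
  total <- 0L
  for (b in unique(a$block)) {
    ab <- a[a$block == b, , drop = FALSE]
    if (nrow(ab) < 2L) next
    t <- tmap[as.character(ab$vcf_index)]
    rel_pred <- diff(ab$hap) != 0L
    rel_true <- diff(t) != 0L
    total <- total + sum(rel_pred != rel_true)
  }
  total
}

#' N50 of phase-block genomic spans
#'
#' Block span is `last site pos - first site pos + 1`; N50 is the span such
#' that blocks at least that long cover half the total phased span.
#'
#' @param assignment Output of [greedy_phase()].
#' @return Numeric N50 (0 for an empty assignment).
#' @export
block_n50 <- function(assignment) {
  if (nrow(assignment) == 0L) return(0)
  spans <- tapply(assignment$pos, assignment$block,
                  function(p) max(p) - min(p) + 1L)
  spans <- sort(as.numeric(spans), decreasing = TRUE)
  spans[which(cumsum(spans) >= sum(spans) / 2)[1L]]
}

#' Threshold grid search on synthetic data
#'
#' Evaluates every admissible `(p1, p2, p3)` combination (`p1 < p2 < p3`)
#' over the supplied grids: INDELs are filtered at those thresholds, the
#' greedy phaser is run on raw SNVs plus the surviving INDELs, and switch
#' errors / block N50 are measured against the simulation truth.
#'
#' @param fm A [fragment_matrix()] (typically `sim$fm`).
#' @param truth Simulation truth table (`vcf_index`, `label`, `alt_hap`).
#' @param p1,p2,p3 Threshold grids (defaults: the ranges used to select the
#'   shipped defaults).
#' @param base_config A [filter_config()] supplying everything but the
#'   thresholds (mode is forced to `indels_only`).
#' @param min_pair_support Link support for the phaser.
#' @return A `data.frame` with one row per admissible triple: `p1`, `p2`,
#'   `p3`, `n_removed`, `switch_errors`, `n50_block`.
#' @export
grid_search <- function(fm, truth,
                        p1 = c(0.6, 0.65, 0.7, 0.75),
                        p2 = c(0.7, 0.75, 0.8, 0.85),
                        p3 = c(0.8, 0.85, 0.9, 0.95),
                        base_config = filter_config(),
                        min_pair_support = 3L) {
  combos <- expand.grid(p1 = p1, p2 = p2, p3 = p3)
  combos <- combos[combos$p1 < combos$p2 & combos$p2 < combos$p3, , drop = FALSE]
  combos <- combos[order(combos$p1, combos$p2, combos$p3), , drop = FALSE]
  rownames(combos) <- NULL
  if (nrow(combos) == 0L) {
    return(cbind(combos, data.frame(n_removed = integer(),
                                    switch_errors = integer(),
                                    n50_block = numeric())))
  }
  snv_idx <- fm$scored$vcf_index[fm$scored$vtype == "SNV"]
  res <- lapply(seq_len(nrow(combos)), function(i) {
    cfg <- filter_config(p1 = combos$p1[i], p2 = combos$p2[i],
                         p3 = combos$p3[i],
                         min_qual = base_config$min_qual,
                         mode = "indels_only",
                         step3_stat = base_config$step3_stat,
                         consistency = base_config$consistency)
    vf <- filter_variants(fm, cfg)
    kept_indel <- vf$decisions$vcf_index[vf$decisions$kept &
                                           vf$decisions$vcf_index %in% vf$filterable]
    ph <- greedy_phase(fm, c(snv_idx, kept_indel), min_pair_support)
    data.frame(n_removed = sum(!vf$decisions$kept),
               switch_errors = switch_errors(ph, truth),
               n50_block = block_n50(ph))
  })
  cbind(combos, do.call(rbind, res))
}
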