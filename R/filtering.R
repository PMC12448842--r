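# The stepwise filter.
#
# Step 1 removes filterable sites with NO neighbor pair score above p1
# (max_score <= p1); steps 2 and 3 tighten the requirement on the remaining
# sites (mean_score < p2, then the step-3 statistic < p3).  Summaries are
# recomputed against the surviving active set between steps, so removing a bad
# site lets its neighbors' summaries recover.  A filterable site with no
# qualifying pair at the step where it would be judged is decided by the VCF
# QUAL field instead (kept iff QUAL >= min_qual); a quality-rescued site stays
# in the active pairing set but is not re-judged later.

#' Filtering configuration
#'
#' @param p1,p2,p3 The three consistency thresholds, `0.5 <= p1 < p2 < p3 <= 1`
#'   (defaults 0.7, 0.8, 0.9).
#' @param min_qual QUAL threshold of the coverage fallback (default 15;
#'   missing QUAL counts as 0).
#' @param mode `"indels_only"` (only INDEL sites may be removed; SNVs still
#'   pair) or `"all_variants"`.
#' @param step3_stat Statistic the stricter third step compares to `p3`:
#'   `"max"` (default) or `"mean"`. See the package vignette for why the best
#'   neighbor link, not the neighborhood average, is the default at this step:
#'   at nanopore-typical allele error rates the expected pairwise concordance
#'   of a *true* site falls near or below 0.9, so a mean comparator at p3
#'   removes true variants wholesale, while a low max is still specific to
#'   sites with no reliable link at all.
#' @param consistency A [consistency_config()].
#' @return A `filter_config` list.
#' @export
filter_config <- function(p1 = 0.7, p2 = 0.8, p3 = 0.9, min_qual = 15,
                          mode = c("indels_only", "all_variants"),
                          step3_stat = c("max", "mean"),
                          consistency = consistency_config()) {
  mode <- match.arg(mode)
  step3_stat <- match.arg(step3_stat)
  if (!(0.5 <= p1 && p1 < p2 && p2 < p3 && p3 <= 1)) {
    stop("thresholds must satisfy 0.5 <= p1 < p2 < p3 <= 1 (got ",
         p1, ", ", p2, ", ", p3, ")")
  }
  stopifnot(inherits(consistency, "consistency_config"))
  structure(list(p1 = p1, p2 = p2, p3 = p3, min_qual = min_qual, mode = mode,
                 step3_stat = step3_stat, consistency = consistency),
            class = "filter_config")
}

#' Which sites may be removed under a filtering mode
#'
#' @param sites A site table (rows assumed het biallelic, e.g. `fm$scored`).
#' @param mode `"indels_only"` or `"all_variants"`.
#' @return Logical vector over rows of `sites`.
#' @export
apply_mode_mask <- function(sites, mode = c("indels_only", "all_variants")) {
  mode <- match.arg(mode)
  if (nrow(sites) == 0L) return(logical(0))
  if (mode == "indels_only") sites$vtype == "INDEL" else rep(TRUE, nrow(sites))
}

#' Run the three-step consistency filter
#'
#' @param fm A [fragment_matrix()].
#' @param config A [filter_config()].
#' @return An object of class `variant_filter`: list with
#'   \describe{
#'     \item{decisions}{one row per VCF record: `vcf_index`, `kept`, `reason`.}
#'     \item{summaries}{final consistency summaries of the surviving active set.}
#'     \item{report}{per-record report table (see [write_report()]).}
#'     \item{steps}{the per-step summaries, as computed before each step.}
#'     \item{config, sites}{inputs.}
#'   }
#'   Reasons: `kept`, `step1_max_le_p1`, `step2_mean_lt_p2`,
#'   `step3_max_lt_p3`/`step3_mean_lt_p3`, `qual_fallback_removed`,
#'   `unscored_passthrough`, `unscored_multiallelic`.
#' @export
filter_variants <- function(fm, config = filter_config()) {
  stopifnot(inherits(fm, "fragment_matrix"), inherits(config, "filter_config"))
  sites <- fm$sites
  scored <- fm$scored
  filterable_idx <- scored$vcf_index[apply_mode_mask(scored, config$mode)]
  qual <- setNames(ifelse(is.na(scored$qual), 0, scored$qual),
                   scored$vcf_index)

  step_specs <- list(
    list(stat = "max_score", strict = FALSE, thr = config$p1,
         reason = "step1_max_le_p1"),
    list(stat = "mean_score", strict = TRUE, thr = config$p2,
         reason = "step2_mean_lt_p2"),
    list(stat = paste0(config$step3_stat, "_score"), strict = TRUE,
         thr = config$p3,
         reason = paste0("step3_", config$step3_stat, "_lt_p3"))
  )

  active <- scored$vcf_index
  reason <- setNames(rep(NA_character_, nrow(scored)), scored$vcf_index)
  rescued <- character(0)
  steps <- vector("list", 3L)
  judged_at <- list()  # summary rows at decision time, for removed sites

  for (k in 1:3) {
    spec <- step_specs[[k]]
    summ <- summarize_sites(fm, config$consistency, active)
    steps[[k]] <- summ
    judge <- intersect(active, setdiff(filterable_idx, rescued))
    if (length(judge) == 0L) next
    rows <- summ[match(judge, summ$vcf_index), , drop = FALSE]

    no_pairs <- !rows$sufficient_coverage
    fb <- judge[no_pairs]
    fb_removed <- fb[qual[as.character(fb)] < config$min_qual]
    fb_rescued <- setdiff(fb, fb_removed)

    val <- rows[[spec$stat]]
    low <- !no_pairs & (if (spec$strict) val < spec$thr else val <= spec$thr)
    removed_k <- judge[low]

    reason[as.character(fb_removed)] <- "qual_fallback_removed"
    reason[as.character(removed_k)] <- spec$reason
    rescued <- c(rescued, as.character(fb_rescued))
    for (v in c(fb_removed, removed_k)) {
      judged_at[[as.character(v)]] <- rows[match(v, judge), , drop = FALSE]
    }
    active <- setdiff(active, c(fb_removed, removed_k))
  }

  final_summ <- summarize_sites(fm, config$consistency, active)
  reason[is.na(reason)] <- "kept"

  # decisions over every VCF record
  dec_reason <- rep("unscored_passthrough", nrow(sites))
  dec_reason[sites$multiallelic] <- "unscored_multiallelic"
  sc <- match(scored$vcf_index, sites$vcf_index)
  dec_reason[sc] <- reason[as.character(scored$vcf_index)]
  decisions <- data.frame(
    vcf_index = sites$vcf_index,
    kept = !dec_reason %in% c("step1_max_le_p1", "step2_mean_lt_p2",
                              "step3_max_lt_p3", "step3_mean_lt_p3",
                              "qual_fallback_removed"),
    reason = dec_reason,
    stringsAsFactors = FALSE
  )

  # report: consistency summary at final state for kept sites, at decision
  # time for removed ones
  stat_of <- function(idx) {
    row <- final_summ[match(idx, final_summ$vcf_index), , drop = FALSE]
    if (is.na(row$vcf_index[1L])) row <- judged_at[[as.character(idx)]]
    row
  }
  rep_rows <- lapply(scored$vcf_index, stat_of)
  rep_stats <- do.call(rbind, rep_rows)
  report <- data.frame(
    chrom = sites$chrom, pos = sites$pos, ref = sites$ref, alt = sites$alt,
    vtype = sites$vtype, n_pairs = NA_integer_,
    max_consistency = NA_real_, mean_consistency = NA_real_,
    qual = sites$qual, decision = ifelse(decisions$kept, "kept", "removed"),
    reason = decisions$reason, stringsAsFactors = FALSE
  )
  report$n_pairs[sc] <- rep_stats$n_pairs
  report$max_consistency[sc] <- rep_stats$max_score
  report$mean_consistency[sc] <- rep_stats$mean_score

  structure(
    list(decisions = decisions, summaries = final_summ, report = report,
         steps = steps, config = config, sites = sites,
         n_scored = nrow(scored), filterable = filterable_idx,
         rescued = as.integer(rescued)),
    class = "variant_filter"
  )
}

#' Filter a VCF by read-backed consistency (one-stop entry point)
#'
#' Reads the VCF, obtains allele calls per read (extracted from a BAM, or read
#' from a HapCUT2-style fragment file), runs [filter_variants()] and returns
#' the decision object; use [write_filtered_vcf()] and [write_report()] on the
#' result to materialize outputs.
#'
#' @param vcf Path to the input VCF.
#' @param bam Path to a coordinate-sorted indexed BAM (ignored when
#'   `fragments` is given).
#' @param fragments Optional path to a pre-computed fragment file.
#' @param config A [filter_config()].
#' @param tagging A [tagging_config()] (BAM route only).
#' @return A `variant_filter` object (see [filter_variants()]) with the input
#'   path recorded in `$vcf_path`.
#' @export
consistency_filter <- function(vcf, bam = NULL, fragments = NULL,
                               config = filter_config(),
                               tagging = tagging_config()) {
  sites <- read_vcf(vcf)
  fm <- if (!is.null(fragments)) {
    fragment_matrix(sites, read_fragment_file(fragments))
  } else if (!is.null(bam)) {
    extract_fragment_matrix(bam, sites, tagging)
  } else {
    stop("provide either `bam` or `fragments`")
  }
  res <- filter_variants(fm, config)
  res$vcf_path <- vcf
  res$fm <- fm
  res
}

#' @export
print.variant_filter <- function(x, ...) {
  tab <- table(x$decisions$reason)
  cat("variant_filter: ", nrow(x$decisions), " VCF records, ",
      x$n_scored, " het biallelic scored, ", length(x$filterable),
      " filterable (mode=", x$config$mode, ")\n", sep = "")
  cat(sprintf("  thresholds (p1, p2, p3) = (%g, %g, %g), qual fallback >= %g\n",
              x$config$p1, x$config$p2, x$config$p3, x$config$min_qual))
  cat("  decisions:\n")
  for (r in names(tab)) cat(sprintf("    %-24s %d\n", r, tab[[r]]))
  invisible(x)
}

#' @export
summary.variant_filter <- function(object, ...) {
  print(object)
  s <- object$summaries
  if (nrow(s) && any(s$sufficient_coverage)) {
    ms <- s$mean_score[s$sufficient_coverage]
    cat(sprintf("  surviving sites: %d with pairs; mean consistency %.3f (min %.3f)\n",
                sum(s$sufficient_coverage), mean(ms), min(ms)))
  }
  invisible(object)
}

#' @export
plot.variant_filter <- function(x, ...) {
  removed_idx <- x$decisions$vcf_index[!x$decisions$kept]
  rep <- x$report
  kept_ms <- rep$mean_consistency[rep$decision == "kept" & !is.na(rep$mean_consistency)]
  rm_ms <- rep$mean_consistency[rep$decision == "removed" & !is.na(rep$mean_consistency)]
  brk <- seq(0.5, 1, by = 0.025)
  hist(pmax(kept_ms, 0.5), breaks = brk, col = "#4daf4a80", border = NA,
       main = "Neighborhood mean consistency", xlab = "mean consistency score",
       ...)
  if (length(rm_ms)) {
    hist(pmax(rm_ms, 0.5), breaks = brk, col = "#e41a1c80", border = NA,
         add = TRUE)
  }
  abline(v = c(x$config$p2, x$config$p3), lty = 2)
  legend("topleft", fill = c("#4daf4a80", "#e41a1c80"),
         legend = c("kept", "removed"), bty = "n")
  invisible(x)
}
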