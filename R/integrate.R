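# Restoration-pattern classification in both omics layers and the
# methylation--expression integration that yields Pattern A / Pattern B
# genes.
#
# The two ordered contrasts throughout are (1) disease vs control and
# (2) treatment vs disease. A methylation restoration pattern is a
# significant change under disease reversed under treatment; likewise for
# expression. Pattern A = hyper/hypo methylation + down/up expression;
# Pattern B = hypo/hyper + up/down.

#' Classify the methylation restoration pattern of a region
#'
#' `hyper_hypo` requires `delta1 >= min_diff`, `delta2 <= -min_diff` and
#' both q-values below `max_q`; `hypo_hyper` is the mirror image;
#' everything else is `none`. Deltas are in percentage points.
#'
#' @param delta1,q1 Delta beta (pp) and adjusted p for contrast 1
#'   (disease vs control).
#' @param delta2,q2 Same for contrast 2 (treatment vs disease).
#' @param min_diff Minimum |delta beta| in pp.
#' @param max_q Significance cutoff applied to `q1` and `q2`.
#' @return Character vector in `{"hyper_hypo", "hypo_hyper", "none"}`.
#' @export
classify_meth_pattern <- function(delta1, q1, delta2, q2,
                                  min_diff = 10, max_q = 0.01) {
  if (any(abs(c(delta1, delta2)) > 100, na.rm = TRUE))
    stop("delta beta outside [-100, 100]")
  sig <- !is.na(q1) & !is.na(q2) & q1 < max_q & q2 < max_q
  out <- rep("none", length(delta1))
  out[sig & delta1 >= min_diff & delta2 <= -min_diff] <- "hyper_hypo"
  out[sig & delta1 <= -min_diff & delta2 >= min_diff] <- "hypo_hyper"
  out
}

#' Classify the expression restoration pattern of a transcript
#'
#' `down_up` requires `fc1 <= -min_fc`, `fc2 >= min_fc` and both p-values
#' below `alpha`; `up_down` is the mirror image. Fold changes are signed
#' linear ratios as from [signed_fold_change()]. The default
#' `min_fc = 1` classifies by direction and significance alone (any
#' significant opposite-signed pair qualifies); set `min_fc = 2` to also
#' require the conventional two-fold (|log2 FC| >= 1) magnitude screen.
#'
#' @param fc1,p1 Signed fold change and p-value for disease vs control.
#' @param fc2,p2 Same for treatment vs disease.
#' @param min_fc Minimum |fold change| (linear).
#' @param alpha p-value cutoff.
#' @return Character vector in `{"down_up", "up_down", "none"}`.
#' @export
classify_expr_pattern <- function(fc1, p1, fc2, p2, min_fc = 1,
                                  alpha = 0.05) {
  if (any(abs(c(fc1, fc2)) < 1, na.rm = TRUE))
    stop("signed fold changes must have magnitude >= 1")
  sig <- !is.na(p1) & !is.na(p2) & p1 < alpha & p2 < alpha
  out <- rep("none", length(fc1))
  out[sig & fc1 <= -min_fc & fc2 >= min_fc] <- "down_up"
  out[sig & fc1 >= min_fc & fc2 <= -min_fc] <- "up_down"
  out
}

#' Min-max scale a vector to the unit interval
#'
#' `(x - min) / (max - min)`; a constant vector maps to all 0.5 (keeping
#' it rank-degenerate without dividing by zero). Used to put expression
#' on the same 0..1 scale as methylation before correlation.
#'
#' @param x Numeric vector, length >= 2.
#' @return Vector in `[0, 1]`.
#' @export
scale_unit_interval <- function(x) {
  stopifnot(length(x) >= 2)
  rng <- range(x, na.rm = TRUE)
  if (rng[1] == rng[2]) return(rep(0.5, length(x)))
  (x - rng[1]) / (rng[2] - rng[1])
}

#' Spearman rank correlation
#'
#' Pearson correlation of average ranks, via [stats::cor()]. When either
#' vector has zero rank variance the correlation is undefined and
#' `NA_real_` is returned (callers exclude such pairs).
#'
#' @param x,y Numeric vectors of equal length >= 3.
#' @return Correlation in `[-1, 1]`, or `NA_real_`.
#' @export
spearman_rho <- function(x, y) {
  stopifnot(length(x) == length(y), length(x) >= 3)
  suppressWarnings(r <- cor(x, y, method = "spearman"))
  if (is.na(r)) NA_real_ else r
}

#' Per-sample pooled window methylation
#'
#' For each requested window, per-sample beta = pooled methylated reads /
#' pooled depth over the CpGs inside it (no depth filter; depth-0 cells
#' are NA). The resulting matrix feeds the methylation--expression
#' correlation.
#'
#' @param cpgs A `cpg_set` (all samples).
#' @param windows Character `chr$start$end` ids, or a data.frame with
#'   `chrom`, `start`, `end`.
#' @param window,step Tiling geometry used to form the ids.
#' @return Numeric matrix (windows x samples), rownames = window ids.
#' @export
window_betas <- function(cpgs, windows, window = 1000, step = 500) {
  stopifnot(inherits(cpgs, "cpg_set"))
  if (is.character(windows)) windows <- parse_region_id(windows)
  ids <- region_id(windows$chrom, windows$start, windows$end)
  map <- site_window_map(cpgs$sites, window, step)
  map$id <- region_id(map$chrom, map$win_start,
                      map$win_start + as.integer(window) - 1L)
  map <- map[map$id %in% ids, , drop = FALSE]
  out <- matrix(NA_real_, length(ids), length(cpgs$samples),
                dimnames = list(ids, cpgs$samples))
  if (nrow(map) == 0) return(out)
  meth <- rowsum(cpgs$meth[map$site, , drop = FALSE], map$id)
  depth <- rowsum(cpgs$depth[map$site, , drop = FALSE], map$id)
  beta <- meth / depth
  beta[depth == 0] <- NA_real_
  out[rownames(beta), ] <- beta
  out
}

#' Integrate methylation and expression restoration patterns
#'
#' For every (region, transcript) link, classifies the methylation
#' pattern from the two window tables and the expression pattern from the
#' two differential-expression tables, keeps the concordant pairings
#' (Pattern A = hyper/hypo + down/up; Pattern B = hypo/hyper + up/down),
#' and -- when per-sample data are supplied -- requires a negative
#' Spearman correlation between window methylation and min-max-scaled
#' expression across all samples. Output is unique on
#' (region id, transcript id).
#'
#' @param meth1,meth2 `dmr_result` tables (all tested windows) for
#'   disease-vs-control and treatment-vs-disease.
#' @param expr1,expr2 `de_result` tables for the same ordered contrasts.
#' @param links data.frame from [link_transcripts()] (columns
#'   `region_id`, `transcript_id`, `gene`).
#' @param sample_betas Optional matrix from [window_betas()] (windows x
#'   all samples).
#' @param sample_expr Optional expression matrix (transcripts x all
#'   samples), e.g. CPM; rows are min-max scaled before correlation.
#' @param min_diff,max_q Methylation pattern thresholds.
#' @param min_fc,alpha Expression pattern thresholds.
#' @param rho_max Records require `rho < rho_max` (default 0: strictly
#'   negative correlation) when per-sample data are available.
#' @return An `integrated_genes` data.frame: `gene`, `transcript_id`,
#'   `dmr_id`, `pattern` (A/B), `delta1`, `q1`, `delta2`, `q2`, `fc1`,
#'   `p1`, `fc2`, `p2`, `rho`.
#' @export
integrate_patterns <- function(meth1, meth2, expr1, expr2, links,
                               sample_betas = NULL, sample_expr = NULL,
                               min_diff = 10, max_q = 0.01,
                               min_fc = 1, alpha = 0.05, rho_max = 0) {
  links <- unique(links[, c("region_id", "transcript_id", "gene")])
  i1 <- match(links$region_id, meth1$id)
  i2 <- match(links$region_id, meth2$id)
  e1 <- match(links$transcript_id, expr1$transcript_id)
  e2 <- match(links$transcript_id, expr2$transcript_id)
  miss_e <- (!is.na(i1) | !is.na(i2)) & (is.na(e1) | is.na(e2))
  if (any(miss_e))
    warning(sum(miss_e), " link(s) to transcripts absent from the ",
            "expression results skipped")
  ok <- !is.na(i1) & !is.na(i2) & !is.na(e1) & !is.na(e2)
  out <- data.frame(gene = links$gene[ok],
                    transcript_id = links$transcript_id[ok],
                    dmr_id = links$region_id[ok],
                    delta1 = meth1$delta_beta[i1[ok]],
                    q1 = meth1$q[i1[ok]],
                    delta2 = meth2$delta_beta[i2[ok]],
                    q2 = meth2$q[i2[ok]],
                    fc1 = expr1$fc_signed[e1[ok]],
                    p1 = expr1$p[e1[ok]],
                    fc2 = expr2$fc_signed[e2[ok]],
                    p2 = expr2$p[e2[ok]],
                    stringsAsFactors = FALSE)
  mp <- classify_meth_pattern(out$delta1, out$q1, out$delta2, out$q2,
                              min_diff = min_diff, max_q = max_q)
  ep <- classify_expr_pattern(out$fc1, out$p1, out$fc2, out$p2,
                              min_fc = min_fc, alpha = alpha)
  out$pattern <- ifelse(mp == "hyper_hypo" & ep == "down_up", "A",
                        ifelse(mp == "hypo_hyper" & ep == "up_down", "B",
                               NA_character_))
  out <- out[!is.na(out$pattern), , drop = FALSE]
  out$rho <- rep(NA_real_, nrow(out))
  if (!is.null(sample_betas) && !is.null(sample_expr) && nrow(out) > 0) {
    common <- intersect(colnames(sample_betas), colnames(sample_expr))
    for (i in seq_len(nrow(out))) {
      b <- sample_betas[out$dmr_id[i], common]
      e <- sample_expr[out$transcript_id[i], common]
      use <- !is.na(b) & !is.na(e)
      out$rho[i] <- if (sum(use) >= 3)
        spearman_rho(b[use], scale_unit_interval(e[use])) else NA_real_
    }
    out <- out[!is.na(out$rho) & out$rho < rho_max, , drop = FALSE]
  }
  out <- unique(out)
  out <- out[order(out$pattern, out$gene, out$dmr_id, out$transcript_id),
             c("gene", "transcript_id", "dmr_id", "pattern",
               "delta1", "q1", "delta2", "q2", "fc1", "p1", "fc2", "p2",
               "rho")]
  rownames(out) <- NULL
  class(out) <- c("integrated_genes", "data.frame")
  out
}

#' Summarise an integration result
#'
#' A gene counts as Pattern A (resp. B) when at least one of its
#' (region, transcript) links carries that pattern; gene counts are over
#' unique symbols.
#'
#' @param ig An `integrated_genes` data.frame.
#' @return List with `n_dmrs_unique`, `n_genes`, `n_pattern_a`,
#'   `n_pattern_b`.
#' @export
integration_summary <- function(ig) {
  list(n_dmrs_unique = length(unique(ig$dmr_id)),
       n_genes = length(unique(ig$gene)),
       n_pattern_a = length(unique(ig$gene[ig$pattern == "A"])),
       n_pattern_b = length(unique(ig$gene[ig$pattern == "B"])))
}

#' @export
print.integrated_genes <- function(x, ...) {
  s <- integration_summary(x)
  cat("Integrated restoration-pattern genes\n",
      "  ", nrow(x), " (DMR, transcript) links; ", s$n_dmrs_unique,
      " unique DMRs; ", s$n_genes, " genes (", s$n_pattern_a,
      " Pattern A, ", s$n_pattern_b, " Pattern B)\n", sep = "")
  if (nrow(x) > 0) print(head(as.data.frame(x), 5))
  invisible(x)
}

#' Restoration-pattern classification of windows across two contrasts
#'
#' Joins two all-window tables on window id and classifies each shared
#' window's methylation restoration pattern.
#'
#' @param meth1,meth2 `dmr_result` tables for the ordered contrasts.
#' @param min_diff,max_q Thresholds as in [classify_meth_pattern()].
#' @return data.frame `id`, `pattern` for windows with a pattern other
#'   than `none`.
#' @export
restoration_patterns <- function(meth1, meth2, min_diff = 10,
                                 max_q = 0.01) {
  common <- intersect(meth1$id, meth2$id)
  i1 <- match(common, meth1$id); i2 <- match(common, meth2$id)
  pat <- classify_meth_pattern(meth1$delta_beta[i1], meth1$q[i1],
                               meth2$delta_beta[i2], meth2$q[i2],
                               min_diff = min_diff, max_q = max_q)
  keep <- pat != "none"
  data.frame(id = common[keep], pattern = pat[keep],
             stringsAsFactors = FALSE)
}

#' Totals of restoration DMRs
#'
#' @param x Either a data.frame from [restoration_patterns()], or the
#'   count of hyper/hypo DMRs (with `n_hypo_hyper` the count of
#'   hypo/hyper DMRs).
#' @param n_hypo_hyper Count of hypo/hyper DMRs when `x` is numeric.
#' @return List `n_hyper_hypo`, `n_hypo_hyper`, `total` (their sum).
#' @export
restoration_summary <- function(x, n_hypo_hyper = NULL) {
  if (is.data.frame(x)) {
    n_hh <- sum(x$pattern == "hyper_hypo")
    n_hp <- sum(x$pattern == "hypo_hyper")
  } else {
    stopifnot(is.numeric(x), is.numeric(n_hypo_hyper))
    n_hh <- x; n_hp <- n_hypo_hyper
  }
  list(n_hyper_hypo = n_hh, n_hypo_hyper = n_hp, total = n_hh + n_hp)
}
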