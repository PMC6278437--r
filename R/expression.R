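# Differential expression between two groups from a raw count matrix:
# library-size (CPM) normalisation, a negative-binomial test with
# moment-estimated dispersion, and the signed linear fold-change
# convention (+r for up, -r for down, |r| >= 1).

#' Counts-per-million normalisation
#'
#' Scales each sample column to sum to one million.
#'
#' @param m Non-negative count matrix (features x samples).
#' @return Numeric CPM matrix of the same shape.
#' @export
normalize_counts <- function(m) {
  m <- as.matrix(m)
  if (any(m < 0)) stop("negative counts")
  libs <- colSums(m)
  if (any(libs == 0))
    stop("all-zero count column for sample: ",
         paste(colnames(m)[libs == 0], collapse = ", "))
  t(t(m) / libs) * 1e6
}

#' Signed linear fold change
#'
#' The reporting convention for expression ratios: with `r = mean_b /
#' mean_a`, returns `r` when `r >= 1` and `-1/r` otherwise, so magnitude
#' is always at least 1 and the sign gives the direction of group b
#' relative to group a. `|fc| >= 2` is equivalent to `|log2 FC| >= 1`.
#'
#' @param mean_a,mean_b Positive group means (after any pseudocount).
#' @return Signed fold change(s).
#' @export
signed_fold_change <- function(mean_a, mean_b) {
  if (any(mean_a <= 0) || any(mean_b <= 0)) stop("means must be positive")
  r <- mean_b / mean_a
  ifelse(r >= 1, r, -1 / r)
}

#' Differential expression test between two groups
#'
#' Counts are scaled to a common library size, and each transcript is
#' tested for a log mean difference between the groups under a
#' negative-binomial variance model. Dispersion is estimated per
#' transcript by the method of moments on the scaled counts and shrunk
#' halfway toward the common (trimmed mean) dispersion; the Wald statistic
#' for the log mean ratio (delta-method standard error) is referred to the
#' standard normal. Significance uses the classical screen
#' `|log2 FC| >= lfc` and raw `p < alpha`.
#'
#' @param m Count matrix (transcripts x samples); an optional `gene`
#'   attribute (named character) supplies gene symbols.
#' @param sample_sheet data.frame with `sample_id`, `group`.
#' @param contrast `c(group_a, group_b)`; fold changes are b over a.
#' @param pseudocount Added to group means before ratios/logs.
#' @param alpha Raw p-value cutoff for the `significant` flag.
#' @param lfc Minimum |log2 fold change| for the `significant` flag.
#' @return A `de_result` data.frame: `transcript_id`, `gene`, `mean_a`,
#'   `mean_b`, `fc_signed`, `log2fc`, `p`, `significant`.
#' @export
de_test <- function(m, sample_sheet, contrast, pseudocount = 0.5,
                    alpha = 0.05, lfc = 1) {
  validate_sample_sheet(sample_sheet)
  stopifnot(length(contrast) == 2)
  ids_a <- intersect(colnames(m),
                     sample_sheet$sample_id[sample_sheet$group == contrast[1]])
  ids_b <- intersect(colnames(m),
                     sample_sheet$sample_id[sample_sheet$group == contrast[2]])
  na <- length(ids_a); nb <- length(ids_b)
  if (na < 2 || nb < 2)
    stop("both groups need >= 2 samples for dispersion estimation")
  gene <- attr(m, "gene") %||% setNames(rownames(m), rownames(m))
  m <- as.matrix(m[, c(ids_a, ids_b), drop = FALSE])

  zero <- rowSums(m) == 0
  if (any(zero))
    message(sum(zero), " transcript(s) with zero counts everywhere skipped")
  keep <- !zero
  x <- m[keep, , drop = FALSE]
  libs <- colSums(m)
  y <- t(t(x) * (mean(libs) / libs))    # counts at a common library size

  ya <- y[, ids_a, drop = FALSE]; yb <- y[, ids_b, drop = FALSE]
  mu_a <- rowMeans(ya); mu_b <- rowMeans(yb)
  va <- apply(ya, 1, var); vb <- apply(yb, 1, var)
  # moment dispersion per group, pooled with weights (n - 1); kept
  # unfloored until after shrinkage so the pooled estimate is unbiased
  # near zero dispersion
  disp_of <- function(v, mu) ifelse(mu > 0, (v - mu) / mu^2, 0)
  phi_tag <- ((na - 1) * disp_of(va, mu_a) + (nb - 1) * disp_of(vb, mu_b)) /
    (na + nb - 2)
  phi_common <- mean(phi_tag, trim = 0.1)
  phi <- pmax(0, 0.5 * phi_tag + 0.5 * phi_common)

  a <- mu_a + pseudocount; b <- mu_b + pseudocount
  lfc_hat <- log(b) - log(a)
  # delta method: var(log mean) ~ (1/mu + phi) / n under NB sampling
  se <- sqrt((1 / a + phi) / na + (1 / b + phi) / nb)
  zstat <- lfc_hat / se
  p <- 2 * pnorm(-abs(zstat))
  log2fc <- lfc_hat / log(2)
  res <- data.frame(transcript_id = rownames(x),
                    gene = unname(gene[rownames(x)]),
                    mean_a = mu_a, mean_b = mu_b,
                    fc_signed = signed_fold_change(a, b),
                    log2fc = log2fc, p = p,
                    significant = abs(log2fc) >= lfc & p < alpha,
                    stringsAsFactors = FALSE)
  rownames(res) <- NULL
  attr(res, "contrast") <- contrast
  attr(res, "params") <- list(pseudocount = pseudocount, alpha = alpha,
                              lfc = lfc, n_skipped = sum(zero))
  class(res) <- c("de_result", "data.frame")
  res
}

#' @export
print.de_result <- function(x, ...) {
  ct <- attr(x, "contrast")
  p <- attr(x, "params")
  cat("Differential expression: ", ct[2], " vs ", ct[1], "\n",
      "  transcripts tested: ", nrow(x), "; significant (|log2FC| >= ",
      p$lfc, ", p < ", p$alpha, "): ", sum(x$significant), "\n", sep = "")
  if (nrow(x) > 0) print(head(as.data.frame(x), 5))
  invisible(x)
}
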