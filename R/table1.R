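# The packaged worked example: the candidate-gene table of the
# three-condition asthma/treatment methylome-expression integration (27
# DMR-transcript rows over 25 unique DMR positions and 18 genes).

#' The packaged candidate-gene integration table
#'
#' 27 (DMR, transcript) rows over 25 unique DMR positions and 18 genes,
#' each carrying the two per-contrast delta-beta/p pairs (percentage
#' points; contrast 1 = disease vs control, contrast 2 = treatment vs
#' disease) and the two signed fold change/p pairs. Serves as the
#' deterministic worked example for the pattern classifiers.
#'
#' @return data.frame with columns `gene`, `pattern` (published label),
#'   `transcript_id`, `dmr_id`, `meth_delta1`, `meth_p1`, `meth_delta2`,
#'   `meth_p2`, `expr_fc1`, `expr_p1`, `expr_fc2`, `expr_p2`.
#' @export
table1_fixture <- function() {
  path <- system.file("extdata", "table1_candidate_genes.tsv",
                      package = "methrestore", mustWork = TRUE)
  read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE,
             colClasses = c(gene = "character", pattern = "character",
                            transcript_id = "character",
                            dmr_id = "character"))
}

#' Classify and summarise the packaged candidate-gene table
#'
#' Runs [classify_meth_pattern()] and [classify_expr_pattern()] over the
#' fixture rows, pairs the layer patterns into Pattern A / Pattern B, and
#' rolls up the unique-DMR and unique-gene counts. The published p-values
#' stand in for the window q-values (the fixture predates the adjustment
#' step); no per-sample values exist in the table, so the correlation
#' filter does not apply here.
#'
#' @param min_diff,max_q Methylation thresholds, see
#'   [classify_meth_pattern()].
#' @param min_fc,alpha Expression thresholds, see
#'   [classify_expr_pattern()].
#' @return List with `n_rows_classified`, `n_dmrs_unique`, `n_genes`,
#'   `n_pattern_a`, `n_pattern_b` and the per-row classification in
#'   `rows`.
#' @export
table1_report <- function(min_diff = 10, max_q = 0.01, min_fc = 1,
                          alpha = 0.05) {
  t1 <- table1_fixture()
  mp <- classify_meth_pattern(t1$meth_delta1, t1$meth_p1,
                              t1$meth_delta2, t1$meth_p2,
                              min_diff = min_diff, max_q = max_q)
  ep <- classify_expr_pattern(t1$expr_fc1, t1$expr_p1,
                              t1$expr_fc2, t1$expr_p2,
                              min_fc = min_fc, alpha = alpha)
  pat <- ifelse(mp == "hyper_hypo" & ep == "down_up", "A",
                ifelse(mp == "hypo_hyper" & ep == "up_down", "B",
                       NA_character_))
  rows <- cbind(t1[, c("gene", "transcript_id", "dmr_id")],
                meth_pattern = mp, expr_pattern = ep, pattern = pat,
                stringsAsFactors = FALSE)
  ok <- !is.na(pat)
  list(n_rows_classified = sum(ok),
       n_dmrs_unique = length(unique(t1$dmr_id[ok])),
       n_genes = length(unique(t1$gene[ok])),
       n_pattern_a = length(unique(t1$gene[ok & pat == "A"])),
       n_pattern_b = length(unique(t1$gene[ok & pat == "B"])),
       rows = rows)
}
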