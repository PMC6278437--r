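# End-to-end orchestration: depth filter -> windowed DMR calling on both
# contrasts -> feature annotation and transcript linking -> differential
# expression on both contrasts -> restoration-pattern integration.

default_params <- function() {
  list(window = 1000, step = 500, min_depth = 20, min_cpgs = 2,
       min_diff = 10, max_q = 0.01, lfc = 1, alpha = 0.05,
       min_fc = 1, pseudocount = 0.5, promoter_flank = 1000,
       link_max_distance = 10000, rho_max = 0)
}

#' Run the full methylation--expression restoration pipeline
#'
#' Executes both ordered contrasts (disease vs control, treatment vs
#' disease) through DMR calling and differential expression, annotates
#' and links the union of DMRs to transcripts, classifies restoration
#' patterns in both layers, and integrates them under the inverse
#' correlation rule. Inputs can be in-memory objects or file paths.
#'
#' @param cpg_samples Named list of per-sample CpG tables (or of file
#'   paths, read with [read_cpg_table()]).
#' @param sample_sheet data.frame with `sample_id`, `group`, or a path.
#' @param counts Count matrix (or path for [read_count_matrix()]).
#' @param models A `transcript_models` object (or an annotation path for
#'   [read_annotation()]).
#' @param groups Character vector of the three condition labels, ordered
#'   control, disease, treatment.
#' @param params Named list overriding entries of the default parameter
#'   set (window 1000, step 500, min_depth 20, min_cpgs 2, min_diff 10,
#'   max_q 0.01, lfc 1, alpha 0.05, min_fc 1, pseudocount 0.5,
#'   promoter_flank 1000, link_max_distance 10000, rho_max 0).
#' @param outdir Optional directory for TSV/BED outputs.
#' @return A `restoration_report`: list with the per-stage results
#'   (`dmr1`, `dmr2`, `de1`, `de2`, `links`, `integrated`), the summary
#'   counts, and the echoed parameters.
#' @export
run_pipeline <- function(cpg_samples, sample_sheet, counts, models,
                         groups = c("control", "disease", "treatment"),
                         params = list(), outdir = NULL) {
  p <- utils::modifyList(default_params(), params)
  stopifnot(length(groups) == 3)
  if (is.character(sample_sheet)) sample_sheet <- read_sample_sheet(sample_sheet)
  if (is.character(counts)) counts <- read_count_matrix(counts)
  if (is.character(models)) models <- read_annotation(
    models, promoter_flank = p$promoter_flank)
  if (is.character(cpg_samples))
    cpg_samples <- lapply(setNames(cpg_samples, names(cpg_samples)),
                          read_cpg_table)
  contrast1 <- groups[1:2]          # disease vs control
  contrast2 <- groups[2:3]          # treatment vs disease

  stage <- function(name, expr) {
    message("[", name, "] ...")
    tryCatch(expr, error = function(e)
      stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE))
  }

  cpgs <- stage("align CpGs", build_cpg_set(cpg_samples))
  dmr1 <- stage("DMR disease vs control",
    call_dmrs(cpgs, sample_sheet, contrast1, window = p$window,
              step = p$step, min_depth = p$min_depth, min_cpgs = p$min_cpgs,
              min_diff = p$min_diff, max_q = p$max_q))
  dmr2 <- stage("DMR treatment vs disease",
    call_dmrs(cpgs, sample_sheet, contrast2, window = p$window,
              step = p$step, min_depth = p$min_depth, min_cpgs = p$min_cpgs,
              min_diff = p$min_diff, max_q = p$max_q))
  message("  windows tested: ", nrow(dmr1), " / ", nrow(dmr2))

  rest <- restoration_patterns(dmr1, dmr2, min_diff = p$min_diff,
                               max_q = p$max_q)
  rest_sum <- restoration_summary(rest)

  dmr_union <- unique(c(dmr1$id[dmr1$dmr], dmr2$id[dmr2$dmr], rest$id))
  ann <- stage("annotate", {
    if (length(dmr_union) > 0) {
      regions <- parse_region_id(dmr_union)
      data.frame(id = dmr_union,
                 feature = classify_region(regions, models),
                 stringsAsFactors = FALSE)
    } else data.frame(id = character(), feature = character())
  })
  links <- stage("link transcripts", {
    if (length(rest$id) > 0)
      link_transcripts(rest$id, models,
                       max_distance = p$link_max_distance)
    else data.frame(region_id = character(), transcript_id = character(),
                    gene = character(), distance = integer())
  })

  de1 <- stage("DE disease vs control",
    de_test(counts, sample_sheet, contrast1, pseudocount = p$pseudocount,
            alpha = p$alpha, lfc = p$lfc))
  de2 <- stage("DE treatment vs disease",
    de_test(counts, sample_sheet, contrast2, pseudocount = p$pseudocount,
            alpha = p$alpha, lfc = p$lfc))

  integ <- stage("integrate", {
    betas <- window_betas(cpgs, rest$id, window = p$window, step = p$step)
    cpm <- normalize_counts(counts)
    integrate_patterns(dmr1, dmr2, de1, de2, links,
                       sample_betas = betas, sample_expr = cpm,
                       min_diff = p$min_diff, max_q = p$max_q,
                       min_fc = p$min_fc, alpha = p$alpha,
                       rho_max = p$rho_max)
  })
  isum <- integration_summary(integ)

  s1 <- summary(dmr1); s2 <- summary(dmr2)
  report <- list(
    contrasts = list(contrast1, contrast2),
    params = p,
    n_windows = c(nrow(dmr1), nrow(dmr2)),
    dmr_counts = list(contrast1 = c(hyper = s1$n_hyper, hypo = s1$n_hypo),
                      contrast2 = c(hyper = s2$n_hyper, hypo = s2$n_hypo)),
    dmr_percent = list(contrast1 = s1$percent, contrast2 = s2$percent),
    restoration = rest_sum,
    n_de = c(sum(de1$significant), sum(de2$significant)),
    integration = isum,
    features = if (nrow(ann) > 0) table(ann$feature) else table(character()),
    dmr1 = dmr1, dmr2 = dmr2, de1 = de1, de2 = de2,
    annotation = ann, links = links, integrated = integ)
  class(report) <- "restoration_report"

  if (!is.null(outdir)) {
    dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
    wtsv <- function(x, f) write.table(as.data.frame(x),
      file.path(outdir, f), sep = "\t", quote = FALSE, row.names = FALSE)
    wtsv(dmr1, "windows_disease_vs_control.tsv")
    wtsv(dmr2, "windows_treatment_vs_disease.tsv")
    write_dmr_bed(dmr1[dmr1$dmr, ],
                  file.path(outdir, "dmrs_disease_vs_control.bed"))
    write_dmr_bed(dmr2[dmr2$dmr, ],
                  file.path(outdir, "dmrs_treatment_vs_disease.bed"))
    wtsv(de1, "de_disease_vs_control.tsv")
    wtsv(de2, "de_treatment_vs_disease.tsv")
    wtsv(integ, "integrated_genes.tsv")
  }
  report
}

#' @export
print.restoration_report <- function(x, ...) {
  cat("Restoration-pattern pipeline report\n")
  cat("  contrasts: ", paste(x$contrasts[[1]], collapse = " -> "), "; ",
      paste(x$contrasts[[2]], collapse = " -> "), "\n", sep = "")
  cat("  windows tested: ", x$n_windows[1], " / ", x$n_windows[2], "\n",
      sep = "")
  for (k in 1:2) {
    ct <- x$dmr_counts[[k]]; pc <- x$dmr_percent[[k]]
    cat("  contrast ", k, " DMRs: ", ct["hyper"], " hyper (",
        pc["hyper"], "%), ", ct["hypo"], " hypo (", pc["hypo"], "%)\n",
        sep = "")
  }
  r <- x$restoration
  cat("  restoration DMRs: ", r$n_hyper_hypo, " hyper/hypo + ",
      r$n_hypo_hyper, " hypo/hyper = ", r$total, "\n", sep = "")
  i <- x$integration
  cat("  integrated: ", i$n_dmrs_unique, " DMRs, ", i$n_genes,
      " genes (", i$n_pattern_a, " Pattern A, ", i$n_pattern_b,
      " Pattern B)\n", sep = "")
  invisible(x)
}
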