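# Seeded three-group simulator: beta-binomial methylomes with planted
# window-level group shifts, negative-binomial expression with planted
# signed fold changes, and a promoter-level coupling between the two
# layers so that planted pairs carry a negative methylation--expression
# correlation.

#' Simulation configuration
#'
#' Defaults describe the three-condition study design the package targets
#' (control n = 3, disease n = 3, treatment n = 4) on a toy genome small
#' enough for a full run in well under a minute: 2 chromosomes x 2 Mb at
#' 10 CpGs/kb, Poisson(30) read depth, beta-binomial precision 30
#' (moderate replicate overdispersion), bimodal background methylation
#' (modes near 0.1 and 0.9), a 30-pp planted methylation shift, 4-fold
#' planted expression changes with NB dispersion 0.1, and 20 planted
#' Pattern A + 5 Pattern B genes over 500 null genes.
#'
#' @param n_control,n_disease,n_treatment Group sizes.
#' @param genome Named vector of chromosome lengths (bp).
#' @param cpg_per_kb Background CpG density.
#' @param depth_mean Mean per-CpG per-sample read depth (Poisson).
#' @param bb_precision Beta-binomial precision (larger = less
#'   overdispersion).
#' @param baseline_modes Modes of the bimodal background beta mixture.
#' @param planted_a,planted_b Numbers of planted Pattern A / B genes.
#' @param n_null_genes Unperturbed genes in the count matrix.
#' @param meth_shift Planted window methylation shift, percentage points.
#' @param expr_fc Planted linear fold change.
#' @param nb_dispersion NB dispersion of expression counts.
#' @param expr_mean_log,expr_sd_log Log-normal baseline expression means.
#' @param cpgs_per_planted_window CpGs placed in each planted window.
#' @param seed Integer seed; every draw is reproducible from it.
#' @return List of class `sim_config`.
#' @export
sim_config <- function(n_control = 3, n_disease = 3, n_treatment = 4,
                       genome = c(chr1 = 2e6, chr2 = 2e6),
                       cpg_per_kb = 10, depth_mean = 30,
                       bb_precision = 30, baseline_modes = c(0.1, 0.9),
                       planted_a = 20, planted_b = 5, n_null_genes = 500,
                       meth_shift = 30, expr_fc = 4, nb_dispersion = 0.1,
                       expr_mean_log = log(200), expr_sd_log = 1,
                       cpgs_per_planted_window = 10, seed = 1) {
  cfg <- as.list(environment())
  stopifnot(cfg$meth_shift >= 0, cfg$planted_a >= 0, cfg$planted_b >= 0,
            all(cfg$baseline_modes > 0 & cfg$baseline_modes < 1))
  cfg$groups <- c("control", "disease", "treatment")
  cfg$sample_sheet <- data.frame(
    sample_id = c(paste0("ctl", seq_len(n_control)),
                  paste0("dis", seq_len(n_disease)),
                  paste0("trt", seq_len(n_treatment))),
    group = rep(cfg$groups, c(n_control, n_disease, n_treatment)),
    stringsAsFactors = FALSE)
  class(cfg) <- "sim_config"
  cfg
}

rbetabinom <- function(n, size, mu, precision) {
  p <- rbeta(n, mu * precision, (1 - mu) * precision)
  rbinom(n, size, p)
}

#' Simulate a three-group methylome with planted restoration windows
#'
#' Background CpGs are placed uniformly with betas drawn from a bimodal
#' mixture; planted windows (aligned to the 1000-bp tiling grid, well
#' separated) receive a window-level group shift: Pattern A windows are
#' hypermethylated under disease and restored under treatment, Pattern B
#' hypomethylated then restored. Per CpG and sample, depth is Poisson and
#' the methylated count beta-binomial. Betas are clipped to [0.02, 0.98]
#' (with a warning if the shift forces clipping).
#'
#' @param config A [sim_config()].
#' @return List with `samples` (named list of per-sample CpG tables),
#'   `sample_sheet`, and `truth` (per planted gene: window id, pattern,
#'   true deltas and fold change).
#' @export
simulate_methylome <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  sheet <- config$sample_sheet
  n_planted <- config$planted_a + config$planted_b

  # planted windows: every 10 kb on the tiling grid, round-robin over chroms
  chroms <- names(config$genome)
  pw <- data.frame(chrom = rep(chroms, length.out = n_planted),
                   start = 10000 * seq_len(n_planted) + 1,
                   stringsAsFactors = FALSE)
  if (n_planted > 0 &&
      any(pw$start + 999 > config$genome[pw$chrom]))
    stop("genome too small for the requested planted windows")
  pw$end <- pw$start + 999
  pw$id <- region_id(pw$chrom, pw$start, pw$end)
  pw$pattern <- rep(c("A", "B"), c(config$planted_a, config$planted_b))
  pw$gene <- sprintf("SIM%03d", seq_len(max(1, n_planted)))[seq_len(n_planted)]

  shift <- config$meth_shift / 100
  base_planted <- runif(n_planted, 0.30, 0.60)
  clip <- function(x) pmin(0.98, pmax(0.02, x))
  dis_beta <- ifelse(pw$pattern == "A", base_planted + shift,
                     base_planted - shift)
  if (n_planted > 0 && any(dis_beta < 0.02 | dis_beta > 0.98))
    warning("planted shift clipped into [0.02, 0.98]")
  dis_beta <- clip(dis_beta)
  base_planted <- clip(base_planted)

  # CpG positions: uniform background plus regular CpGs inside planted
  # windows (so every planted window is testable)
  pos_list <- lapply(chroms, function(ch) {
    len <- config$genome[[ch]]
    n_bg <- round(len / 1000 * config$cpg_per_kb)
    sort(unique(sample.int(len, n_bg)))
  })
  names(pos_list) <- chroms
  planted_pos <- lapply(seq_len(n_planted), function(i)
    as.integer(seq(pw$start[i] + 50, pw$end[i] - 50,
                   length.out = config$cpgs_per_planted_window)))
  sites <- data.frame(chrom = rep(chroms, lengths(pos_list)),
                      pos = unlist(pos_list, use.names = FALSE),
                      stringsAsFactors = FALSE)
  if (n_planted > 0)
    sites <- rbind(sites, data.frame(
      chrom = rep(pw$chrom, each = config$cpgs_per_planted_window),
      pos = unlist(planted_pos, use.names = FALSE),
      stringsAsFactors = FALSE))
  sites <- unique(sites)
  sites <- sites[order(sites$chrom, sites$pos), , drop = FALSE]
  ns <- nrow(sites)

  # per-CpG group means: background bimodal, overridden inside planted
  # windows by the window-level group betas
  mode <- sample(config$baseline_modes, ns, replace = TRUE)
  beta_ctl <- clip(rbeta(ns, mode * 20, (1 - mode) * 20))
  beta_dis <- beta_ctl
  beta_trt <- beta_ctl
  if (n_planted > 0) {
    for (i in seq_len(n_planted)) {
      inw <- sites$chrom == pw$chrom[i] & sites$pos >= pw$start[i] &
        sites$pos <= pw$end[i]
      beta_ctl[inw] <- base_planted[i]
      beta_dis[inw] <- dis_beta[i]
      beta_trt[inw] <- base_planted[i]   # restored under treatment
    }
  }
  beta_by_group <- list(control = beta_ctl, disease = beta_dis,
                        treatment = beta_trt)

  samples <- lapply(seq_len(nrow(sheet)), function(j) {
    mu <- beta_by_group[[sheet$group[j]]]
    depth <- rpois(ns, config$depth_mean)
    meth <- rbetabinom(ns, depth, mu, config$bb_precision)
    data.frame(chrom = sites$chrom, pos = sites$pos, strand = "+",
               meth = meth, unmeth = depth - meth,
               stringsAsFactors = FALSE)
  })
  names(samples) <- sheet$sample_id

  truth <- data.frame(gene = pw$gene, dmr_id = pw$id, pattern = pw$pattern,
                      base_beta = base_planted,
                      true_delta1 = 100 * (dis_beta - base_planted),
                      true_delta2 = 100 * (base_planted - dis_beta),
                      true_fc = ifelse(pw$pattern == "A",
                                       -config$expr_fc, config$expr_fc),
                      stringsAsFactors = FALSE)
  list(samples = samples, sample_sheet = sheet, truth = truth)
}

#' Simulate expression counts coupled to planted methylation windows
#'
#' Planted Pattern A genes are expressed at baseline / `expr_fc` under
#' disease and restored under treatment (Pattern B mirrored); null genes
#' share one mean across groups. Counts are negative binomial. The
#' returned annotation places each planted gene's TSS at the centre of
#' its planted window, linking promoter methylation to expression, which
#' induces the negative cross-sample Spearman correlation for planted
#' pairs; null genes live on their own chromosome.
#'
#' @param config A [sim_config()].
#' @param truth Truth table from [simulate_methylome()].
#' @return List with `counts` (matrix with `gene` attribute), `models`
#'   (a [transcript_models()] annotation) and `truth`.
#' @export
simulate_counts <- function(config, truth) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed + 1L)
  sheet <- config$sample_sheet
  n_planted <- nrow(truth)
  n_genes <- n_planted + config$n_null_genes
  gene <- c(truth$gene, sprintf("NULL%04d", seq_len(config$n_null_genes)))
  tx <- paste0("TX_", gene)

  base_mu <- rlnorm(n_genes, config$expr_mean_log, config$expr_sd_log)
  fc_mult <- function(group) {
    mult <- rep(1, n_genes)
    if (n_planted > 0 && group == "disease") {
      a <- truth$pattern == "A"
      mult[seq_len(n_planted)][a] <- 1 / config$expr_fc
      mult[seq_len(n_planted)][!a] <- config$expr_fc
    }
    mult
  }
  counts <- sapply(seq_len(nrow(sheet)), function(j) {
    mu <- base_mu * fc_mult(sheet$group[j])
    rnbinom(n_genes, mu = mu, size = 1 / config$nb_dispersion)
  })
  dimnames(counts) <- list(tx, sheet$sample_id)
  storage.mode(counts) <- "integer"
  attr(counts, "gene") <- setNames(gene, tx)

  # annotation: planted gene TSS at planted-window centre; null genes on
  # a dedicated decoy chromosome, spaced 20 kb apart
  mk_tx <- function(tid, g, chrom, tss) {
    data.frame(transcript_id = tid, gene = g, chrom = chrom,
               strand = "+", start = tss, end = tss + 4999,
               exon_starts = paste(tss, tss + 3000, sep = ","),
               exon_ends = paste(tss + 999, tss + 4999, sep = ","),
               cds_start = tss + 200, cds_end = tss + 4500,
               stringsAsFactors = FALSE)
  }
  rows <- list()
  if (n_planted > 0) {
    pwin <- parse_region_id(truth$dmr_id)
    rows[[1]] <- do.call(rbind, lapply(seq_len(n_planted), function(i)
      mk_tx(tx[i], gene[i], pwin$chrom[i], pwin$start[i] + 500L)))
  }
  rows[[2]] <- do.call(rbind, lapply(seq_len(config$n_null_genes),
    function(i) mk_tx(tx[n_planted + i], gene[n_planted + i], "chrNull",
                      20000L * i)))
  models <- transcript_models(do.call(rbind, rows))
  list(counts = counts, models = models, truth = truth)
}

#' Simulate a complete coupled dataset
#'
#' Convenience wrapper running [simulate_methylome()] then
#' [simulate_counts()].
#'
#' @param config A [sim_config()].
#' @return List `samples`, `sample_sheet`, `counts`, `models`, `truth`.
#' @export
simulate_dataset <- function(config = sim_config()) {
  me <- simulate_methylome(config)
  ex <- simulate_counts(config, me$truth)
  list(samples = me$samples, sample_sheet = me$sample_sheet,
       counts = ex$counts, models = ex$models, truth = me$truth)
}
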