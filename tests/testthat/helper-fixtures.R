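# Shared in-code fixtures for the test suite.

# a two-group sample sheet
two_group_sheet <- function(na = 3, nb = 3, groups = c("a", "b")) {
  data.frame(sample_id = c(paste0("a", seq_len(na)),
                           paste0("b", seq_len(nb))),
             group = rep(groups, c(na, nb)), stringsAsFactors = FALSE)
}

# per-sample CpG tables for one window's worth of sites: meth/depth given
# as CpG x sample matrices
cpg_samples_from_counts <- function(meth, depth, chrom = "chr1",
                                    pos = NULL, sheet = NULL) {
  pos <- pos %||% (100L + 50L * seq_len(nrow(meth)))
  ids <- colnames(meth) %||% sheet$sample_id
  out <- lapply(seq_along(ids), function(j)
    data.frame(chrom = chrom, pos = pos, strand = "+",
               meth = meth[, j], unmeth = depth[, j] - meth[, j],
               stringsAsFactors = FALSE))
  names(out) <- ids
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# a small but fully-featured simulation, shared across tests
small_config <- function(seed = 5, ...) {
  args <- utils::modifyList(
    list(genome = c(chr1 = 3e5, chr2 = 3e5), cpg_per_kb = 8,
         planted_a = 6, planted_b = 3, n_null_genes = 80, seed = seed),
    list(...))
  do.call(sim_config, args)
}

quiet <- function(expr) suppressWarnings(suppressMessages(expr))

# independent Spearman oracle: average ranks + explicit Pearson formula
brute_spearman <- function(x, y) {
  rk <- function(v) vapply(v, function(z)
    sum(v < z) + (sum(v == z) + 1) / 2, numeric(1))
  rx <- rk(x); ry <- rk(y)
  sum((rx - mean(rx)) * (ry - mean(ry))) /
    sqrt(sum((rx - mean(rx))^2) * sum((ry - mean(ry))^2))
}
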