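# Windowed differential methylation: tiling, depth filtering, the
# group-wise binomial likelihood-ratio test with overdispersion correction,
# and DMR calling with the Diff >= 10 pp / q < 0.01 rule.

#' Tile chromosomes into overlapping windows
#'
#' Sliding 1000-bp windows advanced by 500 bp (the defaults), so that away
#' from chromosome edges every base is covered by exactly two windows.
#' Windows are truncated at the chromosome end.
#'
#' @param chrom_lengths Named numeric vector (or list) of chromosome
#'   lengths in bp.
#' @param window,step Window size and step in bp.
#' @return data.frame with `chrom`, `start`, `end` (1-based inclusive) and
#'   `id` in `chr$start$end` form.
#' @export
tile_windows <- function(chrom_lengths, window = 1000, step = 500) {
  window <- as.integer(window); step <- as.integer(step)
  if (is.na(window) || is.na(step) || window < 1 || step < 1)
    stop("window and step must be positive integers")
  chrom_lengths <- unlist(chrom_lengths)
  if (any(chrom_lengths < 1)) stop("chromosome lengths must be >= 1")
  out <- lapply(names(chrom_lengths), function(ch) {
    len <- as.integer(chrom_lengths[[ch]])
    starts <- seq.int(1L, len, by = step)
    data.frame(chrom = ch, start = starts,
               end = pmin(starts + window - 1L, len),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  out$id <- region_id(out$chrom, out$start, out$end)
  out
}

#' Combine per-sample CpG tables into one aligned set
#'
#' Sites are aligned on (chrom, pos, strand) across samples; a site absent
#' from a sample gets depth 0 there (it will simply fail the depth filter).
#' With `destrand = TRUE`, minus-strand cytosines are shifted one base left
#' and merged with the plus-strand mate of the CpG dyad; the default keeps
#' counts per reported cytosine.
#'
#' @param samples Named list of data.frames as from [read_cpg_table()].
#' @param destrand Collapse CpG dyads onto the plus strand?
#' @return An object of class `cpg_set`: list with `sites` (chrom, pos,
#'   strand), integer matrices `meth` and `depth` (sites x samples), and
#'   `samples`.
#' @export
build_cpg_set <- function(samples, destrand = FALSE) {
  stopifnot(is.list(samples), length(samples) > 0)
  if (is.null(names(samples)) || any(names(samples) == ""))
    stop("samples must be a named list keyed by sample_id")
  if (destrand) {
    samples <- lapply(samples, function(s) {
      minus <- s$strand == "-"
      s$pos[minus] <- s$pos[minus] - 1L
      s$strand <- "+"
      agg_m <- rowsum(s$meth, paste(s$chrom, s$pos))
      agg_u <- rowsum(s$unmeth, paste(s$chrom, s$pos))
      key <- rownames(agg_m)
      sp <- strsplit(key, " ", fixed = TRUE)
      data.frame(chrom = vapply(sp, `[`, "", 1),
                 pos = as.integer(vapply(sp, `[`, "", 2)),
                 strand = "+", meth = as.integer(agg_m[, 1]),
                 unmeth = as.integer(agg_u[, 1]), stringsAsFactors = FALSE)
    })
  }
  keys <- lapply(samples, function(s) paste(s$chrom, s$pos, s$strand))
  all_keys <- sort(unique(unlist(keys)))
  n <- length(all_keys)
  meth <- depth <- matrix(0L, n, length(samples),
                          dimnames = list(NULL, names(samples)))
  for (j in seq_along(samples)) {
    idx <- match(keys[[j]], all_keys)
    meth[idx, j] <- samples[[j]]$meth
    depth[idx, j] <- samples[[j]]$meth + samples[[j]]$unmeth
  }
  sp <- strsplit(all_keys, " ", fixed = TRUE)
  sites <- data.frame(chrom = vapply(sp, `[`, "", 1),
                      pos = as.integer(vapply(sp, `[`, "", 2)),
                      strand = vapply(sp, `[`, "", 3),
                      stringsAsFactors = FALSE)
  ord <- order(sites$chrom, sites$pos, sites$strand)
  structure(list(sites = sites[ord, , drop = FALSE],
                 meth = meth[ord, , drop = FALSE],
                 depth = depth[ord, , drop = FALSE],
                 samples = names(samples)),
            class = "cpg_set")
}

#' Depth-filter CpG sites for a comparison
#'
#' A site is retained only if its read depth is at least `min_depth` in
#' every one of the given samples -- the strict per-sample reading of a
#' minimum-coverage rule, so pooled window counts never mix covered and
#' uncovered samples.
#'
#' @param cpgs A `cpg_set` from [build_cpg_set()].
#' @param sample_ids Samples whose depth must all pass (default: all).
#' @param min_depth Minimum per-sample read depth.
#' @return The filtered `cpg_set`, restricted to `sample_ids`.
#' @export
filter_cpgs <- function(cpgs, sample_ids = NULL, min_depth = 20) {
  stopifnot(inherits(cpgs, "cpg_set"), min_depth >= 1)
  sample_ids <- sample_ids %||% cpgs$samples
  missing <- setdiff(sample_ids, cpgs$samples)
  if (length(missing) > 0) stop("unknown sample(s): ",
                                paste(missing, collapse = ", "))
  d <- cpgs$depth[, sample_ids, drop = FALSE]
  keep <- rowSums(d >= min_depth) == length(sample_ids)
  structure(list(sites = cpgs$sites[keep, , drop = FALSE],
                 meth = cpgs$meth[keep, sample_ids, drop = FALSE],
                 depth = d[keep, , drop = FALSE],
                 samples = sample_ids),
            class = "cpg_set")
}

# Map each site to the tiled windows containing it. Returns a data.frame
# (site_index, chrom, win_start) with one row per (site, window) pair.
site_window_map <- function(sites, window, step) {
  k <- ceiling(window / step)
  maps <- vector("list", k)
  base_idx <- (sites$pos - 1L) %/% step
  for (j in seq_len(k) - 1L) {
    s_idx <- base_idx - j
    start <- s_idx * step + 1L
    ok <- start >= 1L & sites$pos <= start + window - 1L
    maps[[j + 1L]] <- data.frame(site = which(ok),
                                 chrom = sites$chrom[ok],
                                 win_start = start[ok],
                                 stringsAsFactors = FALSE)
  }
  do.call(rbind, maps)
}

# Closed-form group-vs-null binomial LRT on pooled window counts.
# The one-covariate logistic model's MLE is the pooled proportion per
# group, so deviances are available without iterative fitting.
# ma/da etc. are windows x samples matrices for the two groups.
window_lrt <- function(ma, da, mb, db) {
  Ma <- rowSums(ma); Da <- rowSums(da)
  Mb <- rowSums(mb); Db <- rowSums(db)
  pa <- ifelse(Da > 0, Ma / Da, NA_real_)
  pb <- ifelse(Db > 0, Mb / Db, NA_real_)
  p0 <- (Ma + Mb) / (Da + Db)
  ll_grp <- xlogy(Ma, pa) + xlogy(Da - Ma, 1 - pa) +
    xlogy(Mb, pb) + xlogy(Db - Mb, 1 - pb)
  ll_null <- xlogy(Ma + Mb, p0) + xlogy(Da + Db - Ma - Mb, 1 - p0)
  lrt <- pmax(0, 2 * (ll_grp - ll_null))
  # Pearson residual chi-square around the group fit, for overdispersion
  pearson_grp <- function(m, d, p) {
    e <- d * p
    v <- d * p * (1 - p)
    t <- (m - e)^2 / v
    t[!is.finite(t)] <- 0      # depth 0 or fitted proportion 0/1
    rowSums(t)
  }
  x2 <- pearson_grp(ma, da, pa) + pearson_grp(mb, db, pb)
  df <- rowSums(da > 0) + rowSums(db > 0) - 2L
  list(beta_a = pa, beta_b = pb, lrt = lrt, x2 = x2, df = pmax(0L, df))
}

#' Test one window for differential methylation
#'
#' Per-sample methylated/unmethylated counts of the CpGs in a window are
#' summed, and group membership is tested by the logistic-regression
#' likelihood-ratio test (chi-square, 1 df) on those binomial counts. By
#' default the statistic is scaled by an overdispersion factor (Pearson
#' chi-square / residual df; here from this window alone, pooled across
#' windows in [call_dmrs()]), floored at 1, to keep the test calibrated
#' when replicate-to-replicate variation exceeds binomial. With a single
#' sample per group `method = "auto"` falls back to Fisher's exact test on
#' the pooled 2x2 table.
#'
#' @param meth_a,depth_a Numeric matrices (CpGs x samples of group a) of
#'   methylated counts and depths; likewise `meth_b`, `depth_b`.
#' @param method `"auto"` (default), `"lrt"` (uncorrected LRT),
#'   `"qlrt"` (dispersion-corrected LRT) or `"fisher"`.
#' @return A one-row data.frame with `n_cpgs`, `beta_a`, `beta_b`,
#'   `delta_beta` (percentage points, b minus a), `p` and `direction`
#'   (`hyper`/`hypo` of b vs a), or `NULL` when fewer than two CpGs or a
#'   group has zero total depth.
#' @param min_cpgs Minimum number of CpGs for the window to be tested.
#' @export
test_window <- function(meth_a, depth_a, meth_b, depth_b,
                        method = c("auto", "qlrt", "lrt", "fisher"),
                        min_cpgs = 2) {
  method <- match.arg(method)
  meth_a <- rbind(meth_a); depth_a <- rbind(depth_a)
  meth_b <- rbind(meth_b); depth_b <- rbind(depth_b)
  n_cpgs <- nrow(meth_a)
  if (n_cpgs < min_cpgs) return(NULL)
  ma <- matrix(colSums(meth_a), 1); da <- matrix(colSums(depth_a), 1)
  mb <- matrix(colSums(meth_b), 1); db <- matrix(colSums(depth_b), 1)
  if (sum(da) == 0 || sum(db) == 0) {
    warning("window skipped: zero total depth in one group")
    return(NULL)
  }
  if (method == "auto")
    method <- if (ncol(ma) < 2 || ncol(mb) < 2) "fisher" else "qlrt"
  st <- window_lrt(ma, da, mb, db)
  p <- switch(method,
    fisher = fisher.test(matrix(c(sum(ma), sum(da) - sum(ma),
                                  sum(mb), sum(db) - sum(mb)), 2))$p.value,
    lrt = pchisq(st$lrt, df = 1, lower.tail = FALSE),
    qlrt = {
      phi <- if (st$df >= 1) max(1, st$x2 / st$df) else 1
      pchisq(st$lrt / phi, df = 1, lower.tail = FALSE)
    })
  delta <- 100 * (st$beta_b - st$beta_a)
  data.frame(n_cpgs = n_cpgs, beta_a = st$beta_a, beta_b = st$beta_b,
             delta_beta = delta, p = p,
             direction = ifelse(delta > 0, "hyper",
                                ifelse(delta < 0, "hypo", NA_character_)),
             stringsAsFactors = FALSE)
}

#' Call differentially methylated regions between two groups
#'
#' Tiles the covered genome into overlapping windows ([tile_windows()]
#' geometry), pools depth-filtered CpG counts per window and sample, tests
#' every window with at least `min_cpgs` CpGs by the group logistic LRT
#' (overdispersion-corrected with a dispersion factor pooled across all
#' tested windows of the contrast; Fisher's exact fallback when either
#' group has a single sample), adjusts p-values by Benjamini-Hochberg over
#' all tested windows, and flags as DMRs the windows with
#' `|delta_beta| >= min_diff` and `q < max_q`.
#'
#' Overlapping windows are tested and reported independently; adjacent
#' significant windows are never merged.
#'
#' @param samples Named list of per-sample CpG tables, or a `cpg_set`.
#' @param sample_sheet data.frame with `sample_id`, `group`.
#' @param contrast Character vector `c(group_a, group_b)`; `delta_beta`
#'   and `direction` describe group b relative to group a.
#' @param window,step Tiling geometry in bp.
#' @param min_depth Per-sample minimum CpG read depth within the contrast.
#' @param min_cpgs Minimum tested CpGs per window.
#' @param min_diff Minimum |delta beta| in percentage points for a DMR.
#' @param max_q BH q-value cutoff for a DMR.
#' @param method Test method, see [test_window()]; `"auto"` picks the
#'   corrected LRT, or Fisher when a group has one sample.
#' @param destrand Collapse CpG dyads before analysis (only used when
#'   `samples` is a raw list).
#' @return A `dmr_result`: data.frame of all tested windows with columns
#'   `id`, `chrom`, `start`, `end`, `n_cpgs`, `beta_a`, `beta_b`,
#'   `delta_beta`, `p`, `q`, `direction` and logical `dmr`. Attributes
#'   carry the contrast and parameters.
#' @export
call_dmrs <- function(samples, sample_sheet, contrast,
                      window = 1000, step = 500, min_depth = 20,
                      min_cpgs = 2, min_diff = 10, max_q = 0.01,
                      method = c("auto", "qlrt", "lrt", "fisher"),
                      destrand = FALSE) {
  method <- match.arg(method)
  validate_sample_sheet(sample_sheet)
  stopifnot(length(contrast) == 2)
  if (!all(contrast %in% sample_sheet$group))
    stop("contrast group(s) not in sample sheet: ",
         paste(setdiff(contrast, sample_sheet$group), collapse = ", "))
  ids_a <- sample_sheet$sample_id[sample_sheet$group == contrast[1]]
  ids_b <- sample_sheet$sample_id[sample_sheet$group == contrast[2]]
  cpgs <- if (inherits(samples, "cpg_set")) samples
          else build_cpg_set(samples, destrand = destrand)
  cpgs <- filter_cpgs(cpgs, c(ids_a, ids_b), min_depth = min_depth)

  empty <- data.frame(id = character(), chrom = character(),
                      start = integer(), end = integer(),
                      n_cpgs = integer(), beta_a = numeric(),
                      beta_b = numeric(), delta_beta = numeric(),
                      p = numeric(), q = numeric(), direction = character(),
                      dmr = logical(), stringsAsFactors = FALSE)
  params <- list(window = window, step = step, min_depth = min_depth,
                 min_cpgs = min_cpgs, min_diff = min_diff, max_q = max_q,
                 method = method)
  finish <- function(res) {
    attr(res, "contrast") <- contrast
    attr(res, "params") <- params
    class(res) <- c("dmr_result", "data.frame")
    res
  }
  if (nrow(cpgs$sites) == 0) {
    warning("no CpGs pass the depth filter; no testable windows")
    return(finish(empty))
  }
  map <- site_window_map(cpgs$sites, window, step)
  wkey <- paste(map$chrom, map$win_start)
  # per-window, per-sample pooled counts
  meth_w <- rowsum(cpgs$meth[map$site, , drop = FALSE], wkey)
  depth_w <- rowsum(cpgs$depth[map$site, , drop = FALSE], wkey)
  n_cpgs <- as.integer(table(wkey)[rownames(meth_w)])
  keep <- n_cpgs >= min_cpgs
  if (!any(keep)) {
    warning("no windows with >= ", min_cpgs, " CpGs; no testable windows")
    return(finish(empty))
  }
  meth_w <- meth_w[keep, , drop = FALSE]
  depth_w <- depth_w[keep, , drop = FALSE]
  n_cpgs <- n_cpgs[keep]
  ma <- meth_w[, ids_a, drop = FALSE]; da <- depth_w[, ids_a, drop = FALSE]
  mb <- meth_w[, ids_b, drop = FALSE]; db <- depth_w[, ids_b, drop = FALSE]
  ok <- rowSums(da) > 0 & rowSums(db) > 0
  if (any(!ok)) warning(sum(!ok), " window(s) skipped: zero depth in a group")
  ma <- ma[ok, , drop = FALSE]; da <- da[ok, , drop = FALSE]
  mb <- mb[ok, , drop = FALSE]; db <- db[ok, , drop = FALSE]
  n_cpgs <- n_cpgs[ok]
  if (nrow(ma) == 0) {
    warning("no testable windows")
    return(finish(empty))
  }
  if (method == "auto")
    method <- if (length(ids_a) < 2 || length(ids_b) < 2) "fisher" else "qlrt"
  st <- window_lrt(ma, da, mb, db)
  p <- switch(method,
    lrt = pchisq(st$lrt, df = 1, lower.tail = FALSE),
    qlrt = {
      # common overdispersion pooled across windows: stabler than the
      # per-window estimate, whose few residual df make chi-square
      # reference anti-conservative
      phi <- max(1, sum(st$x2) / max(1, sum(st$df)))
      pchisq(st$lrt / phi, df = 1, lower.tail = FALSE)
    },
    fisher = vapply(seq_len(nrow(ma)), function(i) {
      fisher.test(matrix(c(sum(ma[i, ]), sum(da[i, ]) - sum(ma[i, ]),
                           sum(mb[i, ]), sum(db[i, ]) - sum(mb[i, ])),
                         2))$p.value
    }, numeric(1)))
  wins <- do.call(rbind, strsplit(rownames(ma), " ", fixed = TRUE))
  start <- as.integer(wins[, 2])
  delta <- 100 * (st$beta_b - st$beta_a)
  res <- data.frame(chrom = wins[, 1], start = start,
                    end = start + as.integer(window) - 1L,
                    n_cpgs = n_cpgs, beta_a = st$beta_a, beta_b = st$beta_b,
                    delta_beta = delta, p = p,
                    q = p.adjust(p, method = "BH"),
                    direction = ifelse(delta > 0, "hyper",
                                       ifelse(delta < 0, "hypo",
                                              NA_character_)),
                    stringsAsFactors = FALSE)
  res$id <- region_id(res$chrom, res$start, res$end)
  res$dmr <- abs(res$delta_beta) >= min_diff & res$q < max_q
  res <- res[order(res$chrom, res$start),
             c("id", "chrom", "start", "end", "n_cpgs", "beta_a", "beta_b",
               "delta_beta", "p", "q", "direction", "dmr")]
  rownames(res) <- NULL
  finish(res)
}

#' @export
print.dmr_result <- function(x, ...) {
  ct <- attr(x, "contrast")
  cat("Windowed differential methylation: ", ct[2], " vs ", ct[1], "\n",
      sep = "")
  cat("  windows tested: ", nrow(x), "; DMRs: ", sum(x$dmr),
      " (", sum(x$dmr & x$delta_beta > 0), " hyper, ",
      sum(x$dmr & x$delta_beta < 0), " hypo)\n", sep = "")
  p <- attr(x, "params")
  cat("  thresholds: |delta beta| >= ", p$min_diff, " pp, q < ", p$max_q,
      ", >= ", p$min_cpgs, " CpGs, depth >= ", p$min_depth, "\n", sep = "")
  if (nrow(x) > 0) print(head(as.data.frame(x), 5))
  invisible(x)
}

#' @export
summary.dmr_result <- function(object, ...) {
  total <- nrow(object)
  n_hyper <- sum(object$dmr & object$delta_beta > 0)
  n_hypo <- sum(object$dmr & object$delta_beta < 0)
  list(contrast = attr(object, "contrast"), n_windows = total,
       n_hyper = n_hyper, n_hypo = n_hypo,
       percent = if (total > 0) dmr_summary(n_hyper, n_hypo, total)
                 else c(hyper = NA_real_, hypo = NA_real_))
}

#' Hyper/hypo DMR percentages of tested bins
#'
#' @param n_hyper,n_hypo Counts of hyper- and hypomethylated DMRs.
#' @param n_total_bins Total number of tested windows (bins).
#' @return Named numeric vector `c(hyper=, hypo=)`, percentages rounded to
#'   two decimals.
#' @export
dmr_summary <- function(n_hyper, n_hypo, n_total_bins) {
  if (n_total_bins <= 0) stop("n_total_bins must be positive")
  if (n_hyper + n_hypo > n_total_bins)
    stop("more DMRs than tested bins")
  c(hyper = round(100 * n_hyper / n_total_bins, 2),
    hypo = round(100 * n_hypo / n_total_bins, 2))
}
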