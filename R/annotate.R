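# Genomic-feature classification of windows/DMRs and DMR -> transcript
# linking. Six feature classes: promoter, 5' UTR, 3' UTR, CDS, intron,
# intergenic, assigned with fixed precedence over all overlapping
# transcripts.

FEATURE_PRECEDENCE <- c("promoter", "utr5", "utr3", "cds", "intron",
                        "intergenic")

#' Build transcript models
#'
#' Constructs the internal annotation object used by [classify_region()]
#' and [link_transcripts()]. Per transcript the promoter is TSS +/-
#' `promoter_flank` bp (strand-aware TSS); 5'/3' UTRs are the exonic parts
#' outside the CDS span on the respective side; introns are the gene body
#' minus exons. Exonic parts of transcripts without a CDS are ranked at
#' the 3' UTR level for precedence purposes.
#'
#' @param df data.frame with columns `transcript_id`, `gene`, `chrom`,
#'   `strand` (+/-), `start`, `end` (1-based transcript span),
#'   `exon_starts`, `exon_ends` (comma-separated 1-based inclusive), and
#'   optional `cds_start`, `cds_end` (NA for non-coding).
#' @param promoter_flank Promoter half-width in bp around the TSS.
#' @return Object of class `transcript_models`.
#' @export
transcript_models <- function(df, promoter_flank = 1000) {
  need <- c("transcript_id", "gene", "chrom", "strand", "start", "end",
            "exon_starts", "exon_ends")
  if (!all(need %in% names(df)))
    stop("missing columns: ", paste(setdiff(need, names(df)), collapse = ", "))
  if (!all(df$strand %in% c("+", "-"))) stop("strand must be + or -")
  if (is.null(df$cds_start)) df$cds_start <- NA_integer_
  if (is.null(df$cds_end)) df$cds_end <- NA_integer_
  df$tss <- ifelse(df$strand == "+", df$start, df$end)

  split_pos <- function(x) lapply(strsplit(as.character(x), ","),
                                  function(v) as.integer(trimws(v)))
  ex_s <- split_pos(df$exon_starts)
  ex_e <- split_pos(df$exon_ends)

  feat <- list()
  add <- function(class, chrom, start, end, i) {
    keep <- start <= end
    if (!any(keep)) return()
    feat[[length(feat) + 1]] <<- data.frame(
      class = class, chrom = chrom, start = pmax(1L, start[keep]),
      end = end[keep], transcript_id = df$transcript_id[i],
      gene = df$gene[i], stringsAsFactors = FALSE)
  }
  for (i in seq_len(nrow(df))) {
    es <- ex_s[[i]]; ee <- ex_e[[i]]
    o <- order(es); es <- es[o]; ee <- ee[o]
    if (any(es[-1] <= ee[-length(ee)]))
      stop("overlapping/unsorted exons in ", df$transcript_id[i])
    add("promoter", df$chrom[i], df$tss[i] - promoter_flank,
        df$tss[i] + promoter_flank, i)
    cs <- df$cds_start[i]; ce <- df$cds_end[i]
    if (!is.na(cs) && !is.na(ce)) {
      add("cds", df$chrom[i], pmax(es, cs), pmin(ee, ce), i)
      left_s <- es; left_e <- pmin(ee, cs - 1L)        # exonic, left of CDS
      right_s <- pmax(es, ce + 1L); right_e <- ee      # exonic, right of CDS
      if (df$strand[i] == "+") {
        add("utr5", df$chrom[i], left_s, left_e, i)
        add("utr3", df$chrom[i], right_s, right_e, i)
      } else {
        add("utr3", df$chrom[i], left_s, left_e, i)
        add("utr5", df$chrom[i], right_s, right_e, i)
      }
    } else {
      add("utr3", df$chrom[i], es, ee, i)   # non-coding exons
    }
    # introns: gaps between consecutive exons
    if (length(es) > 1)
      add("intron", df$chrom[i], ee[-length(ee)] + 1L, es[-1] - 1L, i)
  }
  feat <- do.call(rbind, feat)
  feat_gr <- GenomicRanges::GRanges(feat$chrom,
                                    IRanges::IRanges(feat$start, feat$end))
  S4Vectors::mcols(feat_gr)$class <- feat$class
  S4Vectors::mcols(feat_gr)$transcript_id <- feat$transcript_id
  body_gr <- GenomicRanges::GRanges(df$chrom,
                                    IRanges::IRanges(df$start, df$end))
  prom_gr <- GenomicRanges::GRanges(df$chrom,
    IRanges::IRanges(pmax(1L, df$tss - promoter_flank),
                     df$tss + promoter_flank))
  tss_gr <- GenomicRanges::GRanges(df$chrom,
                                   IRanges::IRanges(df$tss, df$tss))
  structure(list(transcripts = df, features = feat_gr, body = body_gr,
                 promoter = prom_gr, tss = tss_gr,
                 promoter_flank = promoter_flank),
            class = "transcript_models")
}

#' @export
print.transcript_models <- function(x, ...) {
  cat("transcript_models: ", nrow(x$transcripts), " transcripts, ",
      length(unique(x$transcripts$gene)), " genes, promoter = TSS +/- ",
      x$promoter_flank, " bp\n", sep = "")
  invisible(x)
}

# put two GRanges on the union of their seqlevels so overlap queries on
# disjoint chromosome sets stay silent
align_seqlevels <- function(a, b) {
  lv <- union(GenomeInfoDb::seqlevels(a), GenomeInfoDb::seqlevels(b))
  GenomeInfoDb::seqlevels(a) <- lv
  GenomeInfoDb::seqlevels(b) <- lv
  list(a, b)
}

regions_to_granges <- function(regions) {
  if (is.character(regions)) regions <- parse_region_id(regions)
  GenomicRanges::GRanges(regions$chrom,
                         IRanges::IRanges(regions$start, regions$end))
}

#' Classify regions into genomic feature classes
#'
#' Each region gets exactly one of promoter, utr5, utr3, cds, intron,
#' intergenic, chosen by fixed precedence (promoter first) over all
#' transcripts it overlaps by at least one base.
#'
#' @param regions data.frame with `chrom`, `start`, `end` (1-based), or a
#'   character vector of `chr$start$end` ids.
#' @param models A `transcript_models` object.
#' @return Character vector of feature classes, one per region.
#' @export
classify_region <- function(regions, models) {
  stopifnot(inherits(models, "transcript_models"))
  gr <- regions_to_granges(regions)
  al <- align_seqlevels(gr, models$features)
  gr <- al[[1]]; feats <- al[[2]]
  out <- rep("intergenic", length(gr))
  cls <- S4Vectors::mcols(feats)$class
  for (class in setdiff(FEATURE_PRECEDENCE, "intergenic")) {
    unset <- out == "intergenic"
    if (!any(unset)) break
    hit <- IRanges::overlapsAny(gr[unset], feats[cls == class])
    out[which(unset)[hit]] <- class
  }
  out
}

#' Link regions to transcripts
#'
#' A region is linked to every transcript whose promoter or gene body it
#' overlaps (distance 0); regions touching nothing are linked to the
#' transcript(s) with the nearest TSS within `max_distance` bp. Ties are
#' kept (all equidistant transcripts returned) and links are ordered by
#' distance, then transcript id.
#'
#' @param regions data.frame with `chrom`, `start`, `end`, or character
#'   ids.
#' @param models A `transcript_models` object.
#' @param max_distance Maximum TSS distance in bp for non-overlapping
#'   links.
#' @return data.frame with `region_id`, `transcript_id`, `gene`,
#'   `distance`.
#' @export
link_transcripts <- function(regions, models, max_distance = 10000) {
  stopifnot(inherits(models, "transcript_models"), max_distance >= 0)
  if (is.character(regions)) regions <- parse_region_id(regions)
  gr <- regions_to_granges(regions)
  gr <- align_seqlevels(gr, models$features)[[1]]
  prom <- align_seqlevels(models$promoter, gr)[[1]]
  body <- align_seqlevels(models$body, gr)[[1]]
  tss <- align_seqlevels(models$tss, gr)[[1]]
  ids <- region_id(regions$chrom, regions$start, regions$end)
  tx <- models$transcripts
  res <- list()
  ov1 <- GenomicRanges::findOverlaps(gr, prom)
  ov2 <- GenomicRanges::findOverlaps(gr, body)
  direct <- unique(rbind(
    data.frame(r = S4Vectors::queryHits(ov1), t = S4Vectors::subjectHits(ov1)),
    data.frame(r = S4Vectors::queryHits(ov2), t = S4Vectors::subjectHits(ov2))))
  if (nrow(direct) > 0)
    res[[1]] <- data.frame(region_id = ids[direct$r],
                           transcript_id = tx$transcript_id[direct$t],
                           gene = tx$gene[direct$t], distance = 0L,
                           stringsAsFactors = FALSE)
  no_hit <- setdiff(seq_along(gr), direct$r)
  if (length(no_hit) > 0) {
    d <- GenomicRanges::distance(rep(gr[no_hit], each = length(tss)),
                                 rep(tss, length(no_hit)))
    dm <- matrix(d, nrow = length(tss))
    near <- lapply(seq_along(no_hit), function(k) {
      dk <- dm[, k]
      ok <- !is.na(dk) & dk <= max_distance
      if (!any(ok)) return(NULL)
      best <- min(dk[ok])
      sel <- which(ok & dk == best)
      data.frame(region_id = ids[no_hit[k]],
                 transcript_id = tx$transcript_id[sel],
                 gene = tx$gene[sel], distance = as.integer(best),
                 stringsAsFactors = FALSE)
    })
    res <- c(res, near)
  }
  out <- do.call(rbind, res)
  if (is.null(out))
    return(data.frame(region_id = character(), transcript_id = character(),
                      gene = character(), distance = integer(),
                      stringsAsFactors = FALSE))
  out <- out[order(match(out$region_id, ids), out$distance,
                   out$transcript_id), ]
  rownames(out) <- NULL
  out
}

#' Read a transcript annotation (BED12 or GTF)
#'
#' @param path Annotation file; format guessed from the extension unless
#'   given. BED12 `name` fields of the form `transcript|gene` are split;
#'   otherwise gene = name. GTF needs `transcript_id` and `gene_id` (or
#'   `gene_name`) attributes on exon/CDS features.
#' @param format `"auto"`, `"bed"` or `"gtf"`.
#' @param promoter_flank Passed to [transcript_models()].
#' @return A `transcript_models` object.
#' @export
read_annotation <- function(path, format = c("auto", "bed", "gtf"),
                            promoter_flank = 1000) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.bed$", path, ignore.case = TRUE)) "bed"
              else if (grepl("\\.(gtf|gff)$", path, ignore.case = TRUE)) "gtf"
              else stop("cannot guess annotation format of ", path)
  }
  if (format == "bed") {
    gr <- rtracklayer::import(path, format = "BED")
    blocks <- rtracklayer::blocks(gr)
    name <- S4Vectors::mcols(gr)$name
    sp <- strsplit(name, "|", fixed = TRUE)
    thick <- S4Vectors::mcols(gr)$thick
    cds_s <- BiocGenerics::start(thick)
    cds_e <- BiocGenerics::end(thick)
    no_cds <- is.na(cds_s) | cds_e < cds_s
    df <- data.frame(
      transcript_id = vapply(sp, `[`, "", 1),
      gene = vapply(sp, function(v) if (length(v) > 1) v[2] else v[1], ""),
      chrom = as.character(GenomicRanges::seqnames(gr)),
      strand = as.character(BiocGenerics::strand(gr)),
      start = BiocGenerics::start(gr), end = BiocGenerics::end(gr),
      exon_starts = vapply(blocks, function(b)
        paste(BiocGenerics::start(b), collapse = ","), ""),
      exon_ends = vapply(blocks, function(b)
        paste(BiocGenerics::end(b), collapse = ","), ""),
      cds_start = ifelse(no_cds, NA_integer_, cds_s),
      cds_end = ifelse(no_cds, NA_integer_, cds_e),
      stringsAsFactors = FALSE)
  } else {
    gr <- rtracklayer::import(path, format = "GFF")
    mc <- S4Vectors::mcols(gr)
    ex <- gr[mc$type == "exon"]
    cds <- gr[mc$type == "CDS"]
    gene_of <- function(g) {
      m <- S4Vectors::mcols(g)
      if (!is.null(m$gene_name) && !all(is.na(m$gene_name))) m$gene_name
      else m$gene_id
    }
    tx_ids <- unique(S4Vectors::mcols(ex)$transcript_id)
    rows <- lapply(tx_ids, function(t) {
      e <- ex[S4Vectors::mcols(ex)$transcript_id == t]
      e <- e[order(BiocGenerics::start(e))]
      cc <- cds[S4Vectors::mcols(cds)$transcript_id == t]
      data.frame(
        transcript_id = t, gene = gene_of(e)[1],
        chrom = as.character(GenomicRanges::seqnames(e))[1],
        strand = as.character(BiocGenerics::strand(e))[1],
        start = min(BiocGenerics::start(e)), end = max(BiocGenerics::end(e)),
        exon_starts = paste(BiocGenerics::start(e), collapse = ","),
        exon_ends = paste(BiocGenerics::end(e), collapse = ","),
        cds_start = if (length(cc)) min(BiocGenerics::start(cc)) else NA_integer_,
        cds_end = if (length(cc)) max(BiocGenerics::end(cc)) else NA_integer_,
        stringsAsFactors = FALSE)
    })
    df <- do.call(rbind, rows)
  }
  transcript_models(df, promoter_flank = promoter_flank)
}
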