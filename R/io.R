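# Tabular IO: per-CpG count tables, sample sheets, count matrices, DMR BED.

empty_cpg_table <- function() {
  data.frame(chrom = character(), pos = integer(), strand = character(),
             meth = integer(), unmeth = integer(), stringsAsFactors = FALSE)
}

#' Read a per-CpG methylation count table
#'
#' Reads a whitespace- or tab-delimited cytosine report with columns
#' chromosome, 1-based position, strand, methylated read count,
#' unmethylated read count. Extra columns (e.g. context fields of a
#' Bismark-style cytosine report) are ignored. A header line is detected by
#' type-sniffing the first row. Strands are kept as reported; see
#' [build_cpg_set()] for optional dyad collapsing.
#'
#' @param path Path to the table.
#' @param sample_id Optional sample label attached as an attribute.
#' @return A data.frame with columns `chrom`, `pos`, `strand`, `meth`,
#'   `unmeth`. Per-site depth is `meth + unmeth`; the beta value is
#'   `meth / depth` where depth is positive.
#' @export
read_cpg_table <- function(path, sample_id = NULL) {
  if (!file.exists(path)) stop("no such file: ", path)
  nf <- tryCatch(count.fields(path, comment.char = "#"),
                 error = function(e) stop("cannot parse ", path, ": ",
                                          conditionMessage(e)))
  nf <- nf[!is.na(nf)]
  if (length(nf) == 0) return(empty_cpg_table())
  bad <- which(nf < 5)
  if (length(bad) > 0)
    stop("parse error in ", path, ": line ", bad[1],
         " has ", nf[bad[1]], " fields (>= 5 required)")
  x <- read.table(path, header = FALSE, colClasses = "character",
                  comment.char = "#", stringsAsFactors = FALSE)
  offset <- 0L
  if (suppressWarnings(is.na(as.numeric(x[1, 2])))) {   # header row
    x <- x[-1, , drop = FALSE]
    offset <- 1L
  }
  if (nrow(x) == 0) return(empty_cpg_table())
  num <- function(col, what) {
    v <- suppressWarnings(as.numeric(x[[col]]))
    if (anyNA(v))
      stop("parse error in ", path, ": non-numeric ", what,
           " at line ", which(is.na(v))[1] + offset)
    if (any(v != round(v)))
      stop("validation error in ", path, ": non-integral ", what,
           " at line ", which(v != round(v))[1] + offset)
    v
  }
  pos <- num(2, "position")
  meth <- num(4, "methylated count")
  unmeth <- num(5, "unmethylated count")
  if (any(meth < 0) || any(unmeth < 0))
    stop("validation error in ", path, ": negative count at line ",
         which(meth < 0 | unmeth < 0)[1] + offset)
  if (any(pos < 1))
    stop("validation error in ", path, ": non-positive position at line ",
         which(pos < 1)[1] + offset)
  strand <- x[[3]]
  if (!all(strand %in% c("+", "-")))
    stop("validation error in ", path, ": strand must be + or - at line ",
         which(!strand %in% c("+", "-"))[1] + offset)
  out <- data.frame(chrom = x[[1]], pos = as.integer(pos), strand = strand,
                    meth = as.integer(meth), unmeth = as.integer(unmeth),
                    stringsAsFactors = FALSE)
  if (!is.null(sample_id)) attr(out, "sample_id") <- sample_id
  out
}

#' Write a per-CpG count table
#'
#' Inverse of [read_cpg_table()]; tab-delimited with a header line.
#'
#' @param sites data.frame as returned by [read_cpg_table()].
#' @param path Output path.
#' @export
write_cpg_table <- function(sites, path) {
  write.table(sites[, c("chrom", "pos", "strand", "meth", "unmeth")],
              path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a sample sheet
#'
#' Two-column table mapping `sample_id` to `group`.
#'
#' @param path Path to a TSV with columns sample_id and group (header
#'   optional).
#' @return data.frame with columns `sample_id`, `group`.
#' @export
read_sample_sheet <- function(path) {
  x <- read.table(path, header = FALSE, colClasses = "character",
                  stringsAsFactors = FALSE)
  if (ncol(x) < 2) stop("sample sheet needs two columns: sample_id, group")
  if (identical(tolower(x[1, 1]), "sample_id")) x <- x[-1, , drop = FALSE]
  out <- data.frame(sample_id = x[[1]], group = x[[2]],
                    stringsAsFactors = FALSE)
  validate_sample_sheet(out)
  out
}

validate_sample_sheet <- function(sheet) {
  stopifnot(is.data.frame(sheet),
            all(c("sample_id", "group") %in% names(sheet)))
  if (anyDuplicated(sheet$sample_id))
    stop("duplicate sample_id in sample sheet: ",
         sheet$sample_id[duplicated(sheet$sample_id)][1])
  if (any(table(sheet$group) < 1)) stop("empty group in sample sheet")
  invisible(sheet)
}

#' Read a transcript/gene count matrix
#'
#' TSV with transcript ids in the first column, an optional non-numeric
#' gene-symbol second column, and one integer count column per sample.
#'
#' @param path Path to the TSV (header row required).
#' @return Integer matrix with transcript rownames; if a gene column was
#'   present it is attached as attribute `gene` (named character vector).
#' @export
read_count_matrix <- function(path) {
  x <- read.table(path, header = TRUE, sep = "\t", check.names = FALSE,
                  stringsAsFactors = FALSE)
  ids <- as.character(x[[1]])
  x <- x[, -1, drop = FALSE]
  gene <- NULL
  if (ncol(x) > 0 && !is.numeric(x[[1]])) {
    gene <- setNames(as.character(x[[1]]), ids)
    x <- x[, -1, drop = FALSE]
  }
  m <- as.matrix(x)
  if (any(m < 0)) stop("negative entries in count matrix")
  storage.mode(m) <- "integer"
  rownames(m) <- ids
  if (!is.null(gene)) attr(m, "gene") <- gene
  m
}

#' Write a count matrix
#' @param m Count matrix (transcript rownames), optionally with a `gene`
#'   attribute as produced by [read_count_matrix()].
#' @param path Output path.
#' @export
write_count_matrix <- function(m, path) {
  df <- data.frame(transcript_id = rownames(m), stringsAsFactors = FALSE)
  g <- attr(m, "gene")
  if (!is.null(g)) df$gene <- unname(g[rownames(m)])
  df <- cbind(df, as.data.frame(m, check.names = FALSE))
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Region identifiers in chr$start$end form
#'
#' 1-based inclusive coordinates joined with `$`, the conventional id for a
#' tiled window (e.g. `chr5$75579001$75580000`).
#'
#' @param chrom,start,end Vectors of equal length.
#' @return Character vector of ids.
#' @export
region_id <- function(chrom, start, end) paste(chrom, start, end, sep = "$")

#' Parse chr$start$end identifiers
#' @param id Character vector of ids produced by [region_id()].
#' @return data.frame with columns `chrom`, `start`, `end` (1-based
#'   inclusive).
#' @export
parse_region_id <- function(id) {
  parts <- strsplit(id, "$", fixed = TRUE)
  if (any(lengths(parts) != 3)) stop("malformed region id")
  data.frame(chrom = vapply(parts, `[`, "", 1),
             start = as.integer(vapply(parts, `[`, "", 2)),
             end = as.integer(vapply(parts, `[`, "", 3)),
             stringsAsFactors = FALSE)
}

#' Write DMRs as BED6
#'
#' Emits standard 0-based half-open BED with the 1-based `chr$start$end` id
#' in the name field and `score = round(|delta_beta| * 10)` clamped to
#' 0..1000. A single `#`-prefixed header comment is always written, so an
#' empty DMR set yields a valid (header-only) file.
#'
#' @param dmrs data.frame with columns `chrom`, `start`, `end` (1-based
#'   inclusive) and `delta_beta` (percentage points).
#' @param path Output path.
#' @export
write_dmr_bed <- function(dmrs, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("#chrom\tstart\tend\tname\tscore\tstrand", con)
  if (nrow(dmrs) > 0) {
    score <- pmax(0, pmin(1000, round(abs(dmrs$delta_beta) * 10)))
    lines <- paste(dmrs$chrom, dmrs$start - 1L, dmrs$end,
                   region_id(dmrs$chrom, dmrs$start, dmrs$end),
                   score, ".", sep = "\t")
    writeLines(lines, con)
  }
  invisible(path)
}

#' Read a DMR BED file written by [write_dmr_bed()]
#' @param path Path to the BED file.
#' @return data.frame with 1-based `chrom`, `start`, `end`, `id`, `score`.
#' @export
read_dmr_bed <- function(path) {
  nf <- count.fields(path, comment.char = "#", sep = "\t")
  if (length(nf) == 0)
    return(data.frame(chrom = character(), start = integer(),
                      end = integer(), id = character(), score = numeric(),
                      stringsAsFactors = FALSE))
  x <- read.table(path, header = FALSE, sep = "\t", comment.char = "#",
                  stringsAsFactors = FALSE)
  data.frame(chrom = x[[1]], start = as.integer(x[[2]]) + 1L,
             end = as.integer(x[[3]]), id = x[[4]], score = x[[5]],
             stringsAsFactors = FALSE)
}
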