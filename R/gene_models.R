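#' Gene model tables
#'
#' Genes are stored in a data frame with 0-based, half-open genomic
#' coordinates (`start < end` always) and a `strand` column; the biological
#' 5' and 3' ends (TSS and TES) are derived strand-awarely by [gene_tss()]
#' and [gene_tes()]. Exon blocks are kept in a list-column of two-column
#' matrices (start, end), sorted and non-overlapping within the gene span.
#'
#' @name gene-models
NULL

new_gene_table <- function(gene_id, chrom, strand, start, end,
                           exons = NULL, expression = NA_real_) {
  if (is.null(exons))
    exons <- Map(function(s, e) cbind(start = s, end = e), start, end)
  df <- data.frame(gene_id = as.character(gene_id),
                   chrom = as.character(chrom),
                   strand = as.character(strand),
                   start = as.numeric(start), end = as.numeric(end),
                   expression = as.numeric(expression),
                   stringsAsFactors = FALSE)
  df$exons <- exons
  validate_gene_table(df)
  df
}

validate_gene_table <- function(genes) {
  stopifnot(all(c("gene_id", "chrom", "strand", "start", "end") %in%
                  names(genes)))
  bad <- !genes$strand %in% c("+", "-")
  if (any(bad))
    stop("unknown strand symbol '", genes$strand[which(bad)[1]],
         "' for gene ", genes$gene_id[which(bad)[1]])
  if (any(genes$start >= genes$end))
    stop("gene with tss == tes (empty span): ",
         genes$gene_id[which(genes$start >= genes$end)[1]])
  if (!is.null(genes$exons)) {
    for (i in seq_len(nrow(genes))) {
      ex <- genes$exons[[i]]
      if (is.null(ex) || !nrow(ex)) next
      if (is.unsorted(ex[, 1]) ||
          (nrow(ex) > 1 && any(ex[-1, 1] < ex[-nrow(ex), 2])))
        stop("exons of ", genes$gene_id[i],
             " are not sorted and non-overlapping")
      if (min(ex[, 1]) < genes$start[i] || max(ex[, 2]) > genes$end[i])
        stop("exons of ", genes$gene_id[i], " exceed the gene span")
    }
  }
  invisible(genes)
}

#' Strand-aware biological gene ends
#'
#' On the minus strand the TSS is the larger genomic coordinate and the TES
#' the smaller one; these accessors return the biological 5' and 3' ends.
#'
#' @param genes A gene table.
#' @return Numeric vector of positions (bp).
#' @export
gene_tss <- function(genes) ifelse(genes$strand == "+", genes$start, genes$end)

#' @rdname gene_tss
#' @export
gene_tes <- function(genes) ifelse(genes$strand == "+", genes$end, genes$start)

#' Gene body length in bp
#' @param genes A gene table.
#' @return Numeric vector, `end - start`.
#' @export
gene_length <- function(genes) genes$end - genes$start

format_exons <- function(ex) {
  if (is.null(ex) || !nrow(ex)) return(".")
  paste(sprintf("%d-%d", as.integer(ex[, 1]), as.integer(ex[, 2])),
        collapse = ";")
}

parse_exons <- function(s) {
  if (is.na(s) || s == "." || !nzchar(s)) return(NULL)
  parts <- strsplit(strsplit(s, ";", fixed = TRUE)[[1]], "-", fixed = TRUE)
  m <- do.call(rbind, lapply(parts, function(p) as.numeric(p)))
  colnames(m) <- c("start", "end")
  m
}

#' Read a gene table (TSV or GTF)
#'
#' The TSV dialect has columns `gene_id`, `chrom`, `strand`, `tss`, `tes`,
#' `exons`, `expression`; `tss`/`tes` are biological ends (so `tss > tes` in
#' genomic coordinates for minus-strand genes) and `exons` is a
#' `start-end;start-end` list in ascending genomic 0-based half-open
#' coordinates, or `.` when exon structure is absent (the whole span is then
#' treated as one block). GTF files are read through rtracklayer; exon
#' records are grouped by `gene_id`.
#'
#' @param path Path to the annotation file.
#' @param format `"tsv"` or `"gtf"`; guessed from the extension by default.
#' @return A gene table (see [gene-models]).
#' @export
read_gene_table <- function(path, format = c("auto", "tsv", "gtf")) {
  format <- match.arg(format)
  if (format == "auto")
    format <- if (grepl("\\.gtf(\\.gz)?$", path, ignore.case = TRUE))
      "gtf" else "tsv"
  if (format == "gtf") return(read_gene_gtf(path))
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE,
                          colClasses = c(gene_id = "character",
                                         chrom = "character",
                                         strand = "character",
                                         exons = "character"))
  for (i in seq_len(nrow(df))) {
    line <- i + 1L  # header is line 1
    if (!df$strand[i] %in% c("+", "-"))
      stop("line ", line, ": unknown strand symbol '", df$strand[i], "'")
    if (df$tss[i] == df$tes[i])
      stop("line ", line, ": rejected record, tss == tes")
  }
  start <- pmin(df$tss, df$tes)
  end <- pmax(df$tss, df$tes)
  exons <- lapply(df$exons, parse_exons)
  exons <- Map(function(ex, s, e) if (is.null(ex))
    cbind(start = s, end = e) else ex, exons, start, end)
  expr <- if ("expression" %in% names(df)) df$expression else NA_real_
  new_gene_table(df$gene_id, df$chrom, df$strand, start, end, exons, expr)
}

read_gene_gtf <- function(path) {
  gr <- rtracklayer::import(path, format = "gtf")
  ex <- gr[gr$type == "exon"]
  if (!length(ex)) stop("no exon records in ", path)
  ids <- as.character(ex$gene_id)
  out <- lapply(split(seq_along(ex), ids), function(idx) {
    g <- ex[idx]
    strand <- as.character(GenomicRanges::strand(g))[1]
    if (!strand %in% c("+", "-"))
      stop("unknown strand symbol '", strand, "' for gene ",
           as.character(g$gene_id)[1])
    r <- IRanges::reduce(GenomicRanges::ranges(g))
    list(gene_id = as.character(g$gene_id)[1],
         chrom = as.character(GenomicRanges::seqnames(g))[1],
         strand = strand,
         start = min(IRanges::start(r)) - 1,
         end = max(IRanges::end(r)),
         exons = cbind(start = IRanges::start(r) - 1, end = IRanges::end(r)))
  })
  new_gene_table(
    vapply(out, `[[`, "", "gene_id"),
    vapply(out, `[[`, "", "chrom"),
    vapply(out, `[[`, "", "strand"),
    vapply(out, `[[`, 0, "start"),
    vapply(out, `[[`, 0, "end"),
    lapply(out, `[[`, "exons"))
}

#' Write a gene table as TSV
#'
#' Inverse of [read_gene_table()] on the TSV dialect; `tss`/`tes` are written
#' as biological ends.
#'
#' @param genes A gene table.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gene_table <- function(genes, path) {
  df <- data.frame(gene_id = genes$gene_id, chrom = genes$chrom,
                   strand = genes$strand,
                   tss = as.integer(gene_tss(genes)),
                   tes = as.integer(gene_tes(genes)),
                   exons = vapply(genes$exons, format_exons, ""),
                   expression = genes$expression)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
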