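#' Transcript annotation and exon-transcript incidence matrices
#'
#' A transcript model table maps genes to transcripts to exons with genomic
#' coordinates. Internally coordinates are 0-based half-open; GTF input
#' (1-based closed) is converted at the boundary. Exons are keyed by
#' coordinate: two exons with the same textual id but different coordinates
#' are distinct rows in the incidence matrix.
#'
#' @name annotation
NULL

#' Read a transcript annotation
#'
#' Supports two formats. `"tsv"`: columns `gene_id`, `transcript_id`,
#' `exon_id`, `chrom`, `start`, `end`, `strand` with 0-based half-open
#' coordinates. `"gtf"`: the standard 9-column layout where exon features
#' carry `gene_id`/`transcript_id` attributes and 1-based closed coordinates,
#' converted to the internal convention on read.
#'
#' @param path File path.
#' @param format `"tsv"` or `"gtf"`.
#' @return A `data.frame` of transcript models (one row per exon occurrence)
#'   with columns `gene_id`, `transcript_id`, `exon_id`, `chrom`, `start`,
#'   `end`, `strand`.
#' @export
read_annotation <- function(path, format = c("tsv", "gtf")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path)
  lines <- lines[!grepl("^#", lines) & nzchar(lines)]
  if (length(lines) == 0L) {
    warning("empty annotation: ", path)
    return(data.frame(gene_id = character(), transcript_id = character(),
                      exon_id = character(), chrom = character(),
                      start = integer(), end = integer(),
                      strand = character(), stringsAsFactors = FALSE))
  }
  if (format == "tsv") {
    df <- read.delim(text = lines, header = TRUE, sep = "\t",
                     stringsAsFactors = FALSE)
    need <- c("gene_id", "transcript_id", "exon_id", "chrom", "start",
              "end", "strand")
    if (!all(need %in% names(df)))
      stop("annotation TSV must have columns: ", paste(need, collapse = ", "),
           call. = FALSE)
    models <- df[, need]
  } else {
    fields <- strsplit(lines, "\t", fixed = TRUE)
    bad <- which(vapply(fields, length, 1L) < 9L)
    if (length(bad))
      stop(sprintf("malformed GTF line %d: fewer than 9 fields", bad[1]),
           call. = FALSE)
    f <- do.call(rbind, lapply(fields, function(x) x[1:9]))
    keep <- f[, 3] == "exon"
    f <- f[keep, , drop = FALSE]
    gid <- sub('.*gene_id "([^"]*)".*', "\\1", f[, 9])
    tid <- sub('.*transcript_id "([^"]*)".*', "\\1", f[, 9])
    eid <- ifelse(grepl('exon_id "', f[, 9]),
                  sub('.*exon_id "([^"]*)".*', "\\1", f[, 9]),
                  paste0(f[, 1], ":", f[, 4], "-", f[, 5]))
    start <- suppressWarnings(as.integer(f[, 4]))
    end <- suppressWarnings(as.integer(f[, 5]))
    if (anyNA(start) || anyNA(end)) {
      bad <- which(is.na(start) | is.na(end))[1]
      stop(sprintf("malformed GTF line %d: non-numeric coordinates", bad),
           call. = FALSE)
    }
    models <- data.frame(gene_id = gid, transcript_id = tid, exon_id = eid,
                         chrom = f[, 1], start = start - 1L, end = end,
                         strand = f[, 7], stringsAsFactors = FALSE)
  }
  if (any(models$end <= models$start))
    stop("annotation has exons with end <= start", call. = FALSE)
  models
}

#' Write a transcript annotation in the package TSV format
#'
#' @param models Transcript model `data.frame` as from [read_annotation()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_annotation <- function(models, path) {
  write_tsv_table(models, path)
}

#' Build per-gene exon-transcript incidence matrices
#'
#' For each gene with m measured exons and n transcripts, builds the binary
#' m x n matrix A with `A[j, k] = 1` iff exon j belongs to transcript k.
#' Rows are restricted to the measured exon ids; measured exons that map to
#' no transcript of the gene are dropped (their count is reported via a
#' message). Exon rows are keyed by `exon_id`; a duplicated exon id within a
#' gene that points at two different coordinate spans is an error.
#'
#' @param models Transcript model `data.frame`.
#' @param measured_exons Character vector of exon ids present on the array;
#'   `NULL` means all annotated exons are measured.
#' @return Named list (by gene id) of incidence objects, each a list with
#'   `gene_id`, `exon_ids`, `transcript_ids`, `A` (binary matrix) and
#'   `full_rank` (logical: does A have full column rank).
#' @export
build_incidence <- function(models, measured_exons = NULL) {
  stopifnot(is.data.frame(models))
  key <- paste(models$gene_id, models$exon_id)
  span <- paste(models$chrom, models$start, models$end)
  dup <- tapply(span, key, function(s) length(unique(s)) > 1L)
  if (any(dup))
    stop("duplicate exon id with conflicting coordinates: ",
         names(dup)[dup][1], call. = FALSE)
  out <- lapply(split(models, models$gene_id), function(g) {
    exons <- unique(g$exon_id)
    if (!is.null(measured_exons)) exons <- exons[exons %in% measured_exons]
    if (length(exons) == 0L) return(NULL)
    txs <- unique(g$transcript_id)
    A <- matrix(0L, nrow = length(exons), ncol = length(txs),
                dimnames = list(exons, txs))
    idx <- cbind(match(g$exon_id, exons), match(g$transcript_id, txs))
    idx <- idx[complete.cases(idx), , drop = FALSE]
    A[idx] <- 1L
    keep_rows <- rowSums(A) > 0L
    if (any(!keep_rows)) {
      message(sprintf("gene %s: dropped %d measured exon(s) mapping to no transcript",
                      g$gene_id[1], sum(!keep_rows)))
      A <- A[keep_rows, , drop = FALSE]
    }
    if (nrow(A) == 0L) return(NULL)
    list(gene_id = g$gene_id[1],
         exon_ids = rownames(A),
         transcript_ids = colnames(A),
         A = A,
         full_rank = qr(A)$rank == ncol(A))
  })
  out[!vapply(out, is.null, TRUE)]
}
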