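#' ASV count table with aligned sample metadata
#'
#' The universal data container of the package: a non-negative integer count
#' matrix (samples in rows, amplicon sequence variants in columns) plus a
#' metadata data frame keyed by sample id. Metadata carries the study design:
#' `sample_type` (concrete, a precursor material, or negative_control),
#' `series` (reactive / mitigated / none), `months` since pour, 30-day mean
#' `temperature` (degrees C) and a `replicate` identifier.
#'
#' @param counts integer matrix, samples x ASVs, with unique row and column
#'   names.
#' @param metadata data frame with one row per sample; either row names or a
#'   `sample_id` column must match `rownames(counts)`.
#' @return An object of class `asv_table`.
#' @export
asv_table <- function(counts, metadata) {
  counts <- as.matrix(counts)
  if ((nrow(counts) > 0 && is.null(rownames(counts))) ||
      (ncol(counts) > 0 && is.null(colnames(counts))))
    stop("counts must have sample row names and ASV column names")
  if (is.null(rownames(counts))) rownames(counts) <- character(0)
  if (is.null(colnames(counts))) colnames(counts) <- character(0)
  if (anyDuplicated(rownames(counts)))
    stop("duplicate sample id: ",
         rownames(counts)[duplicated(rownames(counts))][1])
  if (anyDuplicated(colnames(counts)))
    stop("duplicate ASV id: ", colnames(counts)[duplicated(colnames(counts))][1])
  if (any(counts < 0)) stop("negative counts are not allowed")
  if (any(counts != round(counts)))
    stop("non-integer counts in table (first offending ASV: ",
         colnames(counts)[which(counts != round(counts), arr.ind = TRUE)[1, 2]], ")")
  storage.mode(counts) <- "integer"
  metadata <- as.data.frame(metadata)
  if ("sample_id" %in% names(metadata)) rownames(metadata) <- metadata$sample_id
  missing_meta <- setdiff(rownames(counts), rownames(metadata))
  if (length(missing_meta))
    stop("sample(s) present in counts but absent from metadata: ",
         paste(missing_meta, collapse = ", "))
  orphan <- setdiff(rownames(metadata), rownames(counts))
  if (length(orphan))
    stop("metadata row(s) without a counts sample: ", paste(orphan, collapse = ", "))
  metadata <- metadata[rownames(counts), , drop = FALSE]
  structure(list(counts = counts, metadata = metadata), class = "asv_table")
}

#' @export
print.asv_table <- function(x, ...) {
  cat(sprintf("asv_table: %d samples x %d ASVs (total reads %.3g)\n",
              nrow(x$counts), ncol(x$counts), sum(as.numeric(x$counts))))
  if ("sample_type" %in% names(x$metadata)) {
    tt <- table(x$metadata$sample_type)
    cat("sample types:", paste(sprintf("%s=%d", names(tt), tt), collapse = ", "), "\n")
  }
  invisible(x)
}

#' @export
summary.asv_table <- function(object, ...) {
  depths <- rowSums(object$counts)
  cat(sprintf("asv_table: %d samples x %d ASVs\n", nrow(object$counts),
              ncol(object$counts)))
  cat(sprintf("library sizes: min %d, median %.0f, max %d\n",
              min(depths), stats::median(depths), max(depths)))
  cat(sprintf("ASV prevalence: median %.0f samples\n",
              stats::median(colSums(object$counts > 0))))
  invisible(object)
}

#' Sample and ASV identifiers of a table
#'
#' @param table an [asv_table].
#' @return character vector of ids.
#' @export
sample_ids <- function(table) rownames(table$counts)

#' @rdname sample_ids
#' @export
asv_ids <- function(table) colnames(table$counts)

#' Subset an ASV table by samples and/or ASVs
#'
#' Keeps counts and metadata aligned; input order of surviving ids is kept.
#'
#' @param table an [asv_table].
#' @param samples,asvs character vectors of ids (or logical masks) to keep.
#' @return An [asv_table].
#' @export
asv_subset <- function(table, samples = NULL, asvs = NULL) {
  counts <- table$counts
  if (!is.null(samples)) counts <- counts[samples, , drop = FALSE]
  if (!is.null(asvs)) counts <- counts[, asvs, drop = FALSE]
  asv_table(counts, table$metadata[rownames(counts), , drop = FALSE])
}

#' Read and write ASV tables
#'
#' TSV follows the classic OTU-table orientation: ASVs as rows, samples as
#' columns, header cell `#ASV_ID`. The minimal BIOM-style JSON dialect stores
#' ids, shape and integer `[row, column, value]` triples. Metadata is a
#' QIIME-style TSV whose first header is `#SampleID`. Round trips are exact.
#'
#' @param path path to the count table.
#' @param metadata_path path to the metadata TSV.
#' @param dialect `"tsv"` or `"biom"`.
#' @return [read_table()] returns an [asv_table].
#' @export
read_table <- function(path, metadata_path, dialect = c("tsv", "biom")) {
  dialect <- match.arg(dialect)
  meta <- utils::read.delim(metadata_path, check.names = FALSE,
                            stringsAsFactors = FALSE, comment.char = "")
  names(meta)[1] <- "sample_id"
  for (col in c("months", "temperature"))
    if (col %in% names(meta)) meta[[col]] <- as.numeric(meta[[col]])
  if (dialect == "tsv") {
    raw <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE,
                             comment.char = "")
    asvs <- as.character(raw[[1]])
    m <- as.matrix(raw[, -1, drop = FALSE])
    if (any(m != round(m)))
      stop("non-integer counts in ", path)
    counts <- t(m)
    colnames(counts) <- asvs
  } else {
    b <- jsonlite::read_json(path, simplifyVector = TRUE)
    counts <- matrix(0L, nrow = b$shape[2], ncol = b$shape[1],
                     dimnames = list(b$columns, b$rows))
    if (length(b$data)) {
      d <- matrix(as.numeric(b$data), ncol = 3, byrow = is.null(dim(b$data)))
      if (!is.null(dim(b$data))) d <- b$data
      counts[cbind(d[, 2] + 1, d[, 1] + 1)] <- d[, 3]
    }
  }
  asv_table(counts, meta)
}

#' @rdname read_table
#' @param table an [asv_table].
#' @export
write_table <- function(table, path, metadata_path = NULL,
                        dialect = c("tsv", "biom")) {
  dialect <- match.arg(dialect)
  if (dialect == "tsv") {
    m <- t(table$counts)
    df <- data.frame(`#ASV_ID` = rownames(m), m, check.names = FALSE)
    utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  } else {
    nz <- which(t(table$counts) != 0, arr.ind = TRUE)  # row = ASV, col = sample
    triples <- lapply(seq_len(nrow(nz)), function(i) {
      c(nz[i, 1] - 1L, nz[i, 2] - 1L, t(table$counts)[nz[i, , drop = FALSE]])
    })
    obj <- list(id = "asv-table", format = "minimal-biom-json",
                shape = c(ncol(table$counts), nrow(table$counts)),
                rows = colnames(table$counts), columns = rownames(table$counts),
                data = triples)
    jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  }
  if (!is.null(metadata_path)) write_metadata(table$metadata, metadata_path)
  invisible(path)
}

#' @rdname read_table
#' @param metadata metadata data frame (row names are sample ids).
#' @export
write_metadata <- function(metadata, path) {
  df <- data.frame(`#SampleID` = rownames(metadata), metadata,
                   check.names = FALSE, row.names = NULL)
  df$sample_id <- NULL
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read and write FASTA sequence sets
#'
#' Thin wrappers over Biostrings returning plain named character vectors,
#' the representation the network and decontamination stages consume.
#'
#' @param path FASTA file path.
#' @export
read_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  stats::setNames(as.character(x), names(x))
}

#' @rdname read_fasta
#' @param sequences named character vector of DNA sequences.
#' @export
write_fasta <- function(sequences, path) {
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(sequences), path)
  invisible(path)
}

#' Drop ASVs with unexpectedly short sequences
#'
#' Amplicons far below the expected locus length are usually artifacts;
#' anything shorter than `min_len` nucleotides (strictly) is removed.
#'
#' @param table an [asv_table].
#' @param records named character vector of ASV sequences covering the table.
#' @param min_len minimum retained length in nt (default 400).
#' @return list with the filtered `table` and the `dropped` ASV ids.
#' @export
filter_short_asvs <- function(table, records, min_len = 400) {
  ids <- asv_ids(table)
  missing <- setdiff(ids, names(records))
  if (length(missing))
    stop("missing sequence record for ASV(s): ", paste(missing, collapse = ", "))
  len <- nchar(records[ids])
  dropped <- ids[len < min_len]
  keep <- setdiff(ids, dropped)
  list(table = asv_subset(table, asvs = keep), dropped = dropped)
}

#' Merge length variants of the same amplicon
#'
#' An ASV whose sequence is an exact substring of another ASV's sequence is
#' treated as a length variant of the same locus: its counts are added to the
#' longer ASV and the longest sequence is kept as the representative.
#' Containment chains collapse onto their longest member.
#'
#' @inheritParams filter_short_asvs
#' @return list with the merged `table`, updated `records`, and a `merge_map`
#'   (named character: absorbed id -> representative id).
#' @export
merge_length_variants <- function(table, records) {
  ids <- asv_ids(table)
  if (length(setdiff(ids, names(records))))
    stop("missing sequence record for ASV(s): ",
         paste(setdiff(ids, names(records)), collapse = ", "))
  seqs <- records[ids]
  if (any(!nzchar(seqs))) stop("empty sequence record")
  parent <- stats::setNames(ids, ids)
  for (a in ids) {
    containers <- ids[vapply(ids, function(b) {
      !identical(a, b) && nchar(seqs[[b]]) >= nchar(seqs[[a]]) &&
        grepl(seqs[[a]], seqs[[b]], fixed = TRUE)
    }, logical(1))]
    if (!length(containers)) next
    # absorb into the longest container; ties broken by smallest id
    len <- nchar(seqs[containers])
    best <- sort(containers[len == max(len)])[1]
    # identical duplicate sequences: smallest id is the representative
    if (nchar(seqs[[best]]) == nchar(seqs[[a]]) && best > a) next
    parent[a] <- best
  }
  # transitive closure onto final representatives
  resolve <- function(a) { while (parent[a] != a) a <- parent[a]; a }
  rep_of <- vapply(ids, resolve, character(1))
  merge_map <- rep_of[rep_of != ids]
  if (!length(merge_map)) {
    return(list(table = table, records = seqs, merge_map = character(0)))
  }
  keep <- ids[rep_of == ids]
  counts <- table$counts
  merged <- sapply(keep, function(k) {
    members <- ids[rep_of == k]
    if (length(members) == 1L) counts[, members] else rowSums(counts[, members])
  })
  merged <- matrix(as.integer(merged), nrow = nrow(counts),
                   dimnames = list(rownames(counts), keep))
  list(table = asv_table(merged, table$metadata), records = seqs[keep],
       merge_map = merge_map)
}

#' Drop samples with too few reads
#'
#' Removes samples whose library size is below `min_reads`. The default is 5%
#' of the median depth, an outlier rule for failed libraries.
#'
#' @param table an [asv_table].
#' @param min_reads minimum library size retained.
#' @return list with the filtered `table` and the `dropped` sample ids.
#' @export
drop_low_depth_samples <- function(table,
                                   min_reads = 0.05 * stats::median(rowSums(table$counts))) {
  if (min_reads < 0) stop("min_reads must be >= 0")
  depths <- rowSums(table$counts)
  dropped <- names(depths)[depths < min_reads]
  if (length(dropped) == nrow(table$counts))
    stop("min_reads = ", min_reads, " would drop every sample")
  keep <- setdiff(sample_ids(table), dropped)
  list(table = asv_subset(table, samples = keep), dropped = dropped)
}
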