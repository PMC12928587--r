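#' Read domain records from FASTA (and an optional annotation table)
#'
#' Sequences are read with Biostrings; the record id is the first
#' whitespace-delimited token of each FASTA header. When an annotation TSV
#' is supplied it is joined by id: columns `cath_label`, `ss3` and/or `ss8`
#' are recognized, and 8-state strings are reduced to 3 states with
#' [reduce_dssp()] when no `ss3` column is present.
#'
#' @param fasta Path to a FASTA file of amino-acid sequences.
#' @param annot Optional path to a tab-separated annotation table with an
#'   `id` column.
#' @return A [domain_records()] object.
#' @export
read_fasta_records <- function(fasta, annot = NULL) {
  seqs <- Biostrings::readAAStringSet(fasta)
  ids <- vapply(strsplit(names(seqs), "\\s+"), `[`, character(1), 1L)
  rec <- domain_records(id = ids, sequence = as.character(seqs))
  if (!is.null(annot)) {
    ann <- read_annotation_tsv(annot)
    idx <- match(rec$id, ann$id)
    if ("cath_label" %in% names(ann)) rec$cath_label <- ann$cath_label[idx]
    if ("ss3" %in% names(ann)) {
      rec$ss3 <- ann$ss3[idx]
    } else if ("ss8" %in% names(ann)) {
      rec$ss3 <- reduce_dssp(ann$ss8[idx])
    }
    rec <- domain_records(rec$id, rec$sequence, rec$cath_label, rec$ss3)
  }
  rec
}

#' Read an annotation TSV
#'
#' Expects a header row and an `id` column; `cath_label`, `ss3`, `ss8`
#' columns are used when present.
#'
#' @param path Path to the tab-separated file.
#' @return A data frame.
#' @export
read_annotation_tsv <- function(path) {
  ann <- utils::read.delim(path, stringsAsFactors = FALSE, colClasses = "character")
  if (!"id" %in% names(ann)) stop("annotation table lacks an 'id' column", call. = FALSE)
  ann
}

#' Write domain records to FASTA plus annotation TSV
#'
#' @param records A [domain_records()] object.
#' @param fasta Output FASTA path.
#' @param annot Optional output TSV path for `cath_label` / `ss3`.
#' @return Invisibly, `records`.
#' @export
write_corpus <- function(records, fasta, annot = NULL) {
  stopifnot(inherits(records, "domain_records"))
  x <- Biostrings::AAStringSet(records$sequence)
  names(x) <- records$id
  Biostrings::writeXStringSet(x, fasta)
  if (!is.null(annot)) {
    utils::write.table(
      records[, c("id", "cath_label", "ss3")],
      annot, sep = "\t", quote = FALSE, row.names = FALSE, na = ""
    )
  }
  invisible(records)
}

#' Write / read a split manifest TSV (columns id, partition)
#'
#' @param split A [split_dataset()] result.
#' @param path Path to the TSV.
#' @return `read_split_manifest()` returns a `split_assignment` data frame.
#' @export
write_split_manifest <- function(split, path) {
  stopifnot(inherits(split, "split_assignment"))
  utils::write.table(as.data.frame(split)[, c("id", "partition")], path,
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(split)
}

#' @rdname write_split_manifest
#' @export
read_split_manifest <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("id", "partition") %in% names(df))) {
    stop("split manifest needs columns id, partition", call. = FALSE)
  }
  bad <- setdiff(unique(df$partition), c("train", "validation", "test"))
  if (length(bad)) stop("unknown partition label(s): ", paste(bad, collapse = ", "), call. = FALSE)
  structure(df[, c("id", "partition")], class = c("split_assignment", "data.frame"))
}
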