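#' Write transcripts to FASTA
#'
#' Circular topology is encoded as ` topology=circular` in the description
#' line; the RNA class as ` class=<rna_class>`.
#'
#' @param transcripts a [transcript_set].
#' @param path output FASTA path.
#' @export
write_transcript_fasta <- function(transcripts, path) {
  seqs <- Biostrings::DNAStringSet(transcripts$sequence)
  names(seqs) <- sprintf("%s topology=%s class=%s", transcripts$id,
                         transcripts$topology, transcripts$rna_class)
  Biostrings::writeXStringSet(seqs, path)
  invisible(transcripts)
}

#' Read transcripts from FASTA
#'
#' @param path FASTA path; description lines may carry `topology=circular`
#'   and `class=<mrna_utr|lncrna|circrna>` tags (defaults: linear, mrna_utr).
#' @return A [transcript_set].
#' @export
read_transcript_fasta <- function(path) {
  seqs <- Biostrings::readDNAStringSet(path)
  desc <- names(seqs)
  id <- sub("\\s.*$", "", desc)
  topo <- ifelse(grepl("topology=circular", desc), "circular", "linear")
  cls <- rep("mrna_utr", length(desc))
  has <- grepl("class=(\\S+)", desc)
  cls[has] <- sub(".*class=(\\S+).*", "\\1", desc[has])
  transcript_set(id, as.character(seqs), topo, cls)
}

#' Write miRNAs to FASTA
#' @param mirnas a [mirna_set].
#' @param path output FASTA path.
#' @export
write_mirna_fasta <- function(mirnas, path) {
  seqs <- Biostrings::DNAStringSet(mirnas$sequence)
  names(seqs) <- mirnas$id
  Biostrings::writeXStringSet(seqs, path)
  invisible(mirnas)
}

#' Read miRNAs from FASTA
#' @param path FASTA path.
#' @return A [mirna_set].
#' @export
read_mirna_fasta <- function(path) {
  seqs <- Biostrings::readDNAStringSet(path)
  mirna_set(sub("\\s.*$", "", names(seqs)), as.character(seqs))
}

#' Read a gene-set collection in GMT format
#'
#' GMT: one set per line, tab-separated `name`, `description`, members.
#'
#' @param path GMT path.
#' @return Named list of character vectors.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  stats::setNames(lapply(parts, function(p) unique(p[-(1:2)])),
                  vapply(parts, `[`, character(1), 1))
}

#' Write a gene-set collection in GMT format
#' @param sets named list of character vectors.
#' @param path output GMT path.
#' @param descriptions optional descriptions (default `"na"`).
#' @export
write_gmt <- function(sets, path, descriptions = NULL) {
  if (is.null(descriptions)) descriptions <- rep("na", length(sets))
  lines <- vapply(seq_along(sets), function(i) {
    paste(c(names(sets)[i], descriptions[i], sets[[i]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(sets)
}
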