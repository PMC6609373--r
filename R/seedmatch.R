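## Canonical miRNA seed matching on linear and circular transcripts.
## Site taxonomy: with seed = miRNA positions 2-8 (5'->3'),
##   core6 = reverse complement of positions 2-7 (a hexamer on the target),
##   m8    = reverse complement of position 8.
## A target occurrence of core6 at 0-based position i is
##   8mer    if preceded by m8 at i-1 and followed by A at i+6  (start i-1)
##   7mer-m8 if preceded by m8 only                             (start i-1)
##   7mer-A1 if followed by A only                              (start i)
## Each core occurrence yields at most one site (precedence
## 8mer > 7mer-m8 > 7mer-A1). Circular transcripts are scanned with the first
## 7 bases appended, and starts reported modulo length.

.norm_seq <- function(s) {
  s <- toupper(s)
  gsub("U", "T", s, fixed = TRUE)
}

.revcomp <- function(s) {
  chartr("ACGT", "TGCA",
         vapply(s, function(x) paste(rev(strsplit(x, "")[[1]]), collapse = ""),
                character(1), USE.NAMES = FALSE))
}

#' Create a set of miRNA records
#'
#' @param id character vector of miRNA ids.
#' @param sequence 5'->3' sequences (RNA or DNA alphabet), 18-25 nt.
#' @return data.frame of class `mirna_set` with columns `id`, `sequence`
#'   (uppercase DNA alphabet) and `seed` (positions 2-8).
#' @export
mirna_set <- function(id, sequence) {
  sequence <- .norm_seq(sequence)
  if (anyDuplicated(id)) stop("duplicate miRNA id(s)")
  len <- nchar(sequence)
  if (any(len < 18 | len > 25))
    stop("miRNA length must be 18-25 nt: ",
         paste(id[len < 18 | len > 25], collapse = ", "))
  if (any(grepl("[^ACGT]", sequence)))
    stop("miRNA sequences must be over A/C/G/T/U")
  d <- data.frame(id = unname(id), sequence = unname(sequence),
                  seed = unname(substr(sequence, 2, 8)),
                  stringsAsFactors = FALSE)
  rownames(d) <- NULL
  structure(d, class = c("mirna_set", "data.frame"))
}

#' Create a set of transcript records
#'
#' @param id character vector of transcript ids.
#' @param sequence 5'->3' sequences.
#' @param topology `"linear"` or `"circular"` per transcript (circRNAs are
#'   covalently closed, so sites may span the back-splice junction).
#' @param rna_class one of `"mrna_utr"`, `"lncrna"`, `"circrna"` per
#'   transcript.
#' @return data.frame of class `transcript_set`.
#' @export
transcript_set <- function(id, sequence,
                           topology = "linear", rna_class = "mrna_utr") {
  if (anyDuplicated(id))
    stop("duplicate transcript id(s): ",
         paste(unique(id[duplicated(id)]), collapse = ", "))
  sequence <- .norm_seq(sequence)
  topology <- rep_len(topology, length(id))
  rna_class <- rep_len(rna_class, length(id))
  if (!all(topology %in% c("linear", "circular")))
    stop("topology must be 'linear' or 'circular'")
  if (!all(rna_class %in% c("mrna_utr", "lncrna", "circrna")))
    stop("rna_class must be mrna_utr, lncrna or circrna")
  if (any(nchar(sequence) < 8))
    stop("transcript(s) shorter than 8 nt: ",
         paste(id[nchar(sequence) < 8], collapse = ", "))
  d <- data.frame(id = unname(id), sequence = unname(sequence),
                  topology = topology, rna_class = rna_class,
                  stringsAsFactors = FALSE)
  rownames(d) <- NULL
  structure(d, class = c("transcript_set", "data.frame"))
}

.empty_sites <- function() {
  data.frame(mirna = character(), transcript = character(),
             start = integer(), site_type = character(),
             stringsAsFactors = FALSE)
}

## core occurrence positions (0-based) of a hexamer in a character vector
.find_hex <- function(chars, hex) {
  n <- length(chars)
  if (n < 6) return(integer())
  h <- strsplit(hex, "")[[1]]
  ok <- chars[1:(n - 5)] == h[1]
  for (j in 2:6) ok <- ok & chars[j:(n - 6 + j)] == h[j]
  which(ok) - 1L
}

#' Find canonical seed-match sites of one miRNA on one transcript
#'
#' Scans the given strand of the transcript for canonical sites (8mer,
#' 7mer-m8, 7mer-A1) of the miRNA seed. Circular transcripts are scanned with
#' the first 7 bases appended so junction-spanning sites are found; starts
#' are reported modulo the transcript length. Each window is reported once
#' with its strongest type. Ambiguous bases (N) never match.
#'
#' @param transcript one row of a [transcript_set] (or a list with
#'   `id`, `sequence`, `topology`).
#' @param mirna one row of a [mirna_set] (or a list with `id`, `sequence`).
#' @return data.frame with columns `mirna`, `transcript`, `start` (0-based),
#'   `site_type`.
#' @export
find_seed_sites <- function(transcript, mirna) {
  seq <- .norm_seq(transcript$sequence)
  L <- nchar(seq)
  if (L < 8) stop("transcript '", transcript$id, "' shorter than 8 nt")
  mir <- .norm_seq(mirna$sequence)
  circular <- identical(transcript$topology, "circular")
  scan_seq <- if (circular) paste0(seq, substr(seq, 1, 7)) else seq
  chars <- strsplit(scan_seq, "")[[1]]

  seed <- substr(mir, 2, 8)                  # positions 2-8
  core6 <- .revcomp(substr(seed, 1, 6))      # rc of positions 2-7
  m8 <- chartr("ACGT", "TGCA", substr(mir, 8, 8))

  pos <- .find_hex(chars, core6)
  if (!length(pos)) return(.empty_sites())
  n <- length(chars)
  prev <- rep("", length(pos))                       # base at pos-1 (0-based)
  prev[pos >= 1] <- chars[pos[pos >= 1]]
  nxt <- rep("", length(pos))                        # base at pos+6
  nxt[pos + 6 < n] <- chars[pos[pos + 6 < n] + 7L]
  has_m8 <- prev == m8
  has_a1 <- nxt == "A"
  type <- ifelse(has_m8 & has_a1, "8mer",
          ifelse(has_m8, "7mer-m8",
          ifelse(has_a1, "7mer-A1", NA_character_)))
  keep <- !is.na(type)
  pos <- pos[keep]; type <- type[keep]; has_m8 <- has_m8[keep]
  if (!length(pos)) return(.empty_sites())
  if (circular) {
    # one report per core occurrence modulo length, strongest type wins
    posm <- pos %% L
    rank <- c("8mer" = 1L, "7mer-m8" = 2L, "7mer-A1" = 3L)[type]
    o <- order(posm, rank)
    posm <- posm[o]; type <- type[o]; has_m8 <- has_m8[o]
    keep <- !duplicated(posm)
    posm <- posm[keep]; type <- type[keep]; has_m8 <- has_m8[keep]
    start <- ifelse(has_m8, posm - 1L, posm) %% L
  } else {
    start <- ifelse(has_m8, pos - 1L, pos)
  }
  o <- order(start)
  data.frame(mirna = mirna$id, transcript = transcript$id,
             start = as.integer(start[o]), site_type = type[o],
             stringsAsFactors = FALSE)
}

#' Scan every miRNA against every transcript
#'
#' @param transcripts a [transcript_set].
#' @param mirnas a [mirna_set].
#' @return An object of class `target_map`: the concatenated site table
#'   (columns `mirna`, `transcript`, `start`, `site_type`) with the scanned
#'   transcript lengths as an attribute. Invariant to input ordering.
#' @export
build_target_map <- function(transcripts, mirnas) {
  if (anyDuplicated(transcripts$id))
    stop("duplicate transcript id(s)")
  out <- vector("list", nrow(transcripts) * nrow(mirnas))
  k <- 0L
  for (i in seq_len(nrow(transcripts))) {
    tr <- transcripts[i, ]
    for (j in seq_len(nrow(mirnas))) {
      k <- k + 1L
      out[[k]] <- find_seed_sites(tr, mirnas[j, ])
    }
  }
  sites <- do.call(rbind, c(out, list(.empty_sites())))
  sites <- sites[order(sites$mirna, sites$transcript, sites$start), ,
                 drop = FALSE]
  rownames(sites) <- NULL
  lens <- stats::setNames(nchar(transcripts$sequence), transcripts$id)
  structure(sites, class = c("target_map", "data.frame"),
            transcript_lengths = lens[order(names(lens))])
}

#' @export
print.target_map <- function(x, ...) {
  cat("target_map: ", nrow(x), " sites (", length(unique(x$mirna)),
      " miRNAs x ", length(unique(x$transcript)), " transcripts)\n", sep = "")
  print.data.frame(utils::head(as.data.frame(x), 6))
  if (nrow(x) > 6) cat("...\n")
  invisible(x)
}

#' Sites of a target map as a nested list
#'
#' @param map a `target_map`.
#' @return `list(mirna_id = list(transcript_id = data.frame of sites))`.
#' @export
target_map_as_list <- function(map) {
  lapply(split(as.data.frame(map), map$mirna),
         function(d) split(d, d$transcript, drop = TRUE))
}

#' Write a site table to TSV
#' @param map a `target_map` (or compatible data.frame).
#' @param path output TSV path.
#' @export
write_site_table <- function(map, path) {
  utils::write.table(as.data.frame(map)[, c("mirna", "transcript", "start",
                                            "site_type")],
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(map)
}

#' Load a precomputed site table
#'
#' Lets externally predicted target tables stand in for de novo scanning.
#'
#' @param path TSV with columns `mirna`, `transcript`, `start`, `site_type`.
#' @param transcript_lengths optional named vector of transcript lengths; if
#'   provided, `start` values are bounds-checked against them.
#' @return A `target_map`.
#' @export
load_site_table <- function(path, transcript_lengths = NULL) {
  sites <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("mirna", "transcript", "start", "site_type")
  if (!all(need %in% names(sites)))
    stop("site table must have columns: ", paste(need, collapse = ", "))
  sites <- sites[, need, drop = FALSE]
  for (col in c("mirna", "transcript", "site_type"))
    sites[[col]] <- as.character(sites[[col]])
  sites$start <- as.integer(sites$start)
  bad <- setdiff(unique(sites$site_type), c("8mer", "7mer-m8", "7mer-A1"))
  if (length(bad))
    stop("unknown site_type: ", paste(bad, collapse = ", "))
  if (any(sites$start < 0)) stop("negative site start")
  if (!is.null(transcript_lengths)) {
    L <- transcript_lengths[sites$transcript]
    over <- which(!is.na(L) & sites$start >= L)
    if (length(over))
      stop("site start beyond transcript length (row ", over[1], ": ",
           sites$transcript[over[1]], " start ", sites$start[over[1]], ")")
  }
  sites <- sites[order(sites$mirna, sites$transcript, sites$start), ,
                 drop = FALSE]
  rownames(sites) <- NULL
  structure(sites, class = c("target_map", "data.frame"),
            transcript_lengths = transcript_lengths)
}
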