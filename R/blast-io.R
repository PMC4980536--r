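#' Read BLAST tabular output (outfmt 6)
#'
#' Parses the standard 12-column tabular alignment format
#' (`qseqid sseqid pident length mismatch gapopen qstart qend sstart send
#' evalue bitscore`). Malformed rows are reported with their line number.
#'
#' @param path Path to the tabular file.
#' @return A data frame with the 12 standard columns, numeric where
#'   appropriate; `evalue` comes from column 11.
#' @export
read_blast_tabular <- function(path) {
  cols <- c("qseqid", "sseqid", "pident", "length", "mismatch", "gapopen",
            "qstart", "qend", "sstart", "send", "evalue", "bitscore")
  lines <- readLines(path)
  lines <- lines[nzchar(lines) & !grepl("^#", lines)]
  if (!length(lines)) {
    return(as.data.frame(setNames(rep(list(character(0)), 12L), cols)))
  }
  parts <- strsplit(lines, "\t", fixed = TRUE)
  nfield <- vapply(parts, length, 1L)
  if (any(nfield != 12L)) {
    stop("line ", which(nfield != 12L)[1L], ": expected 12 tab-separated ",
         "fields, found ", nfield[nfield != 12L][1L], call. = FALSE)
  }
  df <- as.data.frame(do.call(rbind, parts), stringsAsFactors = FALSE)
  names(df) <- cols
  num <- cols[3:12]
  for (cl in num) {
    v <- suppressWarnings(as.numeric(df[[cl]]))
    if (anyNA(v)) {
      stop("line ", which(is.na(v))[1L], ": non-numeric value '",
           df[[cl]][is.na(v)][1L], "' in column ", cl, call. = FALSE)
    }
    df[[cl]] <- v
  }
  df
}

#' @describeIn read_blast_tabular write a data frame with the 12 standard
#'   columns back to tabular format.
#' @param hits Data frame of alignment rows.
#' @export
write_blast_tabular <- function(hits, path) {
  write.table(hits, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' FASTA input and output
#'
#' Thin wrappers over Biostrings returning/accepting named character
#' vectors, the in-memory sequence representation used throughout.
#'
#' @param path FASTA file path.
#' @return `read_fasta()` returns a named character vector.
#' @export
read_fasta <- function(path) {
  ss <- Biostrings::readAAStringSet(path)
  setNames(as.character(ss), names(ss))
}

#' @rdname read_fasta
#' @param sequences Named character vector of sequences.
#' @export
write_fasta <- function(sequences, path) {
  stopifnot(is.character(sequences), !is.null(names(sequences)))
  ss <- Biostrings::AAStringSet(sequences)
  Biostrings::writeXStringSet(ss, path)
  invisible(path)
}
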