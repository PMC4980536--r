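#' Amino-acid alphabet and background frequencies
#'
#' The 20 standard residues, and the Robinson-Robinson background
#' frequencies conventionally used for protein database-search statistics.
#'
#' @return `aa_alphabet()` returns a character vector of the 20 one-letter
#'   residue codes; `default_aa_freqs()` a named numeric vector of
#'   background frequencies summing to 1.
#' @export
aa_alphabet <- function() {
  c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
    "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")
}

#' @rdname aa_alphabet
#' @export
default_aa_freqs <- function() {
  p <- c(A = 0.07805, R = 0.05129, N = 0.04487, D = 0.05364, C = 0.01925,
         Q = 0.04264, E = 0.06295, G = 0.07377, H = 0.02199, I = 0.05142,
         L = 0.09019, K = 0.05744, M = 0.02243, F = 0.03856, P = 0.05203,
         S = 0.07120, T = 0.05841, W = 0.01330, Y = 0.03216, V = 0.06441)
  p / sum(p)
}

#' The BLOSUM62 substitution matrix
#'
#' Returns the BLOSUM62 scoring matrix (including the ambiguity codes
#' B, Z, X and the stop `*`), as distributed with Biostrings.
#'
#' @return An integer matrix with residue codes as dimnames.
#' @export
blosum62 <- function() {
  env <- new.env()
  utils::data("BLOSUM62", package = "Biostrings", envir = env)
  env$BLOSUM62
}

#' Read a substitution matrix in NCBI text format
#'
#' Parses the plain-text matrix format used by NCBI tools: `#` comment
#' lines, a header row of residue codes, then one row per residue
#' beginning with its code.
#'
#' @param path Path to the matrix file.
#' @return A numeric matrix with residue dimnames.
#' @export
read_score_matrix <- function(path) {
  lines <- readLines(path)
  lines <- lines[!grepl("^\\s*#", lines) & nzchar(trimws(lines))]
  if (length(lines) < 2L) {
    stop("matrix file '", path, "' has no parseable rows", call. = FALSE)
  }
  cols <- strsplit(trimws(lines[1L]), "\\s+")[[1L]]
  rows <- lapply(lines[-1L], function(ln) strsplit(trimws(ln), "\\s+")[[1L]])
  bad <- which(vapply(rows, length, 1L) != length(cols) + 1L)
  if (length(bad)) {
    stop("matrix file '", path, "': row ", bad[1L] + 1L,
         " does not have ", length(cols), " scores", call. = FALSE)
  }
  m <- t(vapply(rows, function(r) as.numeric(r[-1L]), numeric(length(cols))))
  rownames(m) <- vapply(rows, `[[`, "", 1L)
  colnames(m) <- cols
  if (anyNA(m)) stop("matrix file '", path, "': non-numeric score", call. = FALSE)
  m
}

# Encode a sequence as 0-based indices into the matrix rows.
# unknown = "error" rejects residues absent from the matrix;
# unknown = "X" maps them to the matrix's X row when present.
encode_seq <- function(seq, mat, unknown = c("error", "X")) {
  unknown <- match.arg(unknown)
  chars <- strsplit(toupper(seq), "")[[1L]]
  idx <- match(chars, rownames(mat))
  if (anyNA(idx)) {
    if (unknown == "X" && "X" %in% rownames(mat)) {
      idx[is.na(idx)] <- match("X", rownames(mat))
    } else {
      stop("unknown residue symbol(s): ",
           paste(unique(chars[is.na(idx)]), collapse = ", "), call. = FALSE)
    }
  }
  idx - 1L
}
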