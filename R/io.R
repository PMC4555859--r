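#' Read and validate a protein sequence
#'
#' Accepts a plain one-letter residue string, a FASTA-formatted string, or
#' a path to a FASTA file (first record). Validation names the position of
#' the first illegal character.
#'
#' @param x Sequence string, FASTA text, or file path.
#' @return A character scalar of class `"protein_sequence"` (uppercase);
#'   any FASTA header is kept as attribute `header`.
#' @export
#' @examples
#' read_sequence(">x\nACDEFG")
read_sequence <- function(x) {
  if (inherits(x, "protein_sequence")) return(x)
  if (!is.character(x) || length(x) != 1L)
    stop("expected a single character string or file path")
  header <- NULL
  if (!startsWith(x, ">") && file.exists(x)) {
    if (requireNamespace("seqinr", quietly = TRUE)) {
      rec <- seqinr::read.fasta(x, seqtype = "AA", as.string = TRUE,
                                set.attributes = FALSE)
      header <- names(rec)[1]
      s <- toupper(rec[[1]])
    } else {
      lines <- readLines(x)
      header <- sub("^>", "", lines[1])
      s <- toupper(paste(lines[-1], collapse = ""))
    }
  } else if (startsWith(x, ">")) {
    lines <- strsplit(x, "\n")[[1]]
    header <- sub("^>\\s*", "", lines[1])
    s <- toupper(paste(lines[-1], collapse = ""))
  } else {
    s <- toupper(gsub("\\s", "", x))
  }
  if (nchar(s) == 0L) stop("empty sequence")
  bad <- regexpr(paste0("[^", paste(amino_acids(), collapse = ""), "]"), s)
  if (bad > 0)
    stop(sprintf("illegal character '%s' at position %d",
                 substr(s, bad, bad), bad))
  structure(s, class = "protein_sequence", header = header)
}

#' @export
print.protein_sequence <- function(x, ...) {
  h <- attr(x, "header")
  if (!is.null(h)) cat(">", h, "\n", sep = "")
  cat(unclass(x), "\n")
  invisible(x)
}

#' Bundled benchmark protein set
#'
#' Seventeen real benchmark sequences (54 to 279 residues) with their
#' stagnation-threshold calibration. The first seven come from the PDB,
#' the middle five from CASP9 targets, the last five extend the set to
#' larger chains.
#'
#' @return A data frame with columns `pdb_id`, `length`, `sequence`,
#'   `threshold`.
#' @export
#' @examples
#' b <- load_benchmarks()
#' b[b$pdb_id == "1CTF", c("length", "threshold")]
load_benchmarks <- function() {
  gwfold_benchmarks
}

#' Write a conformation to a plain-text file
#'
#' The serialization is the direction string: n - 1 whitespace-separated
#' tokens from 1..12 on one line. With `coords = TRUE` a tab-separated
#' x y z block of the decoded coordinates is appended as comment lines.
#'
#' @param conf A conformation.
#' @param path Output file.
#' @param coords Also dump absolute coordinates (default `FALSE`).
#' @return `path`, invisibly.
#' @export
write_conformation <- function(conf, path, coords = FALSE) {
  conf <- as_conformation(conf)
  lines <- paste(unclass(conf), collapse = " ")
  if (coords) {
    m <- decode_conformation(conf)
    lines <- c(lines, paste0("# ", apply(m, 1, paste, collapse = "\t")))
  }
  writeLines(lines, path)
  invisible(path)
}

#' Read a conformation written by [write_conformation()]
#'
#' @param path Input file (whitespace- or comma-separated direction
#'   tokens; `#` lines ignored).
#' @return A [conformation()].
#' @export
read_conformation <- function(path) {
  lines <- readLines(path)
  lines <- lines[!startsWith(trimws(lines), "#")]
  toks <- unlist(strsplit(paste(lines, collapse = " "), "[,[:space:]]+"))
  toks <- toks[nzchar(toks)]
  conformation(as.integer(toks))
}
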