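# 20 standard amino acids; 'X' marks unknown, '-' marks a gap.
AA20 <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
MSA_ALPHABET <- c(AA20, "X", "-")

new_msa <- function(ids, rows) {
  ids <- as.character(ids)
  rows <- toupper(as.character(rows))
  if (length(ids) != length(rows))
    stop("ids and rows differ in length")
  if (length(rows) < 1L) stop("alignment must contain at least one sequence")
  widths <- nchar(rows)
  if (length(unique(widths)) != 1L) {
    off <- ids[widths != widths[1L]][1L]
    stop("ragged alignment: sequence '", off, "' has width ",
         widths[ids == off][1L], ", expected ", widths[1L])
  }
  if (widths[1L] < 1L) stop("alignment width must be at least 1")
  # normalize any character outside the residue alphabet to 'X'
  chars <- strsplit(rows, "")
  bad <- unique(unlist(lapply(chars, function(ch) ch[!(ch %in% MSA_ALPHABET)])))
  if (length(bad)) {
    warning("unknown characters normalized to 'X': ",
            paste(bad, collapse = " "))
    rows <- vapply(chars, function(ch) {
      ch[!(ch %in% MSA_ALPHABET)] <- "X"
      paste(ch, collapse = "")
    }, character(1))
  }
  structure(list(ids = ids, rows = rows,
                 n_seqs = length(rows), length = widths[1L]),
            class = "msa")
}

#' Read a multiple sequence alignment
#'
#' Reads an alignment either as aligned FASTA or as the wrapped-blocks
#' plain-text dialect in which the alignment is broken into fixed-width
#' blocks (one `identifier subsequence` line per sequence, blocks separated
#' by blank lines) and must be re-concatenated per sequence in block order.
#'
#' Note on orientation: some alignment servers present one *residue
#' position* per output row. This package uses the universal convention:
#' rows are homologous sequences, columns are aligned residue positions.
#'
#' @param path path to the alignment file.
#' @param dialect `"fasta"` for aligned FASTA, `"blocks"` for the
#'   wrapped-blocks dialect.
#' @return An object of class `"msa"` with fields `ids`, `rows`, `n_seqs`
#'   and `length`. All rows have identical width; characters outside the
#'   20 amino acids, `X` and `-` are normalized to `X` with a warning.
#' @examples
#' tf <- tempfile(fileext = ".fasta")
#' writeLines(c(">s1", "ACDEF", ">s2", "ACD-F"), tf)
#' aln <- read_alignment(tf)
#' aln$n_seqs # 2
#' @export
read_alignment <- function(path, dialect = c("fasta", "blocks")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("no such file: ", path)
  if (dialect == "fasta") {
    set <- Biostrings::readBStringSet(path)
    new_msa(names(set), as.character(set))
  } else {
    read_wrapped_blocks(path)
  }
}

# Wrapped-blocks dialect: each block lists the same identifiers in the same
# order; widths within a block are equal; blocks concatenate left to right.
read_wrapped_blocks <- function(path) {
  lines <- readLines(path)
  lines <- sub("\\s+$", "", lines)
  blank <- grepl("^\\s*$", lines)
  if (all(blank)) stop("empty alignment file: ", path)
  blocks <- split(lines[!blank], cumsum(blank)[!blank])
  ids <- NULL
  parts <- NULL
  for (b in blocks) {
    m <- regmatches(b, regexec("^(\\S+)\\s+(\\S+)$", b))
    if (any(lengths(m) != 3L))
      stop("malformed block line: '", b[lengths(m) != 3L][1L], "'")
    bid <- vapply(m, `[`, character(1), 2L)
    bsq <- vapply(m, `[`, character(1), 3L)
    if (is.null(ids)) {
      ids <- bid
      parts <- as.list(bsq)
    } else {
      if (!identical(bid, ids))
        stop("block identifier mismatch: expected the same identifiers in ",
             "the same order in every block")
      parts <- Map(c, parts, bsq)
    }
  }
  new_msa(ids, vapply(parts, paste, character(1), collapse = ""))
}

#' Extract one alignment column
#'
#' @param msa an object of class `"msa"`.
#' @param position 1-based alignment position.
#' @return A list of class `"msa_column"` with `position` and `residues`,
#'   the latter a string of length `msa$n_seqs` giving the residue observed
#'   in each sequence at that position.
#' @export
get_column <- function(msa, position) {
  stopifnot(inherits(msa, "msa"))
  position <- as.integer(position)
  if (length(position) != 1L || is.na(position) ||
      position < 1L || position > msa$length)
    stop("position ", position, " out of range 1..", msa$length)
  structure(list(position = position,
                 residues = paste(substr(msa$rows, position, position),
                                  collapse = "")),
            class = "msa_column")
}

#' @export
print.msa <- function(x, ...) {
  cat("MSA: ", x$n_seqs, " sequences x ", x$length, " positions\n", sep = "")
  show <- utils::head(seq_len(x$n_seqs), 6L)
  w <- min(x$length, 60L)
  for (i in show)
    cat(sprintf("  %-12s %s%s\n", x$ids[i], substr(x$rows[i], 1L, w),
                if (x$length > w) "..." else ""))
  if (x$n_seqs > 6L) cat("  ... (", x$n_seqs - 6L, " more)\n", sep = "")
  invisible(x)
}

#' Write an alignment as aligned FASTA
#'
#' @param msa an `"msa"` object.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_msa_fasta <- function(msa, path) {
  stopifnot(inherits(msa, "msa"))
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_len(msa$n_seqs))
    writeLines(c(paste0(">", msa$ids[i]), msa$rows[i]), con)
  invisible(path)
}
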