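# Per-column complexity scores: VAR (variability), ENT (normalized Shannon
# entropy, 0-100) and KOL (bzip2 compressibility ratio).

column_residues <- function(column) {
  if (inherits(column, "msa_column")) column$residues
  else if (is.character(column) && length(column) == 1L) toupper(column)
  else stop("column must be an 'msa_column' or a single string")
}

# Relative frequencies of counted residue types in a column. Gaps and 'X'
# are excluded by default; include_gaps counts '-' as a 21st type.
column_freqs <- function(residues, include_gaps = FALSE) {
  ch <- strsplit(residues, "")[[1]]
  keep <- ch %in% AA20
  if (include_gaps) keep <- keep | ch == "-"
  ch <- ch[keep]
  if (!length(ch)) return(numeric(0))
  tab <- table(ch)
  as.numeric(tab) / sum(tab)
}

#' Column variability (VAR)
#'
#' Counts the residue types a position tolerates: the number of distinct
#' residue types whose relative frequency in the column is at least
#' `min_freq`. The definition is pluggable via `fun` so alternative
#' variability conventions (which may produce non-integer scores on other
#' scales) can be swapped in without touching downstream code.
#'
#' @param column an `"msa_column"` or a single residue string.
#' @param min_freq minimum relative frequency for a type to be counted
#'   (default 0.01).
#' @param include_gaps count gaps as a residue type (default `FALSE`).
#' @param fun optional replacement `function(freqs)` applied to the vector
#'   of relative type frequencies.
#' @return The variability score; 0 with attribute `undefined = TRUE` for an
#'   all-gap column.
#' @export
column_variability <- function(column, min_freq = 0.01,
                               include_gaps = FALSE, fun = NULL) {
  p <- column_freqs(column_residues(column), include_gaps)
  if (!length(p))
    return(structure(0, undefined = TRUE))
  if (!is.null(fun)) return(fun(p))
  sum(p >= min_freq)
}

#' Column entropy (ENT) on the 0-100 scale
#'
#' Normalized Shannon entropy of the residue-type frequency distribution at
#' an alignment column: `100 * (-sum p * ln p) / ln(20)`, clipped to
#' `[0, 100]`. 0 means fully conserved; 100 means uniform over all 20
#' amino-acid types. Gaps and unknown (`X`) residues are excluded from the
#' frequencies by default.
#'
#' @inheritParams column_variability
#' @return Entropy in `[0, 100]`; `NA` with attribute `undefined = TRUE`
#'   for an all-gap column.
#' @export
column_entropy <- function(column, include_gaps = FALSE) {
  p <- column_freqs(column_residues(column), include_gaps)
  if (!length(p))
    return(structure(NA_real_, undefined = TRUE))
  p <- p[p > 0]
  ent <- 100 * (-sum(p * log(p))) / log(20)
  min(max(ent, 0), 100)
}

#' Column Kolmogorov complexity score (KOL)
#'
#' Practical upper-bound proxy for the algorithmic complexity of the residue
#' string observed at one alignment column: the string (gaps included
#' verbatim, uppercase, one byte per character, no separators or trailing
#' newline) is compressed with the bzip2 block-sorting compressor and the
#' score is the compressed/raw byte ratio (`mode = "ratio"`, default) or the
#' raw compressed byte count (`mode = "bytes"`). The serialization is fixed
#' so scores are bit-reproducible. Because of bzip2 container overhead the
#' ratio exceeds 1 for short or incompressible inputs; no clipping is
#' applied.
#'
#' @inheritParams column_variability
#' @param mode `"ratio"` (default) or `"bytes"`.
#' @param level bzip2 compression level; only 9 (maximum, the default of
#'   base R's compressor) is supported.
#' @return The KOL score, strictly positive.
#' @export
column_kolmogorov <- function(column, mode = c("ratio", "bytes"),
                              level = 9L) {
  mode <- match.arg(mode)
  if (!identical(as.integer(level), 9L))
    stop("only bzip2 level 9 (maximum) is supported")
  s <- column_residues(column)
  if (nchar(s) == 0L) stop("empty column string")
  raw_bytes <- charToRaw(s)
  comp <- memCompress(raw_bytes, type = "bzip2")
  if (mode == "bytes") length(comp)
  else length(comp) / length(raw_bytes)
}

#' Per-position complexity track for an alignment
#'
#' Computes VAR, ENT and KOL for every column of an alignment. All-gap
#' positions are flagged as undefined rather than dropped: their `var` is 0,
#' `ent` is `NA`, and `flag` is `"allgap"`; KOL is still defined (the byte
#' string exists) and is reported.
#'
#' @param msa an `"msa"` object.
#' @param min_freq,include_gaps passed to the column scorers.
#' @return A data frame with columns `position`, `var`, `ent`, `kol`,
#'   `flag` (`"ok"` or `"allgap"`), one row per alignment position.
#' @examples
#' aln <- synth_msa(length = 8, n_seqs = 50, profile = c(1, 20), seed = 1)
#' head(complexity_track(aln))
#' @export
complexity_track <- function(msa, min_freq = 0.01, include_gaps = FALSE) {
  stopifnot(inherits(msa, "msa"))
  pos <- seq_len(msa$length)
  res <- lapply(pos, function(i) {
    col <- get_column(msa, i)
    v <- column_variability(col, min_freq = min_freq,
                            include_gaps = include_gaps)
    e <- column_entropy(col, include_gaps = include_gaps)
    k <- column_kolmogorov(col)
    undef <- isTRUE(attr(v, "undefined")) || isTRUE(attr(e, "undefined"))
    c(var = as.numeric(v), ent = as.numeric(e), kol = k,
      flag = as.numeric(undef))
  })
  m <- do.call(rbind, res)
  data.frame(position = pos, var = m[, "var"], ent = m[, "ent"],
             kol = m[, "kol"],
             flag = ifelse(m[, "flag"] > 0, "allgap", "ok"),
             stringsAsFactors = FALSE)
}

#' Write a complexity track as TSV
#'
#' Columns `position`, `var`, `ent`, `kol`, `flag`; undefined values are
#' rendered as `.`.
#'
#' @param track data frame from [complexity_track()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_complexity_tsv <- function(track, path) {
  out <- track
  for (nm in c("var", "ent", "kol"))
    out[[nm]] <- ifelse(is.na(out[[nm]]), ".",
                        trimws(formatC(out[[nm]], format = "g",
                                       digits = 10)))
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read a complexity track TSV
#'
#' @param path file written by [write_complexity_tsv()].
#' @return A data frame with numeric `var`, `ent`, `kol` (`NA` where `.`).
#' @export
read_complexity_tsv <- function(path) {
  d <- utils::read.table(path, sep = "\t", header = TRUE,
                         na.strings = ".", stringsAsFactors = FALSE)
  d$position <- as.integer(d$position)
  for (nm in c("var", "ent", "kol")) d[[nm]] <- as.numeric(d[[nm]])
  d
}
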