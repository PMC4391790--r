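# Pairwise correlation of per-residue tracks (complexity scores vs AREA,
# B-values, accessibilities, DISP, HST/HSTD).

as_track_df <- function(x, name = "track") {
  if (is.data.frame(x)) {
    if (!all(c("position", "value") %in% names(x)))
      stop(name, " data frame needs columns 'position' and 'value'")
    d <- x[, c("position", "value")]
  } else if (is.numeric(x)) {
    pos <- if (!is.null(names(x))) as.integer(names(x)) else seq_along(x)
    d <- data.frame(position = pos, value = as.numeric(x))
  } else stop(name, " must be a numeric vector or a position/value data frame")
  d <- d[!is.na(d$value), , drop = FALSE]
  d[order(d$position), , drop = FALSE]
}

#' Pair two per-residue tracks for correlation
#'
#' Aligns two tracks by position, pairing `x_i` with `y_{i+lag}` over the
#' positions where both are defined (pairwise deletion of missing values).
#' A positive lag compensates, for instance, for the rightward offset of
#' the triangle-area track, which is computed from residues i and i+2 but
#' reported at i.
#'
#' @param x,y numeric vectors (positions taken from names, else `1..n`) or
#'   data frames with columns `position` and `value`.
#' @param lag integer offset applied to `y`'s positions.
#' @return A list of class `"track_pair"` with `x`, `y`, `positions` and
#'   `n`.
#' @export
pair_tracks <- function(x, y, lag = 0L) {
  dx <- as_track_df(x, "x")
  dy <- as_track_df(y, "y")
  dy$position <- dy$position - as.integer(lag)
  common <- intersect(dx$position, dy$position)
  if (length(common) < 3L)
    stop("fewer than 3 overlapping defined positions (", length(common), ")")
  common <- sort(common)
  structure(list(x = dx$value[match(common, dx$position)],
                 y = dy$value[match(common, dy$position)],
                 positions = common, n = length(common)),
            class = "track_pair")
}

#' Correlation of a track pair
#'
#' Pearson product-moment correlation by default, Spearman on request.
#' `mode = "absolute"` (the default for benchmark-style conservation
#' reports, where all tabulated entries are non-negative) returns `|r|`:
#' for displacement-type tracks the relationship with conservation scores
#' can just as well be an anticorrelation, and it is the tempo of variation
#' along the chain, not its sign, that matters. `mode = "signed"` returns
#' r as is.
#'
#' @param pair a `"track_pair"` from [pair_tracks()].
#' @param mode `"absolute"` (default) or `"signed"`.
#' @param method `"pearson"` (default) or `"spearman"`.
#' @return The coefficient; `NA` with attribute `undefined = TRUE` when
#'   either track has zero variance.
#' @export
correlate_tracks <- function(pair, mode = c("absolute", "signed"),
                             method = c("pearson", "spearman")) {
  stopifnot(inherits(pair, "track_pair"))
  mode <- match.arg(mode)
  method <- match.arg(method)
  if (stats::sd(pair$x) == 0 || stats::sd(pair$y) == 0)
    return(structure(NA_real_, undefined = TRUE))
  r <- stats::cor(pair$x, pair$y, method = method)
  if (mode == "absolute") abs(r) else r
}

#' Correlation report over a named track collection
#'
#' One row per requested (x, y, lag) triple, with the number of paired
#' positions and the coefficient — the layout of a benchmark-style
#' correlation table.
#'
#' @param tracks named list of tracks (numeric vectors or position/value
#'   data frames).
#' @param pairs data frame with columns `x`, `y` (track names) and
#'   optionally `lag` (default 0).
#' @param mode,method passed to [correlate_tracks()].
#' @return A data frame with columns `x`, `y`, `lag`, `n`, `r` (`NA` where
#'   undefined; rendered as `.` by [write_correlation_tsv()]).
#' @export
correlation_report <- function(tracks, pairs,
                               mode = c("absolute", "signed"),
                               method = c("pearson", "spearman")) {
  mode <- match.arg(mode); method <- match.arg(method)
  if (!all(c("x", "y") %in% names(pairs)))
    stop("pairs needs columns 'x' and 'y'")
  if (!"lag" %in% names(pairs)) pairs$lag <- 0L
  miss <- setdiff(unique(c(pairs$x, pairs$y)), names(tracks))
  if (length(miss))
    stop("unknown track name(s): ", paste(miss, collapse = ", "))
  rows <- lapply(seq_len(nrow(pairs)), function(k) {
    tp <- tryCatch(pair_tracks(tracks[[pairs$x[k]]], tracks[[pairs$y[k]]],
                               lag = pairs$lag[k]),
                   error = function(e) NULL)
    if (is.null(tp))
      return(data.frame(x = pairs$x[k], y = pairs$y[k], lag = pairs$lag[k],
                        n = 0L, r = NA_real_))
    data.frame(x = pairs$x[k], y = pairs$y[k], lag = pairs$lag[k],
               n = tp$n,
               r = as.numeric(correlate_tracks(tp, mode, method)))
  })
  do.call(rbind, rows)
}

#' Write a correlation report as TSV
#'
#' @param report data frame from [correlation_report()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_correlation_tsv <- function(report, path) {
  out <- report
  out$r <- ifelse(is.na(out$r), ".", sprintf("%.4f", out$r))
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
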