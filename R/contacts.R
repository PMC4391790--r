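# Contact prediction by box-filtering complexity tracks, and evaluation
# against an experimental contact map via confusion counts and MCC.

#' Construct a score filter
#'
#' An inclusive band `[lower, upper]` on one of the per-position complexity
#' scores. A position passes when its score lies within the band. Defaults
#' are not imposed here; the canonical bands are the VAR/ENT "1:2 box"
#' (VAR 0.5-1.5 together with ENT 50-60) associated with fold-preserving
#' residues, and the KOL band 1.5-3.5.
#'
#' @param score one of `"var"`, `"ent"`, `"kol"`.
#' @param lower,upper inclusive bounds, `lower <= upper`.
#' @return A list of class `"score_filter"`.
#' @export
score_filter <- function(score = c("var", "ent", "kol"), lower, upper) {
  score <- match.arg(score)
  lower <- as.numeric(lower); upper <- as.numeric(upper)
  if (!is.finite(lower) || !is.finite(upper) || lower > upper)
    stop("need finite bounds with lower <= upper")
  structure(list(score = score, lower = lower, upper = upper),
            class = "score_filter")
}

#' Positions passing a set of score filters
#'
#' @param track data frame from [complexity_track()] (columns `position`
#'   and the filtered scores; optional `flag`).
#' @param filters a single [score_filter()] or a list of them.
#' @param combine `"all"` (default): a position must satisfy every filter;
#'   `"any"`: at least one.
#' @return Sorted integer vector of passing positions. Positions flagged
#'   undefined (`flag != "ok"`) never pass.
#' @export
passing_positions <- function(track, filters, combine = c("all", "any")) {
  combine <- match.arg(combine)
  if (inherits(filters, "score_filter")) filters <- list(filters)
  if (!length(filters)) stop("no filters supplied")
  if (!nrow(track)) stop("empty track")
  hits <- vapply(filters, function(f) {
    if (!inherits(f, "score_filter")) stop("filters must be score_filter objects")
    if (!f$score %in% names(track))
      stop("track has no '", f$score, "' column")
    v <- track[[f$score]]
    !is.na(v) & v >= f$lower & v <= f$upper
  }, logical(nrow(track)))
  hits <- matrix(hits, nrow = nrow(track))
  ok <- if (combine == "all") rowSums(hits) == length(filters)
        else rowSums(hits) > 0
  if ("flag" %in% names(track)) ok <- ok & track$flag == "ok"
  sort(as.integer(track$position[ok]))
}

#' Predict contacts from a passing-position set
#'
#' The predicted map is the set of all pairs of passing positions: plotting
#' the filtered score against itself, `(i, j)` with `i < j` is predicted
#' when both `i` and `j` pass. A `pair_score` hook accepts an arbitrary
#' `function(i, j)` returning `TRUE` for predicted pairs, for future
#' pair-scoring extensions.
#'
#' @param positions integer vector of passing positions, subset of `1..L`.
#' @param L protein length.
#' @param pair_score optional vectorized `function(i, j) -> logical`
#'   applied to all i < j pairs instead of the passing-set product.
#' @return A `"contact_map"`.
#' @export
predict_contacts <- function(positions, L, pair_score = NULL) {
  L <- as.integer(L)
  if (!is.null(pair_score)) {
    idx <- which(upper.tri(matrix(0, L, L)), arr.ind = TRUE)
    hit <- pair_score(idx[, 1], idx[, 2])
    return(new_contact_map(idx[hit, , drop = FALSE], L))
  }
  positions <- sort(unique(as.integer(positions)))
  if (length(positions) && (min(positions) < 1L || max(positions) > L))
    stop("positions out of range 1..", L)
  if (length(positions) < 2L)
    return(new_contact_map(matrix(integer(0), 0, 2), L))
  pairs <- t(utils::combn(positions, 2L))
  new_contact_map(pairs, L)
}

pair_key <- function(pairs, L) (pairs[, 1] - 1) * L + pairs[, 2]

#' Confusion counts for a predicted contact map
#'
#' Standard 2 x 2 counts over the pair universe of all i < j pairs (size
#' `L(L-1)/2`), optionally excluding every pair that involves a masked
#' position (e.g. positions without defined scores).
#'
#' @param pred,actual `"contact_map"` objects with equal `L`.
#' @param mask optional integer vector of excluded positions.
#' @return A list of class `"confusion_counts"` with `tp`, `fp`, `fn`,
#'   `tn`, and `mcc`.
#' @export
confusion <- function(pred, actual, mask = NULL) {
  stopifnot(inherits(pred, "contact_map"), inherits(actual, "contact_map"))
  if (pred$L != actual$L)
    stop("contact maps differ in L: ", pred$L, " vs ", actual$L)
  L <- pred$L
  keep_pairs <- function(p) {
    if (is.null(mask) || !nrow(p)) return(p)
    p[!(p[, 1] %in% mask | p[, 2] %in% mask), , drop = FALSE]
  }
  pp <- keep_pairs(pred$pairs)
  ap <- keep_pairs(actual$pairs)
  kp <- pair_key(pp, L); ka <- pair_key(ap, L)
  universe <- L * (L - 1) / 2
  if (!is.null(mask)) {
    m <- length(unique(mask[mask >= 1 & mask <= L]))
    universe <- (L - m) * (L - m - 1) / 2
  }
  tp <- sum(kp %in% ka)
  fp <- length(kp) - tp
  fn <- length(ka) - tp
  tn <- universe - tp - fp - fn
  out <- list(tp = tp, fp = fp, fn = fn, tn = tn)
  out$mcc <- mcc(out)
  structure(out, class = "confusion_counts")
}

#' @export
print.confusion_counts <- function(x, ...) {
  cat(sprintf("TP %d  FP %d  FN %d  TN %d  MCC %.4f\n",
              x$tp, x$fp, x$fn, x$tn, x$mcc))
  invisible(x)
}

#' Matthews correlation coefficient
#'
#' `MCC = (TP*TN - FP*FN) / sqrt((TP+FP)*(TP+FN)*(TN+FP)*(TN+FN))`, with
#' the four marginal sums formed in double precision before multiplication
#' (the product overflows 32-bit integers for protein-sized pair
#' universes). When any marginal sum is zero the coefficient is undefined
#' and 0 is returned by convention.
#'
#' Vectorized: `tp`, `fp`, `fn`, `tn` may be equal-length vectors. The
#' first argument may also be a `"confusion_counts"` object or a data frame
#' with columns `tp`, `fp`, `fn`, `tn`.
#'
#' @param tp,fp,fn,tn non-negative counts.
#' @return MCC in `[-1, 1]`.
#' @examples
#' mcc(122, 1294, 714, 40648) # 0.0890...
#' @export
mcc <- function(tp, fp = NULL, fn = NULL, tn = NULL) {
  if (is.list(tp) && all(c("tp", "fp", "fn", "tn") %in% names(tp))) {
    fp <- tp$fp; fn <- tp$fn; tn <- tp$tn; tp <- tp$tp
  }
  tp <- as.numeric(tp); fp <- as.numeric(fp)
  fn <- as.numeric(fn); tn <- as.numeric(tn)
  if (any(c(tp, fp, fn, tn) < 0)) stop("counts must be non-negative")
  s1 <- tp + fp; s2 <- tp + fn; s3 <- tn + fp; s4 <- tn + fn
  den <- sqrt(s1 * s2 * s3 * s4)
  num <- tp * tn - fp * fn
  ifelse(den == 0, 0, num / den)
}

#' Published contact-prediction benchmark counts
#'
#' Confusion counts (TP, FP, FN, TN) and the reported MCC for contact maps
#' of 20 protein chains predicted by two box filters: `VRN` (the VAR/ENT
#' "1:2 box") and `KLM` (the KOL 1.5-3.5 band). Shipped as a plain-text
#' fixture; the counts are exact printed integers and serve as inputs for
#' verifying the MCC arithmetic and the pair-universe bookkeeping.
#'
#' @return A data frame with columns `protein`, `method`, `tp`, `fp`, `fn`,
#'   `tn`, `mcc`.
#' @export
contact_benchmark <- function() {
  path <- system.file("extdata", "contact_benchmark.tsv",
                      package = "foldsignal", mustWork = TRUE)
  utils::read.table(path, sep = "\t", header = TRUE,
                    stringsAsFactors = FALSE)
}

#' Write a Table-2-style confusion report as TSV
#'
#' @param rows data frame with columns `protein`, `method`, `tp`, `fp`,
#'   `fn`, `tn` (and optionally `mcc`; recomputed when absent).
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_confusion_tsv <- function(rows, path) {
  if (!"mcc" %in% names(rows))
    rows$mcc <- mcc(rows$tp, rows$fp, rows$fn, rows$tn)
  rows$mcc <- sprintf("%.4f", rows$mcc)
  utils::write.table(rows, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Write a contact map as a TSV pair list
#'
#' @param map a `"contact_map"`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_contact_tsv <- function(map, path) {
  stopifnot(inherits(map, "contact_map"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("# L=", map$L), con)
  writeLines("i\tj", con)
  if (nrow(map$pairs))
    writeLines(paste(map$pairs[, 1], map$pairs[, 2], sep = "\t"), con)
  invisible(path)
}

#' Read a contact map written by [write_contact_tsv()]
#'
#' @param path input file path.
#' @return A `"contact_map"`.
#' @export
read_contact_tsv <- function(path) {
  first <- readLines(path, n = 1L)
  L <- as.integer(sub("^# L=", "", first))
  d <- utils::read.table(path, sep = "\t", header = TRUE, skip = 1L)
  new_contact_map(as.matrix(d), L)
}
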