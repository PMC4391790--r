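# Per-residue structural tracks from CA coordinates and secondary-structure
# strings: HST/HSTD encoding, CA-triangle areas, superposition and cognate
# displacements, contact maps, paired-track differences.

new_ca_trace <- function(coords, chain = "A", resno = NULL, icode = NULL) {
  coords <- as.matrix(coords)
  if (ncol(coords) != 3L) stop("coords must be an L x 3 matrix")
  L <- nrow(coords)
  if (is.null(resno)) resno <- seq_len(L)
  if (is.null(icode)) icode <- rep("", L)
  if (length(resno) != L || length(icode) != L)
    stop("residue ids and coordinates differ in length")
  dimnames(coords) <- list(NULL, c("x", "y", "z"))
  structure(list(chain = rep_len(as.character(chain), L),
                 resno = as.integer(resno), icode = as.character(icode),
                 coords = coords, length = L),
            class = "ca_trace")
}

#' @export
print.ca_trace <- function(x, ...) {
  cat("CA trace: ", x$length, " residues, chain ",
      paste(unique(x$chain), collapse = ","), "\n", sep = "")
  invisible(x)
}

#' Read a CA trace from a PDB file
#'
#' Parses fixed-column ATOM records: CA atoms of the requested chain, first
#' model only, highest-occupancy alternate location per residue. Residues
#' lacking a CA atom are simply absent from the trace.
#'
#' @param path path to a PDB file.
#' @param chain chain identifier; `NULL` takes the first chain encountered.
#' @param model_index 1-based model to read from multi-model files.
#' @return An object of class `"ca_trace"` with fields `chain`, `resno`,
#'   `icode`, `coords` (L x 3 matrix, angstrom) and `length`.
#' @export
read_ca_trace <- function(path, chain = NULL, model_index = 1L) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path)
  # restrict to the requested MODEL when the file has several
  mstart <- grep("^MODEL", lines)
  if (length(mstart)) {
    if (model_index > length(mstart))
      stop("model ", model_index, " not present (", length(mstart),
           " models)")
    mend <- c(grep("^ENDMDL", lines), length(lines))[model_index]
    lines <- lines[mstart[model_index]:mend]
  }
  atom <- lines[startsWith(lines, "ATOM")]
  if (!length(atom)) stop("no ATOM records in ", path)
  fld <- function(s, a, b) substr(s, a, b)
  name <- trimws(fld(atom, 13, 16))
  ca <- atom[name == "CA"]
  if (!length(ca)) stop("no CA atoms in ", path)
  chains <- fld(ca, 22, 22)
  if (is.null(chain)) chain <- chains[1L]
  sel <- chains == chain
  if (!any(sel))
    stop("chain '", chain, "' not found; available: ",
         paste(sort(unique(chains)), collapse = " "))
  ca <- ca[sel]
  altloc <- fld(ca, 17, 17)
  resno <- as.integer(fld(ca, 23, 26))
  icode <- trimws(fld(ca, 27, 27))
  occ <- suppressWarnings(as.numeric(fld(ca, 55, 60)))
  occ[is.na(occ)] <- 1
  xyz <- cbind(as.numeric(fld(ca, 31, 38)),
               as.numeric(fld(ca, 39, 46)),
               as.numeric(fld(ca, 47, 54)))
  # one CA per residue: keep the highest-occupancy altloc, first on ties
  key <- paste(resno, icode)
  keep <- unlist(lapply(split(seq_along(key), factor(key, unique(key))),
                        function(idx) idx[which.max(occ[idx])]),
                 use.names = FALSE)
  keep <- sort(keep)
  new_ca_trace(xyz[keep, , drop = FALSE], chain = chain,
               resno = resno[keep], icode = icode[keep])
}

#' Write a CA trace as minimal PDB coordinate records
#'
#' @param trace a `"ca_trace"`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_ca_pdb <- function(trace, path) {
  stopifnot(inherits(trace, "ca_trace"))
  rec <- sprintf(
    "ATOM  %5d  CA  ALA %1s%4d%1s   %8.3f%8.3f%8.3f  1.00  0.00           C",
    seq_len(trace$length), substr(trace$chain, 1, 1), trace$resno,
    ifelse(trace$icode == "", " ", substr(trace$icode, 1, 1)),
    trace$coords[, 1], trace$coords[, 2], trace$coords[, 3])
  writeLines(c(rec, "END"), path)
  invisible(path)
}

# --- HST secondary-structure coding --------------------------------------

# Nominal values: sheet S = 1, helix H = 2, 3-10 helix G = 3, turn T = 4,
# coil C = 5.
HST_CODE <- c(S = 1, H = 2, G = 3, T = 4, C = 5)

#' Map DSSP letters to the HST alphabet
#'
#' `E -> S`, `H -> H`, `G -> G`, `T -> T`, everything else (including B, I,
#' S and blank) `-> C`.
#'
#' @param ss a secondary-structure string or per-residue letter vector.
#' @return A character vector over `{S, H, G, T, C}`.
#' @export
dssp_to_hst <- function(ss) {
  ch <- toupper(if (length(ss) == 1L) strsplit(ss, "")[[1]] else ss)
  out <- rep("C", length(ch))
  out[ch == "E"] <- "S"
  out[ch %in% c("H", "G", "T")] <- ch[ch %in% c("H", "G", "T")]
  out
}

#' Numeric HST encoding of a secondary-structure string
#'
#' Encodes per-residue secondary-structure letters on the nominal scale
#' sheet `S = 1`, helix `H = 2`, 3_10 helix `G = 3`, turn `T = 4`, coil
#' `C = 5`. Letters outside `{S,H,G,T}` are treated as coil.
#'
#' @param ss a letter string (or vector) over the HST alphabet; DSSP input
#'   can be converted first with [dssp_to_hst()].
#' @return An object of class `"hst_track"`: list with `letters`, numeric
#'   `values` and `variant = "HST"`.
#' @examples
#' hst_encode("SCGT")$values # 1 5 3 4
#' @export
hst_encode <- function(ss) {
  ch <- toupper(if (length(ss) == 1L) strsplit(ss, "")[[1]] else as.character(ss))
  if (!length(ch)) stop("empty secondary-structure string")
  ch[!(ch %in% names(HST_CODE))] <- "C"
  structure(list(letters = ch, values = unname(HST_CODE[ch]),
                 variant = "HST"),
            class = "hst_track")
}

#' Differentiate an HST track (HSTD)
#'
#' Marks secondary-structure-element termini as "antispikes": for every
#' maximal run of sheet (`S`) the first and last residues take the value 0,
#' and for every maximal run of helix (`H`) they take 0.5; a run of length 1
#' receives the terminus value once. All other values are unchanged. Low
#' values flag positions under strong conservation pressure, so the
#' antispikes plot below the HST baseline at SSE boundaries.
#'
#' @param track an `"hst_track"` with `variant = "HST"`.
#' @param letters which run letters receive terminus values (default the
#'   canonical `S` and `H`; extendable to `G`/`T`).
#' @return An `"hst_track"` with `variant = "HSTD"`.
#' @examples
#' hst_differentiate(hst_encode("CHHHHC"))$values # 5 0.5 2 2 0.5 5
#' @export
hst_differentiate <- function(track, letters = c("S", "H")) {
  stopifnot(inherits(track, "hst_track"))
  terminus <- c(S = 0, H = 0.5)[letters]
  if (anyNA(terminus)) stop("terminus values defined only for S and H runs")
  vals <- track$values
  r <- rle(track$letters)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  for (k in seq_along(r$values)) {
    lt <- r$values[k]
    if (lt %in% letters) {
      vals[starts[k]] <- terminus[[lt]]
      vals[ends[k]] <- terminus[[lt]]
    }
  }
  structure(list(letters = track$letters, values = vals, variant = "HSTD"),
            class = "hst_track")
}

#' @export
print.hst_track <- function(x, ...) {
  cat(x$variant, " track, ", length(x$values), " residues\n", sep = "")
  invisible(x)
}

# --- CA-trace geometry ---------------------------------------------------

#' Centre of gravity of a CA trace
#'
#' Unweighted arithmetic mean of the CA coordinates. CA-only input keeps the
#' operation well defined without atomic masses; supply `weights` (e.g.
#' masses from a full structure) for a weighted centre.
#'
#' @param trace a `"ca_trace"`.
#' @param weights optional per-residue weights.
#' @return A length-3 numeric vector (x, y, z).
#' @export
center_of_gravity <- function(trace, weights = NULL) {
  stopifnot(inherits(trace, "ca_trace"))
  if (is.null(weights)) colMeans(trace$coords)
  else {
    stopifnot(length(weights) == trace$length)
    colSums(trace$coords * weights) / sum(weights)
  }
}

#' Triangle-area track (AREA)
#'
#' For each position `i = 1 .. L-2`, the area of the triangle with vertices
#' CA(i), CA(i+2) and the protein centre of gravity:
#' `area_i = 0.5 * || (CA_{i+2} - CA_i) x (CG - CA_i) ||`. Consecutive CA
#' atoms sit at an essentially constant 3.81 angstrom, but the i to i+2
#' distance tracks backbone dihedrals, so the area is a scalar proxy for
#' local secondary structure: compact elements (helices) give small areas,
#' turns and coil give large ones. The area is reported at position `i`,
#' which introduces a slight rightward offset relative to residue-centred
#' tracks; correlation analyses can compensate with a lag.
#'
#' @param trace a `"ca_trace"` with `length >= 3`.
#' @param cg centre of gravity; defaults to [center_of_gravity()] of the
#'   trace.
#' @return Numeric vector of `L - 2` areas (angstrom squared), named by
#'   position.
#' @export
triangle_area_track <- function(trace, cg = NULL) {
  stopifnot(inherits(trace, "ca_trace"))
  if (trace$length < 3L) stop("need at least 3 residues for AREA")
  if (is.null(cg)) cg <- center_of_gravity(trace)
  L <- trace$length
  a <- trace$coords[1:(L - 2), , drop = FALSE]
  b <- trace$coords[3:L, , drop = FALSE]
  u <- b - a
  v <- matrix(cg, nrow(a), 3, byrow = TRUE) - a
  cr <- cbind(u[, 2] * v[, 3] - u[, 3] * v[, 2],
              u[, 3] * v[, 1] - u[, 1] * v[, 3],
              u[, 1] * v[, 2] - u[, 2] * v[, 1])
  area <- 0.5 * sqrt(rowSums(cr^2))
  names(area) <- seq_len(L - 2)
  area
}

#' Contact map from a CA trace
#'
#' A residue pair (i, j), i < j, is a contact when the CA-CA distance is at
#' most `cutoff` and `j - i >= min_separation`. The defaults (8 angstrom,
#' separation 1 so that every i < j pair is considered) make the pair
#' universe the full `L(L-1)/2` triangle.
#'
#' @param trace a `"ca_trace"`.
#' @param cutoff distance cutoff in angstrom.
#' @param min_separation minimum sequence separation `j - i`.
#' @return An object of class `"contact_map"`: list with `L` and `pairs`,
#'   an n x 2 integer matrix of contacting positions (i < j).
#' @export
contact_map_from_structure <- function(trace, cutoff = 8.0,
                                       min_separation = 1L) {
  stopifnot(inherits(trace, "ca_trace"), cutoff > 0)
  d <- as.matrix(stats::dist(trace$coords))
  L <- trace$length
  idx <- which(upper.tri(d), arr.ind = TRUE)
  sep_ok <- idx[, 2] - idx[, 1] >= min_separation
  hit <- d[idx] <= cutoff & sep_ok
  new_contact_map(idx[hit, , drop = FALSE], L)
}

new_contact_map <- function(pairs, L) {
  pairs <- matrix(as.integer(pairs), ncol = 2)
  if (nrow(pairs)) {
    swap <- pairs[, 1] > pairs[, 2]
    pairs[swap, ] <- pairs[swap, 2:1]
    if (any(pairs[, 1] == pairs[, 2])) stop("self-pairs are not allowed")
    if (any(pairs < 1L) || any(pairs > L)) stop("pair index out of range")
    pairs <- unique(pairs[order(pairs[, 1], pairs[, 2]), , drop = FALSE])
  }
  dimnames(pairs) <- list(NULL, c("i", "j"))
  structure(list(L = as.integer(L), pairs = pairs), class = "contact_map")
}

#' @export
print.contact_map <- function(x, ...) {
  cat("Contact map: L = ", x$L, ", ", nrow(x$pairs), " contacts of ",
      x$L * (x$L - 1) / 2, " pairs\n", sep = "")
  invisible(x)
}

# --- superposition and displacement --------------------------------------

#' Least-squares rigid-body superposition (Kabsch)
#'
#' Optimal rotation and translation mapping trace I onto trace A in the
#' least-squares sense, via the singular value decomposition of the
#' covariance of the centred coordinate sets, with the determinant
#' correction that excludes reflections.
#'
#' @param traceA,traceI `"ca_trace"` objects of equal length with cognate
#'   residue ordering.
#' @return A list with `rotation` (3 x 3), `translation` (length 3; the
#'   transform is `x %*% t(rotation) + translation`), and `rmsd` after
#'   superposition.
#' @export
superpose <- function(traceA, traceI) {
  stopifnot(inherits(traceA, "ca_trace"), inherits(traceI, "ca_trace"))
  if (traceA$length != traceI$length)
    stop("traces differ in length: ", traceA$length, " vs ", traceI$length)
  if (traceA$length < 3L) stop("need at least 3 residues to superpose")
  P <- traceI$coords # moving
  Q <- traceA$coords # target
  cp <- colMeans(P); cq <- colMeans(Q)
  Pc <- sweep(P, 2, cp); Qc <- sweep(Q, 2, cq)
  H <- crossprod(Pc, Qc)
  sv <- svd(H)
  d <- sign(det(sv$v %*% t(sv$u)))
  D <- diag(c(1, 1, d))
  R <- sv$v %*% D %*% t(sv$u)
  t_vec <- as.numeric(cq - R %*% cp)
  moved <- P %*% t(R) + matrix(t_vec, nrow(P), 3, byrow = TRUE)
  rmsd <- sqrt(mean(rowSums((moved - Q)^2)))
  list(rotation = R, translation = t_vec, rmsd = rmsd)
}

apply_transform <- function(coords, fit) {
  coords %*% t(fit$rotation) +
    matrix(fit$translation, nrow(coords), 3, byrow = TRUE)
}

#' Per-residue cognate displacement track (DISP)
#'
#' Distance in angstrom between cognate CA atoms of the active (A) and
#' inactive (I) conformations, `DISP_i = || CA_i^A - T(CA_i^I) ||`, where T
#' is the least-squares superposition of I onto A (applied by default; set
#' `superpose_first = FALSE` when the two traces already share a frame).
#' DISP is zero everywhere when the two states differ only by a rigid
#' motion; conformational switching shows up as localized displacement.
#'
#' @param traceA,traceI `"ca_trace"` objects of equal length.
#' @param superpose_first superpose I onto A before measuring (default
#'   `TRUE`).
#' @return Numeric vector of per-residue displacements, named by position.
#' @export
displacement_track <- function(traceA, traceI, superpose_first = TRUE) {
  stopifnot(inherits(traceA, "ca_trace"), inherits(traceI, "ca_trace"))
  if (traceA$length != traceI$length)
    stop("traces differ in length: ", traceA$length, " vs ", traceI$length)
  ci <- traceI$coords
  if (superpose_first) ci <- apply_transform(ci, superpose(traceA, traceI))
  disp <- sqrt(rowSums((traceA$coords - ci)^2))
  names(disp) <- seq_len(traceA$length)
  disp
}

#' Absolute-difference track
#'
#' Elementwise `|A - I|` of two per-residue tracks (accessibility OACC,
#' B-value BVLC, ...). Positions missing (`NA`) in either input stay `NA`.
#'
#' @param trackA,trackI numeric vectors of equal length.
#' @return Numeric vector of absolute differences.
#' @export
difference_track <- function(trackA, trackI) {
  if (length(trackA) != length(trackI))
    stop("tracks differ in length: ", length(trackA), " vs ",
         length(trackI))
  abs(trackA - trackI)
}
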