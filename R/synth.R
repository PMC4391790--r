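# Synthetic fixtures: alignments with controlled per-column conservation,
# ideal helix / extended-strand CA traces, hinge-perturbed conformer pairs
# and correlated score tracks. All generators take an explicit seed and
# leave the caller's RNG state untouched.

with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

#' Synthetic multiple sequence alignment with controlled conservation
#'
#' Each column is drawn i.i.d. from a categorical distribution over `k`
#' residue types chosen uniformly at random from the 20 amino acids, where
#' `k` comes from the per-position conservation profile (`k = 1`: fully
#' conserved column; `k = 20`: uniform over the whole alphabet). Within the
#' chosen type set the distribution is uniform by default, or Dirichlet
#' with concentration `alpha` when supplied. Gaps replace residues
#' independently at `gap_rate`.
#'
#' @param length alignment width (positions).
#' @param n_seqs number of sequences.
#' @param profile integer vector of effective residue-type counts in
#'   `1..20`, recycled to `length`.
#' @param gap_rate per-cell gap probability in `[0, 1)`.
#' @param alpha optional Dirichlet concentration for within-set
#'   frequencies (scalar).
#' @param seed RNG seed; identical seeds give identical alignments.
#' @return An `"msa"` object.
#' @export
synth_msa <- function(length, n_seqs, profile = 20L, gap_rate = 0,
                      alpha = NULL, seed = 1L) {
  stopifnot(length >= 1, n_seqs >= 1, gap_rate >= 0, gap_rate < 1)
  profile <- as.integer(rep_len(profile, length))
  if (any(profile < 1L | profile > 20L))
    stop("profile values must lie in 1..20")
  with_seed(seed, {
    cols <- vapply(profile, function(k) {
      types <- sample(AA20, k)
      p <- if (is.null(alpha)) rep(1 / k, k)
           else { g <- stats::rgamma(k, shape = alpha); g / sum(g) }
      res <- sample(types, n_seqs, replace = TRUE, prob = p)
      if (gap_rate > 0)
        res[stats::runif(n_seqs) < gap_rate] <- "-"
      paste(res, collapse = "")
    }, character(1))
    # cols[i] is column i top-to-bottom; transpose into row strings
    mat <- do.call(cbind, strsplit(cols, ""))
    rows <- apply(mat, 1, paste, collapse = "")
    new_msa(sprintf("seq%04d", seq_len(n_seqs)), rows)
  })
}

# deterministic rigid transform derived from an integer offset, used to
# make trace generators "rotation/translation-reproducible"
offset_transform <- function(coords, seed_offset) {
  if (!seed_offset) return(coords)
  ang <- seed_offset * c(0.7, 1.3, 2.1)
  R <- rot_x(ang[1]) %*% rot_y(ang[2]) %*% rot_z(ang[3])
  shift <- seed_offset * c(1.5, -2.5, 3.5)
  coords %*% t(R) + matrix(shift, nrow(coords), 3, byrow = TRUE)
}

rot_x <- function(a) matrix(c(1, 0, 0, 0, cos(a), sin(a), 0, -sin(a), cos(a)), 3)
rot_y <- function(a) matrix(c(cos(a), 0, -sin(a), 0, 1, 0, sin(a), 0, cos(a)), 3)
rot_z <- function(a) matrix(c(cos(a), sin(a), 0, -sin(a), cos(a), 0, 0, 0, 1), 3)

# canonical alpha-helix geometry: 100 degrees of twist per residue, rise
# 1.52 A, radius solved from the 3.81 A consecutive-CA chord constraint:
# radius = sqrt(3.81^2 - 1.52^2) / (2 sin 50deg) ~ 2.2803 A
HELIX_TWIST_DEG <- 100
HELIX_RISE <- 1.52
HELIX_RADIUS <- sqrt(3.81^2 - HELIX_RISE^2) /
  (2 * sin(HELIX_TWIST_DEG / 2 * pi / 180))

#' Ideal alpha-helical CA trace
#'
#' CA atoms on a helix with 100 degrees of twist per residue and rise
#' 1.52 angstrom, the radius solved so that every consecutive CA-CA
#' distance is exactly 3.81 angstrom. `seed_offset` applies a fixed rigid
#' transform (derived deterministically from the offset), giving distinct
#' but reproducible placements.
#'
#' @param n_res number of residues (>= 3).
#' @param seed_offset integer; 0 leaves the canonical placement.
#' @return A `"ca_trace"`.
#' @export
synth_helix_trace <- function(n_res, seed_offset = 0L) {
  stopifnot(n_res >= 3)
  i <- seq_len(n_res) - 1
  theta <- i * HELIX_TWIST_DEG * pi / 180
  coords <- cbind(HELIX_RADIUS * cos(theta),
                  HELIX_RADIUS * sin(theta),
                  i * HELIX_RISE)
  new_ca_trace(offset_transform(coords, seed_offset))
}

#' Extended-strand (zigzag) CA trace
#'
#' Planar zigzag with consecutive CA-CA distance exactly 3.81 angstrom and
#' an i to i+2 distance of 6.5 angstrom (the extended-strand value), as a
#' strand-like control for the triangle-area track.
#'
#' @param n_res number of residues (>= 3).
#' @param seed_offset integer; fixed rigid transform as in
#'   [synth_helix_trace()].
#' @return A `"ca_trace"`.
#' @export
synth_extended_trace <- function(n_res, seed_offset = 0L) {
  stopifnot(n_res >= 3)
  step <- 6.5 / 2
  amp <- sqrt(3.81^2 - step^2) / 2
  i <- seq_len(n_res) - 1
  coords <- cbind(i * step, amp * (-1)^i, 0)
  new_ca_trace(offset_transform(coords, seed_offset))
}

#' Hinge-perturbed conformer pair
#'
#' Emulates a two-state (active/inactive) switch: residues after the hinge
#' are rotated by `angle_deg` about an axis through the hinge CA, and
#' isotropic Gaussian coordinate noise of `noise_sd` is added independently
#' to both copies. With zero noise the static domain is untouched, and each
#' moving residue's displacement equals the rotation chord
#' `2 r sin(angle/2)` where `r` is its perpendicular distance from the
#' axis.
#'
#' @param trace base `"ca_trace"`.
#' @param hinge_index hinge residue, `1 < hinge_index < L`.
#' @param angle_deg rotation angle in degrees.
#' @param axis rotation-axis direction (length-3, need not be unit).
#' @param noise_sd per-coordinate Gaussian noise (angstrom).
#' @param seed RNG seed for the noise.
#' @return A list with `"ca_trace"` elements `A` (unrotated) and `I`
#'   (rotated), plus `axis_point` and `axis` describing the hinge axis.
#' @export
synth_hinge_pair <- function(trace, hinge_index, angle_deg,
                             axis = c(0, 0, 1), noise_sd = 0, seed = 1L) {
  stopifnot(inherits(trace, "ca_trace"))
  L <- trace$length
  if (!(hinge_index > 1 && hinge_index < L))
    stop("hinge_index must lie strictly inside 1..", L)
  u <- axis / sqrt(sum(axis^2))
  p0 <- trace$coords[hinge_index, ]
  ang <- angle_deg * pi / 180
  # Rodrigues rotation about the axis (p0, u)
  K <- matrix(c(0, u[3], -u[2], -u[3], 0, u[1], u[2], -u[1], 0), 3)
  R <- diag(3) + sin(ang) * K + (1 - cos(ang)) * (K %*% K)
  ci <- trace$coords
  mov <- (hinge_index + 1):L
  ci[mov, ] <- sweep(sweep(ci[mov, , drop = FALSE], 2, p0) %*% t(R),
                     2, p0, `+`)
  ca <- trace$coords
  if (noise_sd > 0) {
    with_seed(seed, {
      ca <- ca + matrix(stats::rnorm(3 * L, sd = noise_sd), L, 3)
      ci <- ci + matrix(stats::rnorm(3 * L, sd = noise_sd), L, 3)
    })
  }
  list(A = new_ca_trace(ca, resno = trace$resno),
       I = new_ca_trace(ci, resno = trace$resno),
       axis_point = p0, axis = u)
}

#' Correlated standard-normal track pair
#'
#' `y = rho * x + sqrt(1 - rho^2) * eps` with `x`, `eps` i.i.d. standard
#' normal, so that `cor(x, y)` converges to `rho`.
#'
#' @param n track length.
#' @param rho target correlation in `[-1, 1]`.
#' @param seed RNG seed.
#' @return A list with numeric vectors `x` and `y`.
#' @export
synth_correlated_tracks <- function(n, rho, seed = 1L) {
  stopifnot(n >= 1, rho >= -1, rho <= 1)
  with_seed(seed, {
    x <- stats::rnorm(n)
    eps <- stats::rnorm(n)
    list(x = x, y = rho * x + sqrt(1 - rho^2) * eps)
  })
}
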