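# Shared test fixtures, all built in code.

# Composite "globule": a helix segment and an extended-strand segment, each
# placed about 15 A from the shared centre of gravity (as SSEs sit around a
# protein core). Returns the two segment traces expressed in the common
# frame plus the shared CG.
make_globule <- function(n_helix = 30, n_strand = 30) {
  h <- synth_helix_trace(n_helix)
  hc <- sweep(h$coords, 2, colMeans(h$coords))        # centre the helix
  hc <- hc + matrix(c(0, 15, 0), nrow(hc), 3, byrow = TRUE)
  e <- synth_extended_trace(n_strand)
  ec <- sweep(e$coords, 2, colMeans(e$coords))
  ec <- ec[, c(3, 2, 1)]                               # chain along z
  ec <- ec + matrix(c(0, -15, 0), nrow(ec), 3, byrow = TRUE)
  cg <- colMeans(rbind(hc, ec))
  helix <- h; helix$coords <- hc
  strand <- e; strand$coords <- ec
  list(helix = helix, strand = strand, cg = cg)
}

# Minimal PDB text with two chains and one altloc'd CA, for parser tests.
write_test_pdb <- function(path) {
  at <- function(serial, alt, resno, x, y, z, occ, chain = "A")
    sprintf("ATOM  %5d  CA %1sALA %1s%4d    %8.3f%8.3f%8.3f%6.2f  0.00           C",
            serial, alt, chain, resno, x, y, z, occ)
  lines <- c(
    at(1, " ", 1, 0, 0, 0, 1),
    at(2, "A", 2, 1, 0, 0, 0.4),
    at(3, "B", 2, 2, 0, 0, 0.6),
    at(4, " ", 3, 3, 0, 0, 1),
    at(5, " ", 1, 9, 9, 9, 1, chain = "B"),
    "END")
  writeLines(lines, path)
  path
}

random_rigid_transform <- function(coords, seed = 1L) {
  set.seed(seed)
  ang <- stats::runif(3, 0, 2 * pi)
  cx <- cos(ang); sx <- sin(ang)
  Rx <- matrix(c(1, 0, 0, 0, cx[1], sx[1], 0, -sx[1], cx[1]), 3)
  Ry <- matrix(c(cx[2], 0, -sx[2], 0, 1, 0, sx[2], 0, cx[2]), 3)
  Rz <- matrix(c(cx[3], sx[3], 0, -sx[3], cx[3], 0, 0, 0, 1), 3)
  R <- Rx %*% Ry %*% Rz
  shift <- stats::runif(3, -20, 20)
  coords %*% t(R) + matrix(shift, nrow(coords), 3, byrow = TRUE)
}
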