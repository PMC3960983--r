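# Independent oracles and fixture builders used across the suite.

# Two-pass histogram PMF, written independently of pmf_1d (explicit loop,
# shared-anchor bins); used for the bit-for-bit equivalence check.
naive_pmf_oracle <- function(values, bin_size, temperature = 300) {
  kT <- 0.0019872041 * temperature
  lo <- floor(min(values) / bin_size)
  hi <- ceiling(max(values) / bin_size)
  if (hi <= lo) hi <- lo + 1
  edges <- (lo:hi) * bin_size
  nb <- length(edges) - 1L
  counts <- integer(nb)
  for (v in values) {
    b <- floor((v - edges[1L]) / bin_size + 1e-12) + 1L
    if (b < 1L) b <- 1L
    if (b > nb) b <- nb
    counts[b] <- counts[b] + 1L
  }
  prob <- counts / length(values)
  f <- ifelse(prob > 0, -kT * log(prob), NA_real_)
  f - min(f, na.rm = TRUE)
}

# Dense trapezoid Boltzmann quadrature (independent of the package's
# Simpson rule).
quad_pmf_oracle <- function(energy, edges, temperature = 300, n = 4001) {
  kT <- 0.0019872041 * temperature
  f <- vapply(seq_len(length(edges) - 1L), function(i) {
    xs <- seq(edges[i], edges[i + 1L], length.out = n)
    ys <- exp(-vapply(xs, energy, numeric(1)) / kT)
    h <- xs[2L] - xs[1L]
    -kT * log(sum((ys[-1L] + ys[-n]) / 2) * h)
  }, numeric(1))
  f - min(f)
}

random_rotation <- function() {
  qr_dec <- qr(matrix(stats::rnorm(9), 3, 3))
  Q <- qr.Q(qr_dec)
  if (det(Q) < 0) Q[, 1] <- -Q[, 1]
  Q
}

pdb_atom_line <- function(serial, name, resname, chain, resno, x, y, z,
                          element = substr(name, 1, 1)) {
  paste0("ATOM  ", sprintf("%5d", serial), " ",
         sprintf("%-4s", paste0(" ", name)), " ",
         sprintf("%3s", resname), " ", chain, sprintf("%4d", resno),
         "    ", sprintf("%8.3f%8.3f%8.3f", x, y, z),
         sprintf("%6.2f%6.2f", 1, 0), "          ",
         sprintf("%2s", element))
}

write_mini_pdb <- function(path, coords_list, names, resnames, chain = "A",
                           resnos = seq_along(names)) {
  # coords_list: list of n_models matrices (n_atoms x 3)
  lines <- character(0)
  multi <- length(coords_list) > 1L
  for (m in seq_along(coords_list)) {
    if (multi) lines <- c(lines, sprintf("MODEL     %4d", m))
    xyz <- coords_list[[m]]
    for (i in seq_len(nrow(xyz))) {
      lines <- c(lines, pdb_atom_line(i, names[i], resnames[i], chain,
                                      resnos[i], xyz[i, 1], xyz[i, 2],
                                      xyz[i, 3]))
    }
    if (multi) lines <- c(lines, "ENDMDL")
  }
  writeLines(c(lines, "END"), path)
  path
}

motif_pdb <- function() {
  system.file("extdata", "m2_motifs_synthetic.pdb", package = "amdpmf")
}
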