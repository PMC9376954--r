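# Shared fixtures and independent oracle helpers for the test suite.

ff_default <- default_forcefield(sigma_SS = 0.41, r0_BS = 0.55)

top_r8 <- build_topology(8, 1)

r8_frame <- function(ff = ff_default, L = 35) {
  cg_frame(fibrilsim:::chain_template(8, ff), L = L)
}

perturbed_r8 <- function(sd = 0.02, seed = 4, ff = ff_default) {
  fr <- r8_frame(ff)
  set.seed(seed)
  fr$pos <- fr$pos + matrix(rnorm(length(fr$pos), 0, sd), ncol = 3)
  fr
}

# central finite-difference gradient oracle for the system energy
fd_forces <- function(frame, topology, ff, beads, h = 1e-6,
                      bonded_only = FALSE) {
  out <- matrix(0, length(beads), 3)
  for (bi in seq_along(beads)) {
    for (c in 1:3) {
      fp <- frame
      fp$pos[beads[bi], c] <- fp$pos[beads[bi], c] + h
      fm <- frame
      fm$pos[beads[bi], c] <- fm$pos[beads[bi], c] - h
      ep <- suppressWarnings(
        system_energy_forces(fp, topology, ff, bonded_only))$energy$total
      em <- suppressWarnings(
        system_energy_forces(fm, topology, ff, bonded_only))$energy$total
      out[bi, c] <- -(ep - em) / (2 * h)
    }
  }
  out
}

# brute-force single-linkage clustering oracle: R double loop over all
# inter-chain bead pairs, then repeated label merging until a fixed point
brute_clusters <- function(frame, topology, cutoff = 0.55) {
  nch <- topology$n_chains
  chain <- topology$beads$chain
  pos <- frame$pos
  L <- frame$L
  adj <- matrix(FALSE, nch, nch)
  n <- nrow(pos)
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      if (chain[i] == chain[j]) next
      d <- pos[i, ] - pos[j, ]
      d <- d - L * round(d / L)
      if (sum(d^2) <= cutoff^2) adj[chain[i], chain[j]] <- adj[chain[j], chain[i]] <- TRUE
    }
  }
  labels <- seq_len(nch)
  repeat {
    changed <- FALSE
    for (a in seq_len(nch)) {
      for (b in seq_len(nch)) {
        if (adj[a, b] && labels[b] != labels[a]) {
          m <- min(labels[a], labels[b])
          labels[labels == labels[a] | labels == labels[b]] <- m
          changed <- TRUE
        }
      }
    }
    if (!changed) break
  }
  match(labels, unique(labels))
}

# partition of chains into the same groups, regardless of label numbering?
same_partition <- function(a, b) {
  identical(match(a, unique(a)), match(b, unique(b)))
}

table2_row1 <- function() kinetic_params(7.84, 10.69e-5, 3.07, N = 72, V = 35^3)

kinetic_grid <- function(t_max = 12000) {
  c(seq(0, 95, by = 5), seq(100, 975, by = 25), seq(1000, t_max, by = 100))
}
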