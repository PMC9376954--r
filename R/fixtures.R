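#' Generate geometric test configurations
#'
#' Programmatic generators for the aggregate morphologies the analysis
#' modules are designed to distinguish:
#'
#' * `random_gas`: chains with i.i.d. uniform positions and orientations
#'   (no insertion floor, unlike [place_monomers()]);
#' * `parallel_ribbon`: chains on a 1-D lattice with identical orientation
#'   (a single laminated ribbon; `cn_parameter` is exactly 1);
#' * `antiparallel_pair`: two chains with opposite end-to-end vectors at a
#'   configurable gap (the basic fibril motif);
#' * `annular_ring`: chains arranged around a circle, oriented along the
#'   ring axis (a closed pore-like aggregate); each chain lies within the
#'   cluster cutoff of its two ring neighbors;
#' * `amorphous_blob`: a dense random cluster inside a sphere.
#'
#' Each generated frame is checked against its declared geometric property
#' at generation time (an internal assertion).
#'
#' @param kind One of `"random_gas"`, `"parallel_ribbon"`,
#'   `"antiparallel_pair"`, `"annular_ring"`, `"amorphous_blob"`.
#' @param n_chains Number of chains (forced to 2 for `antiparallel_pair`).
#' @param n_residues Residues per chain.
#' @param L Box edge in nm.
#' @param seed Integer seed (stochastic kinds).
#' @param ff Force field (chain geometry).
#' @param spacing Lattice/ring spacing between adjacent chains (nm).
#' @param gap Gap of the antiparallel pair (nm).
#' @param radius Sphere radius of the amorphous blob (nm).
#' @return A `cg_frame`; build the matching topology with
#'   `build_topology(n_residues, n_chains)`.
#' @export
make_fixture <- function(kind = c("random_gas", "parallel_ribbon",
                                  "antiparallel_pair", "annular_ring",
                                  "amorphous_blob"),
                         n_chains = 10, n_residues = 8, L = 35, seed = 1,
                         ff = default_forcefield(), spacing = 0.5,
                         gap = 0.5, radius = 3) {
  kind <- match.arg(kind)
  template <- chain_template(n_residues, ff)
  template <- sweep(template, 2, colMeans(template))
  m <- nrow(template)
  top <- build_topology(n_residues, n_chains)

  frame <- switch(kind,
    random_gas = {
      set.seed(seed)
      pos <- do.call(rbind, lapply(seq_len(n_chains), function(i) {
        sweep(template %*% t(random_rotation()), 2, runif(3, 0, L), `+`)
      }))
      cg_frame(pos, L = L)
    },
    parallel_ribbon = {
      pos <- do.call(rbind, lapply(seq_len(n_chains), function(i) {
        sweep(template, 2, c(L / 2, L / 2, L / 2 + (i - 1) * spacing), `+`)
      }))
      cg_frame(pos, L = L)
    },
    antiparallel_pair = {
      n_chains <- 2
      top <- build_topology(n_residues, 2)
      # rotate pi about z: the template is planar in xy, so the end-to-end
      # vector reverses exactly
      flip <- diag(c(-1, -1, 1))
      pos <- rbind(
        sweep(template, 2, c(L / 2, L / 2, L / 2), `+`),
        sweep(template %*% flip, 2, c(L / 2, L / 2, L / 2 + gap), `+`)
      )
      cg_frame(pos, L = L)
    },
    annular_ring = {
      # chains parallel to z, centers on a circle in the xy plane
      ring_r <- n_chains * spacing / (2 * pi)
      # align chain long axis (x in the template) with z
      Rz <- matrix(c(0, 0, -1, 0, 1, 0, 1, 0, 0), 3, 3, byrow = TRUE)
      pos <- do.call(rbind, lapply(seq_len(n_chains), function(i) {
        phi <- 2 * pi * (i - 1) / n_chains
        center <- c(L / 2 + ring_r * cos(phi), L / 2 + ring_r * sin(phi),
                    L / 2)
        sweep(template %*% t(Rz), 2, center, `+`)
      }))
      cg_frame(pos, L = L)
    },
    amorphous_blob = {
      set.seed(seed)
      pos <- NULL
      for (i in seq_len(n_chains)) {
        cand <- NULL
        for (try in seq_len(1000)) {
          repeat {
            c0 <- runif(3, -radius, radius)
            if (sum(c0^2) <= radius^2) break
          }
          cand <- sweep(template %*% t(random_rotation()), 2,
                        c0 + L / 2, `+`)
          if (is.null(pos) || .min_cross_dist2(cand, pos, L) >= 0.3^2) break
          cand <- NULL
        }
        if (is.null(cand))
          stop("amorphous_blob: cannot place ", n_chains,
               " chains in a radius-", radius, " nm sphere")
        pos <- rbind(pos, cand)
      }
      cg_frame(pos, L = L)
    }
  )

  .assert_fixture(kind, frame, top, spacing)
  frame
}

# generation-time checks of the declared geometric property of each fixture
.assert_fixture <- function(kind, frame, top, spacing) {
  switch(kind,
    parallel_ribbon = {
      cn <- cn_parameter(end_to_end_units(frame, top))
      stopifnot(abs(cn - 1) < 1e-10)
    },
    antiparallel_pair = {
      u <- end_to_end_units(frame, top)
      stopifnot(abs(sum(u[1, ] * u[2, ]) + 1) < 1e-10)
    },
    annular_ring = {
      cl <- find_clusters(frame, top)
      stopifnot(length(cl$sizes) == 1) # ring neighbors within the cutoff
    },
    amorphous_blob = ,
    random_gas = invisible(NULL)
  )
  invisible(NULL)
}
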