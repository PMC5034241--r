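#' Synthetic curve-pair fixtures with known topology
#'
#' Ground-truth geometries for validating the Gauss machinery without any
#' structure download:
#' \describe{
#'   \item{`hopf`}{two interlocked circles of equal radius in orthogonal
#'     planes, centres one radius apart; linking number +1 with the
#'     orientations used here.}
#'   \item{`torus_link_k`}{a core circle plus a curve winding `k` times
#'     around it on a torus; linking number +k.}
#'   \item{`unlinked_circles`}{two coplanar circles with disjoint interiors;
#'     linking number 0.}
#'   \item{`open_coil_pair`}{two random open walks with bond length
#'     `bond_length` and a self-avoidance bias; no defined linking.}
#'   \item{`cut_hopf_dimer`}{a Hopf link with an arc removed from each circle
#'     at the point farthest from the partner curve, yielding an open toy
#'     "dimer" whose Gaussian entanglement sits near the closed-curve value
#'     of 1; coordinates are scaled so the mean bond length is
#'     `bond_length`.}
#' }
#'
#' @param kind fixture kind (see above).
#' @param n_vertices vertices per curve (closed kinds) or per chain.
#' @param k winding number for `torus_link_k` (non-zero).
#' @param radius main radius (Angstrom-scale, default 10).
#' @param separation centre separation for `unlinked_circles` /
#'   `open_coil_pair` starting offset (default `3 * radius`).
#' @param cut_fraction fraction of each circle removed for
#'   `cut_hopf_dimer` (default 0.15).
#' @param bond_length target bond length for the open kinds (default 3.8).
#' @param seed RNG seed for the random kinds (the global RNG state is
#'   restored on exit).
#' @return A list with `curve_a`, `curve_b` (n x 3 matrices), `closed`
#'   (logical), `known_linking` (integer, `NA` for open kinds) and `kind`.
#' @export
make_fixture <- function(kind = c("hopf", "torus_link_k", "unlinked_circles",
                                  "open_coil_pair", "cut_hopf_dimer"),
                         n_vertices = 400, k = 2, radius = 10,
                         separation = 3 * radius, cut_fraction = 0.15,
                         bond_length = 3.8, seed = 1) {
  kind <- match.arg(kind)
  circle <- function(n, r, centre, u, v) {
    t <- 2 * pi * (seq_len(n) - 1) / n
    sweep(outer(cos(t), r * u) + outer(sin(t), r * v), 2, -centre)
  }
  ex <- c(1, 0, 0); ey <- c(0, 1, 0); ez <- c(0, 0, 1)
  switch(kind,
    hopf = {
      a <- circle(n_vertices, radius, c(0, 0, 0), ex, -ey)
      b <- circle(n_vertices, radius, c(radius, 0, 0), ex, ez)
      list(curve_a = a, curve_b = b, closed = TRUE, known_linking = 1L,
           kind = kind)
    },
    torus_link_k = {
      if (k == 0) stop("k must be non-zero for a torus link")
      r_tube <- radius / 3
      t <- 2 * pi * (seq_len(n_vertices) - 1) / n_vertices
      a <- circle(n_vertices, radius, c(0, 0, 0), ex, -ey)
      b <- cbind((radius + r_tube * cos(k * t)) * cos(t),
                 (radius + r_tube * cos(k * t)) * sin(t),
                 r_tube * sin(k * t))
      list(curve_a = a, curve_b = b, closed = TRUE,
           known_linking = as.integer(k), kind = kind)
    },
    unlinked_circles = {
      a <- circle(n_vertices, radius, c(0, 0, 0), ex, ey)
      b <- circle(n_vertices, radius, c(separation, 0, 0), ex, ey)
      list(curve_a = a, curve_b = b, closed = TRUE, known_linking = 0L,
           kind = kind)
    },
    open_coil_pair = {
      with_fixture_seed(seed, {
        a <- biased_saw(n_vertices, bond_length, origin = c(0, 0, 0))
        b <- biased_saw(n_vertices, bond_length,
                        origin = c(separation, 0, 0))
        list(curve_a = a, curve_b = b, closed = FALSE,
             known_linking = NA_integer_, kind = kind)
      })
    },
    cut_hopf_dimer = {
      # open arcs parametrised away from the point of each circle farthest
      # from its partner, so each gap faces outward
      delta <- pi * cut_fraction
      ta <- seq(pi + delta, pi - delta + 2 * pi, length.out = n_vertices)
      tb <- seq(delta, 2 * pi - delta, length.out = n_vertices)
      a <- cbind(radius * cos(ta), -radius * sin(ta), 0)
      b <- cbind(radius + radius * cos(tb), 0, radius * sin(tb))
      s <- bond_length / mean(c(bond_lengths(a), bond_lengths(b)))
      list(curve_a = a * s, curve_b = b * s, closed = FALSE,
           known_linking = NA_integer_, kind = kind)
    })
}

with_fixture_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()))
  }
  set.seed(seed)
  force(expr)
}

# random open walk with fixed bond length, directional persistence and a
# soft self-avoidance bias (resample a step that lands too close to the
# existing trace)
biased_saw <- function(n, bond_length, origin, persistence = 0.6,
                       max_try = 30) {
  x <- matrix(NA_real_, n, 3)
  x[1, ] <- origin
  dir <- unit(rnorm(3))
  for (i in 2:n) {
    for (try in seq_len(max_try)) {
      cand_dir <- unit(persistence * dir + rnorm(3))
      cand <- x[i - 1, ] + bond_length * cand_dir
      if (i <= 3) break
      d2 <- rowSums(sweep(x[1:(i - 2), , drop = FALSE], 2, cand)^2)
      if (min(d2) > (0.8 * bond_length)^2) break
    }
    x[i, ] <- cand
    dir <- cand_dir
  }
  x
}

#' Convert a fixture to a dimer structure
#'
#' Wraps the two curves of an open-kind fixture (or any two curves) into a
#' [dimer_structure] ready for [gaussian_entanglement()],
#' [closure_linking_number()] or [run_unbinding()].
#'
#' @param fixture result of [make_fixture()].
#' @param pdb_id identifier for the toy dimer.
#' @return A [dimer_structure].
#' @export
fixture_as_dimer <- function(fixture, pdb_id = toupper(fixture$kind)) {
  dimer_structure(ca_chain(fixture$curve_a, "A"),
                  ca_chain(fixture$curve_b, "B"),
                  pdb_id = pdb_id)
}

#' Write chains as a minimal Calpha-only PDB file
#'
#' Produces a valid PDB file (one CA atom per residue, chains A/B, poly-GLY)
#' readable by [read_ca_chains()]. Coordinates must fit the fixed-width PDB
#' coordinate fields (|x| < 10000).
#'
#' @param curves a [ca_chain], a [dimer_structure], or a list of one or two
#'   n x 3 coordinate matrices.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_toy_pdb <- function(curves, path) {
  if (inherits(curves, "dimer_structure"))
    curves <- list(curves$chain_a$coords, curves$chain_b$coords)
  if (inherits(curves, "ca_chain")) curves <- list(curves$coords)
  if (is.matrix(curves)) curves <- list(curves)
  stopifnot(length(curves) >= 1, length(curves) <= 2)
  xyz <- do.call(rbind, lapply(curves, as.matrix))
  if (any(abs(xyz) >= 9999.5))
    stop("coordinate overflow: PDB fields hold |x| < 10000")
  ns <- vapply(curves, nrow, integer(1))
  chain <- rep(c("A", "B")[seq_along(curves)], ns)
  resno <- unlist(lapply(ns, seq_len), use.names = FALSE)
  bio3d::write.pdb(file = path, xyz = as.numeric(t(xyz)),
                   resno = resno, chain = chain,
                   resid = rep("GLY", sum(ns)),
                   elety = rep("CA", sum(ns)))
  invisible(path)
}
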