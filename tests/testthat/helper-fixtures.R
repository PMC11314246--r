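# Hand-built fixtures for analyses that need full control over geometry.

# A bare topology whose "residues" are single point atoms, for
# centre-of-mass and contact arithmetic.
make_point_topology <- function(n, masses = rep(12, n), donor = FALSE,
                                acceptor = FALSE) {
  residues <- tibble::tibble(
    author_index = seq_len(n), code = "G",
    klass = classify_residue(rep("G", n))
  )
  atoms <- tibble::tibble(
    atom = seq_len(n), name = "CA", element = "C",
    author_index = seq_len(n), code = "G", role = "backbone",
    donor = donor, acceptor = acceptor, charge = 0,
    sigma = 3.4, epsilon = 0.1, mass = masses
  )
  structure(list(residues = residues, atoms = atoms), class = "ps_topology")
}

# Trajectory with explicit per-frame coordinates (list of n x 3 matrices).
make_traj <- function(frames, topology, surface = NULL) {
  coords <- array(unlist(frames), dim = c(nrow(frames[[1]]), 3, length(frames)))
  ps_trajectory(topology, coords, surface = surface)
}

wrap_angle_test <- function(x) ((x + pi) %% (2 * pi)) - pi

# Three 4-atom reference shapes with large mutual superposed RMSD (a rod, a
# square and a tetrahedron); superposition removes rotations and
# translations, so distinct *shapes* are needed wherever clusters must
# stay apart.
ref_shapes <- function() {
  list(
    rod = cbind(c(0, 5, 10, 15), 0, 0),
    square = rbind(c(0, 0, 0), c(8, 0, 0), c(8, 8, 0), c(0, 8, 0)),
    tetra = 8 * rbind(c(1, 1, 1), c(1, -1, -1), c(-1, 1, -1), c(-1, -1, 1))
  )
}

# Small standard surface used across tests.
test_surface <- function(ligand = "CH3", nx = 4, ny = 4, terminal_z = 15) {
  build_sam_surface(nx, ny, ligand, terminal_z = terminal_z)
}

# Cached samch3-like synthetic run shared by several test files.
samch3_run <- local({
  cache <- NULL
  function(n_frames = 600, seed = 42) {
    if (is.null(cache)) {
      cache <<- suppressMessages(generate_trajectory(
        scenario_preset("samch3-like", n_frames = n_frames, seed = seed),
        build_sam_surface(8, 8, "CH3")
      ))
    }
    cache
  }
})
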