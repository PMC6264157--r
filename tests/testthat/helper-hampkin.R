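# Shared fixtures and independent oracles for the test suite.

# The default synthetic dimer is used by many tests; build it once.
ref_params <- bundle_params()
ref_model <- build_dimer_model(ref_params)

# independent dihedral oracle (bio3d's torsion.xyz)
bio3d_dihedral <- function(p1, p2, p3, p4) {
  as.numeric(bio3d::torsion.xyz(c(p1, p2, p3, p4)))
}

# a schedule with a single motion column swept over `vals` (frame 1 stays
# the identity)
single_motion_schedule <- function(col, vals) {
  s <- motion_schedule(length(vals) + 1L)
  s[[col]][-1] <- vals
  s
}

# tiny two-atom topology whose single inter-chain CA distance is scripted
# per frame: the hand-countable restraint fixture
scripted_distance_trajectory <- function(distances) {
  atoms <- data.frame(chain = c("A", "B"), resid = 1L, resname = "ALA",
                      atom = "CA", element = "C",
                      x = c(0, 1), y = 0, z = 0, stringsAsFactors = FALSE)
  top <- hk_structure(atoms)
  xyz <- array(0, dim = c(length(distances), 2L, 3L))
  xyz[, 2L, 1L] <- distances
  hk_trajectory(top, xyz)
}
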