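# Internal unit system: lengths in micrometres (um), stresses and moduli in
# megapascals (MPa), forces in millinewtons (mN).  The key identity is
# 1 MPa * 1 um^2 = 1 uN, so Hertz-type expressions evaluated in (MPa, um)
# yield micronewtons; UN_PER_MN converts those to the mN scale used for
# reported forces.
UN_PER_MN <- 1000

un_to_mn <- function(f_un) f_un / UN_PER_MN

mn_to_un <- function(f_mn) f_mn * UN_PER_MN

# Gravitational constant used by the water-drop gauge calibration step,
# chosen with water density 1 g/mL so that 100 uL of water weighs 0.98 mN.
G_MN_PER_UL <- 9.8e-3

# Evaluate `code` under a fixed RNG seed, restoring the caller's RNG state.
# Every stochastic generator in the package goes through this, so results
# are pure functions of (parameters, seed).
with_seed <- function(seed, code) {
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    stats::runif(1)
  }
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  set.seed(seed)
  code
}
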