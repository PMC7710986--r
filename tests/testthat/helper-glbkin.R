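# Shared fixtures built in code.

# A minimal gated one-heme protein with round-number rates.
toy_gated_protein <- function(k_minus_H = 100, k_H = 500,
                              k_prime_on_NO = 5e9, k_NiR = 500) {
  protein_model("toy", list(
    heme_site(has_distal_his = TRUE, k_minus_H = k_minus_H, k_H = k_H,
              k_prime_on_NO = k_prime_on_NO, k_on_O2 = 1e9,
              k_off_O2 = 0.25, k_on_CO = 1.5e5, k_NiR_pH7 = k_NiR)))
}

# Exact slow eigenvalue of the two-state gated binding system
# (6c -> 5c -> bound with re-association k_H): independent closed form used
# as an oracle against both hexacoordinate_kobs and the ODE integrator.
gated_slow_eigenvalue <- function(k_minus_H, k_H, k_prime_on, ligand) {
  s <- k_minus_H + k_H + k_prime_on * ligand
  p <- k_minus_H * k_prime_on * ligand
  (s - sqrt(s^2 - 4 * p)) / 2
}

# Noise-free instrument profile clone.
noiseless <- function(instr) {
  instr$noise_sd <- 0
  instr
}
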