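# Independent oracles, kept deliberately separate from the package's own
# code paths.

# Brute-force monoisotopic mass: expand a formula into a flat list of atoms
# and sum IUPAC atomic masses one atom at a time.
oracle_atom_masses <- c(C = 12.0, H = 1.00782503207, D = 2.01410177785,
                        N = 14.0030740048, O = 15.9949146196)

oracle_flat_mass <- function(counts) {
  atoms <- rep(names(counts), times = unlist(counts))
  total <- 0
  for (a in atoms) total <- total + oracle_atom_masses[[a]]
  total
}

# Closed-form Gaussian peak area oracle: a trace area * dnorm(t, mu, sigma)
# integrates to `area` over an interval covering the peak.
oracle_gaussian_trace <- function(area, mu, sigma, from, to, dt) {
  t <- seq(from, to, by = dt)
  list(time = t, intensity = area * dnorm(t, mu, sigma))
}

# Published two-sided Grubbs critical values (standard tables).
oracle_grubbs_table <- list(
  "0.05" = c("10" = 2.290, "15" = 2.549, "20" = 2.709, "30" = 2.908,
             "40" = 3.036, "50" = 3.128),
  "0.01" = c("10" = 2.482, "20" = 3.001, "30" = 3.236)
)
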