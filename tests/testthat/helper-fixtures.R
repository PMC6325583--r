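# Shared fixtures: fragments and canonical mixtures built in code.

galactose <- fragment_spec("galactose", 6, 6)
glycerol <- fragment_spec("glycerol", 3, 3)
palmitate_acetate <- fragment_spec("16:0", 16, 8)      # even carbons only
palmitate_fame <- fragment_spec("16:0-FAME", 16, 8, 1) # + methyl carbon

# Closed-form binomial pmf, independent of the package's own code paths.
binom_pmf <- function(k, n, p) choose(n, k) * p^k * (1 - p)^(n - k)

two_pop <- function(p_lab, f_lab, p_nat = natural_13c_abundance()) {
  label_populations(c(p_nat, p_lab), c(1 - f_lab, f_lab))
}
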