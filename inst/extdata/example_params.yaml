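# Example parameter file for pdrcea::load_parameters().
#
# Flat key: value pairs using the canonical parameter names (see
# default_parameters()). Keys omitted here keep their base-case values
# when fill_defaults = TRUE. An optional `distributions` block can
# override the PSA family / 95% CI of individual parameters.

# Markov transition probabilities (annual)
p_NPDR_to_DME: 0.1522
p_PDR_to_DME: 0.179
p_PDR_to_SVL: 0.18

# treatment-related probabilities
p_PRP_success: 0.2008
p_recur_post_PRP: 0.0169
p_antiVEGF_DME_success: 0.534
p_endoph_per_injection: 0.0006
p_endoph_treat_success: 0.595
p_loss_followup: 0.2

# mortality and effectiveness relative risks
rr_antiVEGF_vs_PRP_effect: 1.75
rr_recur_antiVEGF_vs_PRP: 1.15
rr_death_diabetes: 1.49
rr_death_SVL: 11.54

# discounting
discount_rate: 0.045

# example distribution override: supply a CI for the SVL mortality RR
distributions:
  rr_death_SVL:
    dist: lognormal
    ci: [9.23, 13.85]
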