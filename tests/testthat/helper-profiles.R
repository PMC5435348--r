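# Shared fixtures: the standard malignant/normal study pair and a small
# plain profile with no signalling-genotype differences, used where a test
# needs simple, analytically tractable cytokinetics.
study_pair <- study_profile_pair()

plain_profile <- function(loss = 0.05, diff = 0.1, quiescent = 0) {
  cell_line_profile("plain", cell_cycle_time = 20,
                    cell_loss_factor = loss,
                    differentiating_fraction = diff,
                    quiescent_fraction = quiescent)
}

# End-of-run live count for a short simulation.
final_live <- function(res) {
  ts <- res$timeseries
  ts$total_live[nrow(ts)]
}
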