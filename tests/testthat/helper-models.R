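# shared shortcuts: default parameters and a fast split-root runner
P <- nf_params()

split_final <- function(preset, ne, duration_h = 144, mutant = "WT",
                        init_pools = "zero") {
  model <- foraging_model(flags = nf_ladder(preset), mutant = mutant)
  unname(final_lengths(integrate_model(model,
    nf_experiment(ne = ne, duration_h = duration_h, l0 = 20,
                  init_pools = init_pools))))
}
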