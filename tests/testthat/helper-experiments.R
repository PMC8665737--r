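# Shared reduced configuration for the training experiments: the tiny model
# preset at a fixed small budget keeps each arm to about a minute.  The
# experiments compare arms against each other, so the cheap greedy decoder
# is used throughout.
ablation_cfg <- function() {
  list(model = model_config("tiny"),
       train = train_config(lr = 4e-3, steps = 120L, batch_size = 8L,
                            chunk_samples = 900L, seed = 1L,
                            eval_reads = 12L, eval_decoder = "greedy"))
}
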