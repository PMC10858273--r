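# Example pipeline configuration for the triadug command-line wrapper.
out: ug_run
seed: 1
# Path to a canonical trial CSV (produced by `simulate` or adapted from
# external data via `dialect`).
data: ug_run/trials.csv
simulate:
  n_triads: 2
  proposer1:
    name: reluctant
    p_decrease_after_accept: 0.25
  proposer2:
    name: outbidder
    share_threshold: 4
  responder:
    weber_w: 0.25
    side_bias: 0.5
sampler:
  chains: 2
  draws: 500
  warmup: 500
baseline:
  lambda_trial: 0.2
  lambda_session: 0.2
  n_sessions: 250000
power:
  n_triads: 2
  n_replicates: 5
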