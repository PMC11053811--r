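# Desk-scale demicellization scenario: linear diblock with stoichiometric
# trigger dosing (see load_config()).
architecture: A30B30
n_chains: 16
cargo_count: 32
trigger_mode: stoichiometric
rp_t: 0.5
rp_b: 0.2
attempt_every: 25
reaction_steps: 60000
phi: 0.12
seed: 101
protocol:
  dt: 0.006
  tstar: 1.8
  gamma: 1.0
  n_pushoff: 2000
  n_equil: 20000
  n_prod: 6000
  snapshot_every: 2000
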