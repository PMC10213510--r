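frame_ms: 50.0
depth: 0.75
cycles:
  low_rate: 1
  high_rate: 3
phases:
- 0.0
- 0.785398163397448
- 1.570796326794897
- 2.356194490192345
- 3.141592653589793
- 3.926990816987241
- 4.71238898038469
- 5.497787143782138
isi_range:
- 400.0
- 800.0
gap_ms:
  male: 1661.0
  female: 1603.0
early_ms:
  male: 1200.0
  female: 1200.0
final_word_ms: 350.0
n_blocks: 3
n_trials_per_block: 40
initial_level:
  early: 1.0
  late: 1.5
bounds:
  early:
  - 0.0
  - 1.0
  late:
  - 0.0
  - 2.0
n_reversals_used: 4
seed: 1
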