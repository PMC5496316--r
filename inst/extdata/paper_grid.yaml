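# Full factorial study grid: 5 sample-size ratios x 2 DIF magnitudes x
# 2 scale lengths x 3 category counts x 13 latent-trait conditions = 780 cells.
base_seed: 20170620
reps: 1000
alpha: 0.05
ratios:
  - [100, 100]
  - [200, 100]
  - [300, 100]
  - [400, 100]
  - [500, 100]
deltas: [0.5, 1.0]
n_items: [5, 10]
n_categories: [3, 5, 7]
conditions: [1, 2, 3, 4, 5, 6, 7, 8, 9, 10, 11, 12, 13]
retry_budget: 5
alpha_item_policy: all_dif_free
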