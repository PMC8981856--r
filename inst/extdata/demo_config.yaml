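dataset: demo_dataset.csv
variables:
  - name: Quantity of prickles
    kind: qualitative
    source: ontology_file
    source_path: prickles_normal.owl
  - name: Petal colour
    kind: qualitative
    source: colour_table
    source_path: demo_colours.csv
  - name: Geographic origin
    kind: qualitative
    source: geo_table
    source_path: demo_geo.csv
  - name: Breeding period
    kind: qualitative
    source: period_table
    source_path: demo_periods.csv
  - name: Number of flowers by volume
    kind: quantitative
distance: both
reduction:
  method: pcoa
  n_dims: 2
  undefined_policy: mean_impute
clustering:
  algorithms: [kmeans, ward]
  k: [2, 3]
archetypes:
  mode: single
seed: 7
output_dir: phenodist_run
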