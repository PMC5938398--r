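# Demonstration configuration: simulate both network dialects, ingest them
# through the shipped catalog and mapping, and analyze leafing-out onsets.
seed: 42
simulate:
  n_plants: 60
  genera: [Acer, Quercus]
  lat_range: [40.0, 60.0]
  lon_range: [-10.0, 30.0]
  years: [2000, 2001, 2002, 2003, 2004, 2005, 2006, 2007, 2008, 2009]
  onset_intercept: 20
  onset_slope: 2.5
  onset_sd: 5
  season_length: 150
  status_cadence: 7
  networks: [status, event]
  fraction_agricultural: 0.05
analysis:
  require_class: true_leaf_present
  exclude_class: senescing_true_leaf_present
  min_records: 50
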