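# Default calibration of the synthetic DSS-colitis multi-omics study.
# Values are study conditions, not code: edit here, never in R sources.
#
# Composition targets encode the published kinetics: Proteobacteria
# (genus Helicobacter) peaks at 32% of total abundance in treated
# C57BL/6 on day 15 and at 29% in treated BALB/c on day 7;
# Verrucomicrobia (Akkermansia) appears only in the BALB/c day-15
# recovery; phylum evenness of treated C57BL/6 falls monotonically.
# Conditions not listed fall back to the shared control profile
# (treatment starts at day 0, so treated day-0 equals control).

seed: 1

design:
  strains: ["C57BL/6", "BALB/c"]
  days: [0, 7, 15]
  arms: [control, treated]
  n_per_group: 3

otu:
  depth: 10000
  concentration: 200
  taxa:
    - {feature_id: OTU1, genus: Bacteroides,     phylum: Bacteroidetes}
    - {feature_id: OTU2, genus: Alistipes,       phylum: Bacteroidetes}
    - {feature_id: OTU3, genus: Lachnospiraceae, phylum: Firmicutes}
    - {feature_id: OTU4, genus: Helicobacter,    phylum: Proteobacteria}
    - {feature_id: OTU5, genus: Akkermansia,     phylum: Verrucomicrobia}
    - {feature_id: OTU6, genus: unclassified,    phylum: unclassified}
  proportions:
    control:
      {Bacteroides: 0.25, Alistipes: 0.15, Lachnospiraceae: 0.40,
       Helicobacter: 0.08, Akkermansia: 0.02, unclassified: 0.10}
    "C57BL/6|7|treated":
      {Bacteroides: 0.35, Alistipes: 0.21, Lachnospiraceae: 0.10,
       Helicobacter: 0.20, Akkermansia: 0.005, unclassified: 0.135}
    "C57BL/6|15|treated":
      {Bacteroides: 0.34, Alistipes: 0.21, Lachnospiraceae: 0.06,
       Helicobacter: 0.32, Akkermansia: 0.005, unclassified: 0.065}
    "BALB/c|7|treated":
      {Bacteroides: 0.34, Alistipes: 0.20, Lachnospiraceae: 0.08,
       Helicobacter: 0.29, Akkermansia: 0.005, unclassified: 0.085}
    "BALB/c|15|treated":
      {Bacteroides: 0.23, Alistipes: 0.15, Lachnospiraceae: 0.30,
       Helicobacter: 0.08, Akkermansia: 0.12, unclassified: 0.12}

# log-scale (natural log) treated mean shifts by label; omitted
# conditions shift by 0. Pro-inflammatory transcripts rise monotonically
# over days in treated C57BL/6 and peak at day 7 in treated BALB/c.
transcript:
  n_features: 120
  n_pro: 30
  n_anti: 30
  baseline_log_mean: 4.6
  baseline_log_mean_sd: 1.0
  log_sd: 0.5
  shifts:
    "C57BL/6|7|treated":  {pro: 0.9163, anti: 0.2624}
    "C57BL/6|15|treated": {pro: 1.3863, anti: 0.4055}
    "BALB/c|7|treated":   {pro: 1.0986, anti: 0.4055}
    "BALB/c|15|treated":  {pro: 0.4055, anti: 0.9163}

# host (serum) metabolites: strongest displacement at C57BL/6 day 15
serum_metabolite:
  n_features: 40
  n_pro: 10
  n_anti: 10
  baseline_log_mean: 2.3
  baseline_log_mean_sd: 0.8
  log_sd: 0.5
  shifts:
    "C57BL/6|7|treated":  {pro: 0.6931, anti: 0.2624}
    "C57BL/6|15|treated": {pro: 1.3863, anti: 0.4055}
    "BALB/c|7|treated":   {pro: 0.9163, anti: 0.4055}
    "BALB/c|15|treated":  {pro: 0.4055, anti: 0.6931}

# microbiota-derived (cecal) metabolites: largest transition at BALB/c day 7
cecal_metabolite:
  n_features: 40
  n_pro: 10
  n_anti: 10
  baseline_log_mean: 2.3
  baseline_log_mean_sd: 0.8
  log_sd: 0.5
  shifts:
    "C57BL/6|7|treated":  {pro: 0.6931, anti: 0.2624}
    "C57BL/6|15|treated": {pro: 1.0986, anti: 0.4055}
    "BALB/c|7|treated":   {pro: 1.3863, anti: 0.4055}
    "BALB/c|15|treated":  {pro: 0.4055, anti: 0.9163}

clinical:
  grade_noise: 1
  weight_sd: 1.0
  severity:
    control:              {weight: 1.0,  stool: 0, blood: 0}
    "C57BL/6|7|treated":  {weight: -8.0, stool: 2, blood: 2}
    "C57BL/6|15|treated": {weight: -16.0, stool: 4, blood: 3}
    "BALB/c|7|treated":   {weight: -10.0, stool: 3, blood: 2}
    "BALB/c|15|treated":  {weight: -4.0, stool: 1, blood: 1}
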