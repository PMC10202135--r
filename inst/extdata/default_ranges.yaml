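# Editable default parameter ranges for the canopy simulator.
# Each entry is [lo, hi]; units in the comments.
leaf_length_rank1: [40.0, 90.0]      # mm, first-rank final blade length
leaf_length_growth: [1.1, 1.5]       # per-rank geometric growth (lengths capped at 200 mm)
leaf_width_max: [4.0, 9.0]           # mm, maximum blade width of the longest rank
inclination: [20.0, 70.0]            # degrees from vertical at insertion
curvature: [0.0, 1.0]                # dimensionless midrib droop
phyllotaxy_jitter: [5.0, 20.0]       # degrees s.d. around 180-degree alternation
sowing_density: [100.0, 400.0]       # plants per square metre
row_spacing: [80.0, 150.0]           # mm
position_jitter_sd: [2.0, 10.0]      # mm
phyllochron: [80.0, 120.0]           # degree-days per leaf
thermal_time: [80.0, 420.0]          # degree-days since emergence (development stage)
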