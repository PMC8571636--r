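# Scaled-down experiment profile: Lotka-Volterra only, four species,
# the contrast-rich TSI settings, 200 replicates per cell.
models: [lotka_volterra]
species_richness: [4]
stressor_richness: [1, 2, 5, 10, 20]
tsi_levels: ["90%", unfixed]
interactions: [false]
replicates: 200
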