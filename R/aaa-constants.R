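# Fixed channel panel of the synthetic PBMC-like samples: scatter, four
# surface markers, four intracellular cytokines.
SYNTH_CHANNELS <- c(
  "FSC-A", "SSC-A", "CD123", "CD11c", "MHC-II", "CD14",
  "IL-6", "IL-12", "TNF-a", "IFN-a"
)
SYNTH_FLUOR_CHANNELS <- SYNTH_CHANNELS[3:10]
SYNTH_CYTOKINE_CHANNELS <- SYNTH_CHANNELS[7:10]
SYNTH_RANGE <- 1e5
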