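>CRP_mature human C-reactive protein, mature monomer (206 aa)
QTDMSRKAFVFPKESDTSYVSLKAPLTKPLKAFTVCLHFYTELSSTRGYS
IFSYATKRQDNEILIFWSKDIGYSFTVGGSEILFEVPEVTVAPVHICTSW
ESASGIVEFWVDGKPRVRKSLKKGYTVGAEASIILGQEQDSFGGNFEGSQ
SLVGDIGNVNMWDFVLSPDEINTIYLGGPFSPNVLNWRALKYEVQGEVFT
KPQLWP
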