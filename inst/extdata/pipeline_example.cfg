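# nitroquant pipeline configuration (key = value; '#' starts a comment)

tol_ppm = 10          # reporter matching tolerance, ppm
window = 0.001        # diagnostic chromatogram half-width, Da
corrections = "n15"   # "", "n15", or "n15+c13"
resolution = 120000   # MS2 resolution for the c13 leakage model
precursor_tol_ppm = 10
rt_gap = 0.5          # minutes
weighted = false
seed = 1

reference = "ref.mzML"
inputs = "r025a.mzML"
outdir = "nitroquant_out"
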