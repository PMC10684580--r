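# Stopped-flow kinetic constants for (KR)n peptides binding the
# seven-module designed Armadillo repeat protein (mean values).
# The 4-repeat peptide row is omitted: its printed off-rate is
# typographically inconsistent with the printed dissociation constant.
peptide,k_on,k_off
(KR)5,3.5e8,1.7e-2
(KR)6,6.3e8,3.0e-3
(KR)7,6.2e8,3.0e-4
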