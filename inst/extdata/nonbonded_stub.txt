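# Minimal nonbonded parameter stub for synthetic fixtures.
# Columns: resname name charge(e) eps(kcal/mol) rmin(nm; self-pair minimum)
# "*" is a wildcard.  These are illustrative values for the synthetic
# systems, not a force-field release.
resname name charge eps rmin
MG   MG    2.00 0.0150 0.24
POT  POT   1.00 0.0870 0.35
CAL  CAL   2.00 0.1200 0.27
*    OE1  -0.76 0.1200 0.34
*    OE2  -0.76 0.1200 0.34
*    OD1  -0.76 0.1200 0.34
*    OD2  -0.76 0.1200 0.34
*    OG1  -0.65 0.1521 0.35
HOH  O    -0.83 0.1521 0.35
ALA  O    -0.51 0.1200 0.34
*    CD    0.62 0.0700 0.40
*    CG    0.62 0.0700 0.40
*    CB    0.00 0.0550 0.40
*    C     0.51 0.1100 0.40
*    CA    0.07 0.0200 0.45
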