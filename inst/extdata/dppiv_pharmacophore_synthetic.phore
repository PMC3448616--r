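# Synthetic stand-in for the common structure-based DPP-IV pharmacophore.
# The published model's feature coordinates are not public; this file
# reproduces its topology (2 mandatory sites: one positive/donor anchored
# at the Glu205/Glu206 dyad region and one hydrophobic/aromatic ring for
# the S1 pocket; 5 optional sites: two H-bond acceptors and three
# hydrophobic/aromatic rings) with plausible binding-site-scale geometry
# and receptor-style excluded volumes. Coordinates are synthetic.
FRAME dppiv-3c45-synthetic
FEATURE positive_or_donor       0.000  0.000  0.000  2.000 mandatory
FEATURE hydrophobic_or_aromatic 4.500  0.300 -0.200  2.000 mandatory
FEATURE acceptor                2.100  3.000  0.600  2.000 optional
FEATURE acceptor               -2.400  2.100 -0.500  2.000 optional
FEATURE hydrophobic_or_aromatic 7.400  2.600  0.300  2.000 optional
FEATURE hydrophobic_or_aromatic 2.200 -3.400  1.100  2.000 optional
FEATURE hydrophobic_or_aromatic -1.600 4.400 -1.400  2.000 optional
EXCLUDE  0.200 -3.100 -3.000 1.500
EXCLUDE  5.100  3.600 -3.100 1.500
EXCLUDE -3.600 -2.400  2.100 1.500
EXCLUDE  8.200 -1.500 -2.000 1.500
EXCLUDE -4.800  1.000  2.800 1.500
EXCLUDE  3.000  6.200 -2.500 1.500
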