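# R1 (MTSSL-labelled cysteine) side-chain internal-coordinate template.
# One atom per line:  atom  bond_ref  angle_ref  dihedral_ref  bond(A)  angle(deg)  dihedral
# A dihedral entry chi1..chi5 marks a rotatable torsion; numeric entries are
# frozen (rigid-geometry, flexible-dihedral model).  Backbone N/CA/CB come
# from the labelled residue.  Nitroxide ring C3-C4=C3 double bond between C3
# and C4; ring = C3,C4,C5,N1,C9 (planar, internal angles chosen so the
# implicit C9-C3 closure bond comes out at 1.51 A); gem-methyls C6/C7 on C5,
# methyl C8 on C9; N1-O1 nitroxide.
SG   CB  CA  N    1.810  114.0  chi1
SD   SG  CB  CA   2.030  103.0  chi2
CE   SD  SG  CB   1.810  103.0  chi3
C3   CE  SD  SG   1.510  112.0  chi4
C4   C3  CE  SD   1.330  127.0  chi5
C5   C4  C3  CE   1.510  116.3  180.0
N1   C5  C4  C3   1.480  100.9  0.0
C9   N1  C5  C4   1.480  110.1  0.0
O1   N1  C5  C4   1.270  122.0  180.0
C6   C5  C4  C3   1.530  111.0  120.0
C7   C5  C4  C3   1.530  111.0  -120.0
C8   C9  N1  C5   1.530  110.0  122.0
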