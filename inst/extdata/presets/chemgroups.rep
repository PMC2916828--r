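# Side-chain chemical-group pseudoatoms, matched as independent points.
# Main-chain atoms are never matched; glycine carries a definition for
# completeness but no rule pairs it.
mode independent
def ALA avg(CB):ALIPH
def VAL avg(CB,CG1,CG2):ALIPH
def LEU avg(CG,CD1,CD2):ALIPH
def ILE avg(CG1,CG2,CD1):ALIPH
def PRO avg(CB,CG,CD):ALIPH
def MET avg(SD):THIO
def CYS avg(SG):THIO
def SER avg(OG):HYDROX
def THR avg(OG1):HYDROX
def TYR avg(OH):HYDROX avg(CG,CD1,CD2,CE1,CE2,CZ):RING
def PHE avg(CG,CD1,CD2,CE1,CE2,CZ):RING
def TRP avg(CG,CD1,CD2,NE1,CE2,CE3,CZ2,CZ3,CH2):RING NE1
def HIS avg(CG,ND1,CD2,CE1,NE2):RING ND1 NE2
def ASP avg(OD1,OD2):CARBOX
def GLU avg(OE1,OE2):CARBOX
def ASN avg(OD1,ND2):AMIDE OD1 ND2
def GLN avg(OE1,NE2):AMIDE OE1 NE2
def LYS NZ
def ARG avg(NE,NH1,NH2,CZ):GUAN
def GLY CA
# equivalences between chemical groups
ALA.(ALIPH) VAL.(ALIPH) LEU.(ALIPH) ILE.(ALIPH) PRO.(ALIPH)
MET.(THIO) CYS.(THIO)
SER.(HYDROX) THR.(HYDROX) TYR.(HYDROX)
TYR.(RING) PHE.(RING) TRP.(RING) HIS.(RING)
ASP.(CARBOX) GLU.(CARBOX)
ASN.(AMIDE) GLN.(AMIDE)
HIS.(ND1) HIS.(NE2) ASN.(ND2) GLN.(NE2) TRP.(NE1) LYS.(NZ) ARG.(GUAN)
ASP.(CARBOX) GLU.(CARBOX) ASN.(OD1) GLN.(OE1) SER.(HYDROX) THR.(HYDROX) TYR.(HYDROX) HIS.(ND1) HIS.(NE2)
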