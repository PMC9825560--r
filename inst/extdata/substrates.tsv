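# megasynth substrate table
# role "starter": acyl group as its thioester, written with the literal
#   trailing motif C(=O)S marking the carrier attachment.
# role "extender": alpha-substituent fragment installed by the Claisen
#   extension; exactly one attachment point written as [*].
# role "amino_acid": full residue thioester N...C(=O)S with the alpha-amine
#   first and the acyl carbon last (the two marked reaction sites).
code	smiles	role	display_name
ace	CC(=O)S	starter	acetyl
prop	CCC(=O)S	starter	propionyl
but	CCCC(=O)S	starter	butyryl
ibut	CC(C)C(=O)S	starter	isobutyryl
benz	c1ccccc1C(=O)S	starter	benzoyl
mal	[*][H]	extender	malonyl
mmal	[*]C	extender	methylmalonyl
emal	[*]CC	extender	ethylmalonyl
mxmal	[*]OC	extender	methoxymalonyl
ala	N[C@@H](C)C(=O)S	amino_acid	L-alanine
arg	N[C@@H](CCCNC(=N)N)C(=O)S	amino_acid	L-arginine
asn	N[C@@H](CC(N)=O)C(=O)S	amino_acid	L-asparagine
asp	N[C@@H](CC(=O)O)C(=O)S	amino_acid	L-aspartate
cys	N[C@@H](CS)C(=O)S	amino_acid	L-cysteine
gln	N[C@@H](CCC(N)=O)C(=O)S	amino_acid	L-glutamine
glu	N[C@@H](CCC(=O)O)C(=O)S	amino_acid	L-glutamate
gly	NCC(=O)S	amino_acid	glycine
his	N[C@@H](Cc1c[nH]cn1)C(=O)S	amino_acid	L-histidine
ile	N[C@@H]([C@@H](C)CC)C(=O)S	amino_acid	L-isoleucine
leu	N[C@@H](CC(C)C)C(=O)S	amino_acid	L-leucine
lys	N[C@@H](CCCCN)C(=O)S	amino_acid	L-lysine
met	N[C@@H](CCSC)C(=O)S	amino_acid	L-methionine
phe	N[C@@H](Cc1ccccc1)C(=O)S	amino_acid	L-phenylalanine
pro	N1CCC[C@H]1C(=O)S	amino_acid	L-proline
ser	N[C@@H](CO)C(=O)S	amino_acid	L-serine
thr	N[C@@H]([C@H](O)C)C(=O)S	amino_acid	L-threonine
trp	N[C@@H](Cc1c[nH]c2ccccc12)C(=O)S	amino_acid	L-tryptophan
tyr	N[C@@H](Cc1ccc(O)cc1)C(=O)S	amino_acid	L-tyrosine
val	N[C@@H](C(C)C)C(=O)S	amino_acid	L-valine
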