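# Default pharmacophore typing rules (atomic mask).
# One rule per line: pattern<TAB>channel<TAB>+|-
# Later rules override earlier ones. Pattern syntax:
#   elements[;cond&cond...]   with conditions
#   h>=N / h=N   attached hydrogen count
#   q<=N / q=N   formal charge
#   nbr:LIST     every bonded neighbour's element is in LIST
#   adj=A=B      bonded to an A atom that has a double bond to a B atom
#   X            expands to the halogens F,Cl,Br,I
N,O;h>=1	donor	+
S;h>=1	donor	+
N,O;q<=0	acceptor	+
F	acceptor	+
N;adj=C=O	acceptor	-
C,S;nbr:C,S,X	hydrophobic	+
X	hydrophobic	+
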