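# BLOSUM62 log-odds with the query-side background replaced by
# NNK phage-display codon frequencies (f_aa = codons/32).
# Rows: query (mimotope) amino acid.  Columns: antigen residue.
# Regenerate with mimomap::derive_nnk_matrix() + write_score_matrix().
    A   R   N   D   C   Q   E   G   H   I   L   K   M   F   P   S   T   W   Y   V
A   4  -1  -2  -2   0  -1  -1   0  -2  -1  -1  -1  -1  -2  -1   1   0  -3  -2   0
R  -3   3  -2  -4  -5  -1  -2  -4  -2  -5  -4   0  -3  -5  -4  -3  -3  -5  -4  -5
N  -1   1   7   2  -2   1   1   1   2  -2  -2   1  -1  -2  -1   2   1  -3  -1  -2
D   0   0   3   8  -1   2   4   1   1  -1  -2   1  -1  -1   1   2   1  -2  -1  -1
C  -1  -4  -4  -4   8  -4  -5  -4  -4  -2  -2  -4  -2  -3  -4  -2  -2  -3  -3  -2
Q  -1   1   0   0  -3   5   2  -2   0  -3  -2   1   0  -3  -1   0  -1  -2  -1  -2
E   1   2   2   4  -2   4   7   0   2  -1  -1   3   0  -1   1   2   1  -1   0   0
G   0  -2   0  -1  -3  -2  -2   6  -2  -4  -4  -2  -3  -3  -2   0  -2  -2  -3  -3
H  -3  -1   0  -2  -4  -1  -1  -3   7  -4  -4  -2  -3  -2  -3  -2  -3  -3   1  -4
I   1  -1  -1  -1   1  -1  -1  -2  -1   6   4  -1   3   2  -1   0   1  -1   1   5
L  -1  -2  -3  -4  -1  -2  -3  -4  -3   2   4  -2   2   0  -3  -2  -1  -2  -1   1
K   1   4   2   1  -1   3   3   0   1  -1   0   7   1  -1   1   2   1  -1   0   0
M  -2  -2  -3  -4  -2  -1  -3  -4  -3   0   1  -2   4  -1  -3  -2  -2  -2  -2   0
F  -1  -2  -2  -2  -1  -2  -2  -2   0   1   1  -2   1   7  -3  -1  -1   2   4   0
P  -2  -3  -3  -2  -4  -2  -2  -3  -3  -4  -4  -2  -3  -5   6  -2  -2  -5  -4  -3
S   0  -2   0  -1  -2  -1  -1  -1  -2  -3  -3  -1  -2  -3  -2   3   0  -4  -3  -3
T  -1  -2  -1  -2  -2  -2  -2  -3  -3  -2  -2  -2  -2  -3  -2   0   4  -3  -3  -1
W  -5  -5  -6  -6  -4  -4  -5  -4  -4  -5  -4  -5  -3  -1  -6  -5  -4   9   0  -5
Y  -2  -2  -2  -3  -2  -1  -2  -3   2  -1  -1  -2  -1   3  -3  -2  -2   2   7  -1
V   0  -3  -3  -3  -1  -2  -2  -3  -3   3   1  -2   1  -1  -2  -2   0  -3  -1   4
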