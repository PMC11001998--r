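REMARK synthetic all-atom toy structure (not a real protein)
ATOM      1  N   MET A   1      -0.399   2.265   1.500  1.00  0.00           N
ATOM      2  CA  MET A   1      -0.164   2.577   1.955  1.00  0.00           C
ATOM      3  C   MET A   1      -0.145   1.094   1.562  1.00  0.00           C
ATOM      4  O   MET A   1       0.934   1.954   2.668  1.00  0.00           O
ATOM      5  CB  MET A   1       0.458   1.555   0.215  1.00  0.00           C
ATOM      6  CG  MET A   1       0.919   2.227   3.261  1.00  0.00           C
ATOM      7  SD  MET A   1      -1.679   2.634   3.849  1.00  0.00           S
ATOM      8  CE  MET A   1      -0.795   4.035  -1.136  1.00  0.00           C
ATOM      9  N   PHE A   2      -2.161  -0.787   3.000  1.00  0.00           N
ATOM     10  CA  PHE A   2      -2.045  -0.649   3.572  1.00  0.00           C
ATOM     11  C   PHE A   2      -3.207  -0.916   3.573  1.00  0.00           C
ATOM     12  O   PHE A   2      -3.836  -0.690   3.652  1.00  0.00           O
ATOM     13  CB  PHE A   2      -0.876  -0.155   2.084  1.00  0.00           C
ATOM     14  CG  PHE A   2      -0.348  -0.782   4.246  1.00  0.00           C
ATOM     15  CD1 PHE A   2      -4.057  -1.213   4.875  1.00  0.00           C
ATOM     16  CD2 PHE A   2      -3.873  -2.992   4.563  1.00  0.00           C
ATOM     17  CE1 PHE A   2      -2.650  -1.254  -0.638  1.00  0.00           C
ATOM     18  CE2 PHE A   2      -3.508   0.802  -0.647  1.00  0.00           C
ATOM     19  CZ  PHE A   2       0.519  -3.664   0.426  1.00  0.00           C
ATOM     20  N   GLY A   3       1.150  -1.992   4.500  1.00  0.00           N
ATOM     21  CA  GLY A   3       1.644  -2.305   4.367  1.00  0.00           C
ATOM     22  C   GLY A   3       0.027  -1.984   4.077  1.00  0.00           C
ATOM     23  O   GLY A   3       2.696  -2.628   5.168  1.00  0.00           O
ATOM     24  N   SER A   4       1.762   1.478   6.000  1.00  0.00           N
ATOM     25  CA  SER A   4       1.193   1.404   5.825  1.00  0.00           C
ATOM     26  C   SER A   4       0.691   1.641   5.483  1.00  0.00           C
ATOM     27  O   SER A   4       2.114  -0.285   5.927  1.00  0.00           O
ATOM     28  CB  SER A   4       2.195   2.940   6.753  1.00  0.00           C
ATOM     29  OG  SER A   4       1.066   3.535   6.357  1.00  0.00           O
ATOM     30  N   LYS A   5      -1.762   1.478   7.500  1.00  0.00           N
ATOM     31  CA  LYS A   5      -1.764   2.053   7.672  1.00  0.00           C
ATOM     32  C   LYS A   5      -2.518   2.325   7.890  1.00  0.00           C
ATOM     33  O   LYS A   5      -0.414   1.352   6.314  1.00  0.00           O
ATOM     34  CB  LYS A   5      -0.537   0.531   8.201  1.00  0.00           C
ATOM     35  CG  LYS A   5      -1.821  -0.528   8.400  1.00  0.00           C
ATOM     36  CD  LYS A   5      -4.458   1.580   7.598  1.00  0.00           C
ATOM     37  CE  LYS A   5      -4.235   0.340   5.818  1.00  0.00           C
ATOM     38  NZ  LYS A   5      -1.238  -1.898   6.081  1.00  0.00           N
ATOM     39  N   TRP A   6      -1.150  -1.992   9.000  1.00  0.00           N
ATOM     40  CA  TRP A   6      -1.145  -1.601   9.455  1.00  0.00           C
ATOM     41  C   TRP A   6      -1.760  -3.025   8.973  1.00  0.00           C
ATOM     42  O   TRP A   6       0.273  -2.164   7.911  1.00  0.00           O
ATOM     43  CB  TRP A   6      -1.318  -3.627   9.432  1.00  0.00           C
ATOM     44  CG  TRP A   6       0.058  -2.679   7.295  1.00  0.00           C
ATOM     45  CD1 TRP A   6       0.747  -2.204   7.091  1.00  0.00           C
ATOM     46  CD2 TRP A   6       1.701  -1.108  10.153  1.00  0.00           C
ATOM     47  NE1 TRP A   6      -3.869  -0.297  10.850  1.00  0.00           N
ATOM     48  CE2 TRP A   6       2.988  -1.275   9.030  1.00  0.00           C
ATOM     49  CE3 TRP A   6      -4.623   1.117   9.602  1.00  0.00           C
ATOM     50  CZ2 TRP A   6      -0.644  -7.006  10.282  1.00  0.00           C
ATOM     51  CZ3 TRP A   6       2.457  -4.213  12.814  1.00  0.00           C
ATOM     52  CH2 TRP A   6       0.161  -6.363  13.197  1.00  0.00           C
END
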