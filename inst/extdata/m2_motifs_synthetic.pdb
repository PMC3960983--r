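REMARK   1 SYNTHETIC COORDINATES - NOT AN EXPERIMENTAL STRUCTURE
REMARK   1 FIVE KEY M2 RECEPTOR RESIDUES BUILT FROM IDEAL RESIDUE GEOMETRY
REMARK   1 AND PLACED TO REPRODUCE PUBLISHED INTER-RESIDUE GEOMETRY:
REMARK   1 TYR206 OH - TYR440 OH = 12.60 A, ARG121 CZ - GLU382 CD = 4.60 A,
REMARK   1 TRP400 CHI1 = -75 DEG, CHI2 = 40 DEG (INACTIVE TOGGLE SWITCH)
ATOM      1  N   ARG A 121       9.999  10.692   7.787  1.00  0.00           N  
ATOM      2  CA  ARG A 121       8.938  10.001   7.056  1.00  0.00           C  
ATOM      3  C   ARG A 121       9.453   8.628   6.663  1.00  0.00           C  
ATOM      4  O   ARG A 121      10.587   8.211   6.859  1.00  0.00           O  
ATOM      5  CB  ARG A 121       8.473  10.811   5.837  1.00  0.00           C  
ATOM      6  CG  ARG A 121       9.549  11.018   4.759  1.00  0.00           C  
ATOM      7  CD  ARG A 121       9.018  11.778   3.545  1.00  0.00           C  
ATOM      8  NE  ARG A 121       8.541  13.087   3.922  1.00  0.00           N  
ATOM      9  CZ  ARG A 121       8.000  14.000   3.000  1.00  0.00           C  
ATOM     10  NH1 ARG A 121       7.552  15.251   3.409  1.00  0.00           N  
ATOM     11  NH2 ARG A 121       7.908  13.653   1.656  1.00  0.00           N1+
ATOM     12  N   TYR A 206       4.639  -0.278   4.042  1.00  0.00           N  
ATOM     13  CA  TYR A 206       5.580  -0.026   2.943  1.00  0.00           C  
ATOM     14  C   TYR A 206       6.941   0.285   3.509  1.00  0.00           C  
ATOM     15  O   TYR A 206       7.040   0.818   4.587  1.00  0.00           O  
ATOM     16  CB  TYR A 206       5.088   1.161   2.114  1.00  0.00           C  
ATOM     17  CG  TYR A 206       3.727   0.850   1.549  1.00  0.00           C  
ATOM     18  CD1 TYR A 206       2.591   1.177   2.265  1.00  0.00           C  
ATOM     19  CD2 TYR A 206       3.616   0.243   0.311  1.00  0.00           C  
ATOM     20  CE1 TYR A 206       1.342   0.893   1.749  1.00  0.00           C  
ATOM     21  CE2 TYR A 206       2.369  -0.047  -0.207  1.00  0.00           C  
ATOM     22  CZ  TYR A 206       1.227   0.280   0.510  1.00  0.00           C  
ATOM     23  OH  TYR A 206       0.000   0.000   0.000  1.00  0.00           O  
ATOM     24  N   GLU A 382       3.235  14.675   8.767  1.00  0.00           N  
ATOM     25  CA  GLU A 382       3.471  15.709   7.751  1.00  0.00           C  
ATOM     26  C   GLU A 382       2.605  16.908   8.043  1.00  0.00           C  
ATOM     27  O   GLU A 382       1.630  16.791   8.747  1.00  0.00           O  
ATOM     28  CB  GLU A 382       3.122  15.154   6.368  1.00  0.00           C  
ATOM     29  CG  GLU A 382       4.085  14.016   6.019  1.00  0.00           C  
ATOM     30  CD  GLU A 382       3.742  13.469   4.657  1.00  0.00           C  
ATOM     31  OE1 GLU A 382       2.822  13.940   4.030  1.00  0.00           O  
ATOM     32  OE2 GLU A 382       4.457  12.457   4.140  1.00  0.00           O  
ATOM     33  N   TRP A 400      -9.565   7.277  10.456  1.00  0.00           N  
ATOM     34  CA  TRP A 400      -9.000   6.000  10.000  1.00  0.00           C  
ATOM     35  C   TRP A 400      -7.651   5.792  10.640  1.00  0.00           C  
ATOM     36  O   TRP A 400      -6.966   6.744  10.929  1.00  0.00           O  
ATOM     37  CB  TRP A 400      -8.844   6.024   8.480  1.00  0.00           C  
ATOM     38  CG  TRP A 400     -10.196   5.862   7.834  1.00  0.00           C  
ATOM     39  CD1 TRP A 400     -11.348   6.419   8.242  1.00  0.00           C  
ATOM     40  CD2 TRP A 400     -10.502   5.073   6.640  1.00  0.00           C  
ATOM     41  NE1 TRP A 400     -12.367   6.046   7.409  1.00  0.00           N  
ATOM     42  CE2 TRP A 400     -11.884   5.221   6.419  1.00  0.00           C  
ATOM     43  CE3 TRP A 400      -9.743   4.274   5.784  1.00  0.00           C  
ATOM     44  CZ2 TRP A 400     -12.474   4.573   5.340  1.00  0.00           C  
ATOM     45  CZ3 TRP A 400     -10.343   3.647   4.729  1.00  0.00           C  
ATOM     46  CH2 TRP A 400     -11.705   3.793   4.504  1.00  0.00           C  
ATOM     47  N   TYR A 440      12.115 -11.499   3.998  1.00  0.00           N  
ATOM     48  CA  TYR A 440      12.910 -10.460   4.666  1.00  0.00           C  
ATOM     49  C   TYR A 440      13.386 -10.972   6.001  1.00  0.00           C  
ATOM     50  O   TYR A 440      12.726 -11.779   6.609  1.00  0.00           O  
ATOM     51  CB  TYR A 440      12.048  -9.214   4.875  1.00  0.00           C  
ATOM     52  CG  TYR A 440      11.573  -8.702   3.541  1.00  0.00           C  
ATOM     53  CD1 TYR A 440      10.379  -9.157   3.013  1.00  0.00           C  
ATOM     54  CD2 TYR A 440      12.328  -7.774   2.849  1.00  0.00           C  
ATOM     55  CE1 TYR A 440       9.940  -8.690   1.790  1.00  0.00           C  
ATOM     56  CE2 TYR A 440      11.896  -7.307   1.623  1.00  0.00           C  
ATOM     57  CZ  TYR A 440      10.698  -7.762   1.091  1.00  0.00           C  
ATOM     58  OH  TYR A 440      10.269  -7.300  -0.112  1.00  0.00           O  
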