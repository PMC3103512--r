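AC  M90001
XX
ID  V$AP1SYN_B
XX
NA  AP1syn
XX
BF  T00001 AP1syn; Species: human, Homo sapiens.
XX
P0      A      C      G      T
01      10      2      2      2
02       2     12      1      1
03       1      1     13      1
04       2      2      2     10
05      12      2      1      1
XX
CC  quality: B
XX
//
AC  M90002
XX
ID  V$AP1SYN_A
XX
NA  AP1syn
XX
BF  T00001 AP1syn; Species: mouse, Mus musculus.
XX
P0      A      C      G      T
01      11      1      2      2
02       1     13      1      1
03       1      1     12      2
04       2      2      1     11
05      13      1      1      1
XX
CC  quality: A
XX
//
AC  M90003
XX
ID  I$EVESYN_01
XX
NA  evesyn
XX
BF  T00101 evesyn; Species: fruit fly, Drosophila melanogaster.
XX
P0      A      C      G      T
01      12      2      1      1
02       1      1      1     13
03       2     12      1      1
04      13      1      1      1
05       1      1     13      1
XX
CC  quality: B
XX
//
AC  M90004
XX
ID  I$BCDSYN_01
XX
NA  bcdsyn
XX
BF  T00102 bcdsyn; Species: fruit fly, Drosophila melanogaster.
XX
P0      A      C      G      T
01       1      1     13      1
02       1     12      2      1
03      13      1      1      1
04       1      1      1     13
05       2      2     11      1
XX
CC  quality: C
XX
//
AC  M90005
XX
ID  V$MULTISYN_01
XX
NA  multisyn
XX
BF  T00201 facA; Species: human, Homo sapiens.
BF  T00202 facB; Species: human, Homo sapiens.
BF  T00203 facC; Species: human, Homo sapiens.
XX
P0      A      C      G      T
01      10      2      2      2
02       2     10      2      2
03       2      2     10      2
04       2      2      2     10
05      10      2      2      2
XX
CC  quality: B
XX
//
AC  M90006
XX
ID  V$ZEROSYN_01
XX
NA  zerosyn
XX
BF  T00301 zerosyn; Species: human, Homo sapiens.
XX
P0      A      C      G      T
01      10      2      2      2
02       0      0      0      0
03       2      2     10      2
04       2      2      2     10
05      10      2      2      2
XX
CC  quality: A
XX
//
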