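# pepdmd square-well parameter table
# Approximate default set: hydrophobics mutually attractive, K/R-D/E
# salt bridges, like charges hard-sphere only; widths = contact + 1.60 A.
VERSION 1
HB 5.0000 1.0000 2.6000 4.6000
GEOM BEAD NH 3.3000
GEOM BEAD CA 3.7000
GEOM BEAD CO 3.5000
GEOM SC A 3.4000 1.6000
GEOM SC S 3.6000 1.7000
GEOM SC C 3.7000 1.8000
GEOM SC T 3.8000 1.9000
GEOM SC P 3.9000 1.9000
GEOM SC V 4.0000 2.0000
GEOM SC N 4.0000 2.1000
GEOM SC D 4.0000 2.1000
GEOM SC L 4.3000 2.4000
GEOM SC I 4.3000 2.4000
GEOM SC Q 4.2000 2.4000
GEOM SC E 4.0000 2.5000
GEOM SC M 4.3000 2.6000
GEOM SC K 4.4000 2.9000
GEOM SC H 4.3000 2.5000
GEOM SC F 4.4000 2.5000
GEOM SC R 4.6000 3.1000
GEOM SC Y 4.5000 2.8000
GEOM SC W 4.7000 2.9000
GEOM BOND N_CA 1.2500
GEOM BOND CA_C 1.2500
GEOM BOND C_N 1.3000
GEOM BOND CA_CA 3.8000
GEOM TOL 0.0200
PAIR G G 0.000000 0.000000
PAIR G A 0.000000 0.000000
PAIR G S 0.000000 0.000000
PAIR G P 0.000000 0.000000
PAIR G V 0.000000 0.000000
PAIR G T 0.000000 0.000000
PAIR G C 0.000000 0.000000
PAIR G L 0.000000 0.000000
PAIR G I 0.000000 0.000000
PAIR G N 0.000000 0.000000
PAIR G D 0.000000 0.000000
PAIR G Q 0.000000 0.000000
PAIR G K 0.000000 0.000000
PAIR G E 0.000000 0.000000
PAIR G M 0.000000 0.000000
PAIR G H 0.000000 0.000000
PAIR G F 0.000000 0.000000
PAIR G R 0.000000 0.000000
PAIR G Y 0.000000 0.000000
PAIR G W 0.000000 0.000000
PAIR A A 5.000000 0.105000
PAIR A S 5.100000 0.000000
PAIR A P 5.250000 0.097211
PAIR A V 5.300000 0.131624
PAIR A T 5.200000 0.000000
PAIR A C 5.150000 0.000000
PAIR A L 5.450000 0.143091
PAIR A I 5.450000 0.143091
PAIR A N 5.300000 0.000000
PAIR A D 5.300000 0.000000
PAIR A Q 5.400000 0.000000
PAIR A K 5.500000 0.000000
PAIR A E 5.300000 0.000000
PAIR A M 5.450000 0.137477
PAIR A H 5.450000 0.000000
PAIR A F 5.500000 0.177482
PAIR A R 5.600000 0.000000
PAIR A Y 5.550000 0.148492
PAIR A W 5.650000 0.177482
PAIR S S 5.200000 0.000000
PAIR S P 5.350000 0.000000
PAIR S V 5.400000 0.000000
PAIR S T 5.300000 0.000000
PAIR S C 5.250000 0.000000
PAIR S L 5.550000 0.000000
PAIR S I 5.550000 0.000000
PAIR S N 5.400000 0.000000
PAIR S D 5.400000 0.000000
PAIR S Q 5.500000 0.000000
PAIR S K 5.600000 0.000000
PAIR S E 5.400000 0.000000
PAIR S M 5.550000 0.000000
PAIR S H 5.550000 0.000000
PAIR S F 5.600000 0.000000
PAIR S R 5.700000 0.000000
PAIR S Y 5.650000 0.000000
PAIR S W 5.750000 0.000000
PAIR P P 5.500000 0.090000
PAIR P V 5.550000 0.121861
PAIR P T 5.450000 0.000000
PAIR P C 5.400000 0.000000
PAIR P L 5.700000 0.132476
PAIR P I 5.700000 0.132476
PAIR P N 5.550000 0.000000
PAIR P D 5.550000 0.000000
PAIR P Q 5.650000 0.000000
PAIR P K 5.750000 0.000000
PAIR P E 5.550000 0.000000
PAIR P M 5.700000 0.127279
PAIR P H 5.700000 0.000000
PAIR P F 5.750000 0.164317
PAIR P R 5.850000 0.000000
PAIR P Y 5.800000 0.137477
PAIR P W 5.900000 0.164317
PAIR V V 5.600000 0.165000
PAIR V T 5.500000 0.000000
PAIR V C 5.450000 0.000000
PAIR V L 5.750000 0.179374
PAIR V I 5.750000 0.179374
PAIR V N 5.600000 0.000000
PAIR V D 5.600000 0.000000
PAIR V Q 5.700000 0.000000
PAIR V K 5.800000 0.000000
PAIR V E 5.600000 0.000000
PAIR V M 5.750000 0.172337
PAIR V H 5.750000 0.000000
PAIR V F 5.800000 0.222486
PAIR V R 5.900000 0.000000
PAIR V Y 5.850000 0.186145
PAIR V W 5.950000 0.222486
PAIR T T 5.400000 0.000000
PAIR T C 5.350000 0.000000
PAIR T L 5.650000 0.000000
PAIR T I 5.650000 0.000000
PAIR T N 5.500000 0.000000
PAIR T D 5.500000 0.000000
PAIR T Q 5.600000 0.000000
PAIR T K 5.700000 0.000000
PAIR T E 5.500000 0.000000
PAIR T M 5.650000 0.000000
PAIR T H 5.650000 0.000000
PAIR T F 5.700000 0.000000
PAIR T R 5.800000 0.000000
PAIR T Y 5.750000 0.000000
PAIR T W 5.850000 0.000000
PAIR C C 5.300000 0.000000
PAIR C L 5.600000 0.000000
PAIR C I 5.600000 0.000000
PAIR C N 5.450000 0.000000
PAIR C D 5.450000 0.000000
PAIR C Q 5.550000 0.000000
PAIR C K 5.650000 0.000000
PAIR C E 5.450000 0.000000
PAIR C M 5.600000 0.000000
PAIR C H 5.600000 0.000000
PAIR C F 5.650000 0.000000
PAIR C R 5.750000 0.000000
PAIR C Y 5.700000 0.000000
PAIR C W 5.800000 0.000000
PAIR L L 5.900000 0.195000
PAIR L I 5.900000 0.195000
PAIR L N 5.750000 0.000000
PAIR L D 5.750000 0.000000
PAIR L Q 5.850000 0.000000
PAIR L K 5.950000 0.000000
PAIR L E 5.750000 0.000000
PAIR L M 5.900000 0.187350
PAIR L H 5.900000 0.000000
PAIR L F 5.950000 0.241868
PAIR L R 6.050000 0.000000
PAIR L Y 6.000000 0.202361
PAIR L W 6.100000 0.241868
PAIR I I 5.900000 0.195000
PAIR I N 5.750000 0.000000
PAIR I D 5.750000 0.000000
PAIR I Q 5.850000 0.000000
PAIR I K 5.950000 0.000000
PAIR I E 5.750000 0.000000
PAIR I M 5.900000 0.187350
PAIR I H 5.900000 0.000000
PAIR I F 5.950000 0.241868
PAIR I R 6.050000 0.000000
PAIR I Y 6.000000 0.202361
PAIR I W 6.100000 0.241868
PAIR N N 5.600000 0.000000
PAIR N D 5.600000 0.000000
PAIR N Q 5.700000 0.000000
PAIR N K 5.800000 0.000000
PAIR N E 5.600000 0.000000
PAIR N M 5.750000 0.000000
PAIR N H 5.750000 0.000000
PAIR N F 5.800000 0.000000
PAIR N R 5.900000 0.000000
PAIR N Y 5.850000 0.000000
PAIR N W 5.950000 0.000000
PAIR D D 5.600000 0.000000
PAIR D Q 5.700000 0.000000
PAIR D K 5.800000 0.300000
PAIR D E 5.600000 0.000000
PAIR D M 5.750000 0.000000
PAIR D H 5.750000 0.000000
PAIR D F 5.800000 0.000000
PAIR D R 5.900000 0.300000
PAIR D Y 5.850000 0.000000
PAIR D W 5.950000 0.000000
PAIR Q Q 5.800000 0.000000
PAIR Q K 5.900000 0.000000
PAIR Q E 5.700000 0.000000
PAIR Q M 5.850000 0.000000
PAIR Q H 5.850000 0.000000
PAIR Q F 5.900000 0.000000
PAIR Q R 6.000000 0.000000
PAIR Q Y 5.950000 0.000000
PAIR Q W 6.050000 0.000000
PAIR K K 6.000000 0.000000
PAIR K E 5.800000 0.300000
PAIR K M 5.950000 0.000000
PAIR K H 5.950000 0.000000
PAIR K F 6.000000 0.000000
PAIR K R 6.100000 0.000000
PAIR K Y 6.050000 0.000000
PAIR K W 6.150000 0.000000
PAIR E E 5.600000 0.000000
PAIR E M 5.750000 0.000000
PAIR E H 5.750000 0.000000
PAIR E F 5.800000 0.000000
PAIR E R 5.900000 0.300000
PAIR E Y 5.850000 0.000000
PAIR E W 5.950000 0.000000
PAIR M M 5.900000 0.180000
PAIR M H 5.900000 0.000000
PAIR M F 5.950000 0.232379
PAIR M R 6.050000 0.000000
PAIR M Y 6.000000 0.194422
PAIR M W 6.100000 0.232379
PAIR H H 5.900000 0.000000
PAIR H F 5.950000 0.000000
PAIR H R 6.050000 0.000000
PAIR H Y 6.000000 0.000000
PAIR H W 6.100000 0.000000
PAIR F F 6.000000 0.300000
PAIR F R 6.100000 0.000000
PAIR F Y 6.050000 0.250998
PAIR F W 6.150000 0.300000
PAIR R R 6.200000 0.000000
PAIR R Y 6.150000 0.000000
PAIR R W 6.250000 0.000000
PAIR Y Y 6.100000 0.210000
PAIR Y W 6.200000 0.250998
PAIR W W 6.300000 0.300000
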