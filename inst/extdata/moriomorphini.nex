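#NEXUS
[Morphological character matrix for the cladistic analysis of Moriomorphini:
 21 ingroup taxa plus the Trechus obtusus outgroup, 75 discrete characters.
 '?' = state unknown (e.g. sex-limited characters lacking specimens);
 '-' = character inapplicable; both are scored as missing.
 Parenthesized cells are polymorphic terminals.]

BEGIN DATA;
  DIMENSIONS NTAX=22 NCHAR=75;
  FORMAT SYMBOLS="0~4" MISSING=? GAP=-;
  MATRIX
  'Trechus obtusus'             1000100000000000001000101000000102020000000000(01)0002000100110000000000001200
  'Meonochilus amplipennis'     000020111001030111311011120100100002011101012012000010011221130214000112120
  'Meonochilus eplicatus'       000020111001020111311011120100101100011101012(01)11000010011221130213000112120
  'Meonochilus placens'         000020111001010111311011120100101100011101012111000010011221130203000112120
  'Meonochilus bellorum'        000020111001020111311001010100100100011100112110000010011231110211011112120
  'Meonochilus rectus'          000020111001020111311001120100100100011101012110000010011221111213000112120
  'Meonochilus spiculatus'      000020111001020011311001120100100100011101012110000010011221111213000112120
  'Raphetis darlingtoni'        210020111000030001310000200101102211111111110012000010011221100211012112120
  'Selenochilus piceus'         211111110010021103300100210100222111111111013011002011001231100201211110101
  'Meonis semistriatus'         221111110010042102200100102100222212112111112011000011001221100111011110011
  'Meonis uncinatus'            221121110010042102200100202000212212112111111010000011001221100411123110011
  'Mecyclothorax lophoides'     010010212000010001300001120100000110012100110110000010010431110311123122220
  'Mecyclothorax montivagus'    000010212000010001200001110102000100011100112010000010010431120004023112220
  'Mecyclothorax punctipennis'  000010212000010001300021111102000100011100112100000010010431120004023112220
  'Neonomius laevicollis'       000110111000010103300021010110101100111100110110000011101001200201213111020
  'Tropopterus duponcheli'      1200(12)02120000220012000000111012023-1011111110010000011011221130201013112020
  'Amblytelus curtus'           100110212000020003300020000101000000212100114000001011211331100112023112220
  'Molopsida pretiosa'          100010212000031101310001120101102001212100111110000010012002210211111111020
  'Theprisa australis'          100010211000030101100011022100102001211111110011000010012002200211111111020
  'Moriomorpha sp Dunoon NSW'   2200102111001102023000000021100020012121101110001101100?20022003???????????
  'Moriomorpha sp Sherbrook V'  220020211100110202300000002110002001212100111000110110002???????01121111020
  'Rossjoycea glacialis'        1000002120000201020000001221001020012111001130110000??212???????11111111020
  ;
END;

BEGIN ASSUMPTIONS;
  TYPESET * default = ord: 1 2 4 5 7 9 15 16 18 19 23 25 26 27 30 31 32 33 34 36 37 45 48 58 59 60 61 68 71 72, unord: 14 39 51 55 57 62 64 66 67 69 73 74;
END;
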