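#NEXUS
BEGIN DATA;
  DIMENSIONS NTAX=7 NCHAR=32;
  FORMAT DATATYPE=STANDARD SYMBOLS="01" MISSING=? GAP=-;
  CHARSTATELABELS
    1 'temporoparietalis present [major/HN/id=14]',
    2 'risorius present [major/HN/id=16]',
    3 'arytenoideus obliquus present [major/HN/id=30]',
    4 'intermediate tendon of omohyoideus present [minor/HN/id=66]',
    5 'rhomboideus minor present [major/FL/id=71]',
    6 'levator claviculae absent [major/FL/id=72]',
    7 'dorsoepitrochlearis absent [major/FL/id=80]',
    8 'pectoralis minor inserts on coracoid process [minor/FL/id=83]',
    9 'flexor pollicis longus present [major/FL/id=101]',
    10 'extensor pollicis brevis present [major/FL/id=106]',
    11 'tendon of long flexor to distal phalanx of digit 1 vestigial [minor/FL/id=112]',
    12 'distinct epitrochleoanconeus absent [major/FL/id=120]',
    13 'contrahentes digitorum to digit 4 absent [major/FL/id=130]',
    14 'contrahentes digitorum to digit 5 absent [major/FL/id=131]',
    15 'adductor pollicis accessorius present [major/FL/id=135]',
    16 'intermetacarpales fused into dorsal interossei [major/FL/id=140]',
    17 'unenumerated HN-FL minor difference (synthetic placeholder) [minor/FL/id=150]',
    18 'psoas minor absent [major/HL/id=167]',
    19 'ischiofemoralis absent [major/HL/id=168]',
    20 'adductor minimus absent [major/HL/id=169]',
    21 'opponens hallucis absent [major/HL/id=170]',
    22 'contrahentes pedis absent [major/HL/id=171]',
    23 'opponens digiti minimi of foot absent [major/HL/id=172]',
    24 'fibularis tertius present [major/HL/id=173]',
    25 'tendons of flexor hallucis longus to digits 3-4 absent [minor/HL/id=174]',
    26 'digit 2 is the interossei axis of the foot [minor/HL/id=175]',
    27 'fibularis longus attaches to medial cuneiform [minor/HL/id=176]',
    28 'soleus attaches to tibia [minor/HL/id=177]',
    29 'flexor digitorum brevis tendon to digit 5 present [minor/HL/id=178]',
    30 'scansorius absent [major/HL/id=179]',
    31 'popliteus-fibula attachment absent [minor/HL/id=180]',
    32 'extensor hallucis longus insertion on proximal big-toe phalanx absent [minor/HL/id=181]'
  ;
  MATRIX
    Outgroup       00000000000000000000000000000000
    Hylobatids     00000000000000000000000000000000
    Pongo          00000001001101010000000000000000
    Gorilla        00000001001101010000000000000000
    P_troglodytes  00010000001000000000000000000111
    P_paniscus     00000001000000010000000000000000
    Homo           11111111110111111111111111111111
  ;
END;
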