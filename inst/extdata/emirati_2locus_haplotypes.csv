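haplotype,frequency,sd
A*02~B*51,0.0750,0.0132
A*26~B*08,0.0525,0.0112
A*33~B*58,0.0250,0.0078
A*03~B*50,0.0250,0.0078
A*11~B*40,0.0250,0.0078
A*32~B*35,0.0225,0.0074
A*24~B*08,0.0200,0.0070
A*33~B*14,0.0200,0.0070
A*01~B*37,0.0150,0.0061
A*03~B*52,0.0150,0.0061
A*03~B*18,0.0100,0.0050
A*11~B*41,0.0100,0.0050
B*35~C*04,0.1175,0.0161
B*50~C*06,0.0800,0.0136
B*51~C*15,0.0700,0.0128
B*51~C*16,0.0525,0.0112
B*14~C*08,0.0450,0.0104
B*58~C*03,0.0450,0.0104
B*40~C*15,0.0400,0.0098
B*52~C*12,0.0325,0.0089
B*51~C*14,0.0300,0.0085
B*37~C*06,0.0200,0.0070
B*73~C*15,0.0175,0.0066
B*49~C*07,0.0175,0.0066
B*18~C*12,0.0175,0.0066
B*07~C*07,0.0150,0.0061
B*41~C*17,0.0150,0.0061
B*53~C*04,0.0150,0.0061
B*57~C*06,0.0125,0.0056
B*38~C*12,0.0125,0.0056
B*42~C*17,0.0125,0.0056
B*15~C*02,0.0100,0.0050
B*45~C*16,0.0100,0.0050
B*08~DRB1*03,0.0975,0.0148
B*50~DRB1*07,0.0475,0.0106
B*52~DRB1*15,0.0300,0.0085
B*40~DRB1*16,0.0275,0.0082
B*58~DRB1*03,0.0250,0.0078
B*14~DRB1*01,0.0150,0.0061
B*14~DRB1*07,0.0150,0.0061
B*18~DRB1*16,0.0150,0.0061
B*37~DRB1*10,0.0125,0.0056
B*41~DRB1*08,0.0100,0.0050
B*53~DRB1*04,0.0100,0.0050
B*49~DRB1*13,0.0100,0.0050
B*15~DRB1*11,0.0100,0.0050
B*42~DRB1*03,0.0100,0.0050
DRB1*03~DQB1*02,0.2125,0.0205
DRB1*16~DQB1*05,0.1725,0.0189
DRB1*07~DQB1*02,0.1100,0.0157
DRB1*04~DQB1*03,0.0875,0.0141
DRB1*15~DQB1*06,0.0850,0.0140
DRB1*11~DQB1*03,0.0650,0.0123
DRB1*13~DQB1*06,0.0475,0.0106
DRB1*01~DQB1*05,0.0450,0.0104
DRB1*10~DQB1*05,0.0375,0.0095
DRB1*14~DQB1*05,0.0225,0.0074
DRB1*08~DQB1*04,0.0125,0.0056
DRB1*04~DQB1*04,0.0100,0.0050
DRB1*12~DQB1*03,0.0100,0.0050
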