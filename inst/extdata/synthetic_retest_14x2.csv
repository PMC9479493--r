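subject,meas_1,meas_2
S1,0.318715216861092,0.315165521814697
S2,0.367910290440331,0.358668012796504
S3,0.379884335746813,0.366745370016224
S4,0.366389974835809,0.358630160517784
S5,0.329819106612389,0.330415468741291
S6,0.358991247577045,0.357516247054738
S7,0.323635125591438,0.330432048540372
S8,0.350585541468568,0.349972175539025
S9,0.323016157003203,0.323651579589506
S10,0.34974631785617,0.349817932411567
S11,0.325179240033322,0.327578321296337
S12,0.33292199007226,0.336051912974523
S13,0.349258246948614,0.341760097687521
S14,0.327523190765774,0.325673459717738
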