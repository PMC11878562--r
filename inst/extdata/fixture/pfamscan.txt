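# pfam_scan.pl synthetic output
synth01_p00001 591 644 589 646 PF90013.1 SynDom_13 Domain 1 54 54 50.0 1e-10 1
synth01_p00001 35 182 33 184 PF90015.1 SynDom_15 Domain 1 148 148 50.0 1e-10 1
synth01_p00001 224 391 222 393 PF90030.1 SynDom_30 Domain 1 168 168 50.0 1e-10 1
synth01_p00003 78 202 76 204 PF90032.1 SynDom_32 Domain 1 125 125 50.0 1e-10 1
synth01_p00003 205 348 203 350 PF90006.1 SynDom_6 Domain 1 144 144 50.0 1e-10 1
synth01_p00003 73 263 71 265 PF90016.1 SynDom_16 Domain 1 191 191 50.0 1e-10 1
synth01_p00005 180 233 178 235 PF90038.1 SynDom_38 Domain 1 54 54 50.0 1e-10 1
synth01_p00005 437 630 435 632 PF90022.1 SynDom_22 Domain 1 194 194 50.0 1e-10 1
synth01_p00005 188 246 186 248 PF90020.1 SynDom_20 Domain 1 59 59 50.0 1e-10 1
synth01_p00011 280 393 278 395 PF90035.1 SynDom_35 Domain 1 114 114 50.0 1e-10 1
synth01_p00013 66 258 64 260 PF90005.1 SynDom_5 Domain 1 193 193 50.0 1e-10 1
synth01_p00013 90 272 88 274 PF90002.1 SynDom_2 Domain 1 183 183 50.0 1e-10 1
synth01_p00014 2 136 1 138 PF90002.1 SynDom_2 Domain 1 135 135 50.0 1e-10 1
synth01_p00014 20 113 18 115 PF90027.1 SynDom_27 Domain 1 94 94 50.0 1e-10 1
synth01_p00015 59 192 57 194 PF90013.1 SynDom_13 Domain 1 134 134 50.0 1e-10 1
synth01_p00015 134 197 132 199 PF90010.1 SynDom_10 Domain 1 64 64 50.0 1e-10 1
synth01_p00015 1 109 1 111 PF90025.1 SynDom_25 Domain 1 109 109 50.0 1e-10 1
synth01_p00018 161 276 159 278 PF90036.1 SynDom_36 Domain 1 116 116 50.0 1e-10 1
synth01_p00018 104 297 102 299 PF90007.1 SynDom_7 Domain 1 194 194 50.0 1e-10 1
synth01_p00019 128 254 126 256 PF90017.1 SynDom_17 Domain 1 127 127 50.0 1e-10 1
synth01_p00019 96 196 94 198 PF90009.1 SynDom_9 Domain 1 101 101 50.0 1e-10 1
synth01_p00020 143 338 141 340 PF90020.1 SynDom_20 Domain 1 196 196 50.0 1e-10 1
synth01_p00020 432 590 430 592 PF90016.1 SynDom_16 Domain 1 159 159 50.0 1e-10 1
synth01_p00020 386 577 384 579 PF90014.1 SynDom_14 Domain 1 192 192 50.0 1e-10 1
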