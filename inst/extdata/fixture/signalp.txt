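# SignalP-5.0 synthetic output
synth01_p00001	OTHER	0.020	0.980	CS pos: 20-21
synth01_p00002	OTHER	0.020	0.980	CS pos: 20-21
synth01_p00003	SP(Sec/SPI)	0.980	0.020	CS pos: 20-21
synth01_p00004	OTHER	0.020	0.980	CS pos: 20-21
synth01_p00005	OTHER	0.020	0.980	CS pos: 20-21
synth01_p00006	OTHER	0.020	0.980	CS pos: 20-21
synth01_p00007	OTHER	0.020	0.980	CS pos: 20-21
synth01_p00008	OTHER	0.020	0.980	CS pos: 20-21
synth01_p00009	OTHER	0.020	0.980	CS pos: 20-21
synth01_p00010	OTHER	0.020	0.980	CS pos: 20-21
synth01_p00011	OTHER	0.020	0.980	CS pos: 20-21
synth01_p00012	OTHER	0.020	0.980	CS pos: 20-21
synth01_p00013	OTHER	0.020	0.980	CS pos: 20-21
synth01_p00014	OTHER	0.020	0.980	CS pos: 20-21
synth01_p00015	OTHER	0.020	0.980	CS pos: 20-21
synth01_p00016	OTHER	0.020	0.980	CS pos: 20-21
synth01_p00017	OTHER	0.020	0.980	CS pos: 20-21
synth01_p00018	OTHER	0.020	0.980	CS pos: 20-21
synth01_p00019	OTHER	0.020	0.980	CS pos: 20-21
synth01_p00020	OTHER	0.020	0.980	CS pos: 20-21
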