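proteome_id	protein_id	start	end	type	residue
synth01	synth01_p00001	22	42	complex	NA
synth01	synth01_p00002	32	55	complex	NA
synth01	synth01_p00002	89	110	complex	NA
synth01	synth01_p00004	1150	1170	complex	NA
synth01	synth01_p00006	3	29	complex	NA
synth01	synth01_p00007	52	80	complex	NA
synth01	synth01_p00007	132	153	complex	NA
synth01	synth01_p00007	855	881	complex	NA
synth01	synth01_p00009	855	884	complex	NA
synth01	synth01_p00009	81	101	complex	NA
synth01	synth01_p00010	52	76	complex	NA
synth01	synth01_p00010	564	591	complex	NA
synth01	synth01_p00011	408	436	complex	NA
synth01	synth01_p00015	192	221	complex	NA
synth01	synth01_p00017	46	68	complex	NA
synth01	synth01_p00017	100	125	complex	NA
synth01	synth01_p00019	305	328	complex	NA
synth01	synth01_p00019	103	129	complex	NA
synth01	synth01_p00020	620	647	complex	NA
synth01	synth01_p00020	683	710	complex	NA
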