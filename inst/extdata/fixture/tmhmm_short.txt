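synth01_p00001 len=680 ExpAA=0.00 First60=0.00 PredHel=0 Topology=o
synth01_p00002 len=500 ExpAA=0.00 First60=0.00 PredHel=0 Topology=o
synth01_p00003 len=428 ExpAA=0.00 First60=0.00 PredHel=0 Topology=o
synth01_p00004 len=1680 ExpAA=0.00 First60=0.00 PredHel=0 Topology=o
synth01_p00005 len=718 ExpAA=0.00 First60=0.00 PredHel=0 Topology=o
synth01_p00006 len=448 ExpAA=0.00 First60=0.00 PredHel=0 Topology=o
synth01_p00007 len=1039 ExpAA=0.00 First60=0.00 PredHel=0 Topology=o
synth01_p00008 len=536 ExpAA=143.50 First60=0.00 PredHel=7 Topology=o
synth01_p00009 len=1111 ExpAA=0.00 First60=0.00 PredHel=0 Topology=o
synth01_p00010 len=604 ExpAA=0.00 First60=0.00 PredHel=0 Topology=o
synth01_p00011 len=489 ExpAA=0.00 First60=0.00 PredHel=0 Topology=o
synth01_p00012 len=551 ExpAA=0.00 First60=0.00 PredHel=0 Topology=o
synth01_p00013 len=295 ExpAA=0.00 First60=0.00 PredHel=0 Topology=o
synth01_p00014 len=137 ExpAA=0.00 First60=0.00 PredHel=0 Topology=o
synth01_p00015 len=228 ExpAA=0.00 First60=0.00 PredHel=0 Topology=o
synth01_p00016 len=276 ExpAA=0.00 First60=0.00 PredHel=0 Topology=o
synth01_p00017 len=153 ExpAA=0.00 First60=0.00 PredHel=0 Topology=o
synth01_p00018 len=303 ExpAA=0.00 First60=0.00 PredHel=0 Topology=o
synth01_p00019 len=364 ExpAA=0.00 First60=0.00 PredHel=0 Topology=o
synth01_p00020 len=712 ExpAA=0.00 First60=0.00 PredHel=0 Topology=o
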