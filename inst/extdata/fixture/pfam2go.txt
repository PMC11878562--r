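!version date: synthetic
Pfam:PF90001 SynDom > GO:synthetic term ; GO:7000025
Pfam:PF90002 SynDom > GO:synthetic term ; GO:7000017
Pfam:PF90002 SynDom > GO:synthetic term ; GO:7000023
Pfam:PF90003 SynDom > GO:synthetic term ; GO:7000003
Pfam:PF90003 SynDom > GO:synthetic term ; GO:7000022
Pfam:PF90004 SynDom > GO:synthetic term ; GO:7000003
Pfam:PF90004 SynDom > GO:synthetic term ; GO:7000009
Pfam:PF90004 SynDom > GO:synthetic term ; GO:7000024
Pfam:PF90005 SynDom > GO:synthetic term ; GO:7000020
Pfam:PF90005 SynDom > GO:synthetic term ; GO:7000021
Pfam:PF90006 SynDom > GO:synthetic term ; GO:7000012
Pfam:PF90006 SynDom > GO:synthetic term ; GO:7000014
Pfam:PF90006 SynDom > GO:synthetic term ; GO:7000017
Pfam:PF90007 SynDom > GO:synthetic term ; GO:7000013
Pfam:PF90008 SynDom > GO:synthetic term ; GO:7000006
Pfam:PF90008 SynDom > GO:synthetic term ; GO:7000016
Pfam:PF90008 SynDom > GO:synthetic term ; GO:7000024
Pfam:PF90009 SynDom > GO:synthetic term ; GO:7000010
Pfam:PF90010 SynDom > GO:synthetic term ; GO:7000011
Pfam:PF90010 SynDom > GO:synthetic term ; GO:7000021
Pfam:PF90011 SynDom > GO:synthetic term ; GO:7000020
Pfam:PF90011 SynDom > GO:synthetic term ; GO:7000021
Pfam:PF90012 SynDom > GO:synthetic term ; GO:7000008
Pfam:PF90012 SynDom > GO:synthetic term ; GO:7000025
Pfam:PF90013 SynDom > GO:synthetic term ; GO:7000007
Pfam:PF90013 SynDom > GO:synthetic term ; GO:7000024
Pfam:PF90014 SynDom > GO:synthetic term ; GO:7000009
Pfam:PF90014 SynDom > GO:synthetic term ; GO:7000010
Pfam:PF90015 SynDom > GO:synthetic term ; GO:7000017
Pfam:PF90016 SynDom > GO:synthetic term ; GO:7000003
Pfam:PF90016 SynDom > GO:synthetic term ; GO:7000009
Pfam:PF90016 SynDom > GO:synthetic term ; GO:7000012
Pfam:PF90017 SynDom > GO:synthetic term ; GO:7000003
Pfam:PF90018 SynDom > GO:synthetic term ; GO:7000002
Pfam:PF90018 SynDom > GO:synthetic term ; GO:7000020
Pfam:PF90019 SynDom > GO:synthetic term ; GO:7000013
Pfam:PF90020 SynDom > GO:synthetic term ; GO:7000014
Pfam:PF90020 SynDom > GO:synthetic term ; GO:7000016
Pfam:PF90021 SynDom > GO:synthetic term ; GO:7000012
Pfam:PF90021 SynDom > GO:synthetic term ; GO:7000025
Pfam:PF90022 SynDom > GO:synthetic term ; GO:7000015
Pfam:PF90022 SynDom > GO:synthetic term ; GO:7000018
Pfam:PF90023 SynDom > GO:synthetic term ; GO:7000012
Pfam:PF90024 SynDom > GO:synthetic term ; GO:7000022
Pfam:PF90024 SynDom > GO:synthetic term ; GO:7000025
Pfam:PF90025 SynDom > GO:synthetic term ; GO:7000009
Pfam:PF90025 SynDom > GO:synthetic term ; GO:7000010
Pfam:PF90026 SynDom > GO:synthetic term ; GO:7000014
Pfam:PF90027 SynDom > GO:synthetic term ; GO:7000018
Pfam:PF90027 SynDom > GO:synthetic term ; GO:7000025
Pfam:PF90028 SynDom > GO:synthetic term ; GO:7000003
Pfam:PF90028 SynDom > GO:synthetic term ; GO:7000005
Pfam:PF90028 SynDom > GO:synthetic term ; GO:7000011
Pfam:PF90029 SynDom > GO:synthetic term ; GO:7000010
Pfam:PF90030 SynDom > GO:synthetic term ; GO:7000007
Pfam:PF90030 SynDom > GO:synthetic term ; GO:7000020
Pfam:PF90031 SynDom > GO:synthetic term ; GO:7000008
Pfam:PF90032 SynDom > GO:synthetic term ; GO:7000004
Pfam:PF90032 SynDom > GO:synthetic term ; GO:7000025
Pfam:PF90033 SynDom > GO:synthetic term ; GO:7000009
Pfam:PF90033 SynDom > GO:synthetic term ; GO:7000012
Pfam:PF90033 SynDom > GO:synthetic term ; GO:7000023
Pfam:PF90034 SynDom > GO:synthetic term ; GO:7000013
Pfam:PF90035 SynDom > GO:synthetic term ; GO:7000005
Pfam:PF90035 SynDom > GO:synthetic term ; GO:7000007
Pfam:PF90036 SynDom > GO:synthetic term ; GO:7000006
Pfam:PF90037 SynDom > GO:synthetic term ; GO:7000022
Pfam:PF90038 SynDom > GO:synthetic term ; GO:7000019
Pfam:PF90039 SynDom > GO:synthetic term ; GO:7000014
Pfam:PF90039 SynDom > GO:synthetic term ; GO:7000023
Pfam:PF90040 SynDom > GO:synthetic term ; GO:7000003
Pfam:PF90040 SynDom > GO:synthetic term ; GO:7000012
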