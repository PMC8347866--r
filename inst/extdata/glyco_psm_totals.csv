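site,donor,dataset,n_glyco
T207,1,proteome,813
T214,1,proteome,1082
T207,1,peptidome,619
T214,1,peptidome,852
T207,2,proteome,465
T214,2,proteome,709
T207,2,peptidome,546
T214,2,peptidome,723
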