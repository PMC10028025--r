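cytology,machine,clinical,n
benign,negative,benign,26
benign,negative,malignant,5
benign,positive,benign,2
benign,positive,malignant,1
atypical,negative,benign,1
atypical,negative,malignant,4
atypical,positive,benign,0
atypical,positive,malignant,10
malignant,negative,benign,0
malignant,negative,malignant,3
malignant,positive,benign,0
malignant,positive,malignant,14
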