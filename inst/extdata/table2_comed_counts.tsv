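drug	event_without	n_without	event_with	n_with
EPIRUBICIN	1512	27859	8	429
ERLOTINIB	1486	27390	34	898
OMEPRAZOLE	1502	27692	18	596
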