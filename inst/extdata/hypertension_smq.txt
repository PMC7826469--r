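# Stand-in term list for the hypertension standardized MedDRA query
# (SMQ 20000147). MedDRA is licensed, so the exact published 10-term
# list cannot ship; override with your own list for production use.
HYPERTENSION
BLOOD PRESSURE INCREASED
HYPERTENSIVE CRISIS
HYPERTENSIVE EMERGENCY
HYPERTENSIVE ENCEPHALOPATHY
BLOOD PRESSURE SYSTOLIC INCREASED
BLOOD PRESSURE DIASTOLIC INCREASED
LABILE HYPERTENSION
ESSENTIAL HYPERTENSION
ACCELERATED HYPERTENSION
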