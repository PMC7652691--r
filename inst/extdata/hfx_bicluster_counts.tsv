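bicluster	single_comorbidity	multi_comorbidity
CHF	536	536
Arrhythmia	545	236
Stroke	37	233
MCMCT	337	518
COPD	510	726
Vascular disease	114	412
Renal failure and diabetes	1062	348
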