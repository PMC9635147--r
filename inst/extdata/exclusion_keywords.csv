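keyword,applies_to,reason
DELETE,DOSE_TEXT,DELETED
SPRAY,FORMULATION,FORMULATION_EXCLUDED
DROP,FORMULATION,FORMULATION_EXCLUDED
NASAL,FORMULATION,FORMULATION_EXCLUDED
NOSE,DOSE_TEXT,NON_ASTHMA_INDICATION
NOSTRIL,DOSE_TEXT,NON_ASTHMA_INDICATION
NASAL,DOSE_TEXT,NON_ASTHMA_INDICATION
NASAL,MEDICATION_NAME,NON_ASTHMA_INDICATION
HAYFEVER,DOSE_TEXT,NON_ASTHMA_INDICATION
RHINITIS,DOSE_TEXT,NON_ASTHMA_INDICATION
SINUS,DOSE_TEXT,NON_ASTHMA_INDICATION
CROHN,DOSE_TEXT,NON_ASTHMA_INDICATION
COLITIS,DOSE_TEXT,NON_ASTHMA_INDICATION
ECZEMA,DOSE_TEXT,NON_ASTHMA_INDICATION
NASOBEC,BRAND,NON_ASTHMA_BRAND
BECONASE,BRAND,NON_ASTHMA_BRAND
FLIXONASE,BRAND,NON_ASTHMA_BRAND
RHINOCORT,BRAND,NON_ASTHMA_BRAND
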