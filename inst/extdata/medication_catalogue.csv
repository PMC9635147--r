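generic_name,class,brand_names,inhaler_type,licensed_strengths_mcg,band_low,band_medium,band_high
BECLOMETASONE,ICS,CLENIL,MDI,50;100;200;250,400,800,2000
AEROBEC,ICS,AEROBEC,MDI,50;100,400,800,2000
BECLAZONE,ICS,BECLAZONE,MDI,50;100;250,400,800,2000
FILAIR,ICS,FILAIR,MDI,50;100,400,800,2000
BUDESONIDE,ICS,PULMICORT,DPI,100;200;400;500,400,800,1600
FLUTICASONE,ICS,FLIXOTIDE,MDI,50;125;250;500,200,500,1000
CICLESONIDE,ICS,ALVESCO,MDI,80;160,,320,640
MOMETASONE,ICS,ASMANEX,DPI,200;400,400,,800
SERETIDE,ICS_LABA,SERETIDE,MDI,50;125;250;500,200,500,1000
SYMBICORT,ICS_LABA,SYMBICORT,DPI,100;200;400,400,800,1600
FOSTAIR,ICS_LABA,FOSTAIR,MDI,100;200,200,400,800
SALMETEROL,LABA,SEREVENT,MDI,25;50,,,
FORMOTEROL,LABA,OXIS;FORADIL;ATIMOS,DPI,6;12,,,
SALBUTAMOL,SABA,VENTOLIN;AIROMIR;SALAMOL,MDI,100;200,,,
TERBUTALINE,SABA,BRICANYL,DPI,500,,,
MONTELUKAST,LTRA,SINGULAIR,NA,4000;5000;10000,,,
THEOPHYLLINE,THEOPHYLLINE,UNIPHYLLIN;NUELIN,NA,,,,
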