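# Drug and diagnosis code lists used by the pipeline.
#
# The ATC -> drug-class map and the GINA dose bands below are implementer-chosen
# defaults (adult maintenance bands in ug/day); the chronic comedication and
# comorbidity lists are likewise defaults, editable for a given extract.
atc_classes:
  SABA: [R03AC02, R03AC03]
  LABA: [R03AC12, R03AC13]
  ICS: [R03BA]
  ICS_LABA: [R03AK06, R03AK07, R03AK08, R03AK10, R03AK11]
  LAMA: [R03BB]
  OCS: [H02AB06, H02AB07]
  OTHER_R03: [R03]
# chronic comedication, distinct ATC level-5 codes (asthma medication excluded)
comedication_atc:
  - A02BC01   # omeprazole
  - A02BC02   # pantoprazole
  - A10BA02   # metformin
  - A10AB05   # insulin aspart
  - B01AC06   # acetylsalicylic acid, low dose
  - C03CA01   # furosemide
  - C07AB02   # metoprolol
  - C08CA01   # amlodipine
  - C09AA02   # enalapril
  - C09CA03   # valsartan
  - C10AA01   # simvastatin
  - C10AA05   # atorvastatin
  - H03AA01   # levothyroxine
  - N02AA05   # oxycodone
  - N05BA04   # oxazepam
  - N06AB06   # sertraline
  - R06AE07   # cetirizine
  - M01AE01   # ibuprofen (chronic use)
# chronic comorbidity ICPC-1 codes (asthma R96 and COPD R95 excluded)
comorbidity_icpc:
  - T90   # diabetes mellitus
  - K86   # uncomplicated hypertension
  - K74   # ischaemic heart disease with angina
  - K77   # heart failure
  - K90   # stroke/CVA
  - T93   # lipid metabolism disorder
  - P76   # depressive disorder
  - L88   # rheumatoid arthritis
  - L90   # knee osteoarthrosis
  - T86   # hypothyroidism
  - N86   # multiple sclerosis
  - D94   # chronic enteritis / ulcerative colitis
gina:
  # daily-dose boundaries in ug/day: <= low_max is low dose, <= medium_max is
  # medium, above is high
  dose_bands:
    R03BA01: {low_max: 500, medium_max: 1000}   # beclometasone
    R03BA02: {low_max: 400, medium_max: 800}    # budesonide
    R03BA05: {low_max: 250, medium_max: 500}    # fluticasone propionate
    R03BA08: {low_max: 160, medium_max: 320}    # ciclesonide
    R03AK06: {low_max: 250, medium_max: 500}    # salmeterol/fluticasone
    R03AK07: {low_max: 400, medium_max: 800}    # formoterol/budesonide
    R03AK08: {low_max: 200, medium_max: 400}    # formoterol/beclometasone
    R03AK10: {low_max: 100, medium_max: 200}    # vilanterol/fluticasone furoate
    R03AK11: {low_max: 250, medium_max: 500}    # formoterol/fluticasone
  # ATC prefixes that mark add-on (step 5) treatment
  addon_atc: [R03BB, R03DX05]
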