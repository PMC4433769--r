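instrument,full_name,scale_range,lower_is_better
LSAS,Liebowitz Social Anxiety Scale,144,TRUE
CGI-S,Clinical Global Impression - Severity,7,TRUE
BSPS,Brief Social Phobia Scale,72,TRUE
FNE,Fear of Negative Evaluation,30,TRUE
FQ-SP,Fear Questionnaire - Social Phobia,40,TRUE
SADS,Social Avoidance and Distress Scale,28,TRUE
SPAI-SP,Social Phobia and Anxiety Inventory - Social Phobia,192,TRUE
SDS,Sheehan Disability Scale,30,TRUE
SPIN,Social Phobia Inventory,68,TRUE
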