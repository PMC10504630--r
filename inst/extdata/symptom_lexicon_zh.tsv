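concept_id	surface_term	kind	notes
menorrhagia	月经量多	term	heavy menstrual bleeding
menorrhagia	经量多	term
menorrhagia	经量增多	term
menorrhagia	月经特别多	term
dysmenorrhea	痛经	term	menstrual pain
dysmenorrhea	经期疼痛	term
prolonged_menstrual_period	经期延长	term	period lasting longer than usual
prolonged_menstrual_period	经期变长	term
prolonged_menstrual_period	月经拖得久	term
menstrual_blood_clots	血块	term	clots in menstrual flow
menstrual_blood_clots	血块多	term
dizziness	头晕	term
dizziness	头昏	term
dizziness	眩晕	term
fatigue	乏力	term
fatigue	疲乏	term
fatigue	没力气	term
fatigue	浑身没劲	term
lower_abdominal_pain	下腹痛	term
lower_abdominal_pain	下腹疼痛	term
lower_abdominal_pain	小腹痛	term
lower_abdominal_pain	小腹胀痛	term
lower_abdominal_pain	肚子痛	term
menstrual_disorder	月经不调	term	irregular menstruation
menstrual_disorder	月经紊乱	term
menstrual_disorder	月经推迟	term
menstrual_disorder	月经提前	term
vaginal_secretion	分泌物增多	term	increased secretion
vaginal_secretion	分泌物多	term
vaginal_secretion	白带增多	term
vaginal_secretion	白带多	term
vaginal_secretion	水样分泌物	term	watery secretion
vaginal_secretion	血性分泌物	term	bloody secretion
vaginal_secretion	排出分泌物	term	excreted secretion
intensified_dysmenorrhea	经痛加重	term	dysmenorrhea worse than before
intensified_dysmenorrhea	经痛加剧	term
intensified_dysmenorrhea	经痛比以前厉害	term
frequent_urination	尿频	term
frequent_urination	小便次数多	term
frequent_urination	老是想小便	term
	没有	negation_cue
	没再	negation_cue
	没	negation_cue
	未见	negation_cue
	未	negation_cue
	无	negation_cue
	不再	negation_cue
	不	negation_cue
	从不	negation_cue
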