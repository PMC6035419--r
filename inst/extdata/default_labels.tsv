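subject_category	object_category	relation_surface	label
Location	Body Part	of	Situated_at
Location	Body Part		Modifies
Observation	Body Part	of	Occurs_in
Observation	Body Part	in	Occurs_in
Pathology	Body Part	of	Occurs_in
Pathology	Body Part	with	Modifies
Medical Activity	Body Part	in	Acts_on
Medical Activity	Body Part	of	Acts_on
Observation	Pathology	as	Indicative_of
Observation	Pathology	of	Indicative_of
Functional Concept	Pathology	of	Describes
Functional Concept	Pathology		Related_to
Pathology	Pathology	are	Be
Pathology	Pathology	include	Has
Medical Activity	Pathology	confirmed	Shows
Medical Activity	Pathology	for	Acts_on
Medical Activity	Observation	performed for	Deals_with
Medical Activity	Observation	of	Acts_on
Observation	Observation	with	Shows
Observation	Observation	of	Shows
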