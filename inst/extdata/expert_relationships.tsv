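# Expert-chosen relationship pairs retained in the knowledge model
# regardless of co-occurrence weight. One documented default; add more
# rows as subject_category<TAB>object_category.
subject_category	object_category
Substance	Observation
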